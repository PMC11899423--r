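#' Scatter matrices
#'
#' Within-class scatter `S_W` (sum over classes of outer products of
#' class-centred samples), between-class scatter `S_B`, and total scatter
#' `S_T = S_W + S_B`. These `d x d` matrices are provided as documented
#' utilities; the CLDA fit itself never forms them (it works through the
#' `M x M` Gram matrix), and `S_T` is unused by CLDA -- it is exposed for
#' completeness and for the PCA + LDA baseline.
#'
#' @param ds a [spectral_dataset()].
#' @return A `d x d` symmetric matrix.
#' @export
scatter_within <- function(ds) {
  A <- centered_sample_matrix(ds)
  A %*% t(A)
}

#' @rdname scatter_within
#' @export
scatter_between <- function(ds) {
  mu <- colMeans(ds$absorbance)
  lev <- class_levels(ds)
  S <- matrix(0, n_channels(ds), n_channels(ds))
  for (cl in lev) {
    idx <- ds$labels == cl
    diff <- colMeans(ds$absorbance[idx, , drop = FALSE]) - mu
    S <- S + sum(idx) * tcrossprod(diff)
  }
  S
}

#' @rdname scatter_within
#' @export
scatter_total <- function(ds) {
  X <- sweep(ds$absorbance, 2, colMeans(ds$absorbance))
  crossprod(X)
}

# d x M matrix A whose columns are the within-class centred samples
# x_m^i - mu_i; S_W = A %*% t(A).
centered_sample_matrix <- function(ds) {
  lev <- class_levels(ds)
  X <- ds$absorbance
  for (cl in lev) {
    idx <- ds$labels == cl
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                      colMeans(X[idx, , drop = FALSE]))
  }
  t(X)
}

# Orthonormal basis of the column span of a d x m matrix via the m x m
# Gram matrix -- never forms the d x d scatter. Returns Q (d x r),
# eigenvalues (r), rank r. Rank tolerance: eigenvalues of the Gram
# matrix below m * eps * lambda_max count as zero; `max_rank` enforces
# a structural cap known a priori (M - C for S_W, C - 1 for S_com),
# guarding against round-off eigenvalues that straddle the tolerance.
gram_range_basis <- function(A, max_rank = Inf) {
  m <- ncol(A)
  if (m == 0) {
    return(list(Q = matrix(0, nrow(A), 0), eigenvalues = numeric(0),
                r = 0L))
  }
  G <- crossprod(A)
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  tol <- m * .Machine$double.eps * max(lam, 0)
  keep <- which(lam > tol & lam > 0)
  if (length(keep) > max_rank) keep <- keep[seq_len(max_rank)]
  r <- length(keep)
  if (r == 0) {
    return(list(Q = matrix(0, nrow(A), 0), eigenvalues = numeric(0),
                r = 0L))
  }
  Q <- A %*% eg$vectors[, keep, drop = FALSE]
  Q <- sweep(Q, 2, sqrt(lam[keep]), "/")
  list(Q = Q, eigenvalues = lam[keep], r = r)
}

#' Orthonormal basis of the range of the within-class scatter
#'
#' Computes the nonzero eigen-structure of `S_W` from the `M x M` Gram
#' matrix of within-class centred samples (never from the `d x d`
#' scatter), which is what makes CLDA tractable in the small-sample
#' regime `d > M - C`. The orthogonal complement of `span(Q)` is the null
#' space of `S_W`, where the common vectors live.
#'
#' @param train a [spectral_dataset()] of training spectra.
#' @return An object of class `scatter_basis`: list with `Q`
#'   (`d x r`, orthonormal columns), `eigenvalues` (nonzero eigenvalues
#'   of `S_W`), `r` (numerical rank of `S_W`).
#' @export
scatter_basis <- function(train) {
  d <- n_channels(train)
  M <- n_samples(train)
  C <- length(class_levels(train))
  if (d <= M - C) {
    stop("regime error: d = ", d, " <= M - C = ", M - C,
         "; the null space of S_W is trivial. Reduce the sample count, ",
         "increase the channel count, or use the PCA + LDA baseline.",
         call. = FALSE)
  }
  b <- gram_range_basis(centered_sample_matrix(train), max_rank = M - C)
  structure(b, class = "scatter_basis")
}

#' @export
print.scatter_basis <- function(x, ...) {
  cat("<scatter_basis> rank ", x$r, ", d = ", nrow(x$Q), "\n", sep = "")
  invisible(x)
}

#' Common vector of a sample
#'
#' Projects a sample onto the null space of the within-class scatter:
#' `x_com = x - Q Q' x`. Within a class this is the same vector for every
#' sample (the class's common vector), because class-mates differ only by
#' directions inside `range(S_W)`.
#'
#' @param x numeric vector of length `d`, or an `n x d` matrix of rows.
#' @param basis a [scatter_basis()].
#' @return A vector (or matrix) of the same shape, orthogonal to every
#'   column of `Q`.
#' @export
common_vector <- function(x, basis) {
  if (is.matrix(x)) {
    if (ncol(x) != nrow(basis$Q) && basis$r > 0) {
      stop("shape error: x has ", ncol(x), " columns, basis has ",
           nrow(basis$Q), " rows.", call. = FALSE)
    }
    if (basis$r == 0) return(x)
    return(x - (x %*% basis$Q) %*% t(basis$Q))
  }
  if (basis$r == 0) return(x)
  if (length(x) != nrow(basis$Q)) {
    stop("shape error: x has length ", length(x), ", basis has ",
         nrow(basis$Q), " rows.", call. = FALSE)
  }
  as.vector(x - basis$Q %*% crossprod(basis$Q, x))
}

#' Fit common-vectors linear discriminant analysis
#'
#' CLDA for the small-sample-size regime (`d > M - C`, where classical
#' LDA is undefined because `S_W` is singular). The fit:
#'
#' 1. computes an orthonormal basis `Q` of `range(S_W)` through the
#'    `M x M` Gram matrix ([scatter_basis()]);
#' 2. projects one representative sample per class (the first, by sample
#'    order -- any choice gives the same result, a property the test
#'    suite asserts) onto `null(S_W)` to obtain the per-class common
#'    vectors `x_com`;
#' 3. eigendecomposes the scatter of the centred common vectors through
#'    its `C x C` Gram matrix and retains the eigenvectors with nonzero
#'    eigenvalue as the projection matrix `W` (`d x (C-1)` columns when
#'    the common vectors are affinely independent). Each column's sign is
#'    fixed so its largest-magnitude entry is positive.
#'
#' The rows of `omegas` (`W' x_com`, one per class) are the
#' discriminative common vectors: every training sample of a class
#' projects exactly onto its class's row, so the training classes
#' collapse to `C` distinct points in the `(C-1)`-dimensional subspace.
#'
#' @param train a [spectral_dataset()] with `C >= 2` classes.
#' @param tol_degenerate two classes whose common vectors are closer than
#'   `tol_degenerate * max(norm(x_com))` are reported as indistinguishable.
#' @return An object of class `clda`: list with `basis`
#'   ([scatter_basis()]), `common_vectors` (`C x d`), `mu_com`, `W`
#'   (`d x (C-1)`), `omegas` (`C x (C-1)`), `class_order`, `d`.
#' @examples
#' ds <- generate_spectra(synthetic_spec(seed = 1))
#' sp <- stratified_split(ds, c(2, 1), seed = 1)
#' fit <- clda(sp$train)
#' fit
#' mean(predict(fit, sp$test) == sp$test$labels)
#' @export
clda <- function(train, tol_degenerate = 1e-8) {
  lev <- class_levels(train)
  C <- length(lev)
  if (C < 2) stop("CLDA needs at least 2 classes.", call. = FALSE)
  basis <- scatter_basis(train)
  d <- n_channels(train)

  reps <- t(vapply(lev, function(cl) {
    train$absorbance[which(train$labels == cl)[1], ]
  }, numeric(d)))
  xcom <- common_vector(reps, basis)          # C x d
  rownames(xcom) <- lev

  norms <- sqrt(rowSums(xcom^2))
  D <- as.matrix(stats::dist(xcom))
  thr <- tol_degenerate * max(norms)
  close <- which(D < thr & upper.tri(D), arr.ind = TRUE)
  if (nrow(close)) {
    stop("degenerate-classes error: common vectors of classes ",
         lev[close[1, 1]], " and ", lev[close[1, 2]],
         " coincide (distance below tolerance); the classes are not ",
         "separable in the null space of S_W.", call. = FALSE)
  }

  mu_com <- colMeans(xcom)
  Acom <- t(sweep(xcom, 2, mu_com))           # d x C
  bs <- gram_range_basis(Acom, max_rank = C - 1)
  W <- bs$Q                                    # d x (<= C-1)
  # sign convention: largest-magnitude entry of each column positive
  if (ncol(W) > 0) {
    signs <- apply(W, 2, function(col) sign(col[which.max(abs(col))]))
    W <- sweep(W, 2, signs, "*")
  }
  omegas <- xcom %*% W                         # C x (C-1)
  rownames(omegas) <- lev

  structure(
    list(basis = basis, common_vectors = xcom, mu_com = mu_com, W = W,
         omegas = omegas, class_order = lev, d = d),
    class = "clda"
  )
}

#' @export
print.clda <- function(x, ...) {
  cat("<clda> ", length(x$class_order), " classes, d = ", x$d,
      ", W: ", x$d, " x ", ncol(x$W), ", rank(S_W) = ", x$basis$r,
      "\n", sep = "")
  invisible(x)
}

#' Project spectra into the CLDA discriminant subspace
#'
#' @param model a fitted [clda()] model.
#' @param ds a [spectral_dataset()] (or bare matrix) with matching `d`.
#' @return An `n x (C-1)` matrix of discriminant coordinates.
#' @export
project_clda <- function(model, ds) {
  X <- if (inherits(ds, "spectral_dataset")) ds$absorbance else as.matrix(ds)
  if (ncol(X) != model$d) {
    stop("shape error: data have ", ncol(X), " channels, model expects ",
         model$d, ".", call. = FALSE)
  }
  X %*% model$W
}

#' Classify spectra by nearest discriminative common vector
#'
#' Each sample is projected by `W` and assigned the class whose
#' discriminative common vector (row of `omegas`) is nearest in Euclidean
#' distance; exact ties go to the lowest class index.
#'
#' @param object a fitted [clda()] model.
#' @param newdata a [spectral_dataset()] or matrix.
#' @param type `"class"` (default) for labels, `"projection"` for the
#'   discriminant coordinates.
#' @param ... unused.
#' @return A character vector of labels, or a projection matrix.
#' @export
predict.clda <- function(object, newdata,
                         type = c("class", "projection"), ...) {
  type <- match.arg(type)
  P <- project_clda(object, newdata)
  if (type == "projection") return(P)
  nearest_row_label(P, object$omegas, object$class_order)
}

# argmin over template rows of Euclidean distance; ties -> lowest index.
nearest_row_label <- function(P, templates, class_order) {
  d2 <- outer(rowSums(P^2), rowSums(templates^2), "+") -
    2 * P %*% t(templates)
  idx <- apply(d2, 1, function(row) which(row <= min(row) + 1e-12)[1])
  class_order[idx]
}

#' @export
tidy.clda <- function(x, ...) {
  om <- x$omegas
  colnames(om) <- paste0("dcv", seq_len(ncol(om)))
  dplyr::bind_cols(tibble::tibble(class = x$class_order),
                   tibble::as_tibble(om))
}

#' @export
glance.clda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_order),
    d = x$d,
    rank_sw = x$basis$r,
    n_discriminants = ncol(x$W),
    min_omega_separation = min(stats::dist(x$omegas))
  )
}
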