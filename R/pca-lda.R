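#' Fit the PCA + Fisher LDA baseline
#'
#' The classical two-stage answer to the small-sample-size problem:
#' compress the spectra by PCA until the within-class scatter is
#' invertible, then extract at most `C - 1` Fisher discriminant
#' directions by solving the generalized eigenproblem
#' `S_B w = lambda S_W w` in the PCA score space.
#'
#' @param train a [spectral_dataset()].
#' @param k number of principal components, or `"auto"` (default): the
#'   smallest `k` explaining at least 99% of training variance, capped at
#'   `M - C` so the within-class scatter stays nonsingular.
#' @param ridge if the within-class scatter in PCA space is numerically
#'   singular it is stabilised by adding `ridge * trace/k` to its
#'   diagonal.
#' @return An object of class `pca_lda`: list with `pca_mean`,
#'   `pca_components` (`d x k`, orthonormal), `lda_directions`
#'   (`k x (C-1)`), `class_centroids_projected` (`C x (C-1)`),
#'   `class_order`, `k`, `d`.
#' @examples
#' ds <- generate_spectra(synthetic_spec(seed = 1))
#' sp <- stratified_split(ds, c(2, 1), seed = 1)
#' fit <- fit_pca_lda(sp$train)
#' mean(predict(fit, sp$test) == sp$test$labels)
#' @export
fit_pca_lda <- function(train, k = "auto", ridge = 1e-10) {
  lev <- class_levels(train)
  C <- length(lev)
  M <- n_samples(train)
  d <- n_channels(train)
  if (C < 2) stop("need at least 2 classes.", call. = FALSE)

  pca_mean <- colMeans(train$absorbance)
  Xc <- sweep(train$absorbance, 2, pca_mean)
  pc <- stats::prcomp(Xc, center = FALSE)
  max_k <- min(d, M - 1)
  if (identical(k, "auto")) {
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- min(which(cumvar >= 0.99), max(M - C, 1L))
  }
  k <- as.integer(k)
  if (k < 1 || k > max_k) {
    stop("k = ", k, " out of range [1, ", max_k, "].", call. = FALSE)
  }
  V <- pc$rotation[, seq_len(k), drop = FALSE]   # d x k
  scores <- Xc %*% V                             # M x k

  sds <- spectral_dataset(scores, seq_len(k), train$labels,
                          train$sample_ids, "pc")
  Sw <- scatter_within(sds)
  Sb <- scatter_between(sds)
  # generalized eigenproblem S_B w = lambda S_W w via solve(S_W) S_B
  if (rcond_sym(Sw) < 1e-12) {
    Sw <- Sw + diag(ridge * sum(diag(Sw)) / k, k)
    if (rcond_sym(Sw) < 1e-14) {
      stop("singular within-class scatter in PCA space; choose a ",
           "smaller k.", call. = FALSE)
    }
  }
  eg <- eigen(solve(Sw, Sb))
  n_dir <- min(C - 1, sum(Re(eg$values) > 1e-10 * max(Re(eg$values))))
  L <- Re(eg$vectors[, seq_len(n_dir), drop = FALSE])  # k x (C-1)
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  signs <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2, signs, "*")

  proj <- scores %*% L
  centroids <- do.call(rbind, lapply(lev, function(cl) {
    colMeans(proj[train$labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- lev

  structure(
    list(pca_mean = pca_mean, pca_components = V, lda_directions = L,
         class_centroids_projected = centroids, class_order = lev,
         k = k, d = d),
    class = "pca_lda"
  )
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @export
print.pca_lda <- function(x, ...) {
  cat("<pca_lda> ", length(x$class_order), " classes, d = ", x$d,
      ", k = ", x$k, " PCs, ", ncol(x$lda_directions),
      " discriminant direction(s)\n", sep = "")
  invisible(x)
}

#' Project spectra through PCA then LDA
#'
#' @param model a fitted [fit_pca_lda()] model.
#' @param ds a [spectral_dataset()] or matrix with matching `d`.
#' @return An `n x (C-1)` matrix of discriminant coordinates.
#' @export
project_pca_lda <- function(model, ds) {
  X <- if (inherits(ds, "spectral_dataset")) ds$absorbance else as.matrix(ds)
  if (ncol(X) != model$d) {
    stop("shape error: data have ", ncol(X), " channels, model expects ",
         model$d, ".", call. = FALSE)
  }
  sweep(X, 2, model$pca_mean) %*% model$pca_components %*%
    model$lda_directions
}

#' Classify spectra with the PCA + LDA baseline
#'
#' Nearest projected class centroid (Euclidean), ties to the lowest
#' class index.
#'
#' @inheritParams predict.clda
#' @param object a fitted [fit_pca_lda()] model.
#' @return A character vector of labels, or a projection matrix.
#' @export
predict.pca_lda <- function(object, newdata,
                            type = c("class", "projection"), ...) {
  type <- match.arg(type)
  P <- project_pca_lda(object, newdata)
  if (type == "projection") return(P)
  nearest_row_label(P, object$class_centroids_projected,
                    object$class_order)
}

#' @export
glance.pca_lda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_order),
    d = x$d,
    k = x$k,
    n_discriminants = ncol(x$lda_directions)
  )
}
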