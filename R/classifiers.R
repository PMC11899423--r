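#' K-nearest-neighbour classification
#'
#' Euclidean-distance majority vote over the `k` nearest training
#' points. Vote ties are broken by the larger summed inverse distance
#' among the tied classes, then by the lowest class index; the tie-break
#' chain is fully deterministic.
#'
#' @param x_train `n_train x p` numeric matrix of training features.
#' @param y_train training labels, length `n_train`.
#' @param x_test `n_test x p` matrix of features to classify.
#' @param k neighbourhood size, `1 <= k <= n_train`; the study's default
#'   back-end uses `k = 7`.
#' @param class_order optional class ordering used for index tie-breaks;
#'   defaults to `sort(unique(y_train))`.
#' @return A character vector of predicted labels.
#' @export
knn_predict <- function(x_train, y_train, x_test, k = 7L,
                        class_order = NULL) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- as.character(y_train)
  n_train <- nrow(x_train)
  if (k < 1 || k > n_train) {
    stop("parameter error: k = ", k, " outside [1, ", n_train, "].",
         call. = FALSE)
  }
  if (is.null(class_order)) class_order <- sort(unique(y_train))
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), "+") -
    2 * tcrossprod(x_test, x_train)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    votes <- table(factor(y_train[nb], levels = class_order))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      inv <- vapply(top, function(cl) {
        sel <- nb[y_train[nb] == cl]
        sum(1 / pmax(sqrt(row[sel]), 1e-300))
      }, numeric(1))
      top <- top[inv >= max(inv) - 1e-12 * max(inv)]
      top <- top[which.min(match(top, class_order))]
    }
    top[1]
  })
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Class priors are the training frequencies; each feature, within each
#' class, is modelled as an independent Gaussian. Per-class variances are
#' floored at `1e-9` times the largest per-class feature variance,
#' because discriminant features can be exactly constant within a class
#' (CLDA training projections are) and a zero variance would make the
#' density degenerate.
#'
#' @param x_train `n x p` numeric feature matrix.
#' @param y_train labels, length `n`; every class needs at least 2
#'   samples so variances are estimable.
#' @param class_order optional class ordering; defaults to sorted labels.
#' @return An object of class `naive_bayes_model`: list with `priors`,
#'   `means` (`C x p`), `vars` (`C x p`, floored), `class_order`.
#' @export
nb_fit <- function(x_train, y_train, class_order = NULL) {
  x_train <- as.matrix(x_train)
  y_train <- as.character(y_train)
  if (is.null(class_order)) class_order <- sort(unique(y_train))
  counts <- table(factor(y_train, levels = class_order))
  if (any(counts < 2)) {
    stop("fit error: class(es) ",
         paste(names(counts)[counts < 2], collapse = ", "),
         " have fewer than 2 samples; variance not estimable.",
         call. = FALSE)
  }
  means <- do.call(rbind, lapply(class_order, function(cl) {
    colMeans(x_train[y_train == cl, , drop = FALSE])
  }))
  vars <- do.call(rbind, lapply(class_order, function(cl) {
    apply(x_train[y_train == cl, , drop = FALSE], 2, stats::var)
  }))
  floor_v <- 1e-9 * max(vars, .Machine$double.xmin)
  if (floor_v <= 0) floor_v <- 1e-30
  vars <- pmax(vars, floor_v)
  rownames(means) <- rownames(vars) <- class_order
  structure(
    list(priors = as.numeric(counts) / length(y_train), means = means,
         vars = vars, class_order = class_order),
    class = "naive_bayes_model"
  )
}

#' Classify with a fitted Gaussian naive Bayes model
#'
#' Computes, in the log domain, `log prior + sum of log Gaussian
#' densities` per class and returns the argmax; ties go to the lowest
#' class index.
#'
#' @param object a [nb_fit()] model.
#' @param newdata `n x p` feature matrix.
#' @param type `"class"` (default) or `"logposterior"` for the
#'   unnormalised per-class log-posterior matrix.
#' @param ... unused.
#' @return A character vector of labels, or an `n x C` numeric matrix.
#' @export
predict.naive_bayes_model <- function(object, newdata,
                                      type = c("class", "logposterior"),
                                      ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$means)) {
    stop("shape error: ", ncol(X), " features, model expects ",
         ncol(object$means), ".", call. = FALSE)
  }
  C <- length(object$class_order)
  lp <- vapply(seq_len(C), function(i) {
    mu <- object$means[i, ]
    v <- object$vars[i, ]
    log(object$priors[i]) -
      0.5 * colSums((t(X) - mu)^2 / v) -
      0.5 * sum(log(2 * pi * v))
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X), ncol = C)
  colnames(lp) <- object$class_order
  if (type == "logposterior") return(lp)
  object$class_order[apply(lp, 1, function(row) {
    which(row >= max(row) - 1e-12 * abs(max(row)))[1]
  })]
}

#' Accuracy and confusion matrix of a prediction
#'
#' @param pred predicted labels.
#' @param truth true labels, same length.
#' @param class_order optional class ordering for the confusion matrix
#'   (rows = truth, columns = predicted); defaults to the sorted union.
#' @return A list of class `classification_eval` with `accuracy`
#'   (correct/total) and `confusion` (`C x C` integer matrix).
#' @export
evaluate_classification <- function(pred, truth, class_order = NULL) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` have different lengths.", call. = FALSE)
  }
  if (length(pred) == 0) {
    stop("empty input: nothing to evaluate.", call. = FALSE)
  }
  if (is.null(class_order)) class_order <- sort(unique(c(pred, truth)))
  unknown <- setdiff(unique(c(pred, truth)), class_order)
  if (length(unknown)) {
    stop("schema error: label(s) ", paste(unknown, collapse = ", "),
         " not in class_order.", call. = FALSE)
  }
  cm <- table(factor(truth, levels = class_order),
              factor(pred, levels = class_order))
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(truth = class_order, pred = class_order))
  structure(
    list(accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
         class_order = class_order),
    class = "classification_eval"
  )
}

#' @export
print.classification_eval <- function(x, ...) {
  cat("<classification_eval> accuracy ", sprintf("%.4f", x$accuracy),
      " (", sum(diag(x$confusion)), "/", sum(x$confusion), ")\n",
      sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.classification_eval <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion),
                          responseName = "n",
                          stringsAsFactors = FALSE))
}

#' @export
glance.classification_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$confusion),
                 n_correct = sum(diag(x$confusion)))
}
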