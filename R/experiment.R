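#' Run one end-to-end classification experiment
#'
#' Pipeline: stratified split -> preprocessing chain (training-derived
#' statistics frozen and reused for the test set) -> feature extraction
#' (CLDA, PCA + LDA, or boosted CLDA) -> back-end classification ->
#' evaluation. Fully deterministic given `(data, arguments)`.
#'
#' Back-ends: `"nearest_common_vector"` uses each extractor's native
#' nearest-template rule (nearest discriminative common vector for CLDA;
#' nearest projected centroid for PCA + LDA; the alpha-weighted weak-
#' hypothesis vote for the boosted model). `"knn"` and `"bayes"` are
#' applied to the extracted features; for the boosted extractor they are
#' fitted per round on that round's projected subset and combined by the
#' alpha-weighted vote.
#'
#' @param data a [spectral_dataset()].
#' @param extractor `"clda"`, `"pca_lda"` or `"adaboost_clda"`.
#' @param classifier `"nearest_common_vector"`, `"knn"` or `"bayes"`.
#' @param preprocess a [preprocess_spec()]; default none (raw spectra).
#' @param knn_k neighbourhood size for the KNN back-end (default 7).
#' @param boost_T boosting rounds for `"adaboost_clda"` (default 10).
#' @param pca_k PCA retention for `"pca_lda"` (default `"auto"`).
#' @param split_ratio train:test ratio (default `c(2, 1)`).
#' @param seed controls the split and all boosting randomness.
#' @return An object of class `experiment_result`: list with `accuracy`,
#'   `confusion`, `model`, `staged` (per-round test accuracies, boosted
#'   extractor only), `config`.
#' @examples
#' ds <- generate_spectra(synthetic_preset("separable", seed = 3))
#' res <- run_experiment(ds, extractor = "clda",
#'                       preprocess = preprocess_spec("SG"))
#' res$accuracy
#' @export
run_experiment <- function(data,
                           extractor = c("clda", "pca_lda",
                                         "adaboost_clda"),
                           classifier = c("nearest_common_vector", "knn",
                                          "bayes"),
                           preprocess = preprocess_spec(),
                           knn_k = 7L, boost_T = 10L, pca_k = "auto",
                           split_ratio = c(2, 1), seed = 1L) {
  extractor <- match.arg(extractor)
  classifier <- match.arg(classifier)
  stage <- "split"
  res <- tryCatch({
    sp <- stratified_split(data, split_ratio, seed)
    stage <- "preprocess"
    pp <- apply_preprocess(sp$train, sp$test, preprocess)
    train <- pp$train; test <- pp$test
    stage <- "feature extraction"
    staged <- NULL
    if (extractor == "adaboost_clda") {
      model <- adaboost_clda(train, T_rounds = boost_T, seed = seed)
      stage <- "classification"
      pred <- boost_backend_predict(model, test, classifier, knn_k)
      staged <- staged_accuracy(model, test, test$labels)
    } else {
      model <- if (extractor == "clda") clda(train)
               else fit_pca_lda(train, k = pca_k)
      stage <- "classification"
      pred <- single_backend_predict(model, train, test, classifier,
                                     knn_k)
    }
    stage <- "evaluation"
    ev <- evaluate_classification(pred, test$labels,
                                  class_levels(data))
    list(model = model, pred = pred, ev = ev, staged = staged)
  }, error = function(e) {
    stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })
  structure(
    list(accuracy = res$ev$accuracy, confusion = res$ev$confusion,
         predictions = res$pred, model = res$model, staged = res$staged,
         config = list(extractor = extractor, classifier = classifier,
                       preprocess = preprocess_label(preprocess),
                       knn_k = knn_k, boost_T = boost_T, pca_k = pca_k,
                       split_ratio = split_ratio, seed = seed)),
    class = "experiment_result"
  )
}

single_backend_predict <- function(model, train, test, classifier,
                                   knn_k) {
  if (classifier == "nearest_common_vector") return(predict(model, test))
  f_train <- predict(model, train, type = "projection")
  f_test <- predict(model, test, type = "projection")
  if (classifier == "knn") {
    knn_predict(f_train, train$labels, f_test, k = knn_k,
                class_order = model$class_order)
  } else {
    predict(nb_fit(f_train, train$labels, model$class_order), f_test)
  }
}

# alpha-weighted vote with a per-round back-end classifier fitted on the
# round's projected bootstrap subset.
boost_backend_predict <- function(model, test, classifier, knn_k) {
  if (classifier == "nearest_common_vector") return(predict(model, test))
  C <- length(model$class_order)
  V <- matrix(0, n_samples(test), C,
              dimnames = list(NULL, model$class_order))
  for (rd in model$rounds) {
    f_test <- project_clda(rd$clda, test)
    h <- if (classifier == "knn") {
      knn_predict(rd$subset_features, rd$subset_labels, f_test,
                  k = min(knn_k, nrow(rd$subset_features)),
                  class_order = model$class_order)
    } else {
      predict(nb_fit(rd$subset_features, rd$subset_labels,
                     model$class_order), f_test)
    }
    pos <- cbind(seq_len(nrow(V)), match(h, model$class_order))
    V[pos] <- V[pos] + rd$alpha
  }
  model$class_order[apply(V, 1, which.max)]
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$config$preprocess, " + ",
      x$config$extractor, " + ", x$config$classifier, "\n", sep = "")
  cat("  accuracy: ", sprintf("%.4f", x$accuracy), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.experiment_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion), responseName = "n",
                          stringsAsFactors = FALSE))
}

#' @export
glance.experiment_result <- function(x, ...) {
  tibble::tibble(
    preprocess = x$config$preprocess,
    extractor = x$config$extractor,
    classifier = x$config$classifier,
    accuracy = x$accuracy,
    seed = x$config$seed,
    T_effective = if (inherits(x$model, "adaboost_clda"))
      x$model$T_effective else NA_integer_
  )
}

#' Run the preprocessing-by-extractor accuracy grid
#'
#' One experiment per (preprocessing chain, extractor) cell with a fixed
#' back-end classifier -- the benchmark layout used to compare feature
#' extractors across preprocessing choices. Failed cells are recorded
#' (accuracy `NA`, message in `error`) and the grid continues.
#'
#' @param data a [spectral_dataset()].
#' @param preprocess_grid named list of [preprocess_spec()]s; default is
#'   the six standard chains MSC, SNV, SG, MSC + SG, SNV + SG,
#'   MSC + SNV.
#' @param extractors character vector of extractors.
#' @param classifier back-end applied in every cell.
#' @inheritParams run_experiment
#' @return A tibble with columns `preprocess`, `extractor`, `accuracy`,
#'   `error`.
#' @export
run_grid <- function(data,
                     preprocess_grid = standard_preprocess_grid(),
                     extractors = c("pca_lda", "clda", "adaboost_clda"),
                     classifier = "knn",
                     knn_k = 7L, boost_T = 10L, pca_k = "auto",
                     split_ratio = c(2, 1), seed = 1L) {
  stopifnot(length(preprocess_grid) > 0, length(extractors) > 0)
  if (is.null(names(preprocess_grid))) {
    names(preprocess_grid) <- vapply(preprocess_grid, preprocess_label,
                                     "")
  }
  cells <- tidyr::expand_grid(preprocess = names(preprocess_grid),
                              extractor = extractors)
  out <- purrr::pmap(cells, function(preprocess, extractor) {
    res <- tryCatch(
      run_experiment(data, extractor = extractor,
                     classifier = classifier,
                     preprocess = preprocess_grid[[preprocess]],
                     knn_k = knn_k, boost_T = boost_T, pca_k = pca_k,
                     split_ratio = split_ratio, seed = seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(accuracy = NA_real_,
                     error = conditionMessage(res))
    } else {
      tibble::tibble(accuracy = res$accuracy, error = NA_character_)
    }
  })
  dplyr::bind_cols(cells, dplyr::bind_rows(out))
}

#' The six standard preprocessing chains
#'
#' MSC, SNV, SG, MSC + SG, SNV + SG and MSC + SNV, with the package's
#' default SG parameters (window 11, order 2, smoothing).
#'
#' @return A named list of [preprocess_spec()]s.
#' @export
standard_preprocess_grid <- function() {
  list("MSC" = preprocess_spec("MSC"),
       "SNV" = preprocess_spec("SNV"),
       "SG" = preprocess_spec("SG"),
       "MSC + SG" = preprocess_spec("MSC", "SG"),
       "SNV + SG" = preprocess_spec("SNV", "SG"),
       "MSC + SNV" = preprocess_spec("MSC", "SNV"))
}

#' Accuracy as a function of the KNN neighbourhood size
#'
#' Sweeps K for each extractor with the KNN back-end, the usual
#' sensitivity analysis for choosing K.
#'
#' @param data a [spectral_dataset()].
#' @param k_values integer vector of K values (default 1..15).
#' @param extractors extractors to sweep.
#' @inheritParams run_experiment
#' @return A tibble with columns `k`, `extractor`, `accuracy`.
#' @export
knn_k_sweep <- function(data, k_values = 1:15,
                        extractors = c("pca_lda", "clda",
                                       "adaboost_clda"),
                        preprocess = preprocess_spec("SG"),
                        boost_T = 10L, pca_k = "auto",
                        split_ratio = c(2, 1), seed = 1L) {
  cells <- tidyr::expand_grid(k = as.integer(k_values),
                              extractor = extractors)
  acc <- purrr::pmap_dbl(cells, function(k, extractor) {
    run_experiment(data, extractor = extractor, classifier = "knn",
                   preprocess = preprocess, knn_k = k, boost_T = boost_T,
                   pca_k = pca_k, split_ratio = split_ratio,
                   seed = seed)$accuracy
  })
  dplyr::mutate(cells, accuracy = acc)
}

#' Plot a K-sweep or grid result
#'
#' @param result tibble from [knn_k_sweep()] or [run_grid()].
#' @return A ggplot object.
#' @export
plot_k_sweep <- function(result) {
  ggplot2::ggplot(result, ggplot2::aes(.data$k, .data$accuracy,
                                       colour = .data$extractor)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "K (nearest neighbours)", y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname plot_k_sweep
#' @export
plot_grid_accuracy <- function(result) {
  ggplot2::ggplot(result, ggplot2::aes(.data$preprocess, .data$accuracy,
                                       fill = .data$extractor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "preprocessing", y = "test accuracy") +
    ggplot2::theme_minimal()
}
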