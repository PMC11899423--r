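#' Fit an AdaBoost.M1 ensemble of CLDA subspaces
#'
#' Boosted common-vectors LDA. Each round:
#'
#' 1. the sample weights are normalised to a distribution `P_t`;
#' 2. a training subset of size `n` is drawn by weighted bootstrap
#'    resampling from `P_t` (CLDA has no per-sample-weight formulation,
#'    so reweighting is realised by resampling; this also keeps the weak
#'    learner genuinely weak -- CLDA fitted on the full set would be
#'    exact on every training sample);
#' 3. CLDA is fitted on the subset, giving a `(C-1)`-dimensional
#'    discriminant subspace;
#' 4. the weak hypothesis `h_t` is the nearest-neighbour rule over the
#'    subset's projected points (equivalently, nearest discriminative
#'    common vector, since subset samples project exactly onto their
#'    class template);
#' 5. the weighted error `e_t = sum P_t(i) [y_i != h_t(x_i)]` is
#'    evaluated over *all* `n` training samples;
#' 6. the loop stops when `e_t = 0` (the perfect round is retained with
#'    its vote weight capped at the value a single weighted error of
#'    `1/(2n)` would give) or `e_t >= 1/2` (the round is discarded);
#'    otherwise the round gets vote weight
#'    `alpha_t = 0.5 * log((1 - e_t) / e_t)` and the weights of
#'    misclassified samples are multiplied by `exp(alpha_t)`, correct
#'    ones by `exp(-alpha_t)` (after the next normalisation the
#'    misclassified samples carry exactly half the total weight).
#'
#' The final classifier is the `alpha`-weighted vote over the retained
#' weak hypotheses.
#'
#' A drawn subset must contain every class; invalid draws are redrawn up
#' to `redraw_budget` times, after which each missing class's
#' highest-weight sample is added.
#'
#' @param train a [spectral_dataset()] satisfying the CLDA regime.
#' @param T_rounds maximum number of boosting rounds (default 10).
#' @param seed integer seed controlling all resampling.
#' @param redraw_budget redraws allowed for class-deficient subsets.
#' @return An object of class `adaboost_clda`: list with `rounds` (each
#'   holding `clda`, `alpha`, `weighted_error`, `subset_ids`, and the
#'   subset's projected features/labels for back-end classifiers),
#'   `class_order`, `T_requested`, `T_effective`, `seed`.
#' @examples
#' ds <- generate_spectra(synthetic_preset("overlapping", seed = 1))
#' sp <- stratified_split(ds, c(2, 1), seed = 1)
#' fit <- adaboost_clda(sp$train, T_rounds = 5, seed = 1)
#' mean(predict(fit, sp$test) == sp$test$labels)
#' @export
adaboost_clda <- function(train, T_rounds = 10L, seed = 1L,
                          redraw_budget = 10L) {
  stopifnot(T_rounds >= 1)
  n <- n_samples(train)
  lev <- class_levels(train)
  w <- rep(1 / n, n)
  rounds <- list()
  withr::with_seed(seed, {
    for (t in seq_len(T_rounds)) {
      p <- w / sum(w)                            # step (1): P_t
      idx <- draw_subset(p, train$labels, lev, redraw_budget)
      sub <- bootstrap_subset(train, idx)
      model <- clda(sub)                         # step (2)
      pred <- predict(model, train)              # step (3): weak h_t
      miss <- pred != train$labels
      eps <- sum(p[miss])                        # step (4)
      if (eps == 0) {
        eps_min <- 1 / (2 * n)
        alpha <- 0.5 * log((1 - eps_min) / eps_min)
        rounds[[length(rounds) + 1]] <-
          make_round(model, sub, alpha, eps, train$sample_ids[idx])
        break
      }
      if (eps >= 0.5) {
        if (!length(rounds)) {
          stop("fit error: first weak learner has weighted error ",
               sprintf("%.3f", eps), " >= 1/2; the classes may be too ",
               "entangled -- consider preprocessing (MSC/SNV/SG).",
               call. = FALSE)
        }
        break
      }
      alpha <- 0.5 * log((1 - eps) / eps)        # step (5), Adaboost vote
      rounds[[length(rounds) + 1]] <-
        make_round(model, sub, alpha, eps, train$sample_ids[idx])
      w <- p * exp(ifelse(miss, alpha, -alpha))  # step (6); renormalised
    }                                            # at next round's step (1)
  })
  structure(
    list(rounds = rounds, class_order = lev,
         T_requested = as.integer(T_rounds),
         T_effective = length(rounds), seed = as.integer(seed)),
    class = "adaboost_clda"
  )
}

# like subset_samples() but tolerant of repeated draws: ids are
# deduplicated with a .1/.2 suffix so the container invariant holds.
bootstrap_subset <- function(ds, idx) {
  spectral_dataset(ds$absorbance[idx, , drop = FALSE], ds$axis,
                   ds$labels[idx], make.unique(ds$sample_ids[idx]),
                   ds$axis_unit)
}

make_round <- function(model, sub, alpha, eps, subset_ids) {
  list(clda = model, alpha = alpha, weighted_error = eps,
       subset_ids = subset_ids,
       subset_features = project_clda(model, sub),
       subset_labels = sub$labels)
}

# weighted bootstrap of size n; every class must appear. Redraw up to
# `budget` times, then top up with each missing class's heaviest sample.
draw_subset <- function(p, labels, lev, budget) {
  n <- length(p)
  for (attempt in seq_len(budget + 1)) {
    idx <- sample.int(n, n, replace = TRUE, prob = p)
    if (all(lev %in% labels[idx])) return(idx)
  }
  missing <- setdiff(lev, labels[idx])
  extra <- vapply(missing, function(cl) {
    cand <- which(labels == cl)
    cand[which.max(p[cand])]
  }, integer(1))
  # replace the lowest-weight draws so the subset size stays n
  repl <- order(p[idx])[seq_along(extra)]
  idx[repl] <- extra
  idx
}

#' @export
print.adaboost_clda <- function(x, ...) {
  cat("<adaboost_clda> ", x$T_effective, " round(s) (requested ",
      x$T_requested, "), ", length(x$class_order), " classes\n", sep = "")
  if (x$T_effective) {
    cat("  alpha: ",
        paste(sprintf("%.3f", vapply(x$rounds, `[[`, 0, "alpha")),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# n x C matrix of alpha-weighted votes from the ensemble's weak learners
vote_matrix <- function(model, ds) {
  C <- length(model$class_order)
  n <- if (inherits(ds, "spectral_dataset")) n_samples(ds) else nrow(ds)
  V <- matrix(0, n, C, dimnames = list(NULL, model$class_order))
  for (rd in model$rounds) {
    h <- predict(rd$clda, ds)
    V[cbind(seq_len(n), match(h, model$class_order))] <-
      V[cbind(seq_len(n), match(h, model$class_order))] + rd$alpha
  }
  V
}

#' Classify spectra with a boosted CLDA ensemble
#'
#' The class maximising the `alpha`-weighted vote of the retained weak
#' hypotheses; ties go to the lowest class index.
#'
#' @param object an [adaboost_clda()] model.
#' @param newdata a [spectral_dataset()] or matrix.
#' @param type `"class"` (default) or `"votes"` for the `n x C` vote
#'   matrix.
#' @param ... unused.
#' @return A character vector of labels, or the vote matrix.
#' @export
predict.adaboost_clda <- function(object, newdata,
                                  type = c("class", "votes"), ...) {
  type <- match.arg(type)
  if (!object$T_effective) stop("empty model.", call. = FALSE)
  V <- vote_matrix(object, newdata)
  if (type == "votes") return(V)
  object$class_order[apply(V, 1, which.max)]
}

#' Accuracy of the vote truncated to the first t rounds
#'
#' Mirrors the per-iteration accuracy curve used to choose the number of
#' boosting rounds: entry `t` is the accuracy of the ensemble restricted
#' to rounds `1..t`.
#'
#' @param model an [adaboost_clda()] model.
#' @param ds a [spectral_dataset()].
#' @param truth true labels, length `n_samples(ds)`.
#' @return A numeric vector of length `T_effective`.
#' @export
staged_accuracy <- function(model, ds, truth) {
  truth <- as.character(truth)
  n <- n_samples(ds)
  if (length(truth) != n) {
    stop("`truth` has length ", length(truth), ", expected ", n, ".",
         call. = FALSE)
  }
  C <- length(model$class_order)
  V <- matrix(0, n, C)
  vapply(model$rounds, function(rd) {
    h <- predict(rd$clda, ds)
    V[cbind(seq_len(n), match(h, model$class_order))] <<-
      V[cbind(seq_len(n), match(h, model$class_order))] + rd$alpha
    mean(model$class_order[apply(V, 1, which.max)] == truth)
  }, numeric(1))
}

#' @export
tidy.adaboost_clda <- function(x, ...) {
  tibble::tibble(
    round = seq_len(x$T_effective),
    weighted_error = vapply(x$rounds, `[[`, 0, "weighted_error"),
    alpha = vapply(x$rounds, `[[`, 0, "alpha"),
    subset_unique = vapply(x$rounds,
                           function(r) length(unique(r$subset_ids)), 0L)
  )
}

#' @export
glance.adaboost_clda <- function(x, ...) {
  errs <- vapply(x$rounds, `[[`, 0, "weighted_error")
  tibble::tibble(
    T_requested = x$T_requested,
    T_effective = x$T_effective,
    mean_weighted_error = mean(errs),
    error_bound = prod(2 * sqrt(errs * (1 - errs)))
  )
}

#' @export
autoplot.adaboost_clda <- function(object, ds = NULL, truth = NULL, ...) {
  df <- tidy(object)
  if (!is.null(ds)) {
    df$accuracy <- staged_accuracy(object, ds, truth)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$round, .data$accuracy)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "boosting round",
                    y = "staged accuracy")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$round,
                                          .data$weighted_error)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "boosting round", y = "weighted error")
  }
  p + ggplot2::theme_minimal()
}
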