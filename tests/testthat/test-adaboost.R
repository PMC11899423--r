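# replay the boosting bookkeeping from the stored rounds: recompute
# each round's weighted error and the weight updates from scratch and
# compare with what the fit recorded.
replay_weights <- function(model, train) {
  n <- n_samples(train)
  w <- rep(1 / n, n)
  out <- list()
  for (rd in model$rounds) {
    p <- w / sum(w)
    miss <- predict(rd$clda, train) != train$labels
    eps <- sum(p[miss])
    w <- p * exp(ifelse(miss, rd$alpha, -rd$alpha))
    out[[length(out) + 1]] <-
      list(eps = eps, miss_mass_after = sum(w[miss]) / sum(w),
           p = p)
  }
  out
}

test_that("vote weights follow alpha = log((1-e)/e)/2 and rebalance to 1/2", {
  # arithmetic of the update rule on the documented worked case:
  # uniform weights over n = 4, one error -> e = 1/4, a = log(3)/2,
  # and after update + renormalisation the errant sample carries 1/2
  # while each correct one carries 1/6.
  eps <- 0.25
  alpha <- 0.5 * log((1 - eps) / eps)
  expect_equal(alpha, 0.5 * log(3), tolerance = 1e-12)
  w <- rep(0.25, 4) * exp(c(alpha, -alpha, -alpha, -alpha))
  w <- w / sum(w)
  expect_equal(w, c(1/2, 1/6, 1/6, 1/6), tolerance = 1e-12)

  # the fitted ensemble must realise the same identities
  ds <- generate_spectra(synthetic_preset("overlapping", seed = 4))
  sp <- stratified_split(ds, c(2, 1), seed = 4)
  model <- adaboost_clda(sp$train, T_rounds = 8, seed = 4)
  expect_gte(model$T_effective, 1L)
  rp <- replay_weights(model, sp$train)
  for (t in seq_along(model$rounds)) {
    rd <- model$rounds[[t]]
    expect_equal(rd$weighted_error, rp[[t]]$eps, tolerance = 1e-12)
    expect_lt(rd$weighted_error, 0.5)
    expect_gt(rd$alpha, 0)
    if (rd$weighted_error > 0) {
      expect_equal(rd$alpha,
                   0.5 * log((1 - rd$weighted_error) /
                               rd$weighted_error),
                   tolerance = 1e-12)
      expect_equal(rp[[t]]$miss_mass_after, 0.5, tolerance = 1e-12)
    }
    expect_equal(sum(rp[[t]]$p), 1, tolerance = 1e-12)
    expect_true(all(rp[[t]]$p >= 0))
  }
})

test_that("training error respects the AdaBoost.M1 product bound", {
  for (seed in c(2, 9, 23)) {
    ds <- generate_spectra(synthetic_preset("overlapping", seed = seed))
    sp <- stratified_split(ds, c(2, 1), seed = seed)
    model <- adaboost_clda(sp$train, T_rounds = 10, seed = seed)
    errs <- vapply(model$rounds, `[[`, 0, "weighted_error")
    bound <- prod(2 * sqrt(errs * (1 - errs)))
    train_err <- mean(predict(model, sp$train) != sp$train$labels)
    expect_lte(train_err, bound + 1e-12)
  }
})

test_that("a perfect weak learner ends the loop with a capped vote", {
  ds <- generate_spectra(synthetic_preset("separable", seed = 2))
  sp <- stratified_split(ds, c(2, 1), seed = 2)
  model <- adaboost_clda(sp$train, T_rounds = 10, seed = 2)
  expect_identical(model$T_effective, 1L)
  expect_identical(model$rounds[[1]]$weighted_error, 0)
  n <- n_samples(sp$train)
  expect_equal(model$rounds[[1]]$alpha,
               0.5 * log((1 - 1 / (2 * n)) / (1 / (2 * n))),
               tolerance = 1e-12)
  # degenerate single-round vote equals the weak classifier
  expect_labels_equal(predict(model, sp$test),
                      predict(model$rounds[[1]]$clda, sp$test))
})

test_that("fitting is deterministic in (train, T, seed)", {
  ds <- generate_spectra(synthetic_preset("overlapping", seed = 5))
  sp <- stratified_split(ds, c(2, 1), seed = 5)
  a <- adaboost_clda(sp$train, T_rounds = 5, seed = 11)
  b <- adaboost_clda(sp$train, T_rounds = 5, seed = 11)
  expect_identical(tidy(a), tidy(b))
  expect_labels_equal(predict(a, sp$test), predict(b, sp$test))
  c_ <- adaboost_clda(sp$train, T_rounds = 5, seed = 12)
  expect_false(identical(a$rounds[[1]]$subset_ids,
                         c_$rounds[[1]]$subset_ids))
})

test_that("the alpha-weighted vote picks the heaviest class", {
  # three hand-made single-direction 'clda' stubs whose omegas force
  # predictions A, B, B on the probe point x = 1
  stub <- function(omega_a, omega_b) {
    structure(list(W = matrix(1, 1, 1),
                   omegas = matrix(c(omega_a, omega_b), 2, 1,
                                   dimnames = list(c("A", "B"))),
                   class_order = c("A", "B"), d = 1L),
              class = "clda")
  }
  rounds <- list(
    list(clda = stub(1, 10), alpha = 0.8),   # predicts A
    list(clda = stub(10, 1), alpha = 0.5),   # predicts B
    list(clda = stub(10, 1), alpha = 0.4))   # predicts B
  model <- structure(list(rounds = rounds, class_order = c("A", "B"),
                          T_requested = 3L, T_effective = 3L,
                          seed = 1L),
                     class = "adaboost_clda")
  x <- matrix(1, 1, 1)
  expect_labels_equal(predict(model, x), "B")       # 0.9 > 0.8
  v <- predict(model, x, type = "votes")
  expect_equal(as.vector(v), c(0.8, 0.9))
  # unanimity wins regardless of alphas
  model$rounds[[1]]$clda <- stub(10, 1)
  expect_labels_equal(predict(model, x), "B")
})

test_that("staged accuracy has length T_effective and sane endpoints", {
  ds <- generate_spectra(synthetic_preset("overlapping", seed = 6))
  sp <- stratified_split(ds, c(2, 1), seed = 6)
  model <- adaboost_clda(sp$train, T_rounds = 6, seed = 6)
  acc <- staged_accuracy(model, sp$test, sp$test$labels)
  expect_length(acc, model$T_effective)
  expect_equal(acc[model$T_effective],
               mean(predict(model, sp$test) == sp$test$labels),
               tolerance = 1e-12)
  expect_error(staged_accuracy(model, sp$test, c("a", "b")), "length")

  # perfect single-round ensembles open at accuracy 1
  dsep <- generate_spectra(synthetic_preset("separable", seed = 3))
  spp <- stratified_split(dsep, c(2, 1), seed = 3)
  msep <- adaboost_clda(spp$train, T_rounds = 3, seed = 3)
  accs <- staged_accuracy(msep, spp$train, spp$train$labels)
  expect_equal(accs[1], 1)
})

test_that("boosting refines the ensemble across seeds", {
  # final staged accuracy at least matches the first round in >= 90%
  # of seeds on the overlapping regime
  wins <- vapply(1:20, function(s) {
    ds <- generate_spectra(synthetic_preset("overlapping", seed = s))
    sp <- stratified_split(ds, c(2, 1), seed = s)
    model <- adaboost_clda(sp$train, T_rounds = 10, seed = s)
    acc <- staged_accuracy(model, sp$test, sp$test$labels)
    acc[length(acc)] >= acc[1]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
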