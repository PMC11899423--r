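test_that("SG reproduces polynomials up to its order and validates params", {
  x <- seq(0, 10, length.out = 60)
  q <- x^2 - 3 * x + 1
  ds <- spectral_dataset(rbind(q, rep(2, 60)), x, c("a", "b"))
  sm <- sg_filter(ds, 7, 2)
  expect_lt(max(abs(sm$absorbance[1, ] - q)), 1e-9)       # quadratic
  expect_lt(max(abs(sm$absorbance[2, ] - 2)), 1e-12)      # constant

  # interpolating fit (window = order + 1) is the identity on anything
  noisy <- spectral_dataset(matrix(rnorm(120), 2), seq_len(60),
                            c("a", "b"))
  expect_equal(sg_filter(noisy, 5, 4)$absorbance, noisy$absorbance,
               tolerance = 1e-10)

  expect_error(sg_filter(ds, 8, 2), "odd")
  expect_error(sg_filter(ds, 7, 7), "poly_order")
  expect_error(sg_filter(ds, 7, 2, derivative = 3), "derivative")
})

test_that("SG smoothing reduces per-channel noise variance", {
  n <- 1000
  withr::with_seed(99, {
    X <- matrix(rnorm(n * 40), n, 40)
  })
  ds <- spectral_dataset(X, seq_len(40), rep("a", n))
  sm <- sg_filter(ds, 11, 2)
  interior <- 6:35
  v_in <- apply(ds$absorbance[, interior], 2, var)
  v_out <- apply(sm$absorbance[, interior], 2, var)
  expect_true(all(v_out < v_in))
})

test_that("MSC inverts the exact scatter model and matches an OLS oracle", {
  withr::with_seed(7, ref <- cumsum(rnorm(30))^2 / 10 + 1)
  ds <- spectral_dataset(rbind(ref, 2 * ref + 1), seq_len(30),
                         c("a", "b"))
  out <- msc(ds, reference = ref)
  expect_equal(out$absorbance[1, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)                         # a=1, b=0
  expect_equal(out$absorbance[2, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)                         # inverted

  # per-spectrum normal-equations oracle on random spectra
  withr::with_seed(8, X <- matrix(rnorm(5 * 30, 1), 5, 30))
  dsr <- spectral_dataset(X, seq_len(30), rep("a", 5))
  cor_pkg <- msc(dsr, reference = ref)$absorbance
  for (i in 1:5) {
    co <- stats::coef(stats::lm(X[i, ] ~ ref))
    expect_equal(cor_pkg[i, ], (X[i, ] - co[1]) / co[2],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  expect_error(msc(dsr, reference = rep(3, 30)),
               "degenerate-reference")
})

test_that("SNV centres and scales rows, is idempotent and affine-invariant", {
  ds <- spectral_dataset(rbind(c(1, 2, 3), c(5, 9, 1)), 1:3,
                         c("a", "b"))
  out <- snv(ds)
  expect_equal(out$absorbance[1, ], c(-1, 0, 1), ignore_attr = TRUE)

  withr::with_seed(21, X <- matrix(rnorm(8 * 25), 8, 25))
  dsr <- spectral_dataset(X, seq_len(25), rep("a", 8))
  z <- snv(dsr)$absorbance
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)

  # affine invariance: snv(alpha x + beta) = snv(x) for alpha > 0
  withr::with_seed(22, {
    alpha <- runif(8, 0.5, 3)
    beta <- rnorm(8)
  })
  dsa <- set_absorbance(dsr, alpha * X + beta)
  expect_equal(snv(dsa)$absorbance, z, tolerance = 1e-10)
  # idempotence
  expect_equal(snv(snv(dsr))$absorbance, z, tolerance = 1e-12)

  expect_error(snv(set_absorbance(dsr, matrix(2, 8, 25))),
               "degenerate-spectrum.*s0001")
})

test_that("chains apply left-to-right with training-frozen statistics", {
  spec0 <- preprocess_spec()
  tr <- random_instance(d = 15, C = 2, n_per = 4, seed = 31)
  te <- random_instance(d = 15, C = 2, n_per = 3, seed = 32)
  out0 <- apply_preprocess(tr, te, spec0)
  expect_identical(out0$train$absorbance, tr$absorbance)
  expect_identical(out0$test$absorbance, te$absorbance)

  # [SNV, SNV] == [SNV]
  out2 <- apply_preprocess(tr, te, preprocess_spec("SNV", "SNV"))
  out1 <- apply_preprocess(tr, te, preprocess_spec("SNV"))
  expect_equal(out2$train$absorbance, out1$train$absorbance,
               tolerance = 1e-12)

  # MSC reference must come from the training set only
  outm <- apply_preprocess(tr, te, preprocess_spec("MSC"))
  ref <- colMeans(tr$absorbance)
  expect_equal(outm$test$absorbance, msc(te, ref)$absorbance,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(outm$test$absorbance,
                                msc(te, "mean")$absorbance)))
})

test_that("MSC + SG shrinks replicate spread on scatter-corrupted spectra", {
  spec <- synthetic_preset("scatter_heavy", seed = 17)
  ds <- generate_spectra(spec)
  sp <- stratified_split(ds, c(2, 1), seed = 17)
  pp <- apply_preprocess(sp$train, sp$test,
                         preprocess_spec(step_msc(), step_sg(11, 2)))
  within_var <- function(d) {
    mean(vapply(split(seq_len(n_samples(d)), d$labels), function(i) {
      mean(apply(d$absorbance[i, , drop = FALSE], 2, var))
    }, numeric(1)))
  }
  expect_lt(within_var(pp$train), within_var(sp$train))
  expect_lt(within_var(pp$test), within_var(sp$test))
})
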