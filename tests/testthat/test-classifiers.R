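test_that("KNN votes and tie-breaks are deterministic", {
  x_tr <- matrix(c(0, 1, 10), 3, 1)
  y_tr <- c("A", "A", "B")
  # k = 1 on a coinciding point returns that point's label
  expect_labels_equal(knn_predict(x_tr, y_tr, matrix(10, 1, 1), k = 1),
                      "B")
  # majority 2:1 at k = 3
  expect_labels_equal(knn_predict(x_tr, y_tr, matrix(0.4, 1, 1), k = 3),
                      "A")
  # k = n_train: global majority everywhere
  expect_labels_equal(
    knn_predict(x_tr, y_tr, matrix(c(-5, 100), 2, 1), k = 3),
    c("A", "A"))
  # vote tie at k = 2 -> summed inverse distance decides
  expect_labels_equal(knn_predict(x_tr, y_tr, matrix(9, 1, 1), k = 2),
                      "B")   # B at distance 1 beats A at distance 8
  # full symmetry falls through to the lowest class index
  x_sym <- matrix(c(-1, 1), 2, 1)
  expect_labels_equal(
    knn_predict(x_sym, c("A", "B"), matrix(0, 1, 1), k = 2), "A")
  expect_error(knn_predict(x_tr, y_tr, matrix(0), k = 4),
               "parameter error")
  expect_error(knn_predict(x_tr, y_tr, matrix(0), k = 0),
               "parameter error")
})

test_that("KNN agrees with class::knn where no ties are possible", {
  skip_if_not_installed("class")
  withr::with_seed(31, {
    x_tr <- matrix(rnorm(60 * 3), 60, 3)
    y_tr <- rep(c("u", "v"), each = 30)
    x_te <- matrix(rnorm(25 * 3), 25, 3)
  })
  for (k in c(1, 3, 7)) {
    ours <- knn_predict(x_tr, y_tr, x_te, k = k)
    ref <- as.character(class::knn(x_tr, x_te, factor(y_tr), k = k))
    expect_labels_equal(ours, ref)
  }
})

test_that("naive Bayes estimates priors, moments and floors variances", {
  withr::with_seed(41, {
    x <- rbind(matrix(rnorm(500, -2), 500, 1),
               matrix(rnorm(500, 2), 500, 1))
  })
  y <- rep(c("neg", "pos"), each = 500)
  fit <- nb_fit(x, y)
  expect_equal(fit$priors, c(0.5, 0.5))
  expect_lt(max(abs(fit$means - c(-2, 2))), 0.15)

  # four balanced classes -> priors 1/4
  ds <- random_instance(d = 3, C = 4, n_per = 5, seed = 2)
  fit4 <- nb_fit(ds$absorbance, ds$labels)
  expect_equal(fit4$priors, rep(0.25, 4))

  # constant feature within a class gets the floor, not zero
  xc <- cbind(c(1, 1, 1, 5, 6, 7))
  fitc <- nb_fit(xc, rep(c("k", "l"), each = 3))
  expect_gt(fitc$vars["k", 1], 0)
  expect_equal(unname(fitc$means["k", 1]), 1)

  expect_error(nb_fit(cbind(1:3), c("a", "a", "b")), "fewer than 2")
})

test_that("naive Bayes decision boundaries follow the closed form", {
  # symmetric two-class model: midpoint ties to the lower class index,
  # anything past it goes to the nearer mean
  fit <- structure(list(priors = c(0.5, 0.5),
                        means = matrix(c(-1, 1), 2, 1,
                                       dimnames = list(c("a", "b"))),
                        vars = matrix(1, 2, 1),
                        class_order = c("a", "b")),
                   class = "naive_bayes_model")
  expect_labels_equal(predict(fit, matrix(0)), "a")
  expect_labels_equal(predict(fit, matrix(0.1)), "b")
  expect_labels_equal(predict(fit, matrix(-0.1)), "a")

  # prior shift moves the boundary by log(p1/p2)/2 toward the rare class
  fit$priors <- c(0.9, 0.1)
  boundary <- log(fit$priors[1] / fit$priors[2]) / 2
  expect_labels_equal(predict(fit, matrix(boundary - 1e-6)), "a")
  expect_labels_equal(predict(fit, matrix(boundary + 1e-6)), "b")
})

test_that("naive Bayes argmax matches a brute-force density oracle", {
  withr::with_seed(51, {
    x_tr <- matrix(rnorm(90 * 2, rep(c(0, 2, 4), each = 30)), 90, 2)
    x_te <- matrix(rnorm(40 * 2, 2), 40, 2)
  })
  y_tr <- rep(c("p", "q", "r"), each = 30)
  fit <- nb_fit(x_tr, y_tr)
  ours <- predict(fit, x_te)
  oracle <- apply(x_te, 1, function(x) {
    post <- vapply(seq_along(fit$class_order), function(i) {
      fit$priors[i] * prod(stats::dnorm(x, fit$means[i, ],
                                        sqrt(fit$vars[i, ])))
    }, numeric(1))
    fit$class_order[which.max(post)]
  })
  expect_labels_equal(ours, oracle)
})

test_that("naive Bayes agrees with e1071 on non-degenerate data", {
  skip_if_not_installed("e1071")
  withr::with_seed(61, {
    x_tr <- matrix(rnorm(80 * 3, rep(c(0, 1.5), each = 40)), 80, 3)
    x_te <- matrix(rnorm(30 * 3, 0.7), 30, 3)
  })
  y_tr <- rep(c("g", "h"), each = 40)
  ours <- predict(nb_fit(x_tr, y_tr), x_te)
  ref <- as.character(predict(
    e1071::naiveBayes(data.frame(x_tr), factor(y_tr)),
    data.frame(x_te)))
  expect_labels_equal(ours, ref)
})

test_that("evaluation counts and cross-tabulates exactly", {
  truth <- rep(c("a", "b", "c", "d"), each = 20)
  ev <- evaluate_classification(truth, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(diag(ev$confusion), c(a = 20, b = 20, c = 20, d = 20))

  pred <- truth; pred[1] <- "b"
  ev2 <- evaluate_classification(pred, truth)
  expect_equal(ev2$accuracy, 79 / 80)
  expect_equal(unname(ev2$confusion["a", "b"]), 1L)
  # row sums are the per-class truth counts; trace/total is accuracy
  expect_equal(unname(rowSums(ev2$confusion)), rep(20L, 4))
  expect_equal(sum(diag(ev2$confusion)) / sum(ev2$confusion),
               ev2$accuracy)

  expect_error(evaluate_classification(character(0), character(0)),
               "empty")
  expect_error(evaluate_classification("x", "a", class_order = c("a")),
               "schema")
})

test_that("naive Bayes argmax survives consistent affine rescaling", {
  withr::with_seed(71, {
    x_tr <- matrix(rnorm(60 * 2, rep(c(0, 2), each = 30)), 60, 2)
    x_te <- matrix(rnorm(20 * 2, 1), 20, 2)
  })
  y_tr <- rep(c("a", "b"), each = 30)
  base <- predict(nb_fit(x_tr, y_tr), x_te)
  scale <- c(3, 0.2); shift <- c(-1, 5)
  xs_tr <- sweep(sweep(x_tr, 2, scale, "*"), 2, shift, "+")
  xs_te <- sweep(sweep(x_te, 2, scale, "*"), 2, shift, "+")
  expect_labels_equal(predict(nb_fit(xs_tr, y_tr), xs_te), base)
})
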