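# Small fixtures shared across test files; all generated in code.

# Two classes in d = 3 whose within-class variation is entirely along
# (0, 1, 0): rank(S_W) = 1, common vectors (1,0,0) and (0,0,1),
# W = (1, 0, -1)/sqrt(2), omegas +/- 1/sqrt(2). All expected values below
# follow by hand from these four vectors.
toy_dataset <- function() {
  spectral_dataset(rbind(c(1, 0, 0), c(1, 1, 0),
                         c(0, 0, 1), c(0, 1, 1)),
                   axis = 1:3, labels = c("a", "a", "b", "b"))
}

# random small-sample instance: d channels, C classes, n_per per class
random_instance <- function(d = 20, C = 3, n_per = 4, seed = 1,
                            sep = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(C * d, sd = sep), C, d)
    X <- centers[rep(seq_len(C), each = n_per), ] +
      matrix(rnorm(C * n_per * d, sd = 0.3), C * n_per, d)
    spectral_dataset(X, seq_len(d),
                     rep(sprintf("c%d", seq_len(C)), each = n_per))
  })
}

# principal angles (radians) between the column spans of two bases,
# via the sine formulation, which stays accurate for tiny angles where
# acos(cos(theta)) loses half the digits
principal_angles <- function(A, B) {
  if (ncol(A) == 0 || ncol(B) == 0) return(numeric(0))
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(qb - qa %*% crossprod(qa, qb))$d
  asin(pmin(pmax(s, 0), 1))
}

# direct (dense) eigendecomposition of S_W: the independent oracle for
# the Gram-matrix route; rank read off at the same structural cap
# (at most M - C nonzero eigenvalues)
direct_sw_range <- function(ds) {
  eg <- eigen(scatter_within(ds), symmetric = TRUE)
  tol <- nrow(eg$vectors) * .Machine$double.eps * max(eg$values, 0)
  r <- min(sum(eg$values > tol),
           n_samples(ds) - length(class_levels(ds)))
  eg$vectors[, seq_len(r), drop = FALSE]
}

expect_labels_equal <- function(x, y) {
  expect_identical(as.character(x), as.character(y))
}
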