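#' Stratified train/test split
#'
#' Partitions a dataset class-by-class into training and test portions in
#' a given integer ratio (the study design here is 2:1, i.e. 40 training
#' and 20 test samples from each class of 60). For class sizes not
#' divisible by the ratio sum, the training count is
#' `floor(n_class * a / (a + b))` and the remainder goes to the test set,
#' so the test set is never short-changed. Assignment within a class is a
#' uniformly random, seed-determined permutation.
#'
#' @param ds a [spectral_dataset()].
#' @param ratio integer pair `c(train, test)`, default `c(2, 1)`.
#' @param seed integer seed controlling the permutation; the caller's RNG
#'   state is left untouched.
#' @return A list of class `split_result` with elements `train`, `test`
#'   (both `spectral_dataset`), `ratio`, `seed`.
#' @examples
#' ds <- generate_spectra(synthetic_spec(seed = 1))
#' sp <- stratified_split(ds, c(2, 1), seed = 7)
#' table(sp$train$labels)
#' @export
stratified_split <- function(ds, ratio = c(2, 1), seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio >= 1))
  ratio <- as.integer(ratio)
  lev <- class_levels(ds)
  counts <- table(factor(ds$labels, levels = lev))
  small <- names(counts)[counts < sum(ratio)]
  if (length(small)) {
    stop("configuration error: class(es) ",
         paste(small, collapse = ", "), " have fewer than ", sum(ratio),
         " samples, the minimum for a ", ratio[1], ":", ratio[2], " split.",
         call. = FALSE)
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(lev, function(cl) {
      idx <- which(ds$labels == cl)
      n_tr <- floor(length(idx) * ratio[1] / sum(ratio))
      sample(idx, n_tr)
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples(ds)), train_idx)
  structure(
    list(train = subset_samples(ds, train_idx),
         test = subset_samples(ds, test_idx),
         ratio = ratio, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> ratio ", x$ratio[1], ":", x$ratio[2],
      ", seed ", x$seed, "\n", sep = "")
  cat("  train: ", n_samples(x$train), " samples; test: ",
      n_samples(x$test), " samples\n", sep = "")
  invisible(x)
}
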