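#' Savitzky-Golay filtering of spectra
#'
#' Replaces each spectrum by its local least-squares polynomial smooth
#' (or derivative). Edge channels are handled by evaluating the first and
#' last window's fitted polynomial, so the channel count is preserved --
#' a 228-channel spectrum stays 228-dimensional through the pipeline.
#' Filtering is exact on polynomials up to `poly_order`.
#'
#' @param ds a [spectral_dataset()].
#' @param window_length odd integer window width, `3 <= window_length <= d`.
#' @param poly_order polynomial order, `0 <= poly_order < window_length`.
#' @param derivative derivative order, `0 <= derivative <= poly_order`;
#'   derivatives are per channel index (the axis spacing is not applied).
#' @return A `spectral_dataset` of identical shape.
#' @export
sg_filter <- function(ds, window_length = 11L, poly_order = 2L,
                      derivative = 0L) {
  d <- n_channels(ds)
  if (window_length %% 2 == 0 || window_length < 3 || window_length > d) {
    stop("parameter error: `window_length` must be odd and in [3, ", d,
         "], got ", window_length, ".", call. = FALSE)
  }
  if (poly_order < 0 || poly_order >= window_length) {
    stop("parameter error: `poly_order` must satisfy 0 <= poly_order < ",
         "window_length.", call. = FALSE)
  }
  if (derivative < 0 || derivative > poly_order) {
    stop("parameter error: `derivative` must satisfy 0 <= derivative <= ",
         "poly_order.", call. = FALSE)
  }
  out <- t(apply(ds$absorbance, 1, signal::sgolayfilt,
                 p = poly_order, n = window_length, m = derivative))
  set_absorbance(ds, out)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum `x` on a reference spectrum by ordinary least
#' squares, `x ~ a * ref + b`, and returns `(x - b) / a`, removing the
#' per-spectrum multiplicative and additive scatter that particle-size
#' differences imprint on diffuse-reflectance NIR measurements.
#'
#' @param ds a [spectral_dataset()].
#' @param reference either the string `"mean"` (use the mean spectrum of
#'   `ds` -- when correcting a test set, pass the frozen training
#'   reference instead; see [apply_preprocess()]) or a numeric vector of
#'   length `d`.
#' @param min_slope spectra whose fitted |a| falls below this tolerance
#'   are degenerate and raise an error.
#' @return A `spectral_dataset`; the reference used is attached as
#'   attribute `"reference"`.
#' @export
msc <- function(ds, reference = "mean", min_slope = 1e-8) {
  if (identical(reference, "mean")) {
    reference <- colMeans(ds$absorbance)
  }
  reference <- as.numeric(reference)
  if (length(reference) != n_channels(ds)) {
    stop("`reference` has length ", length(reference), ", expected ",
         n_channels(ds), ".", call. = FALSE)
  }
  rc <- reference - mean(reference)
  ss_ref <- sum(rc^2)
  if (ss_ref < .Machine$double.eps * length(rc)) {
    stop("degenerate-reference error: reference spectrum is constant.",
         call. = FALSE)
  }
  slope <- as.vector(ds$absorbance %*% rc) / ss_ref
  intercept <- rowMeans(ds$absorbance) - slope * mean(reference)
  bad <- which(abs(slope) < min_slope)
  if (length(bad)) {
    stop("degenerate-fit error: |slope| < ", min_slope, " for sample(s) ",
         paste(ds$sample_ids[utils::head(bad, 3)], collapse = ", "),
         call. = FALSE)
  }
  out <- (ds$absorbance - intercept) / slope
  ds <- set_absorbance(ds, out)
  attr(ds, "reference") <- reference
  ds
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum independently to mean 0 and sample
#' standard deviation 1 (divisor `d - 1`).
#'
#' @param ds a [spectral_dataset()].
#' @return A `spectral_dataset` whose rows each have mean 0, sd 1.
#' @export
snv <- function(ds) {
  m <- rowMeans(ds$absorbance)
  s <- apply(ds$absorbance, 1, stats::sd)
  bad <- which(s < .Machine$double.eps * n_channels(ds))
  if (length(bad)) {
    stop("degenerate-spectrum error: constant spectrum for sample(s) ",
         paste(ds$sample_ids[utils::head(bad, 3)], collapse = ", "),
         call. = FALSE)
  }
  set_absorbance(ds, (ds$absorbance - m) / s)
}

#' Describe an ordered preprocessing chain
#'
#' A `preprocess_spec` is an ordered list of steps, each `MSC`, `SNV` or
#' `SG` with parameters, mirroring the combinations commonly benchmarked
#' in NIR work ("MSC + SG" means MSC first, then SG). An empty spec means
#' raw spectra.
#'
#' @param ... step descriptors created by [step_sg()], [step_msc()],
#'   [step_snv()], or a character shorthand such as
#'   `preprocess_spec("MSC", "SG")`.
#' @return An object of class `preprocess_spec`.
#' @examples
#' preprocess_spec(step_msc(), step_sg(11, 2))
#' preprocess_spec("SNV", "SG")
#' @export
preprocess_spec <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) {
      s <- switch(toupper(s),
                  SG = step_sg(), MSC = step_msc(), SNV = step_snv(),
                  stop("unknown preprocessing method: ", s, call. = FALSE))
    }
    if (!inherits(s, "preprocess_step")) {
      stop("each step must be a preprocess_step or method name.",
           call. = FALSE)
    }
    s
  })
  structure(list(steps = steps), class = "preprocess_spec")
}

#' Preprocessing step descriptors
#'
#' @param window_length,poly_order,derivative see [sg_filter()].
#' @param reference see [msc()].
#' @return A `preprocess_step`.
#' @export
step_sg <- function(window_length = 11L, poly_order = 2L, derivative = 0L) {
  structure(list(method = "SG", window_length = window_length,
                 poly_order = poly_order, derivative = derivative),
            class = "preprocess_step")
}

#' @rdname step_sg
#' @export
step_msc <- function(reference = "mean") {
  structure(list(method = "MSC", reference = reference),
            class = "preprocess_step")
}

#' @rdname step_sg
#' @export
step_snv <- function() {
  structure(list(method = "SNV"), class = "preprocess_step")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  if (!length(x$steps)) {
    cat("<preprocess_spec> raw (no steps)\n")
  } else {
    cat("<preprocess_spec> ",
        paste(vapply(x$steps, `[[`, "", "method"), collapse = " + "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Label of a preprocessing chain, e.g. `"MSC + SG"`
#' @param spec a [preprocess_spec()].
#' @return A string (`"raw"` for the empty chain).
#' @export
preprocess_label <- function(spec) {
  if (!length(spec$steps)) return("raw")
  paste(vapply(spec$steps, `[[`, "", "method"), collapse = " + ")
}

#' Apply a preprocessing chain to training and test spectra
#'
#' Steps are applied left to right. Any statistic derived from data --
#' currently the MSC `"mean"` reference -- is computed on the training
#' set only and reused, frozen, for the test set, so no test-set
#' information leaks into the transform.
#'
#' @param train,test [spectral_dataset()]s; `test` may be `NULL`.
#' @param spec a [preprocess_spec()].
#' @return A list with elements `train` and `test` (the latter `NULL` if
#'   no test set was supplied).
#' @export
apply_preprocess <- function(train, test = NULL, spec = preprocess_spec()) {
  stopifnot(inherits(spec, "preprocess_spec"))
  for (st in spec$steps) {
    if (st$method == "SG") {
      train <- sg_filter(train, st$window_length, st$poly_order,
                         st$derivative)
      if (!is.null(test)) {
        test <- sg_filter(test, st$window_length, st$poly_order,
                          st$derivative)
      }
    } else if (st$method == "MSC") {
      train <- msc(train, st$reference)
      if (!is.null(test)) test <- msc(test, attr(train, "reference"))
    } else if (st$method == "SNV") {
      train <- snv(train)
      if (!is.null(test)) test <- snv(test)
    } else {
      stop("unknown preprocessing method: ", st$method, call. = FALSE)
    }
  }
  list(train = train, test = test)
}
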