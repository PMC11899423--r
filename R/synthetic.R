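#' Specification for the synthetic NIR spectra generator
#'
#' Describes a population of origin-labelled absorbance spectra with the
#' statistical structure the discriminant pipeline assumes: smooth
#' class-dependent Gaussian absorption bands on a sloped baseline,
#' per-spectrum multiplicative/additive scatter, and i.i.d. channel
#' noise. The defaults emulate a 4-origin fruit-authentication study
#' design: 4 classes x 60 samples, 228 channels spanning
#' 5894.5--11111 cm^-1 (900--1700 nm), with shared absorption bands near
#' 6993 and 8475 cm^-1 (water/carbohydrate O-H and C-H overtone regions)
#' whose amplitudes differ by origin.
#'
#' @param n_classes number of classes (default 4).
#' @param samples_per_class samples per class (default 60).
#' @param n_channels spectral channels (default 228).
#' @param axis_range wavenumber range in cm^-1, default
#'   `c(5894.5, 11111)`, gridded uniformly.
#' @param peak_centers shared band centres (cm^-1); must lie inside
#'   `axis_range`.
#' @param peak_widths Gaussian band widths (sd, cm^-1), one per band.
#' @param base_amplitudes band amplitudes common to all classes
#'   (absorbance units).
#' @param amplitude_deltas `n_classes x length(peak_centers)` matrix of
#'   per-class amplitude offsets, scaled by `class_separation`. The
#'   default (for 4 classes) gives each origin a distinct band-amplitude
#'   signature.
#' @param baseline `c(offset, tilt)`: absorbance baseline `offset +
#'   tilt * u` where `u` runs 0..1 across the axis.
#' @param scatter_sd `c(mult, add)`: per-spectrum multiplicative gain
#'   `a ~ N(1, mult^2)` and additive offset `b ~ N(0, add^2)`.
#' @param noise_sd sd of i.i.d. additive channel noise.
#' @param class_separation nonnegative scale on `amplitude_deltas`; 0
#'   makes all classes identically distributed (chance-level regime).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_spectra()], [synthetic_preset()]
#' @export
synthetic_spec <- function(n_classes = 4L,
                           samples_per_class = 60L,
                           n_channels = 228L,
                           axis_range = c(5894.5, 11111),
                           peak_centers = c(6993, 8475, 10300),
                           peak_widths = c(360, 450, 520),
                           base_amplitudes = c(0.45, 0.30, 0.10),
                           amplitude_deltas = NULL,
                           baseline = c(0.30, 0.10),
                           scatter_sd = c(0.05, 0.02),
                           noise_sd = 0.004,
                           class_separation = 1,
                           seed = 1L) {
  stopifnot(n_classes >= 2, samples_per_class >= 1, n_channels >= 2,
            length(axis_range) == 2, axis_range[1] < axis_range[2],
            length(peak_widths) == length(peak_centers),
            length(base_amplitudes) == length(peak_centers),
            all(scatter_sd >= 0), noise_sd >= 0, class_separation >= 0)
  if (any(peak_centers < axis_range[1] | peak_centers > axis_range[2])) {
    stop("configuration error: peak centres must lie inside axis_range.",
         call. = FALSE)
  }
  if (is.null(amplitude_deltas)) {
    base_pattern <- matrix(c( 0.00,  0.00,  0.00,
                              0.04, -0.03,  0.02,
                             -0.03,  0.04, -0.02,
                              0.03,  0.03, -0.03),
                           nrow = 4, byrow = TRUE)
    # recycle/extend the pattern for other class or band counts
    amplitude_deltas <- matrix(0, n_classes, length(peak_centers))
    for (i in seq_len(n_classes)) {
      row <- base_pattern[(i - 1) %% 4 + 1, ]
      shift <- 0.01 * ((i - 1) %/% 4)
      amplitude_deltas[i, ] <- rep_len(row, length(peak_centers)) + shift
    }
  }
  amplitude_deltas <- as.matrix(amplitude_deltas)
  if (!all(dim(amplitude_deltas) ==
           c(n_classes, length(peak_centers)))) {
    stop("configuration error: `amplitude_deltas` must be ", n_classes,
         " x ", length(peak_centers), ".", call. = FALSE)
  }
  structure(
    list(n_classes = as.integer(n_classes),
         samples_per_class = as.integer(samples_per_class),
         n_channels = as.integer(n_channels),
         axis_range = as.numeric(axis_range),
         peak_centers = as.numeric(peak_centers),
         peak_widths = as.numeric(peak_widths),
         base_amplitudes = as.numeric(base_amplitudes),
         amplitude_deltas = amplitude_deltas,
         baseline = as.numeric(baseline),
         scatter_sd = as.numeric(scatter_sd),
         noise_sd = as.numeric(noise_sd),
         class_separation = as.numeric(class_separation),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_classes, " classes x ",
      x$samples_per_class, " samples, ", x$n_channels, " channels (",
      x$axis_range[1], "-", x$axis_range[2], " cm-1), separation ",
      x$class_separation, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Named synthetic regimes
#'
#' Three frozen regimes used throughout the test suite:
#' * `"separable"` -- large class separation, low noise and scatter;
#'   nearest-common-vector CLDA should classify a held-out test set
#'   perfectly.
#' * `"overlapping"` -- reduced separation with appreciable noise, the
#'   regime where single-subspace CLDA misclassifies confusable class
#'   pairs and boosting pays off.
#' * `"scatter_heavy"` -- strong multiplicative/additive scatter,
#'   exercising MSC/SNV correction.
#'
#' @param name one of `"separable"`, `"overlapping"`, `"scatter_heavy"`.
#' @param seed seed stored in the returned spec.
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("separable", "overlapping",
                                      "scatter_heavy"),
                             seed = 1L) {
  name <- match.arg(name)
  switch(name,
    separable = synthetic_spec(class_separation = 2.5,
                               noise_sd = 0.002,
                               scatter_sd = c(0.02, 0.008),
                               seed = seed),
    overlapping = synthetic_spec(class_separation = 0.35,
                                 noise_sd = 0.012,
                                 scatter_sd = c(0.18, 0.08),
                                 seed = seed),
    scatter_heavy = synthetic_spec(class_separation = 1,
                                   noise_sd = 0.004,
                                   scatter_sd = c(0.20, 0.10),
                                   seed = seed)
  )
}

#' Generate a synthetic spectral dataset
#'
#' Each spectrum is
#' `a_s * (sum_k amplitude[class, k] * exp(-(axis - center_k)^2 /
#' (2 width_k^2)) + baseline) + b_s + noise`,
#' with `a_s ~ N(1, mult^2)`, `b_s ~ N(0, add^2)` drawn per sample and
#' i.i.d. Gaussian channel noise. Classes are labelled
#' `origin_1 ... origin_C`; generation is bitwise-deterministic given
#' the spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return A [spectral_dataset()] with
#'   `n_classes * samples_per_class` rows.
#' @examples
#' ds <- generate_spectra(synthetic_spec(seed = 42))
#' ds
#' @export
generate_spectra <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  axis <- seq(spec$axis_range[1], spec$axis_range[2],
              length.out = spec$n_channels)
  u <- (axis - axis[1]) / diff(range(axis))
  base_curve <- spec$baseline[1] + spec$baseline[2] * u
  amps <- sweep(spec$class_separation * spec$amplitude_deltas, 2,
                spec$base_amplitudes, "+")
  # class template spectra: C x d
  bands <- vapply(seq_along(spec$peak_centers), function(k) {
    exp(-(axis - spec$peak_centers[k])^2 / (2 * spec$peak_widths[k]^2))
  }, numeric(spec$n_channels))                     # d x K
  templates <- amps %*% t(bands) +
    matrix(base_curve, spec$n_classes, spec$n_channels, byrow = TRUE)

  n <- spec$n_classes * spec$samples_per_class
  labels <- rep(sprintf("origin_%d", seq_len(spec$n_classes)),
                each = spec$samples_per_class)
  withr::with_seed(spec$seed, {
    a_s <- stats::rnorm(n, 1, spec$scatter_sd[1])
    b_s <- stats::rnorm(n, 0, spec$scatter_sd[2])
    noise <- matrix(stats::rnorm(n * spec$n_channels, 0, spec$noise_sd),
                    n, spec$n_channels)
    X <- a_s * templates[rep(seq_len(spec$n_classes),
                             each = spec$samples_per_class), ,
                         drop = FALSE] + b_s + noise
  })
  spectral_dataset(X, axis, labels,
                   sprintf("%s_s%02d", labels,
                           rep(seq_len(spec$samples_per_class),
                               spec$n_classes)),
                   axis_unit = "cm-1")
}
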