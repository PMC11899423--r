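#' Build a spectral dataset
#'
#' The container passed between every stage of the pipeline: an
#' `n x d` absorbance matrix, the `d` channel positions (wavelength in nm
#' or wavenumber in cm^-1 -- carried as metadata only, no algorithm reads
#' it), and one categorical class label per sample. Classes are ordered
#' lexicographically throughout the package so that discriminative common
#' vectors, confusion matrices and plots are reproducible.
#'
#' @param absorbance numeric matrix, samples in rows, channels in columns.
#' @param axis numeric vector of channel positions, length `ncol(absorbance)`,
#'   strictly monotone (ascending or descending).
#' @param labels character (or factor) vector of class labels, length
#'   `nrow(absorbance)`; at least two distinct classes are required by the
#'   discriminant stages but not by the container itself.
#' @param sample_ids optional character vector of unique sample identifiers;
#'   defaults to `s0001, s0002, ...`.
#' @param axis_unit unit of `axis`, e.g. `"cm-1"` or `"nm"`.
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `absorbance`, `axis`, `labels`, `sample_ids`, `axis_unit`.
#' @examples
#' ds <- spectral_dataset(matrix(rnorm(50), 5, 10), seq(1000, 1900, 100),
#'                        labels = rep(c("a", "b"), c(2, 3)))
#' ds
#' @export
spectral_dataset <- function(absorbance, axis, labels, sample_ids = NULL,
                             axis_unit = "cm-1") {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  axis <- as.numeric(axis)
  labels <- as.character(labels)
  n <- nrow(absorbance)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)

  if (length(labels) != n) {
    stop("`labels` has length ", length(labels), " but `absorbance` has ",
         n, " rows.", call. = FALSE)
  }
  if (length(sample_ids) != n) {
    stop("`sample_ids` has length ", length(sample_ids),
         " but `absorbance` has ", n, " rows.", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("`sample_ids` must be unique.", call. = FALSE)
  }
  if (length(axis) != ncol(absorbance)) {
    stop("`axis` has length ", length(axis), " but `absorbance` has ",
         ncol(absorbance), " columns.", call. = FALSE)
  }
  if (length(axis) > 1) {
    dirs <- sign(diff(axis))
    if (any(dirs == 0) || length(unique(dirs)) > 1) {
      stop("`axis` must be strictly monotone.", call. = FALSE)
    }
  }
  if (anyNA(absorbance)) {
    stop("`absorbance` contains missing values.", call. = FALSE)
  }
  rownames(absorbance) <- sample_ids
  structure(
    list(absorbance = absorbance, axis = axis, labels = labels,
         sample_ids = sample_ids, axis_unit = axis_unit),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("<spectral_dataset> ", nrow(x$absorbance), " samples x ",
      ncol(x$absorbance), " channels\n", sep = "")
  cat("  axis: ", format(min(x$axis)), " to ", format(max(x$axis)), " ",
      x$axis_unit, if (x$axis[1] > x$axis[length(x$axis)]) " (descending)",
      "\n", sep = "")
  cat("  classes: ",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

#' Number of samples / channels / classes in a spectral dataset
#'
#' @param ds a [spectral_dataset()].
#' @return An integer.
#' @export
n_samples <- function(ds) nrow(ds$absorbance)

#' @rdname n_samples
#' @export
n_channels <- function(ds) ncol(ds$absorbance)

#' @rdname n_samples
#' @export
class_levels <- function(ds) sort(unique(ds$labels))

#' Subset a spectral dataset by sample index
#'
#' @param ds a [spectral_dataset()].
#' @param idx integer or logical index over samples.
#' @return A `spectral_dataset` with the selected samples.
#' @export
subset_samples <- function(ds, idx) {
  spectral_dataset(ds$absorbance[idx, , drop = FALSE], ds$axis,
                   ds$labels[idx], ds$sample_ids[idx], ds$axis_unit)
}

#' Replace the absorbance matrix, keeping all metadata
#'
#' Used by preprocessing operators, which change values but never shape.
#' @param ds a [spectral_dataset()].
#' @param absorbance replacement matrix of identical dimensions.
#' @return A `spectral_dataset`.
#' @keywords internal
#' @export
set_absorbance <- function(ds, absorbance) {
  stopifnot(all(dim(absorbance) == dim(ds$absorbance)))
  ds$absorbance <- as.matrix(absorbance)
  rownames(ds$absorbance) <- ds$sample_ids
  ds
}

#' Per-class mean spectra
#'
#' Arithmetic mean spectrum of each class, rows ordered by the
#' lexicographic class order (the same order used for discriminative
#' common vectors and confusion matrices).
#'
#' @param ds a [spectral_dataset()].
#' @return A `C x d` matrix with `rownames` the class levels.
#' @export
class_mean_spectra <- function(ds) {
  if (n_samples(ds) == 0) stop("empty dataset", call. = FALSE)
  lev <- class_levels(ds)
  out <- t(vapply(lev, function(cl) {
    colMeans(ds$absorbance[ds$labels == cl, , drop = FALSE])
  }, numeric(n_channels(ds))))
  rownames(out) <- lev
  out
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.spectral_dataset <- function(x, ...) {
  ab <- x$absorbance
  colnames(ab) <- format(x$axis, trim = TRUE, digits = 10)
  out <- tibble::tibble(sample_id = x$sample_ids, label = x$labels)
  dplyr::bind_cols(out, tibble::as_tibble(ab, .name_repair = "minimal"))
}

#' Long-format view of a spectral dataset
#'
#' One row per (sample, channel); convenient for ggplot2.
#'
#' @param ds a [spectral_dataset()].
#' @return A tibble with columns `sample_id`, `label`, `axis`, `absorbance`.
#' @export
spectra_long <- function(ds) {
  tibble::tibble(
    sample_id = rep(ds$sample_ids, each = n_channels(ds)),
    label = rep(ds$labels, each = n_channels(ds)),
    axis = rep(ds$axis, times = n_samples(ds)),
    absorbance = as.vector(t(ds$absorbance))
  )
}

#' @export
autoplot.spectral_dataset <- function(object, alpha = 0.4, ...) {
  df <- spectra_long(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$absorbance,
                                   group = .data$sample_id,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = paste0("channel (", object$axis_unit, ")"),
                  y = "absorbance", colour = "class") +
    ggplot2::theme_minimal()
}
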