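#' Read a spectral matrix from a delimited text file
#'
#' Wide layout: a header row whose numeric fields are the channel axis,
#' one `sample_id` column and one `label` column, and one row per sample
#' (`orientation = "samples_in_rows"`, the format written by
#' [write_spectra()]). With `orientation = "samples_in_columns"` the file
#' is the transpose: first column is the axis, one column per sample, and
#' two extra rows named `sample_id` / `label`. CSV vs TSV is chosen by
#' file extension (`.tsv`/`.txt` read as tab-separated, anything else as
#' comma-separated).
#'
#' @param path file to read.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"samples_in_columns"`.
#' @param axis_unit unit recorded on the returned dataset.
#' @return A [spectral_dataset()].
#' @seealso [write_spectra()], [read_spectra_long()]
#' @export
read_spectra <- function(path,
                         orientation = c("samples_in_rows",
                                         "samples_in_columns"),
                         axis_unit = "cm-1") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","

  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      fill = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) {
      stop("could not parse ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )

  if (orientation == "samples_in_columns") {
    # first column = axis plus two metadata rows; transpose to wide.
    first <- df[[1]]
    meta_rows <- first %in% c("sample_id", "label")
    if (sum(meta_rows) < 1 || !"label" %in% first) {
      stop("schema error: transposed layout needs a `label` row.",
           call. = FALSE)
    }
    axis <- suppressWarnings(as.numeric(first[!meta_rows]))
    if (anyNA(axis)) {
      stop("parse error: non-numeric axis value in first column.",
           call. = FALSE)
    }
    body <- df[, -1, drop = FALSE]
    labels <- unlist(body[first == "label", ], use.names = FALSE)
    ids <- if ("sample_id" %in% first) {
      unlist(body[first == "sample_id", ], use.names = FALSE)
    } else {
      colnames(body)
    }
    ab <- t(apply(body[!meta_rows, , drop = FALSE], 2, function(col) {
      v <- suppressWarnings(as.numeric(col))
      if (anyNA(v)) stop("parse error: non-numeric absorbance value.",
                         call. = FALSE)
      v
    }))
    return(spectral_dataset(ab, axis, labels, ids, axis_unit))
  }

  if (!"label" %in% names(df)) {
    stop("schema error: no `label` column in ", path, call. = FALSE)
  }
  labels <- as.character(df[["label"]])
  ids <- if ("sample_id" %in% names(df)) as.character(df[["sample_id"]])
         else NULL
  spec_cols <- setdiff(names(df), c("sample_id", "label"))
  axis <- suppressWarnings(as.numeric(spec_cols))
  if (anyNA(axis)) {
    bad <- spec_cols[is.na(axis)]
    stop("parse error: non-numeric axis header field(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  ab <- as.matrix(df[, spec_cols, drop = FALSE])
  if (!is.numeric(ab)) {
    bad <- which(!vapply(df[spec_cols], is.numeric, logical(1)))
    stop("parse error: non-numeric absorbance cell in column ",
         spec_cols[bad[1]], call. = FALSE)
  }
  dimnames(ab) <- NULL
  spectral_dataset(ab, axis, labels, ids, axis_unit)
}

#' Write a spectral dataset to a delimited text file
#'
#' Writes the wide `samples_in_rows` layout read back by [read_spectra()]:
#' header `sample_id,label,<axis values>`, one row per sample. Numeric
#' values are printed with 17 significant digits so the
#' write-then-read round trip is lossless.
#'
#' @param ds a [spectral_dataset()].
#' @param path destination file; extension `.tsv`/`.txt` selects tabs.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  header <- c("sample_id", "label", sprintf("%.17g", ds$axis))
  body <- cbind(ds$sample_ids, ds$labels,
                matrix(sprintf("%.17g", ds$absorbance),
                       nrow = n_samples(ds)))
  lines <- c(paste(header, collapse = sep),
             apply(body, 1, paste, collapse = sep))
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  ok <- tryCatch({ writeLines(lines, con); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("I/O error writing ", path, call. = FALSE)
  invisible(path)
}

#' Read long-format spectra
#'
#' Interoperability reader for tidy long tables with columns
#' `sample_id`, `wavelength` (or `axis`), `absorbance`, `label`.
#'
#' @inheritParams read_spectra
#' @return A [spectral_dataset()].
#' @export
read_spectra_long <- function(path, axis_unit = "cm-1") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  axis_col <- intersect(c("wavelength", "wavenumber", "axis"), names(df))[1]
  need <- c("sample_id", "absorbance", "label")
  if (is.na(axis_col) || !all(need %in% names(df))) {
    stop("schema error: long format needs sample_id, wavelength/axis, ",
         "absorbance, label columns.", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(df, id_cols = c("sample_id", "label"),
                             names_from = dplyr::all_of(axis_col),
                             values_from = "absorbance")
  ab <- as.matrix(wide[, -(1:2)])
  axis <- as.numeric(colnames(ab))
  ord <- order(match(wide$sample_id, unique(df$sample_id)))
  spectral_dataset(ab[ord, , drop = FALSE], axis, wide$label[ord],
                   wide$sample_id[ord], axis_unit)
}
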