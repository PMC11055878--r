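#' Read a single-molecule localization table
#'
#' Reads a delimited-text localization table (comma- or tab-separated, one
#' header line) with columns `frame`, `x`, `y` and optionally `intensity`
#' (coordinates in nm; frame indices 1-based with odd/even parity carrying
#' the stroboscopic pair structure). Records are returned sorted by frame,
#' preserving file order within a frame.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return A tibble with columns `frame`, `x`, `y`, `intensity`.
#' @export
read_localizations <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("localization file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("frame", "x", "y")) {
    if (!col %in% names(tbl)) {
      stop(sprintf("localization table '%s' is missing required column '%s'", path, col))
    }
  }
  if (!"intensity" %in% names(tbl)) tbl$intensity <- NA_real_
  tbl <- tbl[, c("frame", "x", "y", "intensity")]
  if (nrow(tbl) > 0) {
    if (any(!is.finite(tbl$x)) || any(!is.finite(tbl$y))) {
      stop("localization table contains non-finite coordinates")
    }
    if (any(tbl$frame < 1)) stop("localization table contains frame indices < 1")
    tbl$frame <- as.integer(tbl$frame)
    tbl <- tbl[order(tbl$frame), ]
  } else {
    tbl$frame <- integer(0)
  }
  tibble::as_tibble(tbl)
}

#' Write a localization table
#'
#' Writes the delimited-text format that [read_localizations()] reads back
#' (round-trip safe at full double precision).
#'
#' @param records Tibble/data frame with `frame`, `x`, `y` and optionally
#'   `intensity`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(records, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(all(c("frame", "x", "y") %in% names(records)))
  if (!"intensity" %in% names(records)) records$intensity <- NA_real_
  records <- records[, c("frame", "x", "y", "intensity")]
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  writer(records, path, progress = FALSE)
  invisible(path)
}

#' Write a displacement table
#'
#' @param displacements Tibble as produced by [pair_displacements()]
#'   (optionally with `region`/`cell` columns added downstream).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_displacements <- function(displacements, path) {
  readr::write_csv(displacements, path, progress = FALSE)
  invisible(path)
}

#' Read a displacement table written by [write_displacements()]
#' @param path File path.
#' @return A tibble.
#' @export
read_displacements <- function(path) {
  if (!file.exists(path)) stop("displacement file not found: ", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
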