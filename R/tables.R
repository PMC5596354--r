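# CSV output of the per-cell intensity tables. Full-precision writing so a
# write/read round trip reproduces values exactly.

#' Write per-cell intensity tables to CSV
#'
#' Writes two files: `<stem>_cells.csv` with one row per (ommatidium, cell,
#' slice) and `<stem>_summary.csv` with one row per (ommatidium, cell,
#' summary mode). Numeric values are written at full double precision.
#'
#' @param result a `ccrit_result` from [run_ccrit()], or a list with `cells`
#'   and `summaries` tibbles
#' @param stem output path stem (directory must exist)
#' @return named character vector of the two paths, invisibly
#' @export
write_cell_table <- function(result, stem) {
  cells <- result$cells
  summaries <- result$summaries
  if (is.null(cells) || nrow(cells) == 0L) {
    ccrit_abort("result has no per-cell rows", "io_error")
  }
  cells_path <- paste0(stem, "_cells.csv")
  summary_path <- paste0(stem, "_summary.csv")
  out <- cells[, c("ommatidium_label", "cell_number", "slice_index",
                   "integrated_intensity")]
  ok <- try({
    write.csv.full(out, cells_path)
    write.csv.full(summaries[, c("ommatidium_label", "cell_number", "mode",
                                 "mean", "sd")], summary_path)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    ccrit_abort(sprintf("could not write tables at stem '%s'", stem), "io_error")
  }
  invisible(c(cells = cells_path, summary = summary_path))
}

#' Full-precision CSV writer
#' @noRd
write.csv.full <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read tables written by [write_cell_table()]
#'
#' @param stem the path stem used when writing
#' @return list with `cells` and `summaries` tibbles
#' @export
read_cell_table <- function(stem) {
  cells_path <- paste0(stem, "_cells.csv")
  summary_path <- paste0(stem, "_summary.csv")
  if (!file.exists(cells_path) || !file.exists(summary_path)) {
    ccrit_abort(sprintf("no tables found at stem '%s'", stem), "io_error")
  }
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  summaries <- utils::read.csv(summary_path, stringsAsFactors = FALSE)
  list(
    cells = tibble::as_tibble(cells),
    summaries = tibble::as_tibble(summaries)
  )
}
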