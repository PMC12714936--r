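#' Write result tables to CSV files and a JSON bundle
#'
#' Each table becomes `<name>.csv` under `dir`, and all tables are also
#' bundled into a single `report.json` for programmatic consumption. Row
#' order is preserved; channel indices in human-facing tables are 1-based
#' ("Ch 1").
#'
#' @param tables Named, non-empty list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(tables, dir) {
  if (!is.list(tables) || length(tables) == 0L)
    stop("tables must be a non-empty named list of data frames")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("every table must be named")
  if (!all(vapply(tables, is.data.frame, TRUE)))
    stop("every table must be a data frame")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(tables, jp, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read back a JSON report bundle
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return Named list of data frames.
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(out, as.data.frame)
}
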