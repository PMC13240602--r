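#' Write a forcing table to CSV
#'
#' Plain-text interchange format: a commented header records the monthly
#' burn climatology and the nominal cell area, followed by the long
#' cell-year table. [read_forcing()] round-trips it exactly.
#'
#' @param forcing A [carbon_forcing()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(forcing, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# monthly_weights: ",
           paste(format(attr(forcing, "monthly_weights"), digits = 15),
                 collapse = ",")),
    paste0("# cell_area: ",
           format(attr(forcing, "cell_area"), digits = 15))), con)
  utils::write.csv(as.data.frame(forcing), con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a forcing table
#'
#' Reads the CSV dialect written by [write_forcing()] and validates it
#' through [carbon_forcing()]: required columns must be present (a missing
#' column is named in the error), numeric fields must be finite, fractions
#' must lie in [0, 1] with burned + harvested <= 1 per cell-year.
#'
#' @param path File path.
#' @return A [carbon_forcing()] object.
#' @export
read_forcing <- function(path) {
  if (!file.exists(path)) stop("forcing file not found: ", path)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key, default) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(ln)) return(default)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]),
                        ",")[[1]])
  }
  mw <- grab("monthly_weights", default_burn_climatology())
  ca <- grab("cell_area", NULL)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  carbon_forcing(df, monthly_weights = mw, cell_area = ca)
}
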