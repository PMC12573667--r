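#' Write a dose map as a plain-text matrix
#'
#' Writes the dose grid as whitespace-separated values preceded by
#' header comment lines (`# key: value`) carrying the pixel spacing and
#' labels, so a map round-trips through [read_dose_map()] without a
#' sidecar file.
#'
#' @param map a [dose_map()].
#' @param file output path.
#' @export
write_dose_map <- function(map, file) {
  stopifnot(inherits(map, "dose_map"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# spacing_mm: %.10g", map$spacing),
    sprintf("# pattern: %s", map$pattern),
    sprintf("# nominal_dose_gy: %.10g", map$nominal_dose),
    sprintf("# flask_id: %s", map$flask_id)
  ), con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE)
}

#' Read a dose map written by [write_dose_map()]
#'
#' @param file input path.
#' @return a [dose_map()].
#' @export
read_dose_map <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  values <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)]))
  dimnames(values) <- NULL
  dose_map(values, as.numeric(get("spacing_mm")),
           pattern = get("pattern"),
           nominal_dose = as.numeric(get("nominal_dose_gy")),
           flask_id = get("flask_id"))
}

#' Write colony centroids as CSV
#'
#' Columns: `flask_id`, `x_mm`, `y_mm`.
#'
#' @param colonies a `colony_set`.
#' @param file output path.
#' @export
write_colony_csv <- function(colonies, file) {
  df <- data.frame(flask_id = attr(colonies, "flask_id") %||% NA_character_,
                   x_mm = colonies$x_mm, y_mm = colonies$y_mm)
  utils::write.csv(df, file, row.names = FALSE)
}

#' Read colony centroids from CSV
#'
#' Expects `x_mm`/`y_mm` (millimetre) or `x_px`/`y_px` (pixel)
#' coordinate columns; pixel input should then pass through
#' [register_to_common_frame()] with the scan resolution.
#'
#' @param file input path.
#' @return data.frame of centroids.
#' @export
read_colony_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Write a quadrat analysis table as CSV
#'
#' @param table a `quadrat_table`.
#' @param file output path.
#' @export
write_quadrat_csv <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
}

#' Read a quadrat analysis table from CSV
#'
#' @param file input path.
#' @param quadrat_size quadrat side, mm, stored as an attribute.
#' @return a `quadrat_table`.
#' @export
read_quadrat_csv <- function(file, quadrat_size = 1) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  attr(out, "quadrat_size") <- quadrat_size
  class(out) <- c("quadrat_table", "data.frame")
  out
}
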