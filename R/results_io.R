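# Tabular output: one results row per processed pattern, written as CSV
# (UTF-8, '.' decimal) rather than a spreadsheet format.

results_columns <- c("source", "centre_row", "centre_col",
                     "d_period_nm", "fibril_diameter_nm",
                     "bragg_spacing_nm", "order_param",
                     "bragg_spacing_comp_nm", "order_param_comp",
                     "stages_run", "error")

#' Assemble a results row
#'
#' @param source pattern identifier.
#' @param centre numeric `(row, col)` or `NULL`.
#' @param params a `structure_params` object (see
#'   [compute_structure_params()]) or `NULL`.
#' @param stages_run character vector of completed stage names.
#' @param error error message for a failed pattern, or `NA`.
#' @return A one-row `data.frame` with the stable results column order.
#' @export
results_row <- function(source, centre = NULL, params = NULL,
                        stages_run = character(), error = NA_character_) {
  num <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
  p <- function(field) if (is.null(params)) NA_real_ else num(params[[field]])
  data.frame(source = as.character(source),
             centre_row = num(centre[1]), centre_col = num(centre[2]),
             d_period_nm = p("d_period_nm"),
             fibril_diameter_nm = p("fibril_diameter_nm"),
             bragg_spacing_nm = p("bragg_spacing_nm"),
             order_param = p("order_param"),
             bragg_spacing_comp_nm = p("bragg_spacing_comp_nm"),
             order_param_comp = p("order_param_comp"),
             stages_run = paste(stages_run, collapse = ";"),
             error = error,
             stringsAsFactors = FALSE)
}

#' Write results rows to CSV
#'
#' One header line plus one line per pattern, stable column order, numbers
#' at full (>= 6 significant digit) precision, absent values as empty cells.
#'
#' @param rows a `data.frame` of results rows (see [results_row()]) or a
#'   list of such rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    saxs_validation_error("rows must be a nonempty data frame")
  rows <- rows[, intersect(results_columns, names(rows)), drop = FALSE]
  fmt <- function(x) {
    out <- if (is.numeric(x)) trimws(formatC(x, digits = 10, format = "g"))
           else as.character(x)
    out[is.na(x)] <- ""
    out
  }
  rows[] <- lapply(rows, fmt)
  tryCatch(
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE),
    error = function(e) saxs_io_error(paste0("cannot write: ", path)))
  invisible(path)
}

#' Write an orientation profile to CSV
#'
#' Two columns: azimuth in degrees and aligned intensity.
#'
#' @param angles numeric vector of azimuths (degrees), strictly increasing.
#' @param aligned numeric vector, same length.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_orientation_profile <- function(angles, aligned, path) {
  if (length(angles) != length(aligned))
    saxs_validation_error("angles and aligned must have equal length")
  if (length(angles) > 1L && any(diff(angles) <= 0))
    saxs_validation_error("angles must be monotonically increasing")
  df <- data.frame(angle_deg = angles, aligned_intensity = aligned)
  tryCatch(utils::write.csv(df, path, row.names = FALSE, na = "",
                            quote = FALSE),
           error = function(e) saxs_io_error(paste0("cannot write: ", path)))
  invisible(path)
}
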