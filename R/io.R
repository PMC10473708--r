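STATE_CSV_COLUMNS <- c("protein", "start", "end", "sequence", "max_uptake",
                       "state", "exposure_s", "bio_rep", "tech_rep",
                       "centroid_da")

#' Write a state-data CSV
#'
#' One row per peptide x state x exposure x replicate. Exposure is written in
#' seconds; the undeuterated reference uses `0` and the fully-deuterated
#' control the literal token `FD`.
#'
#' @param data State-data tibble (with `is_fd` logical column).
#' @param path Output file.
#' @param header Optional character vector written as leading `#` comment
#'   lines.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(data, path, header = NULL) {
  out <- data |>
    mutate(exposure_s = ifelse(.data$is_fd, "FD",
                               format(.data$exposure_s, trim = TRUE,
                                      scientific = FALSE))) |>
    select(dplyr::all_of(STATE_CSV_COLUMNS))
  write_csv_with_header(out, path, header)
}

#' Read and validate a state-data CSV
#'
#' Parses the comma-separated state-data layout (header row mandatory;
#' `#`-prefixed leading lines are skipped), checks column presence, exposure
#' tokens (numerals or the `FD` sentinel), peptide-metadata consistency and
#' replicate-key uniqueness, and reports row counts and missing-control
#' warnings.
#'
#' @param path CSV file.
#' @param quiet Suppress the validation summary message?
#' @return Validated state-data tibble (`exposure_s` numeric with `NA` on FD
#'   rows, plus the logical `is_fd`), with the validation report in
#'   `attr(, "validation")`.
#' @export
read_state_csv <- function(path, quiet = FALSE) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           exposure_s = readr::col_character(),
                           .default = readr::col_guess()))
  missing_cols <- setdiff(STATE_CSV_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("State CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hdxdiff_parse_error")
  }

  tok <- stringr::str_trim(raw$exposure_s)
  is_fd <- tok == "FD"
  num <- suppressWarnings(as.numeric(tok))
  bad <- which(!is_fd & is.na(num))
  if (length(bad) > 0L) {
    abort(paste0("Malformed exposure token(s) at data row(s): ",
                 paste(utils::head(bad, 10L), collapse = ", "),
                 " (expected a number of seconds or 'FD')."),
          class = "hdxdiff_parse_error")
  }
  data <- raw |>
    mutate(exposure_s = ifelse(is_fd, NA_real_, num), is_fd = is_fd)

  dup <- data |>
    dplyr::count(.data$protein, .data$start, .data$end, .data$sequence,
                 .data$state, .data$exposure_s, .data$is_fd,
                 .data$bio_rep, .data$tech_rep) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("%d duplicated (peptide, state, exposure, replicate) key(s) in %s.",
                  nrow(dup), path),
          class = "hdxdiff_parse_error")
  }

  meta <- distinct(data, .data$protein, .data$start, .data$end,
                   .data$sequence, .data$max_uptake)
  clash <- meta |> dplyr::count(.data$protein, .data$start, .data$end) |>
    filter(.data$n > 1L)
  if (nrow(clash) > 0L) {
    abort("Conflicting sequence/max_uptake metadata for the same peptide coordinates.",
          class = "hdxdiff_parse_error")
  }
  bad_len <- filter(meta, nchar(.data$sequence) != .data$end - .data$start + 1L)
  if (nrow(bad_len) > 0L) {
    abort("Peptide sequence length inconsistent with start/end coordinates.",
          class = "hdxdiff_parse_error")
  }

  controls <- data |>
    distinct(.data$protein, .data$start, .data$end, .data$state) |>
    left_join(
      data |> group_by(.data$protein, .data$start, .data$end, .data$state) |>
        summarise(has_t0 = any(!.data$is_fd & .data$exposure_s == 0),
                  has_fd = any(.data$is_fd), .groups = "drop"),
      by = c("protein", "start", "end", "state"))
  no_t0 <- filter(controls, !.data$has_t0)
  no_fd <- filter(controls, !.data$has_fd)
  warnings <- character()
  if (nrow(no_t0) > 0L) {
    warnings <- c(warnings, paste0(
      "No t=0 reference rows for: ",
      paste(sprintf("%d-%d (%s)", no_t0$start, no_t0$end, no_t0$state),
            collapse = "; ")))
  }
  if (nrow(no_fd) > 0L) {
    warnings <- c(warnings, paste0(
      "No FD control rows for: ",
      paste(sprintf("%d-%d (%s)", no_fd$start, no_fd$end, no_fd$state),
            collapse = "; ")))
  }
  for (w in warnings) warn(w)

  report <- list(
    n_rows = nrow(data),
    n_peptides = nrow(meta),
    rows_per_state = dplyr::count(data, .data$state),
    rows_per_exposure = dplyr::count(data, .data$exposure_s, .data$is_fd),
    replicates = dplyr::summarise(data, n_bio = dplyr::n_distinct(.data$bio_rep),
                                  n_tech = dplyr::n_distinct(.data$tech_rep)),
    warnings = warnings
  )
  if (!quiet) {
    inform(sprintf("Read %d rows: %d peptide(s), %d state(s), %d warning(s).",
                   report$n_rows, report$n_peptides,
                   nrow(report$rows_per_state), length(warnings)))
  }
  attr(data, "validation") <- report
  data
}

#' Export Woods-plot data
#'
#' Writes everything needed to redraw a peptide-level differential plot:
#' one row per peptide x exposure with span coordinates, midpoint, delta,
#' the symmetric confidence limits, significance and direction.
#'
#' @param records An `hdx_differential`.
#' @param path Output CSV; `NULL` returns the table without writing.
#' @param header Optional `#` comment lines.
#' @return The export tibble, invisibly when written.
#' @export
export_woods <- function(records, path = NULL, header = NULL) {
  if (nrow(records) == 0L) {
    abort("No differential records to export.", class = "hdxdiff_input_error")
  }
  out <- records |>
    as_tibble() |>
    mutate(midpoint = (.data$start + .data$end) / 2,
           cl_pos = .data$cl, cl_neg = -.data$cl) |>
    select("start", "end", "midpoint", "exposure_s", "delta_pct",
           "cl_pos", "cl_neg", "significant", "direction")
  if (is.null(path)) return(out)
  write_csv_with_header(out, path, header)
  invisible(out)
}

# Shared writer for pipeline outputs: CSV body under "# " comment lines.
write_csv_with_header <- function(data, path, header = NULL) {
  body <- strsplit(readr::format_csv(data), "\n", fixed = TRUE)[[1]]
  lines <- c(if (length(header) > 0L) paste0("# ", header), body)
  readr::write_lines(lines, path)
  invisible(path)
}
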