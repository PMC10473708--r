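#' Percent exchange of a centroid measurement
#'
#' Normalizes a labeled centroid mass against the undeuterated reference and
#' the fully-deuterated control of the same peptide:
#' `%EX = (m_t - m_0) / (m_f - m_0) * 100`. Because a uniform back-exchange
#' loss scales numerator and denominator alike, %EX is back-exchange
#' corrected by construction. Values slightly below 0 or above 100 arising
#' from measurement noise are preserved unless `clip = TRUE`.
#'
#' @param m_t Centroid mass at exposure t (Da). Vectorized.
#' @param m_0 Undeuterated reference centroid (Da).
#' @param m_f Fully-deuterated control centroid (Da); must exceed `m_0`.
#' @param clip Clip results into `[0, 100]`? Default `FALSE`.
#' @return Percent exchange.
#' @examples
#' percent_exchange(1004, 1000, 1010) # 40
#' @export
percent_exchange <- function(m_t, m_0, m_f, clip = FALSE) {
  if (any(m_f <= m_0)) {
    abort("Fully-deuterated control does not exceed the undeuterated reference (m_f <= m_0).",
          class = "hdxdiff_degenerate_control")
  }
  out <- (m_t - m_0) / (m_f - m_0) * 100
  if (clip) out <- pmin(pmax(out, 0), 100)
  out
}

# Per peptide x state control means: m_0 from t = 0 rows, m_f from FD rows.
# Errors (naming peptides) when either control is missing or degenerate.
control_means <- function(data) {
  key <- c("protein", "start", "end", "sequence", "max_uptake", "state")
  m0 <- data |>
    filter(!.data$is_fd, .data$exposure_s == 0) |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(m0 = mean(.data$centroid_da), .groups = "drop")
  mf <- data |>
    filter(.data$is_fd) |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(mf = mean(.data$centroid_da), .groups = "drop")
  peps <- distinct(data, across(dplyr::all_of(key)))
  ctl <- peps |> left_join(m0, by = key) |> left_join(mf, by = key)
  missing <- filter(ctl, is.na(.data$m0) | is.na(.data$mf))
  if (nrow(missing) > 0L) {
    abort(paste0("Missing t=0 or FD control rows for peptide(s): ",
                 paste(sprintf("%s %d-%d (%s)", missing$protein,
                               missing$start, missing$end, missing$state),
                       collapse = "; ")),
          class = "hdxdiff_degenerate_control")
  }
  degen <- filter(ctl, .data$mf <= .data$m0)
  if (nrow(degen) > 0L) {
    abort(paste0("FD control does not exceed t=0 reference for peptide(s): ",
                 paste(sprintf("%s %d-%d (%s)", degen$protein,
                               degen$start, degen$end, degen$state),
                       collapse = "; ")),
          class = "hdxdiff_degenerate_control")
  }
  ctl
}

#' Aggregate replicate centroids into uptake and percent-exchange summaries
#'
#' For every peptide x state x exposure cell, technical measurements are
#' first averaged within each biological replicate, the biological-replicate
#' means are then averaged, and the reported standard deviations are taken
#' across the biological-replicate means (n - 1 denominator). This nested
#' scheme reflects a design of independent biological repeats, each measured
#' in technical replicate; with a balanced design the nested mean equals the
#' flat mean. Uptake is `centroid - mean(m_0)`; percent exchange is computed
#' from the aggregated masses with [percent_exchange()].
#'
#' @param data State-data tibble (from [simulate_centroids()] or
#'   [read_state_csv()]).
#' @param pooled_technical If `TRUE`, dispersions are instead computed across
#'   all individual measurements of the cell (flat pooling), for sensitivity
#'   analysis. The means are unaffected.
#' @param clip Passed to [percent_exchange()].
#' @return A tibble with one row per peptide x state x exposure:
#'   `mean_uptake`, `sd_uptake` (Da), `mean_pct_ex`, `sd_pct_ex` (%),
#'   `n_bio`, `n_total`, plus the control means `m0`, `mf`.
#' @export
aggregate_replicates <- function(data, pooled_technical = FALSE, clip = FALSE) {
  ctl <- control_means(data)
  key <- c("protein", "start", "end", "sequence", "max_uptake", "state")

  labeled <- data |>
    filter(!.data$is_fd, .data$exposure_s > 0) |>
    left_join(ctl, by = key)

  bio <- labeled |>
    group_by(across(dplyr::all_of(c(key, "exposure_s", "m0", "mf"))),
             .data$bio_rep) |>
    summarise(bio_centroid = mean(.data$centroid_da),
              n_tech = n(), .groups = "drop_last")

  out <- bio |>
    summarise(
      mean_centroid = mean(.data$bio_centroid),
      sd_uptake = sd(.data$bio_centroid),
      n_bio = n(),
      n_total = sum(.data$n_tech),
      .groups = "drop"
    )

  if (pooled_technical) {
    flat <- labeled |>
      group_by(across(dplyr::all_of(c(key, "exposure_s")))) |>
      summarise(sd_flat = sd(.data$centroid_da), .groups = "drop")
    out <- out |>
      left_join(flat, by = c(key, "exposure_s")) |>
      mutate(sd_uptake = .data$sd_flat) |>
      select(-"sd_flat")
  }

  out |>
    mutate(
      mean_uptake = .data$mean_centroid - .data$m0,
      mean_pct_ex = percent_exchange(.data$mean_centroid, .data$m0, .data$mf,
                                     clip = clip),
      sd_pct_ex = .data$sd_uptake / (.data$mf - .data$m0) * 100
    ) |>
    select(dplyr::all_of(key), "exposure_s", "mean_uptake", "sd_uptake",
           "mean_pct_ex", "sd_pct_ex", "n_bio", "n_total", "m0", "mf") |>
    arrange(.data$state, .data$start, .data$end, .data$exposure_s)
}

#' Estimate dataset back-exchange from the fully-deuterated control
#'
#' Back-exchange is the deuterium lost between quench and measurement. It is
#' estimated per peptide as the FD-control deficit relative to the theoretical
#' maximum uptake, `BE = 1 - (m_f - m_0) / (max_uptake * f_D * mass_shift)`,
#' and reported as the unweighted mean across peptides, per state.
#'
#' @param data State-data tibble with FD control rows.
#' @param f_D Deuterium fraction of the labeling buffer (default 0.95,
#'   a 20-fold dilution into deuterated buffer).
#' @param mass_shift_per_D Mass increment per retained deuteron (Da).
#' @return Tibble with `state`, `back_exchange_pct`, `n_peptides`.
#' @export
estimate_back_exchange <- function(data, f_D = 0.95,
                                   mass_shift_per_D = MASS_SHIFT_PER_D) {
  if (!any(data$is_fd)) {
    abort("No fully-deuterated control rows in the table.",
          class = "hdxdiff_degenerate_control")
  }
  control_means(data) |>
    filter(.data$max_uptake > 0) |>
    mutate(be = 1 - (.data$mf - .data$m0) /
             (.data$max_uptake * f_D * mass_shift_per_D)) |>
    group_by(.data$state) |>
    summarise(back_exchange_pct = 100 * mean(.data$be),
              n_peptides = n(), .groups = "drop")
}

#' Dataset quality-control summary
#'
#' Computes the standard HDX-MS map and repeatability metrics, per state:
#' number of distinct peptides, sequence coverage, mean peptide length,
#' per-residue redundancy (mean peptide depth over covered residues),
#' repeatability (the unweighted mean of replicate standard deviations over
#' all peptide x exposure cells, in Da and in %), and back-exchange.
#'
#' @param data State-data tibble.
#' @param protein_length Full construct length in residues; must be at least
#'   the largest peptide end coordinate.
#' @param f_D Deuterium fraction, passed to [estimate_back_exchange()].
#' @param pooled_technical Passed to [aggregate_replicates()].
#' @return Tibble with one row per state: `n_peptides`, `coverage_pct`,
#'   `avg_peptide_length`, `redundancy`, `repeatability_da`,
#'   `repeatability_pct`, `back_exchange_pct`.
#' @export
qc_summary <- function(data, protein_length, f_D = 0.95,
                       pooled_technical = FALSE) {
  if (protein_length < max(data$end)) {
    abort("`protein_length` is smaller than the largest peptide end.",
          class = "hdxdiff_coordinate_error")
  }
  summaries <- aggregate_replicates(data, pooled_technical = pooled_technical)
  be <- estimate_back_exchange(data, f_D = f_D)

  map_stats <- data |>
    distinct(.data$state, .data$protein, .data$start, .data$end) |>
    tidyr::nest(peps = c("protein", "start", "end")) |>
    mutate(stats = purrr::map(.data$peps, function(p) {
      depth <- residue_depth(p, protein_length)
      covered <- depth > 0L
      tibble(
        n_peptides = nrow(p),
        coverage_pct = 100 * mean(covered),
        avg_peptide_length = mean(p$end - p$start + 1),
        redundancy = mean(depth[covered])
      )
    })) |>
    select("state", "stats") |>
    tidyr::unnest("stats")

  rep_stats <- summaries |>
    group_by(.data$state) |>
    summarise(repeatability_da = mean(.data$sd_uptake, na.rm = TRUE),
              repeatability_pct = mean(.data$sd_pct_ex, na.rm = TRUE),
              .groups = "drop")

  map_stats |>
    left_join(rep_stats, by = "state") |>
    left_join(select(be, "state", "back_exchange_pct"), by = "state")
}
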