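#' Dataset repeatability: average replicate standard deviation
#'
#' The noise scale that sets the global confidence limit: the unweighted mean
#' of the replicate standard deviations over all peptide x exposure cells of
#' a state's dataset, in mass units and in percent-exchange units.
#'
#' @param summaries Uptake summaries from [aggregate_replicates()].
#' @return Tibble with `state`, `s_da`, `s_pct`, `n_cells`.
#' @export
hdx_repeatability <- function(summaries) {
  ok <- filter(summaries, .data$n_bio >= 2, !is.na(.data$sd_uptake))
  if (nrow(ok) == 0L) {
    abort("No peptide x exposure cell with >= 2 biological replicates.",
          class = "hdxdiff_insufficient_replication")
  }
  ok |>
    group_by(.data$state) |>
    summarise(s_da = mean(.data$sd_uptake),
              s_pct = mean(.data$sd_pct_ex),
              n_cells = n(), .groups = "drop")
}

#' Global significance limit for differential exchange
#'
#' Pools the two datasets' average replicate standard deviations in
#' quadrature and scales by a critical multiplier:
#' `limit = multiplier * sqrt(s_A^2 + s_B^2)`. With the default multiplier
#' 2.32 (the large-sample two-sided 98% critical value) this is the global
#' 98% confidence limit for a per-cell difference between two state means.
#' Works in Da or in %, whichever units the inputs share.
#'
#' @param s_a,s_b Average replicate SDs of the two states (same units).
#' @param multiplier Critical multiplier (default 2.32).
#' @return The significance limit, in the units of the inputs.
#' @examples
#' global_significance_limit(0.129, 0.111) # 0.395 Da
#' global_significance_limit(2.28, 2.09)   # 7.18 %
#' @export
global_significance_limit <- function(s_a, s_b, multiplier = 2.32) {
  if (any(s_a < 0) || any(s_b < 0)) {
    abort("Standard deviations must be non-negative.",
          class = "hdxdiff_input_error")
  }
  stopifnot(multiplier > 0)
  multiplier * sqrt(s_a^2 + s_b^2)
}

#' Differential percent exchange between two states
#'
#' Computes `delta_pct = %EX(state_a) - %EX(state_b)` for every peptide x
#' exposure cell the two states share, together with the global confidence
#' limit built from both states' repeatability. By convention `state_a` is
#' the wild type, so a positive delta means the region is more stabilized
#' (exchanges less) in `state_b`, and a negative delta means it is
#' destabilized there. A cell is significant when `|delta_pct|` strictly
#' exceeds the limit. Peptides present in only one state are reported in
#' `attr(, "mismatch")`, never silently dropped.
#'
#' @param summaries Uptake summaries from [aggregate_replicates()] containing
#'   both states.
#' @param state_a,state_b State labels; default to the first two states in
#'   the table (in order of appearance), with `state_a` the reference.
#' @param multiplier Critical multiplier for [global_significance_limit()].
#' @return An `hdx_differential` tibble: one row per common peptide x
#'   exposure with `pct_ex_a`, `pct_ex_b`, `delta_pct`, `cl`, `significant`,
#'   `direction`. Attributes: `cl_pct`, `cl_da`, `states`, `multiplier`,
#'   `repeatability`, `mismatch`.
#' @export
differential_uptake <- function(summaries, state_a = NULL, state_b = NULL,
                                multiplier = 2.32) {
  states <- unique(summaries$state)
  state_a <- state_a %||% states[1]
  state_b <- state_b %||% setdiff(states, state_a)[1]
  if (is.na(state_b) || !all(c(state_a, state_b) %in% states)) {
    abort("Need two states present in `summaries`.",
          class = "hdxdiff_input_error")
  }

  rep_tab <- hdx_repeatability(
    filter(summaries, .data$state %in% c(state_a, state_b)))
  ra <- filter(rep_tab, .data$state == state_a)
  rb <- filter(rep_tab, .data$state == state_b)
  cl_pct <- global_significance_limit(ra$s_pct, rb$s_pct, multiplier)
  cl_da <- global_significance_limit(ra$s_da, rb$s_da, multiplier)

  key <- c("protein", "start", "end", "sequence", "max_uptake")
  a <- summaries |> filter(.data$state == state_a) |>
    select(dplyr::all_of(key), "exposure_s",
           pct_ex_a = "mean_pct_ex", uptake_a = "mean_uptake")
  b <- summaries |> filter(.data$state == state_b) |>
    select(dplyr::all_of(key), "exposure_s",
           pct_ex_b = "mean_pct_ex", uptake_b = "mean_uptake")

  only_a <- anti_join(distinct(a, across(dplyr::all_of(key))),
                      distinct(b, across(dplyr::all_of(key))), by = key)
  only_b <- anti_join(distinct(b, across(dplyr::all_of(key))),
                      distinct(a, across(dplyr::all_of(key))), by = key)
  mismatch <- bind_rows(
    mutate(only_a, missing_from = state_b),
    mutate(only_b, missing_from = state_a)
  )
  if (nrow(mismatch) > 0L) {
    warn(sprintf("%d peptide(s) present in only one state; see attr(, 'mismatch').",
                 nrow(mismatch)))
  }

  records <- inner_join(a, b, by = c(key, "exposure_s"))
  if (nrow(records) == 0L) {
    abort("The two states share no peptide x exposure cells.",
          class = "hdxdiff_alignment_error")
  }

  records <- records |>
    mutate(
      delta_pct = .data$pct_ex_a - .data$pct_ex_b,
      delta_da = .data$uptake_a - .data$uptake_b,
      cl = cl_pct,
      significant = abs(.data$delta_pct) > cl_pct,
      direction = dplyr::case_when(
        .data$delta_pct > cl_pct ~ "stabilized",
        .data$delta_pct < -cl_pct ~ "destabilized",
        TRUE ~ "unchanged"
      )
    ) |>
    arrange(.data$start, .data$end, .data$exposure_s)

  structure(records,
            class = c("hdx_differential", class(records)),
            cl_pct = cl_pct, cl_da = cl_da,
            states = c(a = state_a, b = state_b),
            multiplier = multiplier,
            repeatability = rep_tab,
            mismatch = mismatch)
}

#' @export
print.hdx_differential <- function(x, ...) {
  st <- attr(x, "states")
  cat(sprintf("<hdx_differential> %s - %s: %d peptide x exposure cells\n",
              st[["a"]], st[["b"]], nrow(x)))
  cat(sprintf("  global limit: %.2f %%EX (%.3f Da), multiplier %.2f\n",
              attr(x, "cl_pct"), attr(x, "cl_da"), attr(x, "multiplier")))
  cat(sprintf("  significant cells: %d (%.1f%%)\n", sum(x$significant),
              100 * mean(x$significant)))
  NextMethod()
}

#' @rdname differential_uptake
#' @param x An `hdx_differential` object.
#' @param ... Unused.
#' @method tidy hdx_differential
#' @export
tidy.hdx_differential <- function(x, ...) {
  as_tibble(unclass_differential(x))
}

unclass_differential <- function(x) {
  class(x) <- setdiff(class(x), "hdx_differential")
  attr(x, "cl_pct") <- NULL; attr(x, "cl_da") <- NULL
  attr(x, "states") <- NULL; attr(x, "multiplier") <- NULL
  attr(x, "repeatability") <- NULL; attr(x, "mismatch") <- NULL
  x
}

#' @rdname differential_uptake
#' @method glance hdx_differential
#' @export
glance.hdx_differential <- function(x, ...) {
  st <- attr(x, "states")
  tibble(
    state_a = st[["a"]], state_b = st[["b"]],
    cl_pct = attr(x, "cl_pct"), cl_da = attr(x, "cl_da"),
    multiplier = attr(x, "multiplier"),
    n_cells = nrow(x),
    n_peptides = nrow(distinct(as_tibble(x), .data$start, .data$end,
                               .data$sequence)),
    n_significant = sum(x$significant),
    n_mismatch = nrow(attr(x, "mismatch"))
  )
}

#' Classify peptides from their differential records
#'
#' A peptide is called stabilized (destabilized) when its delta exceeds the
#' positive (negative) confidence limit at `min_significant_timepoints` or
#' more exposures; peptides exceeding in both directions are flagged
#' `"mixed"`; all others are `"unchanged"`.
#'
#' @param records An `hdx_differential` (or compatible tibble with
#'   `delta_pct` and `cl`).
#' @param min_significant_timepoints Minimum exceedances required (default 1).
#' @return Tibble with one row per peptide: coordinates, `n_up`, `n_down`,
#'   `label`.
#' @export
classify_peptides <- function(records, min_significant_timepoints = 1L) {
  records |>
    as_tibble() |>
    group_by(.data$protein, .data$start, .data$end, .data$sequence) |>
    summarise(
      n_up = sum(.data$delta_pct > .data$cl),
      n_down = sum(.data$delta_pct < -.data$cl),
      .groups = "drop"
    ) |>
    mutate(label = dplyr::case_when(
      .data$n_up >= min_significant_timepoints &
        .data$n_down >= min_significant_timepoints ~ "mixed",
      .data$n_up >= min_significant_timepoints ~ "stabilized",
      .data$n_down >= min_significant_timepoints ~ "destabilized",
      TRUE ~ "unchanged"
    )) |>
    arrange(.data$start, .data$end)
}

#' Per-residue consensus calls and regions
#'
#' Each residue inherits the most frequent label among the peptides covering
#' it; ties (including a stabilized/destabilized standoff) resolve to
#' `"unchanged"`. Contiguous runs of equal labels are emitted as regions.
#' Residues covered by no peptide are excluded and break runs.
#'
#' @param labels Peptide classification from [classify_peptides()].
#' @param protein_length Construct length; defaults to the largest peptide
#'   end coordinate.
#' @return Tibble of regions (`start`, `end`, `label`), with the per-residue
#'   calls in `attr(, "residues")`.
#' @export
residue_consensus <- function(labels, protein_length = max(labels$end)) {
  lvl <- c("stabilized", "destabilized", "mixed", "unchanged")
  counts <- matrix(0L, protein_length, length(lvl),
                   dimnames = list(NULL, lvl))
  for (i in seq_len(nrow(labels))) {
    idx <- labels$start[i]:labels$end[i]
    counts[idx, labels$label[i]] <- counts[idx, labels$label[i]] + 1L
  }
  depth <- rowSums(counts)
  call <- apply(counts, 1L, function(cnt) {
    m <- max(cnt)
    if (m == 0L) return(NA_character_)
    winners <- lvl[cnt == m]
    if (length(winners) > 1L) "unchanged" else winners
  })

  residues <- tibble(residue = seq_len(protein_length),
                     depth = as.integer(depth), label = call)

  covered <- residues |> filter(!is.na(.data$label))
  regions <- if (nrow(covered) == 0L) {
    tibble(start = integer(), end = integer(), label = character())
  } else {
    covered |>
      mutate(new_run = .data$residue != dplyr::lag(.data$residue, default = -1L) + 1L |
               .data$label != dplyr::lag(.data$label, default = ""),
             run = cumsum(.data$new_run)) |>
      group_by(.data$run) |>
      summarise(start = min(.data$residue), end = max(.data$residue),
                label = .data$label[1], .groups = "drop") |>
      select("start", "end", "label")
  }
  attr(regions, "residues") <- residues
  regions
}

#' Welch test per peptide x exposure (optional hybrid criterion)
#'
#' Welch's two-sample t statistic on the biological-replicate percent-exchange
#' means of the two states, per peptide x exposure cell. Offered as an
#' optional AND-criterion alongside the global confidence limit (the "hybrid"
#' significance test); it never replaces the primary global-limit
#' classification.
#'
#' @param data State-data tibble containing both states with their controls.
#' @param state_a,state_b State labels (defaults as in
#'   [differential_uptake()]).
#' @return Tibble per peptide x exposure: `statistic`, `df`, `p_value`.
#' @export
peptide_welch_test <- function(data, state_a = NULL, state_b = NULL) {
  states <- unique(data$state)
  state_a <- state_a %||% states[1]
  state_b <- state_b %||% setdiff(states, state_a)[1]

  ctl <- control_means(data)
  key <- c("protein", "start", "end", "sequence", "max_uptake", "state")
  bio <- data |>
    filter(!.data$is_fd, .data$exposure_s > 0,
           .data$state %in% c(state_a, state_b)) |>
    left_join(ctl, by = key) |>
    group_by(across(dplyr::all_of(c(key, "exposure_s", "m0", "mf"))),
             .data$bio_rep) |>
    summarise(bio_centroid = mean(.data$centroid_da), .groups = "drop") |>
    mutate(pct_ex = percent_exchange(.data$bio_centroid, .data$m0, .data$mf))

  cells <- bio |>
    group_by(.data$protein, .data$start, .data$end, .data$sequence,
             .data$exposure_s) |>
    tidyr::nest() |>
    ungroup()

  res <- purrr::map(cells$data, function(d) {
    xa <- d$pct_ex[d$state == state_a]
    xb <- d$pct_ex[d$state == state_b]
    if (length(xa) < 2L || length(xb) < 2L) {
      abort("Welch test needs >= 2 biological replicates per state.",
            class = "hdxdiff_insufficient_replication")
    }
    if (sd(xa) == 0 && sd(xb) == 0) {
      # constant replicates: statistic 0 when means agree, infinite otherwise
      eq <- isTRUE(all.equal(mean(xa), mean(xb)))
      return(tibble(statistic = if (eq) 0 else Inf,
                    df = length(xa) + length(xb) - 2,
                    p_value = if (eq) 1 else 0))
    }
    tt <- t.test(xa, xb)
    tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  })

  cells |>
    select(-"data") |>
    dplyr::bind_cols(bind_rows(res)) |>
    arrange(.data$start, .data$end, .data$exposure_s)
}

#' Add the hybrid significance flag
#'
#' AND-combination of the global-limit call with a Welch test at `alpha`:
#' a cell is `significant_hybrid` when it exceeds the global limit *and* its
#' Welch p-value is below `alpha`. The primary `significant` column is left
#' untouched.
#'
#' @param records An `hdx_differential`.
#' @param welch Output of [peptide_welch_test()].
#' @param alpha Welch significance level (default 0.05).
#' @return `records` with `p_value` and `significant_hybrid` columns added.
#' @export
add_hybrid_significance <- function(records, welch, alpha = 0.05) {
  out <- as_tibble(records) |>
    left_join(select(welch, "protein", "start", "end", "sequence",
                     "exposure_s", "p_value"),
              by = c("protein", "start", "end", "sequence", "exposure_s")) |>
    mutate(significant_hybrid = .data$significant & .data$p_value < alpha)
  for (a in c("cl_pct", "cl_da", "states", "multiplier", "repeatability",
              "mismatch")) {
    attr(out, a) <- attr(records, a)
  }
  class(out) <- c("hdx_differential", class(out))
  out
}
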