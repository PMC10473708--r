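#' Define a labeling schedule
#'
#' @param exposures Labeling durations in seconds, strictly increasing.
#' @param include_t0 Emit undeuterated reference rows (exposure 0)?
#' @param include_fd Emit fully-deuterated control rows?
#' @param n_bio Biological replicates.
#' @param n_tech Technical replicates per biological replicate.
#' @return A `labeling_schedule` list.
#' @export
labeling_schedule <- function(exposures = c(10, 60, 600, 3600, 7200),
                              include_t0 = TRUE, include_fd = TRUE,
                              n_bio = 3L, n_tech = 3L) {
  if (any(exposures <= 0) || is.unsorted(exposures, strictly = TRUE)) {
    abort("`exposures` must be strictly positive and strictly increasing.",
          class = "hdxdiff_input_error")
  }
  if (n_bio < 1L || n_tech < 1L) {
    abort("Replicate counts must be >= 1.", class = "hdxdiff_input_error")
  }
  structure(list(exposures = as.numeric(exposures),
                 include_t0 = isTRUE(include_t0),
                 include_fd = isTRUE(include_fd),
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech)),
            class = "labeling_schedule")
}

# Residues of a peptide that contribute deuterium to its centroid:
# peptide positions 2..len, excluding prolines (matches exchangeable_amides).
contributing_residues <- function(start, end, residues) {
  if (start + 1L > end) return(integer(0))
  idx <- (start + 1L):end
  idx[residues[idx] != "P"]
}

#' Simulate peptide centroid masses under EX2 kinetics
#'
#' Forward model: each exchangeable amide i acquires deuterium occupancy
#' `D_i(t) = f_D * (1 - exp(-k_i * t))`, of which a fraction `1 - b` survives
#' back-exchange between quench and measurement. A peptide's centroid at
#' exposure t is `m_0 + mass_shift_per_D * sum_i D_i(t) * (1 - b)` over its
#' contributing residues, and the fully-deuterated (FD) control sits at
#' `m_0 + mass_shift_per_D * max_uptake * f_D * (1 - b)`. Replicate noise is
#' nested: one additive offset per (biological replicate, peptide) with SD
#' `noise_bio_da`, plus an independent per-measurement error with SD
#' `noise_tech_da`. Undeuterated (t = 0) and FD control rows carry technical
#' noise only.
#'
#' @param model An `exchange_model`.
#' @param peptides Peptide tibble from [digest()].
#' @param schedule A [labeling_schedule()].
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param state State label stored in the `state` column.
#' @return A tibble in the state-data layout (`protein`, `start`, `end`,
#'   `sequence`, `max_uptake`, `state`, `exposure_s`, `is_fd`, `bio_rep`,
#'   `tech_rep`, `centroid_da`), with the noise-free ground truth
#'   (per peptide x exposure uptake and percent exchange) in
#'   `attr(, "truth")`.
#' @export
simulate_centroids <- function(model, peptides, schedule = labeling_schedule(),
                               seed = 1L, state = "A") {
  stopifnot(inherits(model, "exchange_model"),
            inherits(schedule, "labeling_schedule"))
  L <- length(model$residues)
  if (any(peptides$start < 1L) || any(peptides$end > L)) {
    abort("Peptide outside the model sequence.",
          class = "hdxdiff_coordinate_error")
  }

  k <- 10^model$log10_k_obs                      # s^-1, NA where no amide
  exposures <- schedule$exposures
  occ <- outer(ifelse(is.na(k), 0, k), exposures,
               function(ki, t) model$f_D * (1 - exp(-ki * t)))

  n_pep <- nrow(peptides)
  uptake_true <- matrix(0, n_pep, length(exposures))  # retained uptake, Da
  for (i in seq_len(n_pep)) {
    idx <- contributing_residues(peptides$start[i], peptides$end[i],
                                 model$residues)
    if (length(idx) > 0L) {
      uptake_true[i, ] <- model$mass_shift_per_D * (1 - model$b) *
        colSums(occ[idx, , drop = FALSE])
    }
  }

  m0 <- vapply(peptides$sequence, peptide_mass, numeric(1), USE.NAMES = FALSE)
  fd_uptake <- model$mass_shift_per_D * (1 - model$b) *
    peptides$max_uptake * model$f_D

  truth <- tidyr::crossing(
    dplyr::select(dplyr::mutate(peptides, .row = dplyr::row_number()),
                  "protein", "start", "end", ".row"),
    exposure_s = exposures
  )
  truth$uptake_da <- uptake_true[cbind(truth$.row,
                                       match(truth$exposure_s, exposures))]
  truth$pct_ex_true <- 100 * truth$uptake_da /
    fd_uptake[truth$.row]
  truth <- dplyr::select(dplyr::mutate(truth, state = state), -".row")

  grid <- tidyr::crossing(
    pep = seq_len(n_pep),
    exposure_s = c(if (schedule$include_t0) 0, exposures,
                   if (schedule$include_fd) NA_real_),
    bio_rep = seq_len(schedule$n_bio),
    tech_rep = seq_len(schedule$n_tech)
  )
  grid$is_fd <- is.na(grid$exposure_s)

  withr::with_seed(seed, {
    bio_offset <- matrix(rnorm(n_pep * schedule$n_bio, 0, model$noise_bio_da),
                         n_pep, schedule$n_bio)
    tech_err <- rnorm(nrow(grid), 0, model$noise_tech_da)
  })

  labeled <- !grid$is_fd & grid$exposure_s > 0
  base <- numeric(nrow(grid))
  base[grid$is_fd] <- m0[grid$pep[grid$is_fd]] + fd_uptake[grid$pep[grid$is_fd]]
  t0 <- !grid$is_fd & grid$exposure_s == 0
  base[t0] <- m0[grid$pep[t0]]
  base[labeled] <- m0[grid$pep[labeled]] +
    uptake_true[cbind(grid$pep[labeled],
                      match(grid$exposure_s[labeled], exposures))] +
    bio_offset[cbind(grid$pep[labeled], grid$bio_rep[labeled])]

  out <- tibble(
    protein = peptides$protein[grid$pep],
    start = peptides$start[grid$pep],
    end = peptides$end[grid$pep],
    sequence = peptides$sequence[grid$pep],
    max_uptake = peptides$max_uptake[grid$pep],
    state = state,
    exposure_s = grid$exposure_s,
    is_fd = grid$is_fd,
    bio_rep = grid$bio_rep,
    tech_rep = grid$tech_rep,
    centroid_da = base + tech_err
  )
  attr(out, "truth") <- truth
  attr(out, "model") <- model
  out
}

#' Generate a synthetic protein sequence
#'
#' Uniform draw over the 19 non-proline amino acids plus prolines at a fixed
#' rate, for building simulation constructs of arbitrary length.
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @param p_proline Proline frequency (default 0.05; position 1 is never
#'   proline so the construct N-terminus is well defined).
#' @return One-letter amino-acid string.
#' @export
random_protein <- function(length, seed = 1L, p_proline = 0.05) {
  stopifnot(length >= 1)
  aa19 <- setdiff(names(RESIDUE_MASS), "P")
  withr::with_seed(seed, {
    aa <- ifelse(stats::runif(length) < p_proline, "P",
                 sample(aa19, length, replace = TRUE))
    aa[1] <- sample(aa19, 1L)
    paste(aa, collapse = "")
  })
}
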