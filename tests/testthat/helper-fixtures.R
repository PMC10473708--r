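# Small in-code fixtures shared across test files.

# A centroid table for one peptide x state x exposure cell, built from
# prescribed biological-replicate uptake means (Da above m0). Technical
# replicates are identical unless `tech_offsets` (per tech rep) is given.
toy_cell_table <- function(bio_uptakes, m0 = 1000, mf = 1010,
                           exposure = 60, state = "A", n_tech = 3,
                           tech_offsets = rep(0, n_tech),
                           sequence = "AAAAAAAAAA") {
  pep <- tibble::tibble(protein = "p", start = 1L,
                        end = nchar(sequence),
                        sequence = sequence,
                        max_uptake = exchangeable_amides(sequence))
  grid <- tidyr::crossing(bio_rep = seq_along(bio_uptakes),
                          tech_rep = seq_len(n_tech))
  labeled <- dplyr::mutate(
    dplyr::bind_cols(pep[rep(1, nrow(grid)), ], grid),
    state = state, exposure_s = exposure, is_fd = FALSE,
    centroid_da = m0 + bio_uptakes[bio_rep] + tech_offsets[tech_rep])
  controls <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_cols(pep[rep(1, nrow(grid)), ], grid),
                  state = state, exposure_s = 0, is_fd = FALSE,
                  centroid_da = m0),
    dplyr::mutate(dplyr::bind_cols(pep[rep(1, nrow(grid)), ], grid),
                  state = state, exposure_s = NA_real_, is_fd = TRUE,
                  centroid_da = mf))
  dplyr::bind_rows(labeled, controls)
}

# A noiseless two-state simulated experiment on a short construct.
sim_pair <- function(seq_len = 60, region = c(30, 45), delta = 2,
                     noise_tech = 0, noise_bio = 0, b = 0.46, seed = 42,
                     schedule = labeling_schedule(),
                     target_mean_length = 10, target_redundancy = 3) {
  sequence <- random_protein(seq_len, seed = seed)
  gp <- list(noise_tech_da = noise_tech, noise_bio_da = noise_bio, b = b)
  model_a <- build_exchange_model(sequence, global_params = gp, seed = seed)
  model_b <- perturb_model(model_a, region, delta)
  peptides <- digest(sequence, target_mean_length, target_redundancy,
                     seed = seed)
  dplyr::bind_rows(
    simulate_centroids(model_a, peptides, schedule, seed = seed + 1L,
                       state = "WT"),
    simulate_centroids(model_b, peptides, schedule, seed = seed + 2L,
                       state = "MUT"))
}

# Noiseless four-parameter logistic series on a 1-min grid.
logistic_series <- function(midpoint = 8, slope = 1.2, lower = 50,
                            upper = 1050, t = 0:25, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    time_min = t,
    value = lower + (upper - lower) / (1 + exp(-slope * (t - midpoint))) +
      stats::rnorm(length(t), 0, noise_sd)))
}
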