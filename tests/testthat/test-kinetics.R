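test_that("disc-to-plant-to-genotype averaging follows the nested scheme", {
  base <- tidyr::crossing(time_min = 0:9, disc = 1:2)
  data <- dplyr::bind_rows(
    tibble::tibble(disc_id = "d1", plant_id = "p1", genotype = "WT",
                   time_min = 0:9, value = 10),
    tibble::tibble(disc_id = "d2", plant_id = "p1", genotype = "WT",
                   time_min = 0:9, value = 10),
    tibble::tibble(disc_id = "d3", plant_id = "p2", genotype = "WT",
                   time_min = 0:9, value = 20))
  avg <- average_discs(data)
  expect_equal(unique(avg$plants$value[avg$plants$plant_id == "p1"]), 10)
  expect_equal(unique(avg$genotypes$mean), 15)
  expect_equal(unique(avg$genotypes$sem), 5)   # SD(10,20)/sqrt(2)
  expect_identical(unique(avg$genotypes$n_plants), 2L)

  single <- average_discs(dplyr::filter(data, plant_id == "p1"))
  expect_true(all(is.na(single$genotypes$sem)))  # undefined, not zero

  ragged <- dplyr::filter(data, !(disc_id == "d3" & time_min == 9))
  expect_error(average_discs(ragged), class = "hdxdiff_alignment_error")
})

test_that("the logistic midpoint is recovered from a noiseless burst", {
  fit <- suppressMessages(
    time_to_half_max(logistic_series(midpoint = 8, slope = 1.2)))
  expect_true(fit$converged)
  expect_equal(fit$t_half, 8, tolerance = 1e-4)
  expect_equal(fit$lower, 50, tolerance = 1e-2)
  expect_equal(fit$upper, 1050, tolerance = 1e-2)
})

test_that("t_half is scale-invariant and time-equivariant", {
  s <- logistic_series(midpoint = 9, slope = 0.9)
  base <- suppressMessages(time_to_half_max(s))$t_half
  scaled <- suppressMessages(time_to_half_max(dplyr::mutate(s, value = value * 3.7)))
  expect_equal(scaled$t_half, base, tolerance = 1e-6)
  shifted <- suppressMessages(time_to_half_max(dplyr::mutate(s, time_min = time_min + 2)))
  expect_equal(shifted$t_half, base + 2, tolerance = 1e-6)
})

test_that("plant-averaged t_half recovery stays within 2% under 5% amplitude noise", {
  # four discs per plant, averaged as in the burst protocol
  grid <- tidyr::crossing(midpoint = c(6, 8, 10), slope = c(0.8, 1.5))
  n_plants <- 10L
  n_discs <- 4L
  err <- purrr::pmap_dbl(grid, function(midpoint, slope) {
    plant_t_half <- vapply(seq_len(n_plants), function(p) {
      discs <- vapply(seq_len(n_discs), function(d) {
        s <- logistic_series(midpoint = midpoint, slope = slope,
                             noise_sd = 0.05 * 1000,
                             seed = 1000 + p * 100 + d)
        suppressMessages(time_to_half_max(s))$t_half
      }, numeric(1))
      mean(discs)
    }, numeric(1))
    mean(abs(plant_t_half - midpoint) / midpoint)
  })
  expect_true(all(err < 0.02))
})

test_that("burst_summary averages disc half-maxima per plant", {
  mk <- function(disc, plant, midpoint) {
    dplyr::mutate(logistic_series(midpoint = midpoint),
                  disc_id = disc, plant_id = plant, genotype = "WT")
  }
  data <- dplyr::bind_rows(mk("d1", "p1", 7), mk("d2", "p1", 9),
                           mk("d3", "p2", 8))
  bs <- suppressMessages(burst_summary(data))
  expect_identical(nrow(bs$discs), 3L)
  p1 <- bs$plants$t_half[bs$plants$plant_id == "p1"]
  expect_equal(p1, 8, tolerance = 1e-3)
})

test_that("the standard curve is an OLS line with diagnostics", {
  conc <- 10 / 2^(0:6)
  exact <- tibble::tibble(concentration_um = conc, fluorescence = 1000 * conc)
  sc <- fit_standard_curve(exact)
  expect_equal(sc$slope, 1000, tolerance = 1e-9)
  expect_equal(sc$intercept, 0, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)

  with_icpt <- tibble::tibble(concentration_um = conc,
                              fluorescence = 50 + 1000 * conc)
  sc2 <- fit_standard_curve(with_icpt)
  expect_equal(tidy(sc2)$estimate, c(50, 1000), tolerance = 1e-9)

  noisy <- withr::with_seed(4, tibble::tibble(
    concentration_um = conc,
    fluorescence = 30 + 800 * conc + stats::rnorm(length(conc), 0, 20)))
  sc3 <- fit_standard_curve(noisy)
  ci <- stats::confint(sc3$fit)["concentration_um", ]
  expect_gt(800, ci[1]); expect_lt(800, ci[2])

  expect_error(fit_standard_curve(exact[1:2, ]), class = "hdxdiff_input_error")
  flat <- tibble::tibble(concentration_um = rep(5, 4), fluorescence = 1:4)
  expect_error(fit_standard_curve(flat), class = "hdxdiff_input_error")
})

test_that("GUS activity normalizes concentration by protein and time", {
  sc <- fit_standard_curve(tibble::tibble(
    concentration_um = 10 / 2^(0:5), fluorescence = 1000 * 10 / 2^(0:5)))
  expect_equal(gus_activity(2500, sc, protein_mg = 0.05, minutes = 30),
               2.5 / (0.05 * 30), tolerance = 1e-9)
  expect_equal(gus_activity(sc$intercept, sc, 0.05, 30), 0)
  expect_equal(gus_activity(2500, sc, 0.10, 30),
               gus_activity(2500, sc, 0.05, 30) / 2, tolerance = 1e-12)
  expect_warning(out <- gus_activity(-10, sc, 0.05, 30), "floored")
  expect_equal(out, 0)
})
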