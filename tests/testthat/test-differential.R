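make_summary <- function(state, pct, sd_pct = 1, sd_da = 0.1,
                         exposure = 60, start = 1L, end = 10L) {
  tibble::tibble(
    protein = "p", start = start, end = end,
    sequence = strrep("A", end - start + 1L),
    max_uptake = end - start, state = state, exposure_s = exposure,
    mean_uptake = pct / 10, sd_uptake = sd_da,
    mean_pct_ex = pct, sd_pct_ex = sd_pct,
    n_bio = 3L, n_total = 9L, m0 = 1000, mf = 1010)
}

test_that("the pooled-SD global limit reproduces the published arithmetic", {
  expect_equal(round(global_significance_limit(0.129, 0.111), 3), 0.395)
  expect_equal(round(global_significance_limit(2.28, 2.09), 2), 7.18)
  expect_equal(global_significance_limit(0, 0), 0)
  expect_error(global_significance_limit(-0.1, 0.1),
               class = "hdxdiff_input_error")
})

test_that("the limit is symmetric and scales linearly with a common factor", {
  for (i in 1:20) {
    s <- withr::with_seed(i, stats::runif(2, 0, 5))
    expect_equal(global_significance_limit(s[1], s[2]),
                 global_significance_limit(s[2], s[1]))
    expect_equal(global_significance_limit(3 * s[1], 3 * s[2]),
                 3 * global_significance_limit(s[1], s[2]))
  }
})

test_that("repeatability is the unweighted mean of cell SDs", {
  s <- dplyr::bind_rows(
    make_summary("A", 30, sd_pct = 2.0, exposure = 60),
    make_summary("A", 60, sd_pct = 2.56, exposure = 600))
  r <- hdx_repeatability(s)
  expect_equal(r$s_pct, 2.28)
  single <- hdx_repeatability(make_summary("A", 30, sd_pct = 1.7))
  expect_equal(single$s_pct, 1.7)
  zero <- dplyr::mutate(s, sd_uptake = 0, sd_pct_ex = 0)
  expect_equal(hdx_repeatability(zero)$s_pct, 0)
  underrep <- dplyr::mutate(s, n_bio = 1L)
  expect_error(hdx_repeatability(underrep),
               class = "hdxdiff_insufficient_replication")
})

test_that("differential records apply the sign convention and the strict boundary", {
  s <- dplyr::bind_rows(
    make_summary("WT", 50, sd_pct = 2.28),
    make_summary("MUT", 42, sd_pct = 2.09))
  d <- differential_uptake(s, "WT", "MUT")
  expect_equal(d$delta_pct, 8)
  expect_equal(attr(d, "cl_pct"), 7.175704, tolerance = 1e-6)
  expect_true(d$significant)
  expect_identical(d$direction, "stabilized")

  identical_states <- dplyr::bind_rows(
    make_summary("WT", 50), make_summary("MUT", 50))
  d0 <- differential_uptake(identical_states, "WT", "MUT")
  expect_equal(d0$delta_pct, 0)
  expect_false(any(d0$significant))

  # |delta| exactly equal to the limit is NOT significant
  cl <- global_significance_limit(1, 1)
  at_limit <- dplyr::bind_rows(
    make_summary("WT", cl, sd_pct = 1), make_summary("MUT", 0, sd_pct = 1))
  db <- differential_uptake(at_limit, "WT", "MUT")
  expect_equal(db$delta_pct, attr(db, "cl_pct"))
  expect_false(db$significant)
  expect_identical(db$direction, "unchanged")
})

test_that("peptides present in one state are reported, never silently dropped", {
  s <- dplyr::bind_rows(
    make_summary("WT", 50), make_summary("MUT", 45),
    make_summary("WT", 70, start = 11L, end = 20L))
  expect_warning(d <- differential_uptake(s, "WT", "MUT"),
                 "only one state")
  expect_identical(nrow(d), 1L)
  mm <- attr(d, "mismatch")
  expect_identical(mm$start, 11L)
  expect_identical(mm$missing_from, "MUT")

  disjoint <- dplyr::bind_rows(
    make_summary("WT", 50), make_summary("MUT", 45, start = 11L, end = 20L))
  suppressWarnings(
    expect_error(differential_uptake(disjoint, "WT", "MUT"),
                 class = "hdxdiff_alignment_error"))
})

test_that("swapping the states negates deltas and swaps the calls", {
  tab <- sim_pair(noise_tech = 0.05, noise_bio = 0.1, delta = 2, seed = 21)
  s <- aggregate_replicates(tab)
  fwd <- differential_uptake(s, "WT", "MUT")
  rev <- differential_uptake(s, "MUT", "WT")
  expect_equal(rev$delta_pct, -fwd$delta_pct)
  expect_equal(attr(rev, "cl_pct"), attr(fwd, "cl_pct"))
  expect_identical(rev$significant, fwd$significant)
  swap <- c(stabilized = "destabilized", destabilized = "stabilized",
            unchanged = "unchanged")
  expect_identical(unname(swap[fwd$direction]), rev$direction)

  lf <- classify_peptides(fwd)
  lr <- classify_peptides(rev)
  expect_identical(unname(swap[lf$label]), lr$label)
})

test_that("peptide classification counts exceedances per direction", {
  recs <- function(deltas, start = 1L) {
    tibble::tibble(protein = "p", start = start, end = start + 9L,
                   sequence = strrep("A", 10), max_uptake = 9L,
                   exposure_s = seq_along(deltas) * 60,
                   delta_pct = deltas, cl = 7.18)
  }
  expect_identical(classify_peptides(recs(c(3, 5, 8, 6, 2)))$label,
                   "stabilized")
  expect_identical(classify_peptides(recs(c(-8, -9, -7.5, -2, -1)))$label,
                   "destabilized")
  expect_identical(classify_peptides(recs(c(3, -5, 6, -6, 2)))$label,
                   "unchanged")
  expect_identical(classify_peptides(recs(c(9, -8, 1, 0, 0)))$label, "mixed")
  expect_identical(
    classify_peptides(recs(c(-8, -2, -1, 0, 0)),
                      min_significant_timepoints = 2)$label,
    "unchanged")
})

test_that("residue consensus applies majority voting with ties to unchanged", {
  lab <- function(start, end, label) {
    tibble::tibble(protein = "p", start = start, end = end,
                   sequence = strrep("A", end - start + 1),
                   n_up = 0L, n_down = 0L, label = label)
  }
  one <- dplyr::bind_rows(lab(10L, 20L, "stabilized"), lab(25L, 35L, "unchanged"))
  reg <- residue_consensus(one, protein_length = 40)
  expect_identical(reg$label[reg$start == 10], "stabilized")
  expect_identical(reg$end[reg$start == 10], 20L)
  residues <- attr(reg, "residues")
  expect_true(all(is.na(residues$label[c(1:9, 21:24, 36:40)])))

  tie <- dplyr::bind_rows(lab(1L, 10L, "stabilized"), lab(1L, 10L, "destabilized"))
  expect_identical(residue_consensus(tie, 10)$label, "unchanged")

  three <- dplyr::bind_rows(lab(1L, 10L, "destabilized"),
                            lab(3L, 12L, "destabilized"),
                            lab(5L, 14L, "stabilized"))
  cons <- attr(residue_consensus(three, 14), "residues")
  # brute-force majority per residue
  expected <- vapply(1:14, function(r) {
    votes <- c(r >= 1 & r <= 10, r >= 3 & r <= 12, r >= 5 & r <= 14)
    lbl <- c("destabilized", "destabilized", "stabilized")[votes]
    if (length(lbl) == 0) return(NA_character_)
    tt <- table(lbl)
    win <- names(tt)[tt == max(tt)]
    if (length(win) > 1) "unchanged" else win
  }, character(1))
  expect_identical(cons$label, expected)
})

test_that("the Welch statistic matches a hand computation and its limits", {
  two_state <- function(bio_a, bio_b) {
    dplyr::bind_rows(toy_cell_table(bio_a, state = "A"),
                     toy_cell_table(bio_b, state = "B"))
  }
  same <- two_state(c(1, 1.2, 1.4), c(1, 1.2, 1.4))
  w <- peptide_welch_test(same, "A", "B")
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)

  apart <- two_state(c(1.0, 1.05, 1.1), c(5.0, 5.05, 5.1))
  expect_lt(peptide_welch_test(apart, "A", "B")$p_value, 0.01)

  # hand-computed Welch on bio-level %EX means (uptake / 10 Da * 100)
  ha <- c(10, 12, 14); hb <- c(50, 51, 52)
  w2 <- peptide_welch_test(two_state(ha / 10, hb / 10), "A", "B")
  se <- sqrt(var(ha) / 3 + var(hb) / 3)
  t_hand <- (mean(ha) - mean(hb)) / se
  df_hand <- se^4 / ((var(ha) / 3)^2 / 2 + (var(hb) / 3)^2 / 2)
  expect_equal(w2$statistic, t_hand, tolerance = 1e-9)
  expect_equal(w2$df, df_hand, tolerance = 1e-9)
  expect_equal(w2$p_value, 2 * stats::pt(t_hand, df_hand), tolerance = 1e-9)

  solo <- dplyr::bind_rows(toy_cell_table(c(1), state = "A", n_tech = 3),
                           toy_cell_table(c(1, 1.2), state = "B", n_tech = 3))
  expect_error(peptide_welch_test(solo, "A", "B"),
               class = "hdxdiff_insufficient_replication")
})

test_that("the hybrid flag ANDs the global limit with the Welch test", {
  tab <- sim_pair(noise_tech = 0.05, noise_bio = 0.1, delta = 2, seed = 31)
  s <- aggregate_replicates(tab)
  d <- differential_uptake(s, "WT", "MUT")
  w <- peptide_welch_test(tab, "WT", "MUT")
  h <- add_hybrid_significance(d, w)
  expect_true(all(h$significant_hybrid[h$significant_hybrid] %in% TRUE))
  expect_true(all(!h$significant_hybrid | h$significant))
  expect_identical(h$significant, d$significant)  # primary call untouched
})
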