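#' Build a per-residue EX2 exchange model
#'
#' Constructs the ground-truth kinetic model the simulator works from: one
#' observed exchange rate per exchangeable backbone amide. In the EX2 regime
#' the observed rate is the intrinsic chemical rate divided by the protection
#' factor (PF), so structure enters the model as a log10 shift of the rate.
#' Baseline `log10(k_obs)` values are drawn from a two-component normal
#' mixture (a fast, weakly protected population and a slow, strongly
#' protected one), which reproduces the heterogeneous uptake spread real
#' proteins show across a 10 s - 2 h labeling series. Residues inside each
#' element of `region_specs` are slowed by their `log10_pf_shift` (positive
#' shift = more protected).
#'
#' Position 1 and prolines carry no exchangeable amide and get `NA` rates.
#'
#' @param sequence One-letter amino-acid string of the construct.
#' @param region_specs List of `list(start, end, log10_pf_shift)` in construct
#'   coordinates (1-based, closed).
#' @param global_params Named list overriding any of: `p_fast`, `fast_mean`,
#'   `fast_sd`, `slow_mean`, `slow_sd` (mixture of baseline log10 rates, s^-1),
#'   `f_D` (deuterium fraction of the labeling buffer), `b` (back-exchange
#'   fraction), `noise_tech_da`, `noise_bio_da` (replicate noise SDs, Da),
#'   `mass_shift_per_D`.
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param residue_offset Full-protein number of the construct's first residue.
#' @return An `exchange_model` object.
#' @export
build_exchange_model <- function(sequence, region_specs = list(),
                                 global_params = list(), seed = 1L,
                                 residue_offset = 1L) {
  aa <- check_sequence(sequence)
  L <- length(aa)

  defaults <- list(
    p_fast = 0.4, fast_mean = -1.5, fast_sd = 0.4,
    slow_mean = -3.5, slow_sd = 0.6,
    f_D = 0.95, b = 0.46,
    noise_tech_da = 0.06, noise_bio_da = 0.13,
    mass_shift_per_D = MASS_SHIFT_PER_D
  )
  unknown <- setdiff(names(global_params), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown global_params: ", paste(unknown, collapse = ", ")),
          class = "hdxdiff_input_error")
  }
  p <- utils::modifyList(defaults, global_params)
  stopifnot(p$f_D >= 0, p$f_D <= 1, p$b >= 0, p$b < 1,
            p$noise_tech_da >= 0, p$noise_bio_da >= 0)

  exch <- seq_len(L) > 1L & aa != "P"
  log10_k <- rep(NA_real_, L)
  withr::with_seed(seed, {
    n <- sum(exch)
    fast <- stats::runif(n) < p$p_fast
    draws <- ifelse(fast,
                    rnorm(n, p$fast_mean, p$fast_sd),
                    rnorm(n, p$slow_mean, p$slow_sd))
    log10_k[exch] <- draws
  })

  model <- structure(
    list(sequence = paste(aa, collapse = ""), residues = aa,
         residue_offset = as.integer(residue_offset),
         log10_k_obs = log10_k,
         f_D = p$f_D, b = p$b, mass_shift_per_D = p$mass_shift_per_D,
         noise_tech_da = p$noise_tech_da, noise_bio_da = p$noise_bio_da),
    class = "exchange_model")

  for (spec in region_specs) {
    model <- apply_region_shift(model, spec[[1]], spec[[2]], -spec[[3]])
  }
  model
}

check_region <- function(model, start, end) {
  L <- length(model$residues)
  if (start < 1L || end > L || end < start) {
    abort(sprintf("Region [%d, %d] outside construct bounds [1, %d].",
                  start, end, L),
          class = "hdxdiff_coordinate_error")
  }
}

apply_region_shift <- function(model, start, end, log10_delta) {
  check_region(model, start, end)
  idx <- start:end
  model$log10_k_obs[idx] <- model$log10_k_obs[idx] + log10_delta
  model
}

#' Perturb an exchange model over a region
#'
#' Returns a copy of `model` in which residues in `region` exchange
#' `10^log10_pf_delta`-fold faster (deprotection; use a negative value for
#' protection). This is how a "mutant" state is derived from a "wild-type"
#' ground truth. The input model is not modified.
#'
#' @param model An `exchange_model`.
#' @param region Length-2 integer vector `c(start, end)`, construct coordinates.
#' @param log10_pf_delta Log10 fold-change in observed rate; `+2` means 100x
#'   faster exchange (a 100-fold loss of protection).
#' @return A new `exchange_model`.
#' @export
perturb_model <- function(model, region, log10_pf_delta) {
  stopifnot(inherits(model, "exchange_model"), length(region) == 2L)
  apply_region_shift(model, as.integer(region[1]), as.integer(region[2]),
                     log10_pf_delta)
}

#' @export
print.exchange_model <- function(x, ...) {
  n_exch <- sum(!is.na(x$log10_k_obs))
  cat(sprintf(
    "<exchange_model> %d residues (offset %d), %d exchangeable amides\n",
    length(x$residues), x$residue_offset, n_exch))
  cat(sprintf("  f_D = %.3f, back-exchange b = %.3f\n", x$f_D, x$b))
  cat(sprintf("  noise: tech %.3f Da, bio %.3f Da\n",
              x$noise_tech_da, x$noise_bio_da))
  invisible(x)
}

#' Tidy a per-residue exchange model
#'
#' @param x An `exchange_model`.
#' @param ... Unused.
#' @return A tibble with one row per residue: construct position, full-protein
#'   residue number, amino acid, and `log10_k_obs` (`NA` where no exchangeable
#'   amide exists).
#' @method tidy exchange_model
#' @export
tidy.exchange_model <- function(x, ...) {
  tibble(
    position = seq_along(x$residues),
    residue = seq_along(x$residues) + x$residue_offset - 1L,
    aa = x$residues,
    log10_k_obs = x$log10_k_obs
  )
}
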