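#' Average leaf-disc luminescence series to plants and genotypes
#'
#' Disc traces from the same plant are averaged pointwise; plant means are
#' then averaged pointwise per genotype with the standard error of the mean
#' (SD across plants / sqrt(n_plants)). A genotype with a single plant gets
#' `NA` SEM (undefined, not zero).
#'
#' @param data Long plate-reader tibble: `disc_id`, `plant_id`, `genotype`,
#'   `time_min`, `value`. All discs must share one time grid.
#' @return List of two tibbles: `plants` (`genotype`, `plant_id`, `time_min`,
#'   `value`) and `genotypes` (`genotype`, `time_min`, `mean`, `sem`,
#'   `n_plants`).
#' @export
average_discs <- function(data) {
  grids <- data |>
    group_by(.data$disc_id) |>
    summarise(grid = paste(sort(.data$time_min), collapse = ","),
              .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1L) {
    abort("Discs do not share a common time grid.",
          class = "hdxdiff_alignment_error")
  }

  plants <- data |>
    group_by(.data$genotype, .data$plant_id, .data$time_min) |>
    summarise(value = mean(.data$value), .groups = "drop")

  genotypes <- plants |>
    group_by(.data$genotype, .data$time_min) |>
    summarise(mean = mean(.data$value),
              sem = if (n() > 1L) sd(.data$value) / sqrt(n()) else NA_real_,
              n_plants = n(), .groups = "drop")

  list(plants = plants, genotypes = genotypes)
}

# Four-parameter logistic: lower + (upper - lower) / (1 + exp(-slope*(t - mid)))
fpl <- function(t, lower, upper, midpoint, slope) {
  lower + (upper - lower) / (1 + exp(-slope * (t - midpoint)))
}

#' Time to half-maximal burst from a luminescence series
#'
#' Finds the time of maximal signal, keeps all points from the start of the
#' series through five points past the maximum, and fits a four-parameter
#' logistic to that window. The time at which the fitted curve crosses
#' halfway between its lower and upper asymptotes — the logistic midpoint —
#' is reported as `t_half`. Fitting the whole rising phase rather than only
#' the six points around the maximum keeps the four parameters identifiable.
#'
#' @param data Tibble for a single series with columns `time_min`, `value`
#'   (>= 8 points).
#' @return One-row tibble: `t_max`, `t_half`, `lower`, `upper`, `midpoint`,
#'   `slope`, `converged`. On fit failure `converged` is `FALSE` and the fit
#'   fields are `NA` (callers exclude such rows from averages).
#' @export
time_to_half_max <- function(data) {
  stopifnot(all(c("time_min", "value") %in% names(data)))
  d <- arrange(data, .data$time_min)
  if (nrow(d) < 8L) {
    abort("Need >= 8 points to fit the sigmoid.",
          class = "hdxdiff_input_error")
  }
  if (is.unsorted(d$time_min, strictly = TRUE) || any(!is.finite(d$value))) {
    abort("Times must be strictly increasing and values finite.",
          class = "hdxdiff_input_error")
  }
  imax <- which.max(d$value)
  iend <- min(imax + 5L, nrow(d))
  if (iend < imax + 5L) {
    inform("Maximum close to the end of the series; fit window truncated.")
  }
  w <- d[seq_len(iend), ]
  t_max <- d$time_min[imax]

  fit <- tryCatch(
    stats::nls(value ~ SSfpl(time_min, lower, upper, midpoint, scal),
               data = w),
    error = function(e) NULL)
  if (is.null(fit)) {
    rng <- range(w$value)
    start <- list(lower = rng[1], upper = rng[2],
                  midpoint = mean(range(w$time_min)),
                  slope = 4 / diff(range(w$time_min)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ fpl(time_min, lower, upper, midpoint, slope),
        data = w, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  if (is.null(fit)) {
    return(tibble(t_max = t_max, t_half = NA_real_, lower = NA_real_,
                  upper = NA_real_, midpoint = NA_real_, slope = NA_real_,
                  converged = FALSE))
  }
  cf <- coef(fit)
  slope <- if ("scal" %in% names(cf)) 1 / cf[["scal"]] else cf[["slope"]]
  tibble(t_max = t_max, t_half = cf[["midpoint"]],
         lower = cf[["lower"]], upper = cf[["upper"]],
         midpoint = cf[["midpoint"]], slope = slope, converged = TRUE)
}

#' Per-disc, per-plant burst summaries
#'
#' Applies [time_to_half_max()] to every disc and averages the resulting
#' half-maximum times per plant. Discs whose fit did not converge are
#' excluded from the plant averages with a message.
#'
#' @param data Long plate-reader tibble (`disc_id`, `plant_id`, `genotype`,
#'   `time_min`, `value`).
#' @return List of two tibbles: `discs` (per-disc fit results) and `plants`
#'   (`genotype`, `plant_id`, `t_half`, `n_discs`).
#' @export
burst_summary <- function(data) {
  discs <- data |>
    group_by(.data$genotype, .data$plant_id, .data$disc_id) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(fit = purrr::map(.data$data, time_to_half_max)) |>
    select(-"data") |>
    tidyr::unnest("fit")

  n_bad <- sum(!discs$converged)
  if (n_bad > 0L) {
    inform(sprintf("%d disc fit(s) did not converge; excluded from plant averages.",
                   n_bad))
  }

  plants <- discs |>
    filter(.data$converged) |>
    group_by(.data$genotype, .data$plant_id) |>
    summarise(t_half = mean(.data$t_half), n_discs = n(), .groups = "drop")

  list(discs = discs, plants = plants)
}

#' Fit a fluorometric standard curve
#'
#' Ordinary least-squares line through the dilution series, e.g. 4-MU
#' fluorescence against known concentration.
#'
#' @param data Tibble with columns `concentration_um` and `fluorescence`
#'   (>= 3 points, non-degenerate concentrations).
#' @return A `standard_curve` object with `slope` (fluorescence per µM),
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_standard_curve <- function(data) {
  stopifnot(all(c("concentration_um", "fluorescence") %in% names(data)))
  if (nrow(data) < 3L || sd(data$concentration_um) == 0) {
    abort("Standard curve needs >= 3 points with varying concentration.",
          class = "hdxdiff_input_error")
  }
  fit <- lm(fluorescence ~ concentration_um, data = data)
  # direct R^2 avoids summary.lm's essentially-perfect-fit warning
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((data$fluorescence - mean(data$fluorescence))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = nrow(data), fit = fit),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> fluor = %.4g * conc + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n)
}

#' Enzyme activity from fluorescence via a standard curve
#'
#' Converts fluorescence to product concentration with the standard curve
#' (`conc = (fluorescence - intercept) / slope`), then normalizes to protein
#' amount and incubation time: `activity = conc / (protein_mg * minutes)` in
#' µM product per mg protein per minute. Readings below the curve intercept
#' yield negative concentrations and are floored at zero with a warning.
#'
#' @param fluorescence Fluorescence reading(s), arbitrary units. Vectorized.
#' @param curve A `standard_curve`.
#' @param protein_mg Protein amount in the assayed volume (mg, > 0).
#' @param minutes Incubation time (min, > 0).
#' @return Activity in µM · mg^-1 · min^-1.
#' @export
gus_activity <- function(fluorescence, curve, protein_mg, minutes) {
  stopifnot(inherits(curve, "standard_curve"),
            all(protein_mg > 0), all(minutes > 0))
  conc <- (fluorescence - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warn("Fluorescence below the standard-curve intercept; activity floored at 0.")
    conc <- pmax(conc, 0)
  }
  conc / (protein_mg * minutes)
}
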