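---
title: "Methods: differential HDX-MS with a pooled-SD global confidence limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential HDX-MS with a pooled-SD global confidence limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdiff)
```

## The measurement model

Backbone amide hydrogens exchange with solvent deuterium at observed rates
$k_{obs} = k_{int}/PF$ in the EX2 regime, where $PF$ is the protection
factor conferred by structure. A peptic peptide integrates its residues'
deuterium occupancies into one centroid mass. `hdxdiff` works at that
peptide-centroid level — the level at which vendor software (DynamX-style
state data) exports results — and never attempts residue-resolved rate
fitting.

Percent exchange normalizes each labeled centroid $m_t$ between the
undeuterated reference $m_0$ and the fully-deuterated control $m_f$:

$$\%EX = \frac{m_t - m_0}{m_f - m_0} \times 100.$$

Because a uniform back-exchange loss multiplies both $m_t - m_0$ and
$m_f - m_0$ by the same factor $(1-b)$, %EX is back-exchange corrected by
construction; the package property-tests this cancellation across
$b \in \{0, 0.25, 0.49\}$ on simulated data. Values slightly outside
$[0, 100]$ arise from noise and are deliberately kept (no clipping by
default) so dispersion statistics remain unbiased.

## Replicate structure and repeatability

The supported design is nested: independent biological preparations, each
measured in technical replicate (default 3 × 3). `aggregate_replicates()`
averages technical measurements within each biological replicate, then
averages the biological means; the reported SD is taken across biological
means with the $n-1$ denominator, because biological repeats are the
independent unit. Whether dataset-level "repeatability" should instead pool
technical dispersion is not decidable from the target description; the
biological-level value is primary here and a `pooled_technical` flag provides
the alternative for sensitivity analysis. With a balanced design the nested
mean equals the flat mean, which the tests assert.

Repeatability $\bar{s}$ is the *unweighted* mean of cell SDs over all
peptide × exposure cells (no length or uptake weighting — the reference
reports single dataset-level numbers with no weighting stated), in both Da
and %EX units.

## The global confidence limit

For two states with repeatability $\bar{s}_A$, $\bar{s}_B$,

$$CL = m \cdot \sqrt{\bar{s}_A^2 + \bar{s}_B^2}, \qquad m = 2.32.$$

The multiplier 2.32 is the large-degrees-of-freedom two-sided 98% critical
value ($z_{0.99} \approx 2.326$); it reproduces the published limits exactly
(0.129/0.111 Da → 0.395 Da; 2.28/2.09 % → 7.18 %), which is how it was
fixed as the default. Users preferring an exact small-sample $t$ convention
can pass any `multiplier`. Significance is *strict* exceedance
($|\Delta\%EX| > CL$): a delta exactly at the limit is not called.

A peptide is classified stabilized/destabilized when it exceeds the limit in
one direction at `min_significant_timepoints` (default 1) or more labeling
times — differential uptake curves typically cross the limit at some, not
all, times. Exceedances in both directions flag the peptide `"mixed"`
rather than forcing a direction. Residue-level consensus is majority voting
among covering peptides with ties resolved to `"unchanged"`; contiguous
equal-label runs become regions. Peptides present in only one state are
excluded from the comparison but always reported in the `mismatch`
attribute, since silent intersection would hide coverage asymmetry between
datasets.

An optional Welch test on biological-replicate %EX means
(`peptide_welch_test()` + `add_hybrid_significance()`) implements the
"hybrid" criterion as an AND-combination; it never alters the primary
global-limit call.

## The simulator: what it emulates

`build_exchange_model()` + `simulate_centroids()` generate state-data tables
from explicit ground truth:

* per-residue occupancy $D_i(t) = f_D (1 - e^{-k_i t})$, retained as
  $D_i(t)(1-b)$ after back-exchange; peptide uptake is the sum over
  contributing residues times 1.00628 Da per deuteron;
* the FD control sits at $m_0 + 1.00628 \cdot \text{max\_uptake} \cdot f_D
  (1-b)$, so saturation equals the FD plateau by construction;
* noise is nested: one $\mathcal{N}(0, \sigma_{bio})$ offset per
  (biological replicate, peptide) shared across exposures, plus independent
  $\mathcal{N}(0, \sigma_{tech})$ per measurement. The shared offset is what
  makes nested aggregation distinguishable from flat pooling in tests.

Defaults are set to the published experimental scale and were fixed once,
before validation, as the package's standard study conditions: exposures
10/60/600/3600/7200 s; 3 × 3 replicates; $f_D = 0.95$ (a 20-fold dilution,
19 volumes deuterated into 1 protiated); $b = 0.46$; digest targets of mean
length 13 at redundancy 5.5 over a 348-residue construct (≈ 150 overlapping
peptides at 100% coverage). Baseline $\log_{10} k_{obs}$ values are drawn
from a stated two-component normal mixture (40% "fast" at $-1.5 \pm 0.4$,
60% "slow" at $-3.5 \pm 0.6$, rates in s⁻¹), which spreads uptake
realistically across the five-decade labeling window; a sequence-dependent
intrinsic-rate table is unnecessary because the analysis under test only
ever sees centroids. Noise defaults $\sigma_{bio} = 0.13$,
$\sigma_{tech} = 0.06$ Da were chosen so the *observed* biological-replicate
repeatability lands in the published 0.11–0.13 Da band: the mean of $n = 3$
sample SDs underestimates the underlying scale by the factor
$c_4 = \Gamma(3/2)/\Gamma(1) \cdot \sqrt{2/2} \approx 0.886$, so the
generating SDs sit above the band the estimator reports.

The exchangeable-amide count is `length − prolines(2..n) − 1`: prolines have
no amide NH, and the N-terminal residue's deuteron is lost too fast to
survive quench (the exclusion width is configurable, 1 vs 2, since
laboratories differ and the reference does not state its convention).

What the simulator does **not** emulate: EX1/bimodal isotope envelopes,
spectral-level isotope distributions, pH/temperature intrinsic-rate
chemistry, residue-specific back-exchange, peptide misassignment, or m/z
calibration drift. Passing tests therefore demonstrate the statistical
machinery is correct under EX2 assumptions with Gaussian nested noise — not
that any instrument artifact is handled.

## Numerical and degenerate-input choices

* Controls: $m_0$ and $m_f$ are means over all of a state's t=0 / FD rows;
  missing or inverted controls ($m_f \le m_0$) abort with the peptide named.
* Determinism: every stochastic step takes a seed and uses
  `withr::with_seed`, so the global RNG stream is never disturbed; the same
  configuration and seed yield byte-identical pipeline output bundles.
* The per-cell null rate of the full nested pipeline is slightly above the
  nominal $2\Phi(-2.32) \approx 2\%$ because $\bar{s}$ carries the $c_4$
  small-sample bias; the test-suite's false-call bounds account for this.
* Sigmoid fits (`time_to_half_max()`): the four-parameter logistic is fit to
  all points from the series start through five points past the maximum.
  Fitting only the six points around the maximum under-determines four
  parameters; the full rising phase keeps them identifiable while the
  "+5 points" cap still excludes the post-burst decay, which the logistic
  cannot represent. `stats::nls` with the `SSfpl` self-start is tried first,
  then `minpack.lm::nlsLM` from heuristic starts; a double failure returns a
  flagged, excluded record rather than an error. $t_{1/2}$ is the fitted
  midpoint (the logistic's half-maximum point), making it scale-invariant
  and time-shift-equivariant. Disc values are averaged per plant; at 5%
  amplitude noise the single-disc midpoint error can reach ~2.7% at shallow
  slopes, while the plant-level average (4 discs) stays within 2%, and the
  tests assert the latter because that is the quantity the protocol reports.
* Standard curves are straight OLS lines (the dilution series is linear in
  concentration); activity readings below the intercept floor at zero with a
  warning rather than reporting negative concentrations.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise every code path while
remaining quick to run: hand-countable fixtures (2–3 peptides) for exact
arithmetic; 20 000 peptide × exposure cells for the null-calibration of the
98% limit (observed exceedance asserted within [1.5%, 2.7%]); 100 seeded
runs of a 120-residue construct with an implanted 100×-deprotected region
for recovery (≥ 95/100 required, false calls bounded by the $c_4$-corrected
null rate); and one full published-scale emulation (348 residues, ≈ 150
peptides, 3 × 3 replicates, five exposures) for the QC-table ranges.

## Known limitations

Peptide identity is keyed on (protein, start, end, sequence): charge states,
retention-time alignment and envelope deconvolution are upstream concerns.
The global limit treats all cells as sharing one noise scale; peptides with
atypical noise (long peptides, poor envelopes) are neither down-weighted nor
flagged beyond the optional Welch hybrid. Back-exchange is estimated and
simulated as a single dataset-level factor, matching how it is reported, not
as a per-residue property. The consensus voting weights every covering
peptide equally regardless of length or exposure count.
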