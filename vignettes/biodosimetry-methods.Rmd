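---
title: "Statistical methods for dicentric and G2-PCC biodosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for dicentric and G2-PCC biodosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccdose)
```

## The measurement and its data model

After an acute photon exposure, mis-rejoined chromosome breaks appear in
peripheral blood lymphocytes as unstable aberrations: dicentrics, rings
and acentric fragments. Scored per cell, their frequency is a dose meter.
Two preparations are supported: colcemid-arrested metaphases (the
classical dicentric assay, reliable up to roughly 5 Gy) and calyculin
A-induced G2-phase prematurely condensed chromosomes (G2-PCC), which
remain scorable to 20 Gy because heavily damaged cells never need to
reach mitosis. With combined centromere/telomere FISH probes every object
falls into one of six categories (`aberration_classes()`); a multicentric
with C centromeres is recorded as C − 1 *dicentric equivalents*, the
convention under which yields stay additive in the number of pairwise
mis-rejoinings.

A `score_sheet` holds dose points in whichever representation the source
recorded: per-cell records (canonical), per-class count distributions, or
bare totals. Statistics that need a finer representation than is present
report "unavailable" rather than imputing — the bundled ring series, for
example, carries totals only, so its dispersion column is `NA` by design.
Per-cell storage is canonical because distributions and totals are
derivable views of it, never the reverse.

## Dispersion screening

For N cells carrying X aberrations in total, the package reports the
yield Y = X/N with empirical standard error √(s²/N), the dispersion
index s²/Y (s² the N−1-denominator sample variance), its standard error
√(2(1 − 1/X)/(N − 1)), and the standardized form

U = (s²/Y − 1) / √(2(1 − 1/X)/(N − 1)),

which is approximately standard normal when per-cell counts are Poisson —
the expected state for a uniform whole-body exposure. Overdispersion
(U > 1.96) suggests inhomogeneous exposure; the statistic is undefined,
and reported as `NA`, when Y = 0 or X < 2. The N−1 variance convention
was chosen because it reproduces the dispersion and U columns of the
bundled study table to printing precision (±0.02) at all 13 irradiated
doses; the N-denominator variant agrees at 2 decimals for the yield but
was not needed. One caveat about that table: its printed *yield* SEs mix
conventions between doses (most match the Poisson √(Y/N), one matches
the empirical √(s²/N), two match neither at 2 decimals), so the package
reports the empirical SE consistently and the tests deliberately do not
assert the printed yield-SE column.

## Linear-quadratic calibration

Aberration yields after acute photon exposure follow the linear-quadratic
form Y(D) = c + αD + βD² (c: background per cell; α: per Gy; β: per Gy²).
With per-dose totals X_i over N_i cells and X_i ~ Poisson(N_i·Y(D_i)),
the totals are sufficient, so `fit_lq_poisson()` needs no per-cell data.

Numerical choices:

- **Optimizer.** Newton iteration on the log-likelihood with an active-set
  treatment of the non-negativity constraints c, α, β ≥ 0: a coefficient
  sitting at zero with an outward-pointing gradient is frozen for that
  iteration, the Newton step is taken in the remaining coordinates, and
  backtracking line search guarantees monotone ascent. Starting values
  come from unweighted least squares on the yields, clipped to be
  non-negative.
- **Convergence.** Relative log-likelihood change below 1e-10, or
  projected gradient norm below 1e-8 scaled by the total count (the
  natural size of the score equations); at most 200 iterations, and a
  fit error with diagnostics otherwise. Tests verify the score equations
  vanish at the reported optimum and that the likelihood beats a dense
  grid search around the truth.
- **Uncertainty.** Standard errors from the inverse observed information
  over the interior free coefficients. A coefficient that lands on the
  zero boundary is flagged and given no SE — the quadratic approximation
  is invalid there — rather than a misleading number.
- **Degenerate input.** All-zero totals, or fewer dose points than free
  coefficients, are refused outright.

`goodness_of_fit()` reports the Poisson deviance with df = doses − free
coefficients. The bundled 0–20 Gy G2-PCC series illustrates why dose
range matters: its high-dose yields saturate far below any LQ
extrapolation of the low-dose curve, so a full-range fit carries a large
deviance and externally reported full-range coefficients shipped with the
package (`reference_curve("cabas_dicentric")`, `"cabas_ring"`) are kept
as provenance metadata only — their fitting protocol is unrecorded and
no function treats them as a reproduction target. The related published
linearity R² values are likewise not reproduced: the regression they
summarize (variables, weights, dose range) is unspecified.

## Dose estimation

`estimate_dose()` inverts the calibration curve at the observed yield:
doses at or below background clamp to 0, otherwise
D = (−α + √(α² + 4β(y − c)))/(2β). Confidence limits use the exact
(Garwood) Poisson limits on the raw count — lower = χ²(a/2; 2X)/2 (0 when
X = 0), upper = χ²(1 − a/2; 2X + 2)/2 — converted to yields and pushed
through the monotone inverse curve, which preserves their count-scale
coverage. This construction reproduces the bundled study's published
95% intervals to ±0.02 Gy at all nine irradiated condition × dose cells,
which is how it was identified as the method behind them. Two deliberate
properties:

- **Curve uncertainty is not folded in.** The interval reflects scoring
  (Poisson) error only, matching the reproduced behaviour; this is
  anti-conservative when the calibration itself is noisy, and the
  simulation checks therefore state coverage "with the curve treated as
  known". The symmetric ± values printed alongside the published point
  estimates are *not* reproduced by first-order propagation (which gives
  different numbers) and are not a package output; the CI bounds are
  primary, with a labelled delta-method SE (`method = "delta"`, Poisson
  se(Y) = √X/N over the local slope) available for comparison.
- **Zero counts estimate 0 (0–UCL)** rather than failing, the useful
  triage answer. The bundled zero-dose rows are reported but not
  pass/fail-checked: one printed zero-dose entry equals its own upper
  limit and does not follow the count-limit construction.

`triage_truncate()` implements the emergency protocol of scoring until 50
cells or 30 cumulative dicentric equivalents, whichever comes first.

## Spectrum comparison

Whether the *composition* of damage differs between preparations is asked
with a baseline-category multinomial logit: for category k, the log odds
against the reference category are a_k + donor_k + b_k·D² + c_k·D²·G2,
with G2 = 0 for metaphase and 1 for G2-PCC. Design choices where the
problem was genuinely open:

- **Reference category**: compound fragments, the largest class, for
  well-conditioned odds; permuting categories or re-referencing changes
  only the parameterization, not fitted probabilities (tested).
- **Dose enters as D² only.** Over the narrow dose grids compared here
  the two-track term dominates and a separate linear term is poorly
  identified; the interaction of interest is therefore placed on D².
- **Aggregated counts per (dose × donor × preparation)** are the
  observations, since per-cell co-occurrence across categories is not
  recorded; the multinomial conditions on each observation's total.
- **Fitting** is delegated to `nnet::multinom` (tight tolerance), with
  coefficients, SEs and Wald z extracted; the maximized multinomial
  kernel is cross-checked in the tests against direct computation.

Because the exact model variant and covariance estimator behind the
source study's printed p-values are unspecified, only the *direction* of
its one significant finding is asserted: on the bundled counts the
dicentric interaction coefficient is negative (dicentrics' spectrum share
grows more slowly with D² in G2-PCCs). The test suite checks the Wald
interaction test holds its nominal 5% size (±2 points) on null
simulations. `yield_correlation()` complements this with the Pearson
correlation of per-dose total yields between preparations (> 0.999 in
both bundled donors; one bundled row's printed total disagrees with the
sum of its categories by 6 counts, and the package sums the categories).

## What the simulator does and does not emulate

`simulate_score_sheet()` draws per-cell counts independently per
aberration class around LQ mean yields — the exact generative model the
dispersion statistics, the Poisson likelihood and the exact limits
assume. Options add negative-binomial overdispersion (gamma-mixed
Poisson, shape `nb_size`) or a two-component partial-body mixture (each
cell irradiated with probability f, background otherwise, no cell-death
weighting — a beyond-study extension kept deliberately simple). A seed is
mandatory, the generator (Mersenne-Twister) is recorded on the sheet, and
identical configurations reproduce byte-identical sheets.

Not emulated: co-occurrence between aberration classes within a cell
(each class has an independent stream, as no joint data were available to
calibrate one), scoring error, culture kinetics, or selection against
heavily damaged cells — the saturation visible in the bundled 20 Gy data
is precisely such a selection effect, so passing simulation tests
validate the statistics under their stated assumptions, not the assay's
behaviour at extreme doses.

## Problem sizes and verification scale

The checks are sized for a desk run: dispersion calibration uses 500
replicates of 150–200-cell sheets; LQ recovery, 100 seeded replicates at
1000–5000 cells per dose over 6 doses with a 3-SE criterion; interval
coverage, 1000 direct count draws plus 200 full simulate–fit–estimate
chains at a 2 Gy, 50-cell target; spectrum size and power, 500 and 200
replicates of 4-arm studies. The whole suite runs in well under a minute
on one core, and every number quoted in this vignette or the README is
recomputed by the tests or the `analysis/` scripts at those sizes.
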