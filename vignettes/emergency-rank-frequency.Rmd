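---
title: "Methods: rank-frequency analysis of emergency admission diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-frequency analysis of emergency admission diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emfreq)
```

## The problem

Emergency admissions look random patient by patient, yet the *mix* of
diagnoses a hospital admits is strikingly reproducible from year to year.
If the rank-frequency profile of discharge diagnoses is stable and follows
a simple parametric decay, it can be used for planning: above all, to
define the minimal set of conditions — the "vital few" — that duty-roster
physicians must competently handle, and to predict next year's case load
per diagnosis with an honest interval.

`emfreq` implements that analysis end to end: ICD-10 preprocessing,
per-year frequency tables normalized per 100,000 catchment inhabitants,
a ranked profile with prediction intervals, two competing parametric models
for the profile's decay, and cumulative 80/20 coverage analysis. A
deterministic synthetic-data generator with a known ground-truth law makes
every stage testable without registry data.

## Preprocessing

* **Parsing.** Codes are uppercased, whitespace-stripped, and checked
  against the ICD-10 lexical shape (letter + two digits, optionally more
  detail characters, dotted or not). Only the shape is checked — no
  catalogue lookup. Malformed codes are dropped with a log (default) or
  abort the run (`strict = TRUE`); both behaviours are deterministic and
  the dropped count is reported, so every input record is accounted for.
* **Truncation.** Analysis happens at the 3-character category level
  (`I21.0 → I21`). The 4th character onward encodes sub-site/variant
  detail that fragments counts without changing what competence a
  clinician needs. We normalize every code to its category rather than
  literally removing one trailing character, because registry extracts mix
  3-, 4- and 5-character depth and "length − 1" would corrupt
  already-truncated codes (`I21 → I2`).
* **Chapter groups.** Categories are grouped by the *first letter* of the
  code, with A and B merged into one infectious-disease group. This is
  deliberately not the official ICD-10 chapter ranges (which would merge C
  with D00–D48): letter groups are what duty rosters and registry
  summaries actually use, and C (neoplasms) vs D (blood) remain distinct.
  Non-Z letters each form their own group, including U and the external
  cause letters V–Y if present; exclusion lists beyond Z are left to
  configuration.
* **Z exclusion.** Z-chapter codes ("factors influencing health status")
  are by definition not emergencies and are removed before tabulation; the
  excluded count is part of the run manifest.
* **Roster split.** A YAML mapping assigns chapter groups (with optional
  per-category overrides) to the surgical or medical on-call team. The
  shipped default reflects a typical small/medium-hospital split (S, T, K,
  M, O and external causes to surgical; A/B, C–J, L, N, P–R, U to
  medical); it is a local policy, not a standard, and is meant to be
  edited. Unmapped categories become `"unassigned"` with a warning, never
  silently dropped.

## The ranked profile and its prediction intervals

For each scope (whole cohort, one chapter group, one roster arm) we count
admissions per (category, year), convert to rates per 100,000 inhabitants
(`count × 1e5 / population`; the population is configurable per year, with
a single constant as the default since a full population series is rarely
available), and rank categories by the across-year mean rate. Ranking uses
one global order — the display that planners read — with ties broken
lexicographically by category code for reproducibility.

Each category's interval is the frequentist **prediction interval for one
future year's value** from its `n` annual replicates:

\[
\bar{x} \pm t_{0.975,\,n-1}\; s \sqrt{1 + 1/n},
\]

clipped below at 0 because rates are non-negative. We chose the
single-future-observation PI (not a confidence interval for the mean)
because the planning question is "what will next year look like". By
default PIs are computed on the same scale that is displayed (normalized
rates); a flag switches to raw counts. A Monte-Carlo test confirms the
interval's ~95% coverage for a fresh annual draw at `n = 6`.

Profiles can be truncated for display to the smallest top-rank prefix
covering a chosen share of admissions (e.g. 80%, hiding the long rare
tail). Truncation is by share of admissions, not by count of categories,
with the alternative reading available through the cumulative curve.

## The two candidate laws

The profile is fitted by two models with different tail behaviour:

* **Exponential decay** \(f(x) = b_0 e^{-b_1 x}\) over 1-based rank
  \(x\), fitted by Levenberg–Marquardt nonlinear least squares
  (`minpack.lm`), starting values \(b_0 = 1000\), \(b_1 = 0.1\), bounds
  \(b_0, b_1 \ge 0\), tolerances `ftol = ptol = 1e-8`, at most 10,000
  evaluations; all recorded in the fit object. Rank is 1-based so the top
  diagnosis is already decayed to \(b_0 e^{-b_1}\) rather than pinned at
  \(b_0\). A perfectly flat profile is solved in closed form
  (\(b_1 = 0\), \(b_0\) the common value), and a failed start falls back
  to a log-linear least-squares start before reporting non-convergence.
  For Poisson count data an optional iteratively reweighted fit
  (`weights = "poisson"`, weights `1/fitted`) gives variance-correct,
  calibrated standard errors; the unweighted fit remains the default
  because it is the conventional histogram fit.
* **Pareto (power law)** with density
  \(f(x \mid \alpha, k, C) = C\,\alpha k^\alpha / x^{\alpha+1}\) on
  \(x \ge k\). Estimation is closed-form maximum likelihood on the
  frequency values: \(\hat{k} = \min(x_i)\) (the data can never lie below
  the support) and \(\hat\alpha = n / \sum \log(x_i/\hat{k})\). A sample
  with all values equal makes \(\hat\alpha\) undefined and raises an
  error rather than returning infinity. The closed form is verified in
  the tests against direct numerical maximization of the log-likelihood.

**What `x` means in each model.** The exponential is a curve over *rank*;
the Pareto is a density over *frequency*. To overlay and score both on the
same axis we use the Pareto rank-size mapping: in a Pareto(\(\alpha, k\))
sample of size \(n\), the expected frequency at rank \(r\) is approximately
the quantile \(x_r = k\,(n/r)^{1/\alpha}\). This mapping makes
\(\hat{k} = \min(x_i)\) exact at the last rank and makes \(\hat\alpha\)
recoverable from a profile generated under the law; a rank-size grid
without the \(1/\alpha\) exponent would make the tail exponent
unidentifiable from the generated profile, so the exponent is part of the
grid definition. The constant \(C\) is not estimated by likelihood: it is
fixed so the fitted rank curve's total equals the observed total — the
natural normalization for overlaying a density-shaped curve on a count
histogram, and flagged as a package decision in the fit output.

**Model comparison.** Both fitted curves are evaluated on the profile's
rank grid and scored by residual sum of squares (default — the visual
criterion made quantitative), or by Gaussian-error AIC with both models
carrying two counted parameters (\(b_0, b_1\) vs \(\alpha, C\);
\(\hat{k}\) is an order statistic). Lower score wins; exact ties prefer
the exponential with a note. Simulation tests require the generating law
to be preferred in well over 90% of Poisson-noised replicates in each arm.

## Vital few / 80-20 analysis

The cumulative curve gives the exact share of admissions covered by the
top \(r\) categories. `vital_few_set()` returns the minimal prefix whose
share reaches the threshold (default 0.8; attainment uses ≥, so a
category landing exactly on the boundary is included), together with the
top-10 share and a flag for the community-diagnosis rule of thumb that the
ten most common conditions cover ≥ 80% of the load. Minimality is
brute-force-verified in the tests on 1,000 random tables. The vital-few
set is invariant under population rescaling and count scaling.

## The synthetic-data generator

The generator emulates a six-year admission stream from a 315,000-person
catchment area — the default study conditions — with:

* a ground-truth law (exponential, canonical \(b_0 = 1000, b_1 = 0.1\);
  or Pareto via the rank-size grid above),
* per-year counts that are either exactly the rounded expected counts
  (`noise = "none"`, round-half-to-even with a floor of 1 so the category
  set is identical across years and runs) or independent Poisson draws
  (`noise = "poisson"`) — annual Poisson totals are an assumption, chosen
  as the simplest arrival model consistent with year-to-year stochastic
  variation, not an empirical finding,
* a Z-chapter contamination fraction of the whole stream (default 0.027,
  the order of magnitude seen in practice: a few percent of discharges are
  Z-coded non-emergencies), appended as `round(N \cdot z/(1-z))` records
  so the Z share of the total is exactly `z`,
* optional per-year multiplicative factors for a secular trend
  (default 1), and
* deterministic synthetic ICD codes: chapter letters cycle A…Y (Z is
  reserved for contamination) with the digit pair incrementing on each
  wrap, so the labels are lexically valid, unique, exercise the A/B merge,
  and flow through the real preprocessing unmodified.

The generator is fully deterministic given its seed and restores the
caller's RNG state. What it does **not** emulate: age/sex structure,
comorbidity, readmission clustering, seasonality, within-year arrival
dynamics, admission-vs-discharge diagnosis discrepancies. Passing tests
therefore demonstrate the *statistical machinery* is correct under the
stated laws — not that real registry data follow those laws.

## Numerical and design choices

* Rounding: round-half-to-even (R's `round`) with floor 1 under
  `noise = "none"`; this slightly perturbs non-integer expected counts, so
  exact 1e-6 end-to-end recovery is asserted on integer-valued laws
  (e.g. \(b_0 = 512, b_1 = \log 2\)) and statistical recovery elsewhere.
* Ties in ranking: lexicographic by category code, documented and tested.
* Degenerate inputs: flat profiles (closed-form exponential fit; Pareto
  raises a degeneracy error), empty scopes (error), populations and
  thresholds validated with field-named messages.
* Optimizer: `nls.lm` tolerances 1e-8, max 10,000 evaluations; recorded
  in every fit result.
* Problem sizes in the test-suite simulations (e.g. 200 replicates per
  model-selection arm, 10,000 Monte-Carlo replicates for PI coverage, 500
  simulated years for generator convergence at 10 categories) were chosen
  to keep each statistical check's own sampling error an order of
  magnitude below the margin it asserts.

## Reproducibility

`run_pipeline()` is deterministic given configuration + seed and writes a
manifest recording package version, seed, a configuration hash, and the
per-stage record accounting (input = malformed + Z-excluded + retained).
Re-running a configuration reproduces byte-identical CSV/JSON outputs, and
re-reading the pipeline's own CSV output reproduces identical downstream
results.

## Known limitations

* Frequencies, not incidence: readmissions are counted as workload, so
  profiles must not be read as disease incidence.
* No multi-morbidity handling; one main discharge diagnosis per admission.
* The Pareto threshold is fixed at the sample minimum by the closed-form
  estimator; no data-driven threshold selection or bootstrap
  goodness-of-fit tests for power-law membership are provided.
* Only exponential and Pareto alternatives are compared; lognormal or
  stretched-exponential tails are out of scope.
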