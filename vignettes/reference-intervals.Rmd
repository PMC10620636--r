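---
title: "Estimating reference intervals from routine laboratory data"
author: "rilab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating reference intervals from routine laboratory data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilab)
```

## Scope and model

A reference interval (RI) for a laboratory analyte is the central range —
here the central `coverage` fraction, default 95% — of the analyte's
distribution in a reference population, bounded by the 2.5th and 97.5th
percentiles. `rilab` estimates RIs from routine clinical measurements in
two settings:

* **pooled**: all stratified values are available to one analysis
  (`estimate_ri()`);
* **federated**: values stay at their site of origin and only uniform-width
  binned frequency tables are exchanged (`federated_estimate()`).

The statistical model behind the indirect estimators is a mixture: an
observed hospital distribution \(F\) is
\(F = (1-\pi)\,F_{\text{physio}} + \pi\,F_{\text{patho}}\), with a
physiological component assumed Gaussian (possibly after a Box-Cox
transform) and one or more pathological components displaced from it. The
indirect methods differ in how they isolate \(F_{\text{physio}}\).

## Pipeline and safeguards

Every estimate runs the same pipeline: minimum-n gate, single-pass
3-sigma outlier screen, method, percentile bootstrap.

**Minimum-n gate.** Reference samples of fewer than `min_n = 120`
patients are refused outright; the refusal is a typed return value
(`ri_refusal`) carrying `n` and the threshold, so callers and the CLI
(exit code 2) can distinguish "too few patients" from failure. The gate is
applied to the incoming sample size, before outlier screening, making the
refusal behavior an exact step function of n at 120. In federated mode the
gate applies to the aggregate table total.

**Outlier screen.** `three_sigma_filter()` removes values outside
`mean ± sigma_k · sd` (default `sigma_k = 3`), with both moments taken
from the full sample in a single pass — deliberately not re-iterated, so
the screen removes ≈ `2·pnorm(-3)` ≈ 0.27% of a clean Gaussian sample and
cannot cascade. Degenerate inputs (n < 2, zero SD) pass through unchanged
with a diagnostic note rather than erroring, since cleaning must never
fail on data that are merely unusual.

**Bootstrap.** Both limits get `ci_level = 90%` percentile-bootstrap CIs
from `bootstrap_B = 500` resamples. Resampling happens *after* outlier
screening (the screened sample is the estimator's actual input, so its
sampling distribution is what the CI should reflect); resamples on which
an estimator fails are dropped and counted, and more than 50% failures is
an `unstable_bootstrap` error. All randomness in one call flows from a
single recorded seed (`rng_seed`), making results bit-reproducible.

## The four estimators

**Nonparametric (direct).** Limits are the sample quantiles at
interpolated rank \(p(n+1)\) (R's type-6 convention), clamped to the
observed extremes — the standard direct recipe. The rank convention is a
choice; type 6 is the one conventionally paired with RI percentile
estimation, and its slight outward bias at moderate n is visible (and
acceptable) in the coverage checks the test suite runs.

**Robust Box-Cox (indirect, skewed unimodal data).** The sample is
shifted by \(1 - \min x\) if non-positive, power-transformed with the
Box-Cox λ maximizing the profile likelihood on \([-3, 3]\) (grid search at
0.1 resolution, then golden-section polish), and summarized on the
transformed scale by Tukey biweight statistics: location with cutoff
`c = 6` raw-MAD units, scale by the biweight midvariance with the
customary `c = 9` cutoff. The raw midvariance is ≈ 1% anti-conservative
for Gaussian data, so it is divided by its asymptotic value under the
standard normal, 1.00917866, computed once by numerical integration — the
same consistency-constant device as the MAD's 1.4826. Limits
\(T_{bi} \pm z_{0.975}\, s_{bi}\) are inverted through the transform and
shift. Inversion that leaves the transform's domain, zero variance, or a
zero MAD raise typed errors instead of returning an extrapolated interval.

**Iterative trimming (indirect, multimodal mixtures).** Starting from the
full-sample mean and SD, the sample is trimmed to the central region
\(\mu \pm z_t \sigma\) (`trim_z = 1.645`, the central 90% — wide enough to
keep estimation efficient, narrow enough to exclude moderately displaced
pathological mass), and the truncated-sample SD is corrected by the exact
SD-deflation factor of a Gaussian truncated at \(\pm z_t\),
\(\sqrt{1 - 2 z_t \phi(z_t) / (2\Phi(z_t) - 1)}\). Iteration stops when σ
is stable to `tol = 1e-6` relative, capped at `max_iter = 100`
(`no_convergence` beyond that). One degeneracy rule is worth stating: if
the converged central region contains the *entire* sample, nothing was
trimmed, the truncation correction is invalid (the data cannot be the
center of a wider Gaussian), and the method refuses with
`degenerate_trim` — e.g. for all mass at two distant points, which would
otherwise converge silently to an inflated σ.

**Bhattacharya (indirect, multimodal mixtures).** For a Gaussian
component binned at width h, successive log-count differences
\(y_i = \ln n_{i+1} - \ln n_i\) are linear in the bin position; fitting a
line with slope b and intercept a to a qualifying segment gives
\(\hat\sigma^2 = -h/b - h^2/12\) (Sheppard's binning correction) and
\(\hat\mu = -a/b - h/2\), the latter exact when \(y_i\) is regressed on
the center of bin \(i+1\) — the convention used here, verified exactly on
noise-free expected counts. Automation choices, all exposed in
`estimator_settings()`:

* points enter only where both bin counts are ≥ `bhat_min_count = 5`;
* candidate segments are maximal *decreasing* runs of ≥ `bhat_min_run = 4`
  points, where "decreasing" allows steps within `bhat_noise_z = 2`
  standard errors of the Poisson noise of a log-count difference step
  (variance ≈ \(1/n_i + 4/n_{i+1} + 1/n_{i+2}\)). Strict decrease — the
  noise-free limit of this rule — fragments a component's descending limb
  at any realistic sample size;
* segments are fitted by inverse-variance *weighted* least squares
  (\(\mathrm{var}(y_i) \approx 1/n_i + 1/n_{i+1}\)) and qualify when the
  weighted R² ≥ `bhat_r2_min = 0.95` and the slope is negative; unweighted
  R² would be dominated by near-empty tail bins;
* the method's default binning targets `bhat_target_bins = 20` bins over
  the sample range, coarser than the federated histogram default of 50:
  with \(h \ll \sigma\) the per-bin log-count step drowns in counting
  noise and even a perfect fit cannot reach the R² gate. At
  \(h \approx 0.5\sigma\) the fit recovers μ and σ of simulated components
  to well under 1%;
* among qualifying components the **main** one is that implying the
  largest share of the total counts (observed counts over the segment's
  bins divided by their fitted Gaussian probabilities); the full component
  table is kept in diagnostics.

Method selection is explicitly the caller's: the package deliberately does
not auto-detect modality or skewness, because any such dispatch rule would
itself need validation against the data at hand.

## Federated estimation

The federated path enforces "no copy, no move" structurally. Each site
screens outliers *locally* (on its own mean and SD — global moments are
never shared; for sites drawn from a common population the bounds differ
only by sampling noise), bins its values on a shared `bin_spec`, and may
obfuscate counts. The cross-site function,
`federated_estimate_from_tables()`, accepts `frequency_table` objects
only — a payload of bin structure and counts — and this contract is
asserted in the tests. Aggregation is element-wise summation (the
plaintext stand-in for encrypted aggregation; `masked_aggregation()`
demonstrates the same interface with pairwise additive masks). Limits are
read off the joint histogram by cumulative-count interpolation, and CIs
come from multinomial resampling of the aggregate counts.

Bin widths come from a 1-2-5 ladder (`choose_bin_spec()`), rounding *up*
so the bin count never exceeds the target — coarser bins release less
information. The shared specification should come from a per-analyte
catalogue; the fallback negotiates it from per-site (min, max) summaries,
the only other statistic a site then reveals. With ~50 bins over the data
range, federated limits stay within one bin width of the pooled
nonparametric limits for any partition of the same data, and aggregation
is bit-exactly partition-invariant.

Obfuscation uses two-sided geometric (discrete Laplace) noise with
parameter \(e^{-\varepsilon}\), clamped at zero, default off: the
mechanism is the discrete analogue of the Laplace mechanism, but the
package makes no differential-privacy accounting claims — ε is a noise
scale, not a certified privacy budget.

## The synthetic-data generator

`generate_site_dataset()` emulates what the estimators assume about
routine data: per-analyte mixtures of a Gaussian or lognormal
physiological component and displaced pathological components, a linear
age effect centered at age 50, additive sex offsets, diagnosis codes
linked to pathology only with probability `p_icd` (default 0.8 — billing
diagnoses are imperfect proxies), benign filler diagnoses, device
metadata, and the dataset conventions of the record model (first
measurement per case is meaningful because cases can carry several;
pediatric ages have 3 decimals, adult ages are whole years). Per-site
streams derive from a master seed by site index, so adding a site never
perturbs existing ones.

What it deliberately does **not** emulate: longitudinal physiology within
a patient, seasonal or drift effects, inter-analyte correlation, realistic
ICD-10-GM catalogue frequencies, device-dependent bias. Passing tests on
generated data therefore show that the estimators recover the parameters
of the generating mixture under covariate structure — not that any
specific hospital's data meet the mixture assumptions.

## Numerical choices and problem sizes

Degenerate inputs are mapped to typed conditions
(`rilab_insufficient_sample`, `rilab_degenerate_sample`,
`rilab_no_convergence`, `rilab_degenerate_trim`,
`rilab_no_component_found`, `rilab_insufficient_bins`,
`rilab_bin_spec_mismatch`, ...) rather than messages, and ties/edge values
follow fixed rules: half-open bins \([e, e+h)\) with edge values in the
upper bin, timestamp ties resolved by input order, age intervals closed on
both ends, ICD matching on normalized (dot-free, uppercased) prefixes.

The validation suite works at sizes chosen to make Monte-Carlo tolerances
meaningful on a single CPU in minutes: quantile convergence and outlier
fractions at n = 10⁵–10⁶, estimator recovery at n = 10⁴ (clean Gaussian,
agreement of all four methods within ±0.1) and n = 2–5 × 10⁴ (mixtures
with 15–20% pathological mass), bootstrap calibration over 300 replicates
of n = 500 with B = 500, and the minimum-n gate swept across cohort sizes
115–125.

## Known limitations

* RI validation/transference for cohorts below 120 patients is out of
  scope, as are partitioning tests (e.g. Harris–Boyd) and age-continuous
  RI curves.
* The robust Box-Cox method assumes a unimodal (if skewed) reference
  distribution and does not verify it; on strongly multimodal input its
  interval reflects the pooled mixture.
* Units are assumed pre-harmonized per LOINC; the loader refuses mixed
  units rather than converting.
* The federated path simulates the aggregation topology of a secure
  deployment but provides no cryptographic protection; the obfuscation
  stub carries no formal privacy accounting.
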