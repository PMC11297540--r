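---
title: "Constructing diagnostic intervals from linked claims data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing diagnostic intervals from linked claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxinterval)
```

## The problem

The diagnostic interval is the time from a patient's first
cancer-related healthcare contact to the cancer diagnosis date.  It is
not recorded anywhere: it must be *constructed* from administrative
claims by deciding, per patient, which encounter opened the route to
diagnosis.  dxinterval implements the encounter-category /
lookback-window approach used in colorectal-cancer claims research:

1. **Categorize** every billing claim, emergency-department (ED) visit
   and hospitalization by service code.
2. **Profile** each category's encounter frequency in 30-day bins
   before diagnosis (27 bins, a 2-year-plus horizon), pooled over the
   cohort; keep categories occurring more often in the 0--3 months
   before diagnosis than in the 24--27-month baseline.
3. Derive a per-category **lookback window** by statistical process
   control (SPC): how far before diagnosis that category's encounter
   counts are elevated above baseline.
4. The patient's **index date** is the earliest encounter inside its
   category's window; procedure encounters with a referring physician
   extend the interval to the first visit with that physician within
   365 days before the procedure.  Interval = diagnosis − index + 1
   days (a diagnosis-day contact is a 1-day interval).
5. Classify each interval as **asymptomatic** (screen-detected proxy:
   the first-encounter-date set is a stool test (gFOBT) or lower GI
   endoscopy, alone or with a consultation, outside the ED) or
   **symptomatic**, and into one of **nine pathways** by lower GI
   endoscopy / imaging / ED-presentation combinations.
6. Estimate income-quintile differences in the conditional 50th and
   90th percentile interval by **quantile regression** with
   pair-bootstrap confidence intervals, stratified by symptom status.

Real linked registry–claims extracts are access-restricted, so the
package ships a synthetic generator of the full linked table set
(persons, cancer registry, insurance-eligibility spans, encounters)
with ground-truth labels; every stage is tested against that ground
truth.

## The quantile-regression layer

For quantile level $\tau$, coefficients minimise the check loss
$\sum_i \rho_\tau(y_i - x_i'\beta)$ with
$\rho_\tau(u) = u(\tau - \mathbf{1}\{u<0\})$.  This is a linear
program; `fit_quantile()` solves it with a Frisch–Newton primal-dual
interior-point method (compiled, one $p \times p$ solve per
iteration), runs to a relative duality gap of $10^{-10}$, and verifies
the subgradient condition
$\#\{r_i < 0\} \le n\tau \le \#\{r_i \le 0\}$ on the returned
solution.  An interior-point solver was chosen over simplex because
the coverage simulations refit the model tens of thousands of times at
$n = 20{,}000$; tests cross-check the fits against an independent
simplex implementation and against exhaustive enumeration of
basis solutions on small problems.

Confidence intervals use the nonparametric pair bootstrap (rows of
$(y, X)$ resampled with replacement; percentile bounds; degenerate
resamples redrawn and counted).  The source study does not state its
CI method; the pair bootstrap is assumption-light for skewed,
heteroscedastic outcomes, and this is a documented deviation risk when
comparing intervals to published ones.  Reported p-values are normal
approximations from the bootstrap standard error.

The design is fixed by the analysis plan: income-quintile dummies with
quintile 5 (highest) as reference; adjusted models add age centred at
65, sex (male reference), rural residence (rurality score ≥ 45) and
diagnosis year centred at 2019.  Comorbidity burden and stage are
conceptualised as on the causal pathway from income to the interval
and therefore never enter as covariates; stage effects are examined by
stratification instead.

## The SPC lookback chart

Per category, pooled bin counts are screened with a Shewhart-style
count chart: baseline mean $\mu$, upper control limit
$\mu + k\max(\sqrt{\mu}, 1)$ with $k = 2$ by default — a deliberately
liberal two-sigma limit, since missing a true cancer-related window
biases intervals short.  Three operational choices matter and were
validated by simulation (`spc_lookback()`):

* **Integer control limit.**  Bin counts are integers, so a bin
  signals only when its count strictly exceeds
  $\lceil \mathrm{UCL} \rceil$, the usual convention for attributes
  charts.
* **Phase-I trimmed baseline.**  $\mu$ is first estimated from the
  oldest six bins, then re-estimated from all bins older than the
  detected crossing (iterated to a fixed point).  A three-bin baseline
  estimate is too noisy: with baseline mean 4 per bin, its sampling
  error alone drives spurious distant crossings in over 10% of step
  profiles.
* **Sustained elevation.**  The crossing bin is the most distant bin
  $b$ such that bins $b, b-1$ (persistence 2) signal *and* at least
  80% of bins from $b$ to diagnosis signal.  A lookback window asserts
  elevated contact over its whole span, so two isolated noisy bins far
  from diagnosis must not set it.

With these choices, step profiles with baseline mean 4 and a fivefold
step at bins 3, 7 or 12 are recovered exactly in 96--98% of
replicates; the package's acceptance suite checks ≥ 95%.  Selected
categories with no qualifying crossing receive a 90-day floor — by
construction they are elevated in the 0--3-month selection window.

Category selection itself uses a strict ratio test (mean of bins 0--2
greater than the mean of bins 24--26) with a minimum recent count of
5.  With pooled cohort-scale counts, a category with *no* real change
still passes a strict ratio test with probability near one half; such
categories almost always lack a sustained crossing and end up with the
90-day floor, which bounds the noise they can inject into intervals.

## What the generator emulates — and what it does not

`sim_config()` defaults are calibrated to published stratified
tabulations of an Ontario colon-cancer cohort diagnosed 2007--2019
(N = 64,303), bundled as `reference_counts()`:

* quintile sizes, asymptomatic shares, ED-presentation shares and
  same-day-diagnosis shares per quintile, straight from the printed
  counts;
* per-(status, quintile) interval distributions: log-normal
  (symptomatic) and gamma (asymptomatic) continuous parts plus a
  same-day point mass, jointly fitted so the *mixture* reproduces the
  printed medians and 90th percentiles (e.g. symptomatic quintile 1:
  126 / 410 days against quintile 5: 116 / 392 — a 10-day median and
  18-day 90th-percentile gap);
* additive covariate effects (about +0.9 days per year of age above
  the mean, +18 days for women, −12 for rural residence, −1 per
  calendar year), centred at their population means so the marginal
  calibration is preserved;
* encounter histories: per-category Poisson background in 30-day bins
  with rates reflecting claims reality (routine primary-care and
  laboratory contacts frequent; colonoscopies, CT and contrast studies
  rare), a surge multiplier on cancer-related categories between
  interval onset and diagnosis, screening-test onset encounters for
  asymptomatic patients, symptom-coded or ED onset encounters for
  symptomatic ones, and referring-physician links whose prior visit
  always exists within 365 days.  Symptomatic referral chains stay
  inside the surge window (a referral follows first presentation);
  screening referrals may precede onset, as routine care does.

True intervals are truncated at 600 days: pre-diagnosis surges longer
than 20 months are clinically implausible, and the cap sits above
every configured 90th percentile, so the conditional-quantile
estimands at $\tau \le 0.9$ are untouched.

Two properties of real data are deliberately *not* reproduced.  First,
the generator knows each patient's true onset; the pipeline does not,
and its measured intervals are inflated by background encounters that
fall inside lookback windows before onset (with default settings the
median absolute error against ground truth is about 25 days, and
measured distribution medians sit well above the true ones).  This is
a property of the measurement method itself, which its originators
note cannot be validated against real first contacts.  Second, the
asymptomatic share and ED share measured by the classifier are
attenuated relative to their generator inputs, because noise or
referral encounters sometimes displace the true onset encounter at the
index date — under the classification rule a referral consultation
alone on the index date is symptomatic.  Passing tests therefore
demonstrate correctness of the construction rules and recovery of
*relative* income gradients, not that every descriptive share matches
the published cohort.

Parameter-recovery tests consequently regress the generator's *true*
intervals: with an injected 15-day quintile-1-vs-5 shift of the
conditional 90th percentile at $n = 20{,}000$, the adjusted estimate's
95% bootstrap CI covers 15 in ≈95% of replicates (and covers 0 under
the null generator).

## Numerical and procedural choices

* **Day conventions.**  All arithmetic is on whole days; interval =
  difference + 1, forced by the published equivalence of same-day
  diagnosis with a 1-day interval.  Bin $b$ covers days
  $30b + 1$ to $30b + 30$ before diagnosis; diagnosis-day encounters
  contribute to no profile bin but are eligible index contacts.
* **Eligibility.**  Continuous insurance coverage over the 730 days
  before diagnosis tolerates administrative gaps of ≤ 30 days
  (claims-study convention; the source text states no gap rule).
  Death on the diagnosis date is retained — exclusion requires death
  strictly before diagnosis.  Patients are excluded by the first
  applicable rule only, in the printed order.
* **Referral linkage** is attempted for every eligible
  procedure-flagged encounter, not only the index candidate, and the
  index is the minimum over all candidates — "earliest" semantics.
  Ties on the index date retain all co-dated encounters for the
  classifier.
* **Quantiles** in descriptive tables use linear interpolation
  (type 7) and are reported as whole days, rounded half-up, matching
  printed-table conventions; percents round half-up to one decimal.
* **Determinism.**  Every patient's encounter stream is seeded from
  (master seed, patient id), so histories are invariant to cohort
  ordering; `run_pipeline()` bundles are byte-identical across reruns
  of the same configuration, and the manifest stores the configuration
  hash and seed.
* **Simulation sizes.**  The bundled demo runs 5,000 patients;
  coverage simulations use 100 replicates of 20,000 patients with
  B = 200 bootstrap resamples, and single-estimate recovery checks use
  100,000--500,000 patients where only a handful of fits is needed.
* **10th percentile** fits are supported but off by default; at that
  percentile the interval distribution barely varies between income
  groups, and published results there were null.

## Known limitations

* The SPC chart operates on cohort-pooled profiles; with very large
  cohorts even clinically trivial elevations become statistically
  detectable far from diagnosis, lengthening lookbacks.  The sustained-
  elevation requirement mitigates but does not remove this.
* The measured interval is the method's estimand, not the true onset:
  validation against ground truth is only possible in simulation.
* Bootstrap p-values are normal approximations; for small strata the
  percentile CI is the more trustworthy summary.
* The synthetic codemap is a coarse abstraction (each category stands
  for a narrow code stratum); real extracts need a jurisdiction-
  specific map supplied to `categorize_encounters()`.
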