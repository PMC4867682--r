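---
title: "Methods: isotope-dilution partitioning of plant P sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-dilution partitioning of plant P sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopart)
```

## The problem

When a phosphorus fertilizer — mineral or a recycled product such as
manure, fish sludge, meat bone meal, or wood ash — is applied to soil, the
P a plant takes up is a mixture of fertilizer-derived, soil-derived, and
seed-derived P. Chemical extraction cannot separate these sources;
radioisotope dilution can. `isopart` implements the complete calculation
chain for a carrier-free ³³P tracer design with two labeling routes:

* **Direct labeling** — the fertilizer itself carries the tracer. The
  specific activity (SA, Bq per mg P) of plant P relative to the fertilizer
  SA gives the fertilizer-derived fraction directly:
  \[\mathrm{P_{df\,fert}} = \frac{SA_{plant}}{SA_{fert}}\times
  \mathrm{uptake}.\]
* **Indirect labeling** — the plant-available soil pool is labeled to
  isotopic near-equilibrium before an *unlabeled* fertilizer is applied.
  The fertilizer dilutes the SA of plant P relative to an unfertilized
  reference, so
  \[\mathrm{P_{df\,soil}} = \frac{SA_{plant}^{P+}}{SA_{plant}^{NoP}}
  \times(\mathrm{uptake}-\mathrm{P_{df\,seed}}),\qquad
  \mathrm{P_{df\,fert}} = \mathrm{uptake}-\mathrm{P_{df\,soil}}
  -\mathrm{P_{df\,seed}}.\]

Fertilizer recovery is `pdf_fertilizer / dose x 100` and relative agronomic
efficiency (RAE) is a product's recovery as a percentage of the recovery of
water-soluble mineral P at the same dose.

## Radioactivity bookkeeping

All activities are corrected back to the soil-labeling date with the factor
\(2^{t/T_{1/2}}\). The protocol this package emulates does not state the
half-life it used; we adopt the standard ³³P value of 25.383 d as a
configurable constant (`half_life_days`). Correction is applied per sample
at ingest; tables may carry either an `elapsed_days` column or a
`count_date` plus a configured `reference_date`. Units are fixed
package-wide: Bq, mg P, kg dry soil, SA in Bq per mg P.

## The seed correction and the SA mass basis

The sown seed is an unlabeled P source shared by every pot. Its
contribution is calibrated in a sand-culture experiment where the
fertilizer is direct-labeled, so seed P is the only unlabeled source and
`pdf_seed = uptake - activity / sa_fert` is observable per pot. A straight
line `pdf_seed = a * uptake + b` fitted to that experiment
(`fit_seed_model()`) predicts the seed contribution in the soil pots.
Negative predictions are clamped at zero and flagged.

One genuinely open design point is which P mass the plant SA in the
indirect formula is computed on. We compute the SA of *both* the
unfertilized reference and the fertilized plant on the seed-corrected mass,
`activity / (uptake - pdf_seed)`. This is the only reading under which the
indirect route is algebraically exact: the ratio of seed-corrected SAs is
exactly the soil-derived share of non-seed P, and on noise-free data the
direct and indirect routes return identical fertilizer P (a property the
test suite asserts at 1e-9). Computing the fertilized plant's SA on total
uptake instead would bias the soil term by the factor
`(uptake - pdf_seed)/uptake` (about 10% here).

The direct route applies no seed subtraction: an unlabeled seed does not
bias an SA ratio whose only labeled source is the fertilizer. The packaged
synthetic calibration (`a = 0.06`, `b = 0.28` mg P kg⁻¹) was chosen once so
that predicted seed P spans 0.65–0.95 mg P per pot — 8.6–10.7% of uptake —
across the pot uptake range, the range the emulated study reports; the true
slope and intercept were never published.

## Aggregation, flags, and RAE

All ratios are computed per pot and then averaged (mean-of-ratios), because
the emulated design reports per-replicate spread and drops individual
replicates. Consequently, recomputing summary cells from published *means*
can differ slightly from published summaries; worked-example tolerances
account for that. Physically impossible intermediate values are never
silently erased: a negative indirect fertilizer P gets
`NEGATIVE_PDF_FERTILIZER`, an SA ratio above 1 under direct labeling gets
`IMPOSSIBLE_RATIO`, clamped seed predictions get `CLAMPED_SEED`. With
`exclude_flagged = TRUE` (default) flagged pots are excluded from
summaries, mirroring the emulated study's exclusion of one replicate. RAE
is referenced to the mean mineral-P recovery *within the same soil*
(`reference_treatment`, default `"MinP"`), and is 100 for the reference
itself by construction.

## Exchange kinetics and E₁min

Availability of soil inorganic P is characterized by the decline of
solution radioactivity after a carrier-free spike into a pre-equilibrated
1:10 soil:water suspension:

\[\frac{r(t)}{R} = m\left[t + m^{1/n}\right]^{-n}
+ \frac{10\,C_P}{P_i},\]

where \(m\) is roughly the fraction remaining at 1 min, \(n\) the
disappearance rate, \(C_P\) the steady-state solution P (mg L⁻¹), and
\(P_i\) the inorganic-P basis (soil total P − organic P + fertilizer dose;
1024 − 456 (+30) mg kg⁻¹ for the study soil). The exchangeable pool within
one minute is

\[E_{1min} = \frac{10\,C_P\,R}{r(1)}.\]

Estimation holds \(C_P\) and \(P_i\) fixed at their measured values and
minimizes unweighted squared error on \(r(t)/R\) (weights are exposed for
sensitivity checks) under box constraints \(m\in(10^{-6},1]\),
\(n\in(10^{-6},0.999)\), using bound-constrained quasi-Newton iteration
with a polish restart. Start values: \(m_0\) = first observation minus the
equilibrium floor; \(n_0\) = negative log–log slope of the first three
floor-subtracted points; fallback (0.3, 0.4). On noise-free data the
objective reaches machine zero, where the optimizer's gradient test reports
"false convergence" although the parameters are exact; convergence is
therefore judged on parameter stability and residual size. The source
protocol mentions a "statistical refinement" of the fit it does not define;
no refinement step is implemented.

E-values can be computed from the fitted curve at t = 1 (default,
`e_value_source = "fitted"`) or from the raw 1-min observation (`"raw"`);
the published tables do not say which was used, and on clean data the two
coincide. A fitted E₁min is always within its physical bounds
\([10\,C_P,\;P_i]\).

## Resin and microbial P

Resin-extractable P proxies plant-available P. Under indirect labeling the
fertilizer-derived fraction of that pool is
`(1 - SA_fertilized / SA_NoP) x 100`, with the reference SA taken as the
per soil x day mean over unfertilized extracts (parallel to the plant-side
reference). Microbial P is the fumigation-extraction difference
`(fumigated - unfumigated) / sorption_factor`. The emulated protocol's
spike test showed released P was fully recovered on the resin, so
`sorption_factor` defaults to 1 and no flush-to-biomass conversion factor
is applied; both remain parameters.

## The synthetic-data generator

Because no raw per-pot data were deposited, the generator is the package's
test bed. It emulates the stated world of the design: two soils x seven
treatments x four replicates at a dose of 30 mg P kg⁻¹; soil labeling
1.1 MBq kg⁻¹; a direct-labeled mineral control at SA 40 kBq mg⁻¹; a
five-rate (0–30 mg P kg⁻¹) seed experiment with 0.71 mg seed P per pot;
kinetics sampled at 1, 4, 10, 30, 60, 90 min with R in the 600–900 Bq mL⁻¹
range. Noise is multiplicative Gaussian truncated at zero, default CV 5%
for P measurements and 2% for activities (no error model was published;
these are realistic bench magnitudes and are config keys). Treatment-level
truth (fertilizer shares 0.12–0.42, uptakes 6–11 mg P kg⁻¹, resin/microbial
pools) is *synthetic*: patterned on the magnitudes of a P-deficient
temperate soil, not reproductions of measured values.

Two modeling choices deserve emphasis:

* Activities are generated from one consistent mixing model (labeled soil
  pool or labeled fertilizer), then emitted decay-*uncorrected* with
  elapsed times, so ingestion genuinely exercises decay correction.
* In the seed experiment, between-pot uptake scatter is biological — pots
  move *along* the calibration line — while measurement noise enters
  through the counted activity only. Putting measurement error on the
  regressor too would bias the fitted slope upward (errors-in-variables),
  which the downstream correction does not intend; the unbiasedness of the
  slope estimator is asserted in the tests.

A green synthetic test therefore establishes that the equations are
implemented exactly and that estimators behave under the assumed noise; it
does not establish that real soils satisfy the model assumptions
(homogeneous labeling, steady-state exchange, no remineralization of
labeled microbial P).

## Numerical and degenerate-input policy

* Decay correction refuses negative elapsed times (chronology errors).
* `specific_activity`, recovery, RAE, and the indirect reference all
  refuse nonpositive denominators with explicit errors.
* A kinetics series must be strictly increasing in time with
  \(0 < r(t) \le R\); non-monotone wiggles beyond a relative tolerance
  (default 10%) warn. A flat series is a degenerate-series error.
* `validate_table()` reports *all* schema violations with row numbers
  before any computation runs.

## Known limitations

Only single-pool 1-min E-values are computed (no multi-compartment E(t));
ANOVA/posthoc machinery is delegated to standard tools; regression
p-values are descriptive with no multiple-testing correction; uncertainty
is reported as replicate spread only — no propagation through SA ratios.
Published summary means shipped under `inst/extdata/` are summary
statistics for worked-example checks, not raw data.
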