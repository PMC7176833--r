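---
title: "Methods: perinatal cost-of-illness modelling in pericost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perinatal cost-of-illness modelling in pericost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericost)
```

`pericost` estimates the societal economic burden of maternal depression
over pregnancy and the first postpartum year. This vignette is the package's
account of the model, its assumptions, the choices that were genuinely open,
and what the synthetic data can and cannot show.

## The cohort structure and depression grouping

The pipeline consumes participant × wave interview records from a perinatal
cohort followed at four waves: baseline at the first antenatal visit
(typically second trimester), 8 months gestation, and 3 and 12 months
postpartum. At each wave a woman is classed *depressed* when her Hamilton
Rating Scale for Depression (HRSD) score is **strictly greater than 8**.
Strict inequality is the canonical reading here ("a cut-off of 8" is also in
circulation for this instrument); the cutoff is a parameter
(`hrsd_cutoff`) so a `>= 8` convention is one keystroke away. A missing
HRSD score makes the wave's status *unknown*: the record is excluded from
that wave's group summaries and the exclusion is counted in the run log
rather than silently dropped.

Grouping is **per wave, not longitudinal**: a woman contributes to the
depressed cell at one wave and the non-depressed cell at another if her
symptoms change. The model conditions on per-wave status because almost the
whole cohort is symptomatic at baseline (the default synthetic flow retains
419 of 425 enrolled, only 16 of them non-depressed at wave 1), which makes a
baseline-status longitudinal contrast statistically hopeless. The
corresponding limitation is inherited: totals "for the depressed group" are
totals for a synthetic woman who is depressed at every wave, and no
transition probabilities between the states of being depressed and not are
modelled.

## The Markov model

Costs are organised in a four-state Markov structure on a 3-month cycle:
2 cycles in 0–6 months antenatal, 1 in 6–9 months antenatal, 1 in 0–3
months postnatal, 3 in 3–12 months postnatal — 7 cycles, a 21-month
horizon. Wave *w* populates state *w*. Eight separate models are built:
{depressed, non-depressed} × {provider, patient} × {mother, child}.

Per-cycle state costs are estimated as the sample mean and standard
deviation across the wave's group members, after these mapping rules:

* **Ambulatory care** (clinic + hospital outpatient visits, 3-month recall)
  enters the cycle at face value, multiplied by unit costs (provider) or
  valued as time + travel + fees (patient).
* **Inpatient days** are collected over a 6-month recall and are **halved**
  to a 3-month cycle — the minimal assumption consistent with the cycle
  length.
* **Antenatal visit totals** (asked once, at wave 2, for the whole
  pregnancy) are spread evenly across the **3 antenatal cycles**; **well-baby
  visit totals** (asked at wave 4, for the first year) are spread across the
  **4 postnatal cycles**. Antenatal visits belong to the mother's models,
  well-baby visits to the child's, both at the clinic-visit unit cost.
  For states sourced from other waves (e.g. the antenatal share of state 1),
  the participant's own wave-2/wave-4 total is joined in; participants lost
  before reporting it are imputed the group mean of the observed totals,
  which leaves the group mean unbiased and only understates the variance
  slightly.
* **Delivery** (site and facility days, reported at wave 3) enters the
  0–3 months postnatal state only, at the delivery-day unit cost of the
  reported site (midwife obstetric unit or hospital). All reported delivery
  days carry the full site rate; whether days beyond the first should revert
  to a general inpatient rate is not observable from the data we emulate,
  and using the site rate throughout keeps delivery cost a single
  interpretable product.

The deterministic total is the cycle-weighted sum of state means. **No
discounting and no half-cycle correction** are applied: over a 21-month
horizon discounting is immaterial, and a half-cycle correction would imply
precision about within-cycle timing that interview recall does not support.

## Probabilistic sensitivity analysis

Each state's per-cycle cost is given a gamma distribution by method of
moments — shape = μ²/σ², scale = σ²/μ, so shape·scale = μ and
shape·scale² = σ² exactly; σ = 0 degenerates to a point mass. The gamma is
applied at the **cost level** (not to the underlying utilisation counts):
state cost moments are the quantities carried by the model, and gamma on a
non-negative, right-skewed cost is the standard choice. Each model draws all
four states independently per iteration (no correlation structure is
asserted between periods), accumulates the cycle-weighted total, and repeats
for `n_iterations` (default 10,000). The 90% uncertainty interval is the
empirical 5th–95th percentile range, not a normal approximation. Each model
has its own seeded random stream derived from the run seed, so reruns are
byte-identical. Mother and child dyad totals are combined **per iteration**
(sums of draws), because interval endpoints are not additive.

## Provider unit costs

Unit costs use gross costing: facility expenditure divided by activity over
the same period. Hospital expenditure is split into inpatient-day and
outpatient-visit unit costs with the patient day equivalent convention
(an outpatient visit = one-third of an inpatient day): with
PDE = inpatient_days + opd_visits/3, the cost per inpatient day is
expenditure/PDE and the outpatient cost is a third of it, which reallocates
the expenditure exactly — `ipd_days·ipd_cost + opd_visits·opd_cost =
expenditure` is property-tested. Delivery-day rates at MOUs and hospitals
are direct gross-costed entries of the finance table rather than derived
from the hospital split, keeping the obstetric rate distinct from the
general inpatient rate (both conventions are expressible through the
table). Real provincial finance data are not redistributable, so the
package ships `synthetic_finance_table()`, a labelled synthetic stand-in
calibrated to plausible 2014/15 magnitudes (R400 per clinic visit, R1200
per inpatient day, R2500/R5000 per MOU/hospital delivery day).

All internal arithmetic is in ZAR at 2014/15 prices; conversion to USD
(11.69 ZAR/USD, the 2014/15 average) happens once, at reporting, to avoid
compounding rounding.

## Patient costs and the opportunity cost of time

Care-seeking time (travel + waiting + consultation, recorded in minutes per
ambulatory visit) is valued at a single cohort-wide hourly rate: mean
baseline per-capita household income × 12 / (228 working days × 8 hours).
A uniform rate values every woman's hour equally — an equity choice, and the
package exposes `working_days_per_year` / `working_hours_per_day` if the
labour-supply assumption should differ. Three exclusions are built in:
children's own time is never valued (they do not work); the mother's
accompanying time on child visits is valued at the same rate; and no time
cost attaches to delivery or inpatient episodes, whose durations largely
overlap non-working hours. Travel expenses and user fees enter at reported
values per 3-month recall window.

Cost-to-income shares divide a wave's total household care-seeking cost by
**the respondent's own** per-capita household income over the same 3
months (the cohort-mean denominator is available as an alternative but the
own-household reading is implemented as primary). Spending above 10% of
per-capita income is flagged catastrophic; no single threshold is canonical
in this literature, so 10% — the most conventional — is the default and it
is a parameter (`catastrophic_threshold`). Participants with non-positive
imputed income are excluded from share statistics and counted in the
output.

## Socioeconomic outcomes

Banded household income is made continuous by regressing band midpoints on
employment, education and the wealth score, with predictions clipped to the
respondent's reported band; bounded bands use arithmetic midpoints and the
open top band uses 1.5 × its lower bound. The regression is refit at each
wave with that wave's covariates. The wealth index is the first principal
dimension of a correspondence analysis of the indicator matrix of asset and
service-access variables (dwelling type/ownership, electricity, water,
income-source fixity, banking, food-shop type, education) — indicator-matrix
MCA, not the Burt variant, since only the first dimension is used. It is
computed **per wave**, so the index tracks each time point's sample. The
sign is oriented so that electricity access loads positively (MCA is
sign-indeterminate; anchoring on an unambiguously wealth-positive category
makes "richer" mean richer). SES groups are a quantile cut of the score,
binary poorer/richer by default, ties broken by stable participant order.
Group contrasts use Kruskal–Wallis for quantitative outcomes and Pearson's
χ² (uncorrected) for categorical ones, delegated to the standard `stats`
implementations and wrapped with group summaries.

## What the synthetic generator emulates — and what it does not

`cohort_config()` defaults encode the emulated study conditions: screening
flow 2192 screened / 425 enrolled / 6 excluded / 419 retained; wave-1
depression prevalence 403/419 with later-wave prevalences 0.72 / 0.62 /
0.55 (plausible calibration — the printed group sizes available for the
later waves are not mutually consistent, so exact prevalences are not
recoverable); 4% monotone attrition per wave; negative-binomial utilisation
counts (overdispersion is the norm for visit counts) with higher inpatient
means and hospital-delivery probability (0.45 vs 0.25) in the depressed
group and *equal* antenatal/well-baby means across groups; gamma times and
out-of-pocket amounts; income-band and employment distributions tilted
against the depressed group; and asset indicators driven by a latent wealth
score shifted down by 0.5 when depressed. Children are collapsed to one
aggregate child-cost stream per mother.

The generator deliberately does **not** emulate: intervention arms or
treatment effects (all women are pooled irrespective of arm), item-level
screening instruments (enrolment is a single thresholded draw),
within-person correlation of depression over time (an autocorrelation
parameter exists but defaults to 0), item non-response (attrition is the
only missingness), within-wave per-visit time variation (per-wave means
stand for each visit), or any dependence between a participant's
utilisation across waves. Passing tests therefore demonstrate that the
pipeline's arithmetic and distributional machinery are correct under these
idealised conditions — not that real perinatal cost data meet them, and not
that the default calibration reproduces any particular cohort's cost
levels.

## Numerical and degenerate-input choices

* Seeded determinism everywhere: the generator seeds once per cohort; PSA
  seeds one stream per model, derived from the run seed by offset.
* σ = 0 (or μ = 0) state costs become point masses; μ = 0 with σ > 0 is an
  error (the gamma is undefined), as are negative moments.
* Division-by-zero is an explicit, named error: zero activity in gross
  costing, zero PDE in the hospital split, non-positive income in the
  valuation.
* Empty group × wave cells abort a state summary with the cell named; an
  attrition-emptied cell in the generator is logged, not fatal.
* MCA drops constant variables with a logged warning and refuses
  all-constant input; quantile grouping refuses fewer distinct scores than
  groups.
* Unit costs are stored at full precision; only reports round.

## Problem sizes used by the test suite

The suite exercises distributional-recovery properties at 5,000
participants, Kruskal–Wallis calibration over 2,000 null simulations at
n = 30 per group, end-to-end parameter recovery on a 2,000-participant
no-attrition cohort across all 8 models (deterministic totals against
closed-form means within 2 sampling standard errors, with the covariance
induced by the spreading rules included in the error), and 10,000-iteration
PSA checks against closed-form gamma quantiles. These sizes make the checks
sharp while keeping the default suite fast.

## Known limitations

Gross costing cannot differentiate ward- or service-level intensity; the
patient-day-equivalent one-third rule is a convention, not an estimate;
self-reported utilisation with 3- and 6-month recall is noisy in ways the
generator idealises; per-wave grouping overstates the persistence of
depression when interpreting "group totals"; and the uniform hourly rate
understates costs for high earners and overstates them for women out of the
labour force — by design, as an equity weighting.
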