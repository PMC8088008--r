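---
title: "Methods: first-trimester dating from CRL, model development and method comparison"
author: "gestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-trimester dating from CRL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestage)
```

## The problem

Gestational age (GA) in early pregnancy is assigned either from the
recalled date of the last menstrual period (LMP) — GA is the scan-to-LMP
day difference over 7, in decimal weeks throughout this package — or
from ultrasound fetal biometry, which in the first trimester means the
crown-rump length (CRL, cm). Recall error makes LMP dating noisy and,
on average, biased by a few days; ultrasound dating depends on which
published CRL formula is applied. Both effects matter downstream: the
preterm-birth (PTB) threshold at 37 completed weeks turns small GA
shifts into reclassification of individual pregnancies, even when
population-level PTB rates barely move.

`gestage` packages the full workflow for studying this: a registry of
CRL dating formulae, a data-driven model-development pipeline
(denoising, truncation supplementation, fractional-polynomial search,
covariate selection), agreement analytics (Bland-Altman), and PTB
rate/classification comparison — plus a synthetic cohort generator so
that every stage is testable without access to restricted cohort data.

## The dating formulae

The registry normalises every formula to CRL in cm and GA in weeks,
recording the source publication's unit convention. The central entry
is the population-specific quadratic

$$GA = -0.02294\,CRL^2 + 1.15018\,CRL + 6.73526,$$

which is strictly increasing up to CRL $= 1.15018/(2 \times 0.02294)
\approx 25$ cm, far beyond its declared 0-10 cm validity range, so it is
invertible everywhere it is used. Six published comparators ship with
it (Hadlock; Robinson-Fleming; McLennan-Schluter; Sahota; Verburg;
INTERGROWTH-21st). Their coefficients were transcribed from the original
publications and should be treated as provisional: each entry carries
its citation, and `export_formulae()` / `import_formulae()` give a YAML
override path to correct any entry without touching code. A sanity
envelope is enforced by test: every registered formula stays within
±2 weeks of the central quadratic over CRL 1-8 cm (the shipped set stays
within 1.1 weeks).

Out-of-range CRL evaluates with a warning rather than an error: the
truncation-supplementation step (below) deliberately evaluates Hadlock
beyond the first trimester.

## The synthetic cohort: a stated world

`synthetic_config()` fixes a generative model whose defaults are the
conditions the source setting states or implies; they are not tuning
knobs. Per participant (each with an RNG stream derived from
`(seed, participant index)`, so enlarging a cohort never perturbs
existing rows):

* **True growth law**: true CRL at a scan is the inverse of the truth
  formula (default the central quadratic) at the true GA.
* **Enrolment**: true GA at the dating scan is uniform on 6-14 weeks.
  Because the quadratic's image starts at 6.74 weeks (its intercept at
  CRL = 0), the draw is truncated below to the formula's attainable
  image — an enrolment floor of ~6.8 weeks. A beta-shaped preset
  (`enrolment_preset("garbhini_like")`) approximates the late-skewed
  enrolment actually observed (median ~11.7 weeks) but is not the
  default, since the exact empirical shape is unknown.
* **Truncation**: CRL is recorded only while true GA < 14 weeks, the
  clinical practice bound; a second scan occurs at 11-14 weeks with
  probability 0.3.
* **LMP recall error**: the observed LMP date is the true date minus
  `lmp_bias_days = 3` (positive bias = LMP recalled earlier = LMP-based
  GA inflated; 3 days is the overestimation reported for this setting),
  minus day-level noise with SD 13 days, with a 5% fraction further
  shifted by ±28 days (a missed cycle, direction random). The 13-day
  noise is derived, not guessed: with the bias and gross-error settings
  fixed, it reproduces the reported ~2.0-week SD of USG-LMP differences
  ($\sqrt{(13/7)^2 + 0.05\,(28/7)^2} \approx 2.06$ weeks).
* **CRL measurement noise**: additive Gaussian, SD 0.1 cm — the scale
  of intra-observer calliper variability.
* **Delivery**: GA at delivery is a two-component truncated-normal
  mixture — term N(39.0, 1.2) on [37, 45], preterm N(34.5, 2.0) on
  [20, 37) — with mixture weight `preterm_fraction = 0.14` (inside the
  11.3-16.5% range different dating methods produce, and bracketing the
  39.0-week term median). Truncation at the 37-week boundary makes the
  realised preterm fraction equal the mixture weight exactly, which the
  law-of-large-numbers tests rely on; the boundary is nudged half a day
  so that rounding dates to whole days cannot flip a drawn preterm
  across 37.0.
* **Covariates** (BMI, flags for smoking/tobacco/alcohol/unreliable
  LMP/contraception, age, weight, height, abdominal girth, education,
  state) are drawn independently of GA at prevalences loosely matched to
  the cohort's baseline table. Independence is deliberate: in this
  stated world GA depends on CRL alone, which is exactly the conclusion
  the feature-selection pipeline is expected to rediscover.

**What a green test does not establish.** The generator reproduces the
reported agreement structure (mean difference −0.44 weeks, difference
SD ~2.0, PTB Jaccard ~0.5 between LMP and the truth formula) but not
every joint feature of real data: recall error is symmetric and
uncorrelated with everything, so heavy noise inflates the LMP-based PTB
rate by several points through term-to-preterm leakage, whereas the real
cohort showed near-equal rates (13.99 vs 14.53 per 100). That near-equality
presumably reflects skew and correlation in real recall error that this
model does not attempt. Consequently the end-to-end acceptance test
asserts what the model can state — individual-level agreement (Jaccard)
markedly below population-rate agreement — and not rate equality to
within one point. Covariate joint distributions and fetal-growth
biology are likewise out of scope.

## Denoising

Two routes to a modelling dataset mirror the study design:

* `clinical_filter()` excludes observations with an unreliable-LMP flag,
  smoking/tobacco/alcohol use, or BMI outside [18.5, 25). The exact
  study criteria are not public; the predicate set is fully replaceable
  and per-criterion exclusion counts are logged. Filtering is idempotent.
* `dbscan_filter()` removes low-density points in the (CRL cm,
  GA weeks) plane with DBSCAN at eps 0.5, minPts 20 — the study's
  parameters. **Feature space**: raw units, not z-scores, because an eps
  of 0.5 is only meaningful on a declared scale and the study presents
  raw-unit axes; `standardize = TRUE` is available and the choice is
  recorded in the output metadata. The neighbour count includes the
  point itself (classic DBSCAN; implementations differ, so it is stated).
  Border points reachable from several clusters join the cluster whose
  seed core has the lowest index — a deterministic tie-break that the
  brute-force test oracle replicates exactly. Note that eps/minPts are
  density parameters: at a few hundred observations the default settings
  label most of a realistic cohort noise; they behave as intended from
  roughly a thousand observations up, matching the scale of the original
  analysis (~2500 observations).

## Truncation supplementation and the fractional-polynomial search

CRL truncation at 14 weeks leaves the right margin of the CRL-GA curve
unanchored. `supplement_truncated()` appends simulated observations
from the Hadlock relation over 15-18 weeks (GA uniform, CRL by formula
inversion, Gaussian jitter on the GA response), flagged
`supplemented = TRUE`. How many points and how much jitter the original
analysis used is unstated; the pipeline defaults are 10% of the
training rows and the residual SD of a quadratic pilot fit (a two-pass
scheme), both configurable and recorded in provenance.

`fit_fp()` searches fractional polynomials of degree 1 or 2 with powers
from the canonical set \{−2, −1, −0.5, 0, 0.5, 1, 2, 3\} (0 = log;
a repeated power $p$ contributes $x^p$ and $x^p\log x$), fitting each
candidate by OLS and selecting by in-sample $R^2$ — the study's stated
criterion; AIC is reported alongside for diagnostics. Exact $R^2$ ties
(which arise only in degenerate data) resolve toward the candidate with
the smallest total power magnitude, by visiting candidates in that
order and requiring a strict improvement of more than $10^{-10}$.
Since every degree-1 model is nested in a degree-2 candidate, the
degree-2 search can never return a lower in-sample $R^2$. Predictors
must be positive whenever log or fractional powers are in the set;
offending rows are named rather than perturbed.

## Covariate selection

`boruta_select()` re-implements the shadow-feature algorithm on a
compact compiled random forest (bagged CART regression trees, per-node
feature subsampling of $p/3$, minimum node size 5). Three calibration
choices matter and were made after explicit failure analysis:

* **Importance is out-of-bag permutation importance**, not in-sample
  split gain. Split-gain importance systematically rewards chance
  correlations: in a finite sample some pure-noise column correlates
  with the response at the ~2-sigma level, deep greedy splits exploit it
  repeatedly, and the column beats its permuted shadows in well over
  half the rounds — so pure noise gets "confirmed". OOB permutation
  importance measures damage to held-out-of-bag predictions and keeps
  the shadow comparison calibrated. (The gain measure remains available
  via `importance = "variance"` for diagnostics.)
* **Three shadow replicates per active feature** (`shadow_mult = 3`):
  the hit benchmark is the maximum shadow importance, and a max over a
  thin shadow pool is too easy to beat; extra independent permutations
  raise the bar without touching real features.
* **Bonferroni uses the full candidate count in every round.**
  Correcting only over the still-undecided set lets a lucky straggler
  face no correction once it is the last one standing.

With these, across 20 fresh datasets a planted linear signal among nine
noise features is confirmed (and nothing else) in 20/20, and pure noise
yields zero confirmations in 19/20 — the behaviour the binomial
false-positive arithmetic predicts.

`glm_select()` offers two modes, both labelled assumptions because the
original GLM procedure is unspecified: an L1-penalised linear model
with the penalty chosen by cross-validation (`lambda.1se`; an explicit
`penalty` bypasses CV, with `penalty = 0` recovering the OLS support
and `penalty -> Inf` the empty set), and backward stepwise AIC.
`union_features()` merges confirmed sets over a shared candidate
universe. `build_candidate_equations()` enumerates all feature subsets
crossed with linear/log/quadratic/fractional per-feature forms, always
keeping the CRL quadratic as base, and `evaluate_candidates()` scores
them by held-out $R^2$. On data generated with GA depending on CRL
alone, no candidate beats the CRL-only baseline by more than 0.01 —
the package-level restatement of "covariates did not improve the
dating model".

## Agreement and preterm-birth comparison

`bland_altman()` reports the mean, SD (n−1), and mean ± 1.96 SD limits
of agreement of paired differences, always labelled with the explicit
orientation (`a - b`) to keep the sign unambiguous; the 1.96 multiplier
matches the conventional 95% band (a small-sample t correction is
available by flag but off by default). The percent outside the LoA uses
strict inequality. The optional trend is the OLS slope of difference on
pair mean with a 95% CI; CIs on the LoA themselves are not produced.

`ptb_report()` applies each dating method's redating semantics —
delivery GA is the method's GA at the anchor scan (the first, by
default) plus calendar time to delivery; the `"lmp"` pseudo-method
dates from the recalled LMP directly. Classification uses
"before 37 completed weeks": exactly 37.0 is term. Rates per 100 live
births carry Wilson score intervals by default (Clopper-Pearson by
flag; the interval method is printed beside the interval because the
original is unspecified). Pairwise differences use two-sided Fisher
exact tests with Bonferroni correction by the number of pairs;
individual-level agreement uses the Jaccard coefficient of the preterm
sets (defined as 1 when both sets are empty). Sensitivity/specificity/
balanced accuracy require an explicitly declared reference standard —
truth labels on synthetic data, a user-named column on real data,
never silently the LMP method, because the original's reference is
unstated. Participants with missing delivery dates drop out of the
affected denominators with logged counts.

## Numerical choices and degenerate inputs

* GA is decimal weeks everywhere; dates are ISO-8601 in files and
  `Date` in memory; day differences are exact integers divided by 7.
* CRL plausibility at read time: 0 < CRL ≤ 10 cm (CRL at 14 weeks is
  ~8.5 cm), configurable per schema; violating rows are rejected into a
  reasoned exclusion log rather than failing the read.
* Formula inversion is bisection (`uniroot`) to 1e-12 on strictly
  monotone registered forms; registration itself rejects non-monotone
  or non-positive expressions on a 1000-point grid.
* `r_squared()` errors on constant observations and returns negative
  values unclamped (flagged), which held-out evaluation of an external
  model can legitimately produce.
* Degenerate DBSCAN inputs: empty input gives empty labels; fewer rows
  than minPts warns and labels everything noise.
* Random streams: the generator and Boruta derive per-unit seeds below
  $2^{31}$ from the master seed; global RNG state is saved and restored,
  so package calls do not perturb a caller's random sequence.

## Known limitations

* Comparator coefficients are best-effort transcriptions (the
  McLennan-Schluter entry least certain); the YAML override path is the
  supported correction mechanism.
* Two scans of one participant enter paired analyses as independent
  observations, as in the original design; no repeated-measures
  variance components are modelled.
* The recall-error model is symmetric and independent; see the
  generator section for what that excludes.
* No second/third-trimester multi-parameter biometry, no PTB
  subcategories, no birthweight centiles.
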