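# gestage

First-trimester pregnancy dating from crown-rump length (CRL), and what
the choice of dating method does to preterm-birth (PTB) statistics.

## The problem

Gestational age (GA) in early pregnancy is estimated either from the
recalled last menstrual period (LMP) — GA = (scan date − LMP date)/7 in
decimal weeks — or from ultrasound CRL through a published dating
formula. Recall error biases and disperses the LMP estimate; the choice
of CRL formula shifts the ultrasound estimate. Because preterm birth is
defined by a hard threshold (delivery before 37 completed weeks), these
shifts change the estimated PTB rate and, more dramatically, *which*
pregnancies are classified preterm: two methods can report similar
population rates while agreeing on barely half of the individual
preterm calls.

`gestage` is an R package for epidemiologists and perinatal researchers
working on this problem. It provides:

* a **formula registry** with the population-specific quadratic

  GA = −0.02294·CRL² + 1.15018·CRL + 6.73526  (CRL cm, GA weeks)

  and six published comparators (Hadlock, Robinson–Fleming,
  McLennan–Schluter, Sahota, Verburg, INTERGROWTH-21st), normalised to
  cm/weeks, invertible, and overridable via YAML;
* a **cohort data model** (scan-level CSV, validation with a reasoned
  exclusion log, ISO-8601 dates);
* a **synthetic cohort generator** with a configurable LMP recall-error
  model (bias + day-level noise + missed-cycle gross errors), CRL
  truncation at 14 weeks, and a term/preterm delivery mixture;
* **denoising** by clinical criteria or DBSCAN (eps 0.5, minPts 20 on
  the raw CRL × GA plane);
* **model development**: truncation supplementation from the Hadlock
  relation (15–18 weeks) and exhaustive fractional-polynomial search
  (powers {−2, −1, −0.5, 0, 0.5, 1, 2, 3}) selected by R²;
* **covariate selection**: Boruta (shadow features on a compiled
  random-forest regressor) and GLM (L1 / stepwise) routes, their union,
  and candidate-equation enumeration;
* **method comparison**: Bland–Altman limits of agreement, pairwise
  formula matrices, PTB rates with Wilson/Clopper–Pearson intervals,
  pairwise Fisher exact tests (Bonferroni), Jaccard classification
  agreement, and sensitivity/balanced accuracy against a declared
  reference.

## Worked example

```r
library(gestage)

predict_ga_garbhini(c(1.2, 4.0, 7.5))
#> [1]  8.082442 10.968940 14.071235

cfg <- synthetic_config(n_participants = 2000, seed = 7)
coh <- generate_cohort(cfg)
coh
#> <cohort_table> synthetic: N_p = 2000 participants, N_o = 2470 observations

model <- fit_dating_pipeline(coh, denoise = "dbscan")
model
#> <fp_model> degree 2 powers ( 0, 0.5 )
#> (Intercept)      log(x)       x^0.5
#>    2.897981   -1.400795    5.234783
#> R^2 = 0.7374, sigma = 1.519 weeks, n = 2438 (222 supplemented)

obs <- coh$observations[!is.na(coh$observations$crl_cm), ]
bland_altman(predict_ga("garbhini_ga1", obs$crl_cm, warn_out_of_range = FALSE),
             obs$ga_lmp_weeks, orientation = "usg - lmp")
#> <ba_result> usg - lmp: mean -0.461 +/- 1.954 weeks, LoA (-4.290, 3.367),
#>             5.08% outside (n = 2439)

rep <- ptb_report(coh, c("garbhini_ga1", "hadlock", "lmp"), reference = "truth")
rep
#> <ptb_comparison> 2000 participants, 3 methods (reference: truth)
#>         method   k    n  rate ci_lower ci_upper
#> 1 garbhini_ga1 268 1984 13.51    12.07    15.08
#> 2      hadlock 364 1984 18.35    16.71    20.11
#> 3          lmp 421 2000 21.05    19.32    22.89

round(rep$jaccard["garbhini_ga1", "lmp"], 2)
#> [1] 0.48
```

Reading the numbers: this synthetic cohort plants a 3-day LMP recall
bias and ~2-week recall dispersion. The Bland–Altman row shows the
ultrasound-minus-LMP mean difference of −0.46 weeks (≈ −3/7: LMP
overestimates GA by the planted 3 days) with 95% limits of agreement
about ±2 SD wide. The fitted degree-2 fractional polynomial tracks the
true growth law to within a few hundredths of a week inside the data
range — at this noise level several power pairs are statistically
interchangeable, so the selected pair varies by seed while the curve
does not. The PTB table shows how the same deliveries yield rates from
13.5 to 21.1 per 100 depending only on the dating method, and the
Jaccard coefficient of 0.48 says the LMP and CRL methods agree on less
than half of the individual preterm calls even though both rates are
"plausible" — the package's headline phenomenon.

## Command-line interface

```sh
exec/gestage formulae list
exec/gestage simulate --n 1000 --seed 1 --out cohort.csv --truth truth.csv
exec/gestage filter --in cohort.csv --method dbscan --eps 0.5 --min-points 20 --out filtered.csv
exec/gestage fit --in cohort.csv --denoise dbscan --degree 2 --out model.yaml
exec/gestage compare --in cohort.csv --a garbhini_ga1 --b lmp
exec/gestage ptb --in cohort.csv --formulae garbhini_ga1,hadlock,lmp --reference truth --out report.json
```

## Documentation

`vignettes/gestage-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, the numerical choices
(tie-breaks, tolerances, degenerate inputs), and known limitations.
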