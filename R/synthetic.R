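# Synthetic cohort generator.
#
# Emulates the statistical structure the dating analysis assumes: a true
# CRL-GA growth law, enrolment before 14 weeks with CRL truncation at 14
# weeks, an optional 11-14 week second scan, LMP recall error (systematic
# bias + day-level noise + a gross-error fraction of +/- one cycle), CRL
# measurement noise, and a delivery GA mixture with a configurable
# preterm fraction. Covariates are drawn independently of GA: in the
# stated world GA depends on CRL alone, which is exactly what the
# feature-selection pipeline is expected to rediscover.

#' Configuration for the synthetic cohort generator
#'
#' All parameters of the generative model, with defaults chosen to mirror
#' the study setting (see the methods vignette for the reasoning behind
#' each value):
#'
#' * enrolment GA uniform on 6-14 weeks (truncated below to the truth
#'   formula's attainable image);
#' * LMP recalled 3 days early on average (`lmp_bias_days = 3`, the
#'   direction and size of recall bias reported for this cohort), with
#'   13-day recall noise and a 5% gross-error fraction of +/- 28 days
#'   (one missed cycle) — together these give an USG-LMP difference SD
#'   of about 2.0 weeks, the dispersion reported for the cohort;
#' * CRL measurement noise 0.1 cm;
#' * delivery GA a two-component truncated-normal mixture: term
#'   N(39.0, 1.2) on \[37, 45\], preterm N(34.5, 2.0) on \[20, 37), with
#'   mixture weight `preterm_fraction` (default 0.14, inside the 11.3-16.5%
#'   range the different dating methods produce);
#' * covariate flag prevalences loosely matched to the cohort's baseline
#'   table (e.g. 7.3% contraceptive use, 27% underweight via the BMI
#'   distribution).
#'
#' @param n_participants Number of participants.
#' @param seed Integer master seed. Each participant gets an RNG stream
#'   derived from `(seed, participant index)`, so enlarging the cohort
#'   never perturbs existing rows.
#' @param truth_formula_id Registered formula used as the true growth law.
#' @param enrolment_ga_dist List: `type` `"uniform"` (default, `min`/`max`)
#'   or `"beta"` (`shape1`, `shape2`, rescaled to `min`/`max`); the beta
#'   preset `enrolment_preset("garbhini_like")` approximates the cohort's
#'   late-skewed enrolment (median ~11.7 weeks).
#' @param second_scan_prob Probability of an 11-14 week second scan.
#' @param crl_noise_sd_cm SD of additive CRL measurement noise, cm.
#' @param lmp_bias_days Systematic recall bias in days; positive means
#'   LMP is recalled earlier than truth, inflating LMP-based GA.
#' @param lmp_noise_sd_days SD of day-level LMP recall noise.
#' @param gross_error_frac Fraction of participants with a gross LMP
#'   error of `+/- gross_error_shift_days` (direction random).
#' @param gross_error_shift_days Magnitude of the gross error, days.
#' @param preterm_fraction Probability that delivery GA < 37 weeks.
#' @param delivery_ga_dist List with `term_mean`, `term_sd`,
#'   `preterm_mean`, `preterm_sd` (weeks).
#' @param covariate_prevalence Named list of Bernoulli flag prevalences
#'   (`smoker`, `tobacco`, `alcohol`, `unreliable_lmp`, `contraceptive`).
#' @param crl_truncation_weeks CRL recorded only when true GA is below
#'   this (clinical practice stops CRL at 14 weeks).
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_participants = 1000,
                             seed = 1L,
                             truth_formula_id = "garbhini_ga1",
                             enrolment_ga_dist = list(type = "uniform",
                                                      min = 6, max = 14),
                             second_scan_prob = 0.3,
                             crl_noise_sd_cm = 0.1,
                             lmp_bias_days = 3,
                             lmp_noise_sd_days = 13,
                             gross_error_frac = 0.05,
                             gross_error_shift_days = 28,
                             preterm_fraction = 0.14,
                             delivery_ga_dist = list(term_mean = 39.0,
                                                     term_sd = 1.2,
                                                     preterm_mean = 34.5,
                                                     preterm_sd = 2.0),
                             covariate_prevalence = list(smoker = 0.03,
                                                         tobacco = 0.10,
                                                         alcohol = 0.02,
                                                         unreliable_lmp = 0.20,
                                                         contraceptive = 0.073),
                             crl_truncation_weeks = 14) {
  cfg <- list(n_participants = n_participants, seed = as.integer(seed),
              truth_formula_id = truth_formula_id,
              enrolment_ga_dist = enrolment_ga_dist,
              second_scan_prob = second_scan_prob,
              crl_noise_sd_cm = crl_noise_sd_cm,
              lmp_bias_days = lmp_bias_days,
              lmp_noise_sd_days = lmp_noise_sd_days,
              gross_error_frac = gross_error_frac,
              gross_error_shift_days = gross_error_shift_days,
              preterm_fraction = preterm_fraction,
              delivery_ga_dist = delivery_ga_dist,
              covariate_prevalence = covariate_prevalence,
              crl_truncation_weeks = crl_truncation_weeks)
  probs <- c(second_scan_prob, gross_error_frac, preterm_fraction,
             unlist(covariate_prevalence))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (crl_noise_sd_cm < 0 || lmp_noise_sd_days < 0) {
    stop("noise SDs must be non-negative")
  }
  if (n_participants < 0) stop("n_participants must be >= 0")
  get_formula(truth_formula_id) # fails early on unknown id
  class(cfg) <- "synthetic_config"
  cfg
}

#' Enrolment-distribution presets
#'
#' `"uniform"` is the default stated world; `"garbhini_like"` is a
#' beta-shaped alternative skewed towards late first-trimester enrolment
#' (median ~11.6 weeks, approximating the cohort's reported median 11.71,
#' IQR 9.29-13.0 — the exact empirical shape is unknown).
#'
#' @param name Preset name.
#' @return A distribution list for `enrolment_ga_dist`.
#' @export
enrolment_preset <- function(name = c("uniform", "garbhini_like")) {
  name <- match.arg(name)
  switch(name,
         uniform = list(type = "uniform", min = 6, max = 14),
         garbhini_like = list(type = "beta", shape1 = 1.8, shape2 = 1.0,
                              min = 6, max = 14))
}

draw_enrolment_ga <- function(dist, n, lo_attainable) {
  lo <- max(dist$min %||% 6, lo_attainable)
  hi <- dist$max %||% 14
  if (identical(dist$type, "beta")) {
    lo_q <- (lo - dist$min) / (dist$max - dist$min)
    u <- runif(n, min = stats::pbeta(lo_q, dist$shape1, dist$shape2), max = 1)
    dist$min + (dist$max - dist$min) *
      stats::qbeta(u, dist$shape1, dist$shape2)
  } else {
    runif(n, lo, hi)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 100003) %% 2147483629L)
}

#' Generate a synthetic cohort
#'
#' Draws, per participant and from a participant-specific RNG stream:
#' a true LMP date; a true GA at the dating scan; true CRL from the
#' inverted truth formula; observed CRL with Gaussian measurement noise
#' (recorded only while true GA is below the truncation point); an
#' observed LMP date shifted by the systematic bias, day-level recall
#' noise and possibly a gross +/- one-cycle error; an optional second
#' scan at 11-14 weeks; a delivery GA from the term/preterm mixture; and
#' independent covariate flags. Dates are rounded to whole days, as in
#' any real cohort record.
#'
#' Ground truth (true GA per scan, true CRL, true delivery GA, true
#' preterm label) is attached to the result and retrievable with
#' [truth_table()].
#'
#' @param config A [synthetic_config()].
#' @return A `cohort_table` with provenance `"synthetic"`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_participants = 50, seed = 7))
#' coh
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  entry <- get_formula(config$truth_formula_id)
  ga_image_lo <- entry$fn(entry$valid_crl_range[1])
  base_date <- as.Date("2019-01-01")
  dd <- config$delivery_ga_dist
  n <- config$n_participants

  obs_list <- vector("list", n)
  truth_scan_list <- vector("list", n)
  part_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(participant_seed(config$seed, i))
    pid <- sprintf("P%05d", i)
    true_lmp <- base_date + floor(runif(1, 0, 365))

    ga_scan1 <- draw_enrolment_ga(config$enrolment_ga_dist, 1, ga_image_lo + 0.05)
    scan_ga <- ga_scan1
    scan_idx <- 1L
    if (runif(1) < config$second_scan_prob) {
      ga_scan2 <- runif(1, 11, 14)
      if (round(ga_scan2 * 7) > round(ga_scan1 * 7)) {
        scan_ga <- c(scan_ga, ga_scan2)
        scan_idx <- c(scan_idx, 2L)
      }
    }
    scan_dates <- true_lmp + round(scan_ga * 7)
    true_ga <- as.numeric(scan_dates - true_lmp) / 7  # day-resolution truth

    crl_true <- rep(NA_real_, length(true_ga))
    measurable <- true_ga < config$crl_truncation_weeks &
      true_ga >= ga_image_lo
    if (any(measurable)) {
      crl_true[measurable] <- invert_formula(config$truth_formula_id,
                                             true_ga[measurable],
                                             extend_cm = 2)
    }
    crl_obs <- crl_true + rnorm(length(crl_true), 0, config$crl_noise_sd_cm)
    crl_obs <- ifelse(!is.na(crl_obs) & crl_obs < 0.05, 0.05, crl_obs)

    lmp_err <- config$lmp_bias_days +
      round(rnorm(1, 0, config$lmp_noise_sd_days))
    if (runif(1) < config$gross_error_frac) {
      lmp_err <- lmp_err + sample(c(-1, 1), 1) * config$gross_error_shift_days
    }
    obs_lmp <- true_lmp - lmp_err

    is_preterm <- runif(1) < config$preterm_fraction
    delivery_ga <- if (is_preterm) {
      truncnorm::rtruncnorm(1, a = 20, b = 37 - 1 / 14,
                            mean = dd$preterm_mean, sd = dd$preterm_sd)
    } else {
      truncnorm::rtruncnorm(1, a = 37, b = 45,
                            mean = dd$term_mean, sd = dd$term_sd)
    }
    delivery_date <- true_lmp + round(delivery_ga * 7)
    true_delivery_ga <- as.numeric(delivery_date - true_lmp) / 7

    cp <- config$covariate_prevalence
    flags <- vapply(cp, function(p) runif(1) < p, logical(1))
    bmi <- rnorm(1, 20.5, 3.2)
    height_cm <- rnorm(1, 153, 5)
    weight_kg <- bmi * (height_cm / 100)^2
    girth_cm <- rnorm(1, 80, 8)
    age <- round(pmin(pmax(rnorm(1, 23.5, 4), 18), 42))
    education <- sample(0:6, 1, prob = c(0.216, 0.086, 0.151, 0.186,
                                         0.209, 0.122, 0.030))
    state <- sample(c("HR", "UP", "DL", "RJ", "other"), 1,
                    prob = c(0.55, 0.2, 0.1, 0.08, 0.07))

    k <- length(true_ga)
    obs_list[[i]] <- data.frame(
      participant_id = pid, scan_index = scan_idx,
      scan_date = scan_dates, lmp_date = obs_lmp,
      crl_cm = crl_obs, delivery_date = delivery_date,
      smoker = flags[["smoker"]], tobacco = flags[["tobacco"]],
      alcohol = flags[["alcohol"]],
      unreliable_lmp = flags[["unreliable_lmp"]],
      contraceptive = flags[["contraceptive"]],
      bmi = bmi, weight_kg = weight_kg, height_cm = height_cm,
      abdominal_girth_cm = girth_cm, age_years = age,
      maternal_education = education, resident_state = state,
      stringsAsFactors = FALSE)
    truth_scan_list[[i]] <- data.frame(
      participant_id = pid, scan_index = scan_idx,
      true_ga_weeks = true_ga, true_crl_cm = crl_true,
      stringsAsFactors = FALSE)
    part_rows[[i]] <- data.frame(
      participant_id = pid, true_delivery_ga_weeks = true_delivery_ga,
      preterm_true = true_delivery_ga < 37, stringsAsFactors = FALSE)
  }

  obs <- do.call(rbind, obs_list)
  if (is.null(obs)) {
    obs <- data.frame(participant_id = character(0), scan_index = integer(0),
                      scan_date = as.Date(character(0)),
                      lmp_date = as.Date(character(0)),
                      crl_cm = numeric(0),
                      delivery_date = as.Date(character(0)))
  }
  truth <- list(scans = do.call(rbind, truth_scan_list),
                participants = do.call(rbind, part_rows))
  cohort <- as_cohort_table(obs, provenance = "synthetic",
                            extra_meta = list(truth = truth,
                                              config = config))
  cohort
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort A `cohort_table` produced by [generate_cohort()].
#' @return List with `scans` (participant_id, scan_index, true GA, true
#'   CRL) and `participants` (true delivery GA, true preterm label).
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!identical(cohort$metadata$provenance, "synthetic") ||
      is.null(cohort$metadata$truth)) {
    stop("cohort carries no ground truth (not produced by generate_cohort)")
  }
  cohort$metadata$truth
}
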