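# Method-agreement analytics: Bland-Altman analysis and all-pairs
# formula comparison matrices. Difference orientation is always a - b
# and is recorded in the result so the sign is never ambiguous (USG - LMP
# negative means the LMP method overestimates GA).

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`. Limits of agreement are
#' `mean +/- 1.96 * SD` (SD with n-1 denominator); the 1.96 multiplier is
#' the conventional 95% band, with an optional small-sample t correction.
#' `pct_outside_loa` counts pairs strictly outside the closed LoA
#' interval. The optional trend is the OLS slope of the difference on the
#' pair mean, with a 95% CI.
#'
#' @param ga_a,ga_b Paired numeric vectors (GA in weeks here, but the
#'   analysis is generic); pairs with a missing member are dropped.
#' @param orientation Label recorded in the result, e.g. `"usg - lmp"`.
#' @param t_correction Use the t quantile instead of 1.96.
#' @param trend Also fit difference ~ mean.
#' @return A `ba_result`: `n`, `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `pct_outside_loa`, and optionally `trend_slope`,
#'   `trend_ci`.
#' @examples
#' ba <- bland_altman(c(10, 11, 12), c(11, 11, 11))
#' ba$loa_lower; ba$loa_upper # -1.96, 1.96
#' @export
bland_altman <- function(ga_a, ga_b, orientation = "a - b",
                         t_correction = FALSE, trend = FALSE) {
  if (length(ga_a) != length(ga_b)) stop("paired vectors differ in length")
  ok <- is.finite(ga_a) & is.finite(ga_b)
  a <- ga_a[ok]; b <- ga_b[ok]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs")

  d <- a - b
  m <- mean(d)
  s <- sd(d)
  mult <- if (t_correction) stats::qt(0.975, n - 1) else 1.96
  lo <- m - mult * s
  hi <- m + mult * s
  outside <- d < lo | d > hi
  res <- list(n = n, mean_diff = m, sd_diff = s,
              loa_lower = lo, loa_upper = hi,
              pct_outside_loa = 100 * mean(outside),
              orientation = orientation, loa_multiplier = mult)
  if (trend) {
    pair_mean <- (a + b) / 2
    fit <- lm(d ~ pair_mean)
    ci <- stats::confint(fit)["pair_mean", ]
    res$trend_slope <- unname(coef(fit)["pair_mean"])
    res$trend_ci <- unname(ci)
  }
  structure(res, class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<ba_result> %s: mean %.3f +/- %.3f weeks, LoA (%.3f, %.3f), %.2f%% outside (n = %d)\n",
              x$orientation, x$mean_diff, x$sd_diff, x$loa_lower,
              x$loa_upper, x$pct_outside_loa, x$n))
  invisible(x)
}

#' All-pairs Bland-Altman matrix of dating formulae
#'
#' Evaluates every registered formula in `formula_ids` on the cohort's
#' CRL values and runs a Bland-Altman analysis for every ordered pair.
#' Entry (i, j) has `mean_diff` equal to minus that of (j, i); the
#' diagonal is the zero element.
#'
#' @param cohort A `cohort_table`; rows without CRL are dropped.
#' @param formula_ids Character vector of at least 2 registered ids; the
#'   pseudo-id `"lmp"` uses `ga_lmp_weeks` instead of a CRL formula.
#' @return List with `mean_diff` matrix, `sd_diff` matrix, and the full
#'   `ba` matrix of `ba_result` objects.
#' @export
pairwise_formula_matrix <- function(cohort, formula_ids) {
  stopifnot(inherits(cohort, "cohort_table"), length(formula_ids) >= 2)
  obs <- cohort$observations
  keep <- !is.na(obs$crl_cm)
  if ("lmp" %in% formula_ids) keep <- keep & !is.na(obs$ga_lmp_weeks)
  obs <- obs[keep, , drop = FALSE]
  ga <- sapply(formula_ids, function(id) {
    if (identical(id, "lmp")) obs$ga_lmp_weeks
    else predict_ga(id, obs$crl_cm, warn_out_of_range = FALSE)
  })
  k <- length(formula_ids)
  mean_m <- sd_m <- matrix(0, k, k, dimnames = list(formula_ids, formula_ids))
  ba_m <- matrix(list(), k, k, dimnames = list(formula_ids, formula_ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ba <- bland_altman(ga[, i], ga[, j],
                       orientation = paste(formula_ids[i], "-", formula_ids[j]))
    mean_m[i, j] <- ba$mean_diff
    sd_m[i, j] <- ba$sd_diff
    ba_m[[i, j]] <- ba
  }
  list(mean_diff = mean_m, sd_diff = sd_m, ba = ba_m, n = nrow(obs))
}

#' Evaluate a model or formula against a truth column
#'
#' Predicts GA from CRL on the test cohort with either a fitted
#' `fp_model` or a registered formula id, then reports \eqn{R^2} against
#' the declared truth column and a Bland-Altman analysis (predictions
#' minus truth).
#'
#' @param model_or_formula An `fp_model` or a registered formula id.
#' @param test_cohort A `cohort_table`.
#' @param truth Truth column name in the observations (default
#'   `"ga_lmp_weeks"`, the observable stand-in on real data) or a numeric
#'   vector aligned with the observation rows (e.g. synthetic true GA).
#' @return List with `r2` and `ba` (a `ba_result`).
#' @export
evaluate_on_test <- function(model_or_formula, test_cohort,
                             truth = "ga_lmp_weeks") {
  stopifnot(inherits(test_cohort, "cohort_table"))
  obs <- test_cohort$observations
  truth_vec <- if (is.character(truth)) obs[[truth]] else truth
  if (is.null(truth_vec) || length(truth_vec) != nrow(obs)) {
    stop("truth column missing or misaligned")
  }
  ok <- !is.na(obs$crl_cm) & is.finite(truth_vec)
  if (!any(ok)) stop("empty test set after dropping incomplete rows")
  crl <- obs$crl_cm[ok]
  pred <- if (inherits(model_or_formula, "fp_model")) {
    predict(model_or_formula, crl)
  } else {
    predict_ga(model_or_formula, crl, warn_out_of_range = FALSE)
  }
  list(r2 = r_squared(truth_vec[ok], pred),
       ba = bland_altman(pred, truth_vec[ok],
                         orientation = "prediction - truth"))
}
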