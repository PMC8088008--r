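# Truncation-aware fractional-polynomial regression of GA on CRL.
#
# CRL is not measured past 14 weeks, so a curve fitted to first-trimester
# data alone is unanchored at the right margin. The remedy is to
# supplement the dataset with simulated observations from a reference
# relation (Hadlock) over 15-18 weeks before searching fractional-
# polynomial forms.

fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_term <- function(x, p) if (p == 0) log(x) else x^p

fp_design <- function(x, powers) {
  if (length(powers) == 1) {
    m <- cbind(fp_term(x, powers))
  } else if (powers[1] == powers[2]) {
    # repeated power p: x^p and x^p * log(x)  (p = 0: log x and (log x)^2)
    t1 <- fp_term(x, powers[1])
    m <- cbind(t1, t1 * log(x))
  } else {
    m <- cbind(fp_term(x, powers[1]), fp_term(x, powers[2]))
  }
  colnames(m) <- fp_term_names(powers)
  m
}

fp_term_names <- function(powers) {
  nm <- function(p) if (p == 0) "log(x)" else paste0("x^", p)
  if (length(powers) == 2 && powers[1] == powers[2]) {
    t1 <- nm(powers[1])
    c(t1, paste0(t1, "*log(x)"))
  } else {
    vapply(powers, nm, character(1))
  }
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} about the mean of `y`. On held-out
#' data with an externally fitted model the value can be negative; it is
#' returned as-is (not clamped) with an attribute noting the clamp that
#' reporting may apply.
#'
#' @param y Observed values, length >= 2, non-constant.
#' @param y_hat Predictions, same length.
#' @return Numeric scalar in (-Inf, 1].
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("y is constant: R-squared undefined")
  val <- 1 - sum((y - y_hat)^2) / ss_tot
  if (val < 0) attr(val, "note") <- "negative R-squared (worse than mean-only)"
  val
}

#' Fit a fractional-polynomial regression
#'
#' Exhaustive search over degree-1 powers or degree-2 power pairs from
#' `power_set` (default Royston-Altman \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\};
#' power 0 denotes log; a repeated power p contributes \eqn{x^p} and
#' \eqn{x^p\log x}). Each candidate is fitted by ordinary least squares
#' and the candidate with maximal in-sample \eqn{R^2} wins; exact ties go
#' to the candidate with smaller total power magnitude (visited first).
#'
#' @param x Positive predictor (CRL in cm here; log and negative powers
#'   require positivity — offending rows are named in the error).
#' @param y Response (GA in weeks).
#' @param degree 1 or 2.
#' @param power_set Numeric vector of candidate powers.
#' @return An `fp_model`: powers, coefficients (intercept first),
#'   standard errors, `r_squared`, `aic`, residual SD `sigma`, `n_obs`.
#' @examples
#' x <- runif(100, 1, 9)
#' y <- -0.02294 * x^2 + 1.15018 * x + 6.73526
#' fit_fp(x, y, degree = 2)$powers # c(1, 2)
#' @export
fit_fp <- function(x, y, degree = 2, power_set = fp_power_set()) {
  stopifnot(degree %in% c(1, 2), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < degree + 2) stop("need at least degree + 2 points")
  needs_pos <- any(power_set < 1 | power_set != round(power_set)) ||
    0 %in% power_set
  if (needs_pos && any(x <= 0)) {
    stop("x must be positive for log/fractional/negative powers; ",
         "offending rows: ", paste(head(which(x <= 0), 10), collapse = ", "))
  }

  ps <- sort(power_set)
  cands <- if (degree == 1) {
    lapply(ps, function(p) p)
  } else {
    out <- list()
    for (i in seq_along(ps)) for (j in i:length(ps)) {
      out[[length(out) + 1]] <- c(ps[i], ps[j])
    }
    out
  }
  # visit simpler candidates first so exact R^2 ties resolve to them
  ord <- order(vapply(cands, function(p) sum(abs(p)), numeric(1)))
  cands <- cands[ord]

  best <- NULL
  for (powers in cands) {
    X <- cbind(`(Intercept)` = 1, fp_design(x, powers))
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X)) next # collinear candidate (e.g. constant x)
    rss <- sum(fit$residuals^2)
    r2 <- r_squared(y, y - fit$residuals)
    if (is.null(best) || r2 > best$r_squared + 1e-10) {
      n <- length(y)
      k <- ncol(X)
      sigma2 <- rss / (n - k)
      XtX_inv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(diag(XtX_inv) * sigma2)
      best <- list(degree = length(powers), powers = powers,
                   coefficients = setNames(fit$coefficients, colnames(X)),
                   se = setNames(se, colnames(X)),
                   r_squared = as.numeric(r2),
                   aic = n * log(2 * pi * rss / n) + n + 2 * (k + 1),
                   sigma = sqrt(sigma2), n_obs = n)
    }
  }
  if (is.null(best)) stop("no admissible fractional-polynomial candidate")
  best$supplemented_n <- 0L
  class(best) <- "fp_model"
  best
}

#' @export
print.fp_model <- function(x, ...) {
  cat("<fp_model> degree", x$degree, "powers (",
      paste(x$powers, collapse = ", "), ")\n")
  print(round(x$coefficients, 6))
  cat(sprintf("R^2 = %.4f, sigma = %.3f weeks, n = %d (%d supplemented)\n",
              x$r_squared, x$sigma, x$n_obs, x$supplemented_n))
  invisible(x)
}

#' Predict GA from a fitted fractional-polynomial model
#'
#' @param object An `fp_model`.
#' @param crl_cm CRL values in cm (must be positive if the model uses
#'   log or fractional powers).
#' @param ... Unused.
#' @return GA in decimal weeks.
#' @export
predict.fp_model <- function(object, crl_cm, ...) {
  X <- cbind(1, fp_design(crl_cm, object$powers))
  drop(X %*% object$coefficients)
}

#' Supplementation specification
#'
#' @param source_formula_id Reference relation used to simulate the
#'   beyond-truncation tail (default `"hadlock"`, validated 15-18 weeks).
#' @param ga_range GA range (weeks) of simulated observations.
#' @param n_points Number of simulated rows; `NULL` means 10% of the
#'   training rows (pipeline default).
#' @param noise_sd_weeks Gaussian jitter SD on the simulated GA response;
#'   `NULL` means the residual SD of a quadratic pilot fit (two-pass).
#' @param seed RNG seed for the simulated rows.
#' @return A `supplement_spec` list.
#' @export
supplement_spec <- function(source_formula_id = "hadlock",
                            ga_range = c(15, 18), n_points = NULL,
                            noise_sd_weeks = NULL, seed = 1L) {
  stopifnot(length(ga_range) == 2, ga_range[1] <= ga_range[2])
  if (!is.null(n_points)) stopifnot(n_points >= 0)
  structure(list(source_formula_id = source_formula_id, ga_range = ga_range,
                 n_points = n_points, noise_sd_weeks = noise_sd_weeks,
                 seed = as.integer(seed)),
            class = "supplement_spec")
}

#' Supplement a CRL-truncated dataset with simulated tail observations
#'
#' Appends `n_points` rows with GA sampled uniformly over `ga_range`,
#' CRL obtained by inverting the source formula at that GA, and the GA
#' response jittered by Gaussian noise. Appended rows carry
#' `supplemented = TRUE`. Deterministic under the spec's seed.
#'
#' @param df Data frame with columns `crl_cm` and `ga_lmp_weeks`.
#' @param spec A [supplement_spec()] with `n_points` and
#'   `noise_sd_weeks` resolved (non-`NULL`).
#' @return `df` with appended rows and a logical `supplemented` column.
#' @export
supplement_truncated <- function(df, spec = supplement_spec(n_points = 0,
                                                            noise_sd_weeks = 0)) {
  stopifnot(inherits(spec, "supplement_spec"),
            all(c("crl_cm", "ga_lmp_weeks") %in% names(df)))
  if (is.null(spec$n_points) || is.null(spec$noise_sd_weeks)) {
    stop("n_points and noise_sd_weeks must be resolved before supplementation")
  }
  if (is.null(df$supplemented)) df$supplemented <- FALSE
  if (spec$n_points == 0) return(df)

  entry <- get_formula(spec$source_formula_id)
  image <- entry$fn(entry$valid_crl_range)
  if (spec$ga_range[1] < image[1] || spec$ga_range[2] > image[2]) {
    stop("ga_range [", spec$ga_range[1], ", ", spec$ga_range[2],
         "] outside the image [", round(image[1], 2), ", ",
         round(image[2], 2), "] of '", spec$source_formula_id, "'")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  ga <- runif(spec$n_points, spec$ga_range[1], spec$ga_range[2])
  crl <- invert_formula(spec$source_formula_id, ga)
  ga_obs <- ga + rnorm(spec$n_points, 0, spec$noise_sd_weeks)

  add <- df[0, , drop = FALSE][seq_len(spec$n_points), , drop = FALSE]
  add$crl_cm <- crl
  add$ga_lmp_weeks <- ga_obs
  add$supplemented <- TRUE
  if (!is.null(add$participant_id)) add$participant_id <- "SUPPLEMENT"
  out <- rbind(df, add)
  rownames(out) <- NULL
  out
}

#' End-to-end dating-model pipeline
#'
#' Denoise (DBSCAN by default, clinical criteria or nothing as
#' alternatives) -> resolve supplementation defaults (10% of training
#' rows, pilot-fit residual SD) -> supplement the 15-18 week tail ->
#' exhaustive fractional-polynomial search. Returns the winning model
#' with stage-by-stage counts in `provenance`, study-flowchart style.
#'
#' @param cohort A `cohort_table` with `crl_cm` and `ga_lmp_weeks`.
#' @param denoise `"dbscan"`, `"clinical"` or `"none"`.
#' @param supplement A [supplement_spec()], or `NULL` to skip.
#' @param degree Fractional-polynomial degree searched (default 2).
#' @param eps,min_points DBSCAN parameters (used when
#'   `denoise = "dbscan"`).
#' @param criteria Clinical criteria (used when `denoise = "clinical"`).
#' @return An `fp_model` with a `provenance` element.
#' @export
fit_dating_pipeline <- function(cohort, denoise = c("dbscan", "clinical", "none"),
                                supplement = supplement_spec(),
                                degree = 2, eps = 0.5, min_points = 20,
                                criteria = default_clinical_criteria()) {
  denoise <- match.arg(denoise)
  stopifnot(inherits(cohort, "cohort_table"))
  prov <- list(n_input = cohort$metadata$n_o, denoise = denoise)

  work <- switch(denoise,
    dbscan = dbscan_filter(cohort, eps = eps, min_points = min_points)$cohort,
    clinical = clinical_filter(cohort, criteria)$cohort,
    none = cohort)
  prov$n_after_denoise <- work$metadata$n_o

  df <- work$observations
  df <- df[!is.na(df$crl_cm) & !is.na(df$ga_lmp_weeks),
           c("crl_cm", "ga_lmp_weeks"), drop = FALSE]
  if (nrow(df) < degree + 2) stop("denoising left too few rows to fit")
  prov$n_complete <- nrow(df)

  if (!is.null(supplement)) {
    if (is.null(supplement$n_points)) {
      supplement$n_points <- round(0.10 * nrow(df))
    }
    if (is.null(supplement$noise_sd_weeks)) {
      pilot <- fit_fp(df$crl_cm, df$ga_lmp_weeks, degree = 2,
                      power_set = c(1, 2))
      supplement$noise_sd_weeks <- pilot$sigma
    }
    df <- supplement_truncated(df, supplement)
  }
  prov$n_supplemented <- sum(df$supplemented %||% FALSE)
  prov$n_fit <- nrow(df)

  model <- fit_fp(df$crl_cm, df$ga_lmp_weeks, degree = degree)
  model$supplemented_n <- as.integer(prov$n_supplemented)
  model$provenance <- prov
  model
}
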