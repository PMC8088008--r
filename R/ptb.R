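# Preterm-birth classification per dating method, population rates with
# confidence intervals, pairwise Fisher tests, and individual-level
# agreement (Jaccard). The headline phenomenon this module quantifies:
# two dating methods can produce near-identical population PTB rates
# while disagreeing on which individuals are preterm.

#' Classify preterm birth
#'
#' Preterm is delivery strictly before 37 completed weeks; a GA of
#' exactly 37.0 is term.
#'
#' @param ga_delivery_weeks Numeric vector of delivery GA in decimal
#'   weeks; values outside (0, 50\] are a validation error.
#' @return Logical vector, `TRUE` = preterm; `NA` propagates.
#' @export
classify_ptb <- function(ga_delivery_weeks) {
  bad <- !is.na(ga_delivery_weeks) &
    (ga_delivery_weeks < 0 | ga_delivery_weeks > 50)
  if (any(bad)) {
    stop("implausible delivery GA (weeks): ",
         paste(head(round(ga_delivery_weeks[bad], 2), 5), collapse = ", "))
  }
  ga_delivery_weeks < 37.0
}

#' Preterm-birth rate per 100 live births with 95% CI
#'
#' Wilson score interval by default; exact Clopper-Pearson on request.
#' Both are reported on the per-100 scale.
#'
#' @param flags Logical vector of preterm flags (`NA` dropped with a
#'   count).
#' @param ci `"wilson"` or `"clopper-pearson"`.
#' @return List: `k`, `n`, `rate`, `ci_lower`, `ci_upper`, `ci_method`,
#'   `n_missing`.
#' @export
ptb_rate <- function(flags, ci = c("wilson", "clopper-pearson")) {
  ci <- match.arg(ci)
  n_missing <- sum(is.na(flags))
  flags <- flags[!is.na(flags)]
  n <- length(flags)
  if (n == 0) stop("no non-missing flags: empty denominator")
  k <- sum(flags)
  p <- k / n
  if (ci == "wilson") {
    z <- qnorm(0.975)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  } else {
    lo <- if (k == 0) 0 else qbeta(0.025, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(0.975, k + 1, n - k)
  }
  list(k = k, n = n, rate = 100 * p, ci_lower = 100 * lo, ci_upper = 100 * hi,
       ci_method = ci, n_missing = n_missing)
}

#' Pairwise Fisher's exact tests on preterm counts
#'
#' For every pair of methods, a two-sided Fisher's exact test on the
#' 2x2 table (preterm, term) x (method i, method j), with Bonferroni
#' correction (multiply by the number of pairs, cap at 1).
#'
#' @param k_vector Named preterm counts per method.
#' @param n_vector Denominators per method (same order).
#' @param correction `"bonferroni"` or `"none"`.
#' @return List of matrices `p_raw` and `p_adjusted` (diagonal `NA`).
#' @export
fisher_pairwise <- function(k_vector, n_vector,
                            correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(k_vector) == length(n_vector), all(k_vector <= n_vector))
  if (any(n_vector == 0)) stop("zero denominator")
  k <- length(k_vector)
  ids <- names(k_vector) %||% paste0("m", seq_len(k))
  m_pairs <- k * (k - 1) / 2
  p_raw <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tab <- matrix(c(k_vector[i], n_vector[i] - k_vector[i],
                    k_vector[j], n_vector[j] - k_vector[j]),
                  nrow = 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    p_raw[i, j] <- p_raw[j, i] <- p
  }
  p_adj <- if (correction == "bonferroni") pmin(1, p_raw * m_pairs) else p_raw
  list(p_raw = p_raw, p_adjusted = p_adj, n_pairs = m_pairs)
}

#' Jaccard similarity of two preterm sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both sets are empty
#' (total agreement that nobody is preterm).
#'
#' @param preterm_set_a,preterm_set_b Vectors of participant ids
#'   classified preterm by each method.
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
jaccard <- function(preterm_set_a, preterm_set_b) {
  a <- unique(preterm_set_a); b <- unique(preterm_set_b)
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Sensitivity, specificity and balanced accuracy
#'
#' Against a declared reference standard — never silently the LMP
#' method: on synthetic data use the truth labels, on real data the
#' caller must name the reference.
#'
#' @param pred_flags,reference_flags Equal-length logical vectors; pairs
#'   with a missing member are dropped.
#' @return List: `sensitivity`, `specificity`, `balanced_accuracy`,
#'   confusion counts. A one-class reference leaves the affected metric
#'   `NaN` with a warning.
#' @export
classification_metrics <- function(pred_flags, reference_flags) {
  stopifnot(length(pred_flags) == length(reference_flags))
  ok <- !is.na(pred_flags) & !is.na(reference_flags)
  p <- pred_flags[ok]; r <- reference_flags[ok]
  tp <- sum(p & r); fn <- sum(!p & r)
  fp <- sum(p & !r); tn <- sum(!p & !r)
  if (tp + fn == 0 || tn + fp == 0) {
    warning("reference contains a single class; affected metric undefined")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       tp = tp, fn = fn, fp = fp, tn = tn, n = sum(ok))
}

#' Preterm-birth comparison report across dating methods
#'
#' For each method, delivery GA is the method's GA at the anchor dating
#' scan plus the calendar time from that scan to delivery (redating
#' semantics); participants are then classified preterm and the module
#' computes rates with CIs, all pairwise Fisher tests (Bonferroni) and
#' Jaccard coefficients, and — when a reference is declared —
#' sensitivity / specificity / balanced accuracy per method.
#'
#' The pseudo-method `"lmp"` dates from the recalled LMP:
#' `(delivery_date - lmp_date) / 7`. Participants without a delivery
#' date (or without the anchor scan data a method needs) are dropped
#' from that method's denominator, with counts reported.
#'
#' @param cohort A `cohort_table`.
#' @param formula_ids Methods to compare: registered formula ids and/or
#'   `"lmp"`.
#' @param reference Optional reference classification: `"truth"` (the
#'   synthetic truth labels), one of `formula_ids`, or a named logical
#'   vector keyed by participant id.
#' @param anchor_scan Which scan anchors redating when two exist
#'   (default 1, the dating scan).
#' @param ci Interval type for [ptb_rate()].
#' @return A `ptb_comparison`: `classifications` (participant x method
#'   logical matrix), `rates` (data frame), `fisher` (matrices),
#'   `jaccard` (matrix), `metrics` (per method vs reference, if any),
#'   `dropped` (per-method missing-denominator counts).
#' @export
ptb_report <- function(cohort, formula_ids, reference = NULL,
                       anchor_scan = 1L, ci = "wilson") {
  stopifnot(inherits(cohort, "cohort_table"), length(formula_ids) >= 1)
  obs <- cohort$observations
  anchor <- obs[obs$scan_index == anchor_scan, , drop = FALSE]
  anchor <- anchor[!duplicated(anchor$participant_id), , drop = FALSE]
  out <- cohort$outcomes
  anchor <- merge(anchor, out, by = "participant_id", all.x = TRUE)

  ga_delivery <- function(id) {
    elapsed <- as.numeric(anchor$delivery_date - anchor$scan_date) / 7
    if (identical(id, "lmp")) {
      as.numeric(anchor$delivery_date - anchor$lmp_date) / 7
    } else {
      ga_scan <- ifelse(is.na(anchor$crl_cm), NA_real_,
                        predict_ga(id, anchor$crl_cm,
                                   warn_out_of_range = FALSE))
      ga_scan + elapsed
    }
  }

  cls <- vapply(formula_ids, function(id) classify_ptb(ga_delivery(id)),
                logical(nrow(anchor)))
  cls <- matrix(cls, nrow = nrow(anchor),
                dimnames = list(anchor$participant_id, formula_ids))
  dropped <- colSums(is.na(cls))

  rates <- do.call(rbind, lapply(formula_ids, function(id) {
    r <- ptb_rate(cls[, id], ci = ci)
    data.frame(method = id, k = r$k, n = r$n, rate = r$rate,
               ci_lower = r$ci_lower, ci_upper = r$ci_upper)
  }))

  ks <- setNames(rates$k, rates$method)
  ns <- setNames(rates$n, rates$method)
  fisher <- if (length(formula_ids) >= 2) {
    fisher_pairwise(ks, ns, correction = "bonferroni")
  } else NULL

  jac <- matrix(NA_real_, length(formula_ids), length(formula_ids),
                dimnames = list(formula_ids, formula_ids))
  for (i in seq_along(formula_ids)) for (j in seq_along(formula_ids)) {
    both <- !is.na(cls[, i]) & !is.na(cls[, j])
    jac[i, j] <- jaccard(rownames(cls)[both & cls[, i]],
                         rownames(cls)[both & cls[, j]])
  }

  metrics <- NULL
  if (!is.null(reference)) {
    ref_flags <- resolve_reference(reference, cohort, cls)
    metrics <- do.call(rbind, lapply(formula_ids, function(id) {
      m <- classification_metrics(cls[, id],
                                  ref_flags[rownames(cls)])
      data.frame(method = id, sensitivity = m$sensitivity,
                 specificity = m$specificity,
                 balanced_accuracy = m$balanced_accuracy, n = m$n)
    }))
  }

  structure(list(classifications = cls, rates = rates, fisher = fisher,
                 jaccard = jac, metrics = metrics, dropped = dropped,
                 anchor_scan = anchor_scan,
                 reference = if (is.character(reference)) reference else
                   if (!is.null(reference)) "user-supplied" else NA_character_),
            class = "ptb_comparison")
}

resolve_reference <- function(reference, cohort, cls) {
  if (is.logical(reference)) {
    if (is.null(names(reference))) {
      stop("a logical reference must be named by participant id")
    }
    return(reference)
  }
  if (identical(reference, "truth")) {
    tt <- truth_table(cohort)$participants
    return(setNames(tt$preterm_true, tt$participant_id))
  }
  if (reference %in% colnames(cls)) {
    return(setNames(cls[, reference], rownames(cls)))
  }
  stop("reference must be 'truth', one of the compared methods, or a ",
       "named logical vector")
}

#' @export
print.ptb_comparison <- function(x, ...) {
  cat("<ptb_comparison> ", nrow(x$classifications), " participants, ",
      ncol(x$classifications), " methods (reference: ", x$reference, ")\n",
      sep = "")
  print(transform(x$rates, rate = round(rate, 2),
                  ci_lower = round(ci_lower, 2),
                  ci_upper = round(ci_upper, 2)))
  invisible(x)
}
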