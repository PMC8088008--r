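test_that("preterm boundary follows 'before 37 completed weeks'", {
  expect_true(classify_ptb(36.857))   # 36 weeks 6 days
  expect_false(classify_ptb(37.0))    # boundary is term
  expect_false(classify_ptb(39.0))
  expect_error(classify_ptb(-1), "implausible")
  expect_error(classify_ptb(55), "implausible")
})

test_that("rates and intervals: printed-count probe and Wilson closed form", {
  # 251 preterm of 1510 livebirths: 16.62 per 100
  r <- ptb_rate(rep(c(TRUE, FALSE), c(251, 1510 - 251)))
  expect_equal(round(r$rate, 2), 16.62)

  r2 <- ptb_rate(c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$rate, 25)
  # Wilson interval computed from the closed form, independently
  z <- qnorm(0.975); n <- 4; p <- 0.25
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(r2$ci_lower, 100 * lo)
  expect_equal(r2$ci_upper, 100 * hi)

  r0 <- ptb_rate(rep(FALSE, 20))
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_lower, 0)
  expect_error(ptb_rate(logical(0)), "empty")

  cp <- ptb_rate(rep(c(TRUE, FALSE), c(3, 17)), ci = "clopper-pearson")
  expect_equal(cp$ci_lower, 100 * qbeta(0.025, 3, 18))
  expect_equal(cp$ci_upper, 100 * qbeta(0.975, 4, 17))
})

test_that("Wilson interval covers ~95% over binomial simulation", {
  set.seed(12)
  p_true <- 0.14; n <- 1500; reps <- 1e4
  ks <- rbinom(reps, n, p_true)
  z <- qnorm(0.975)
  phat <- ks / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  covered <- mean(100 * p_true >= 100 * (centre - half) &
                  100 * p_true <= 100 * (centre + half))
  expect_gte(covered, 0.94)
  expect_lte(covered, 0.96)
  # spot-check the package agrees with the closed form on one draw
  r <- ptb_rate(rep(c(TRUE, FALSE), c(ks[1], n - ks[1])))
  expect_equal(r$ci_lower, 100 * (centre[1] - half[1]))
})

test_that("Fisher pairwise matches hypergeometric enumeration and the
           Bonferroni definition", {
  # table (1,9 / 11,3): two-sided p from the tail enumeration oracle
  p_oracle <- fisher_oracle(1, 9, 11, 3)
  expect_equal(p_oracle, 0.002759, tolerance = 1e-3)
  res <- fisher_pairwise(k_vector = c(m1 = 1, m2 = 11),
                         n_vector = c(10, 14), correction = "none")
  expect_equal(res$p_raw["m1", "m2"], p_oracle, tolerance = 1e-9)

  ks <- c(a = 30, b = 45, c = 10); ns <- c(200, 200, 200)
  res3 <- fisher_pairwise(ks, ns)
  expect_equal(res3$n_pairs, 3)
  expect_equal(res3$p_adjusted, pmin(1, res3$p_raw * 3))
  same <- fisher_pairwise(c(5, 5), c(50, 50))
  expect_equal(same$p_raw[1, 2], 1)
  expect_error(fisher_pairwise(c(1, 0), c(10, 0)), "zero denominator")
})

test_that("jaccard set algebra", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
})

test_that("classification metrics arithmetic", {
  perfect <- classification_metrics(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  ref <- rep(c(TRUE, FALSE), c(3, 7))
  allterm <- classification_metrics(rep(FALSE, 10), ref)
  expect_equal(allterm$sensitivity, 0)
  expect_equal(allterm$specificity, 1)
  expect_equal(allterm$balanced_accuracy, 0.5)

  m <- classification_metrics(rep(c(TRUE, FALSE, TRUE, FALSE),
                                  c(8, 2, 1, 9)),
                              rep(c(TRUE, FALSE), c(10, 10)))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$balanced_accuracy, 0.85)
  expect_warning(classification_metrics(c(TRUE, FALSE), c(TRUE, TRUE)),
                 "single class")
})

test_that("ptb_report: self-agreement, threshold monotonicity, and
           sensitivity ordering under planted bias", {
  on.exit(reset_formulae())
  register_formula("garbhini_plus05",
                   function(crl) 0.5 - 0.02294 * crl^2 + 1.15018 * crl +
                     6.73526,
                   valid_crl_range = c(0, 10), source = "test offset")
  register_formula("garbhini_copy",
                   function(crl) -0.02294 * crl^2 + 1.15018 * crl + 6.73526,
                   valid_crl_range = c(0, 10), source = "test copy")
  coh <- generate_cohort(synthetic_config(n_participants = 800, seed = 23))
  rep1 <- ptb_report(coh, c("garbhini_ga1", "garbhini_copy"))
  expect_equal(unname(rep1$jaccard[1, 2]), 1)
  expect_equal(unname(rep1$fisher$p_raw[1, 2]), 1)

  rep2 <- ptb_report(coh, c("garbhini_ga1", "garbhini_plus05"),
                     reference = "truth")
  k <- setNames(rep2$rates$k, rep2$rates$method)
  # the +0.5-week method assigns higher GA everywhere, so it can only
  # cross the 37-week threshold for fewer (or equal) participants
  expect_lte(k[["garbhini_plus05"]], k[["garbhini_ga1"]])
  s <- setNames(rep2$metrics$sensitivity, rep2$metrics$method)
  expect_gte(s[["garbhini_ga1"]], s[["garbhini_plus05"]])
})
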