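make_xy <- function(n = 600, p = 8, seed = 1, informative = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- if (informative) 3 * X[, 1] + rnorm(n) else rnorm(n)
  list(X = X, y = y)
}

test_that("random forest learns a planted signal and ranks it first", {
  d <- make_xy(seed = 3)
  fit <- rf_regression(d$X, d$y, num_trees = 150, seed = 42)
  expect_gt(r_squared(d$y, fit$oob_prediction), 0.6)
  expect_equal(names(which.max(fit$importance)), "x1")
  expect_error(rf_regression(d$X, rep(1, nrow(d$X))), "constant")
})

test_that("boruta confirms the planted feature, is deterministic, and never
           confirms an adversarial constant feature", {
  d <- make_xy(seed = 5)
  sel <- boruta_select(d$X, d$y, seed = 5, num_trees = 100)
  expect_true("x1" %in% sel$confirmed)
  expect_equal(setdiff(sel$confirmed, "x1"), character(0))

  sel2 <- boruta_select(d$X, d$y, seed = 5, num_trees = 100)
  expect_identical(sel, sel2)

  Xc <- cbind(d$X[, 1:3], constant = 1)
  selc <- boruta_select(Xc, d$y, seed = 6, num_trees = 100)
  expect_false("constant" %in% selc$confirmed)
})

test_that("lasso selection finds the informative feature; penalty limits
           behave as stated", {
  d <- make_xy(seed = 7)
  sel <- glm_select(d$X, d$y, method = "lasso", seed = 7)
  expect_true("x1" %in% sel$confirmed)
  # infinite shrinkage empties the confirmed set
  sel_inf <- glm_select(d$X, d$y, method = "lasso", penalty = 1e9)
  expect_length(sel_inf$confirmed, 0)
  # no shrinkage keeps (almost surely) every feature, like OLS support
  sel0 <- glm_select(d$X, d$y, method = "lasso", penalty = 0)
  expect_setequal(sel0$confirmed, colnames(d$X))
})

test_that("stepwise selection works and flags rank deficiency", {
  d <- make_xy(n = 300, p = 4, seed = 8)
  sel <- glm_select(d$X, d$y, method = "stepwise")
  expect_true("x1" %in% sel$confirmed)
  Xdup <- cbind(d$X, x_dup = d$X[, 1])
  expect_error(glm_select(Xdup, d$y, method = "stepwise"), "rank-deficient")
})

test_that("union of selections is plain set union over a shared universe", {
  mk <- function(conf, universe) {
    gestage:::new_selection_result(conf, setdiff(universe, conf),
                                   character(0), list(), "test")
  }
  u <- c("A", "B", "C", "D")
  expect_setequal(union_features(mk(c("A", "B"), u), mk(c("B", "C"), u)),
                  c("A", "B", "C"))
  expect_setequal(union_features(mk(character(0), u), mk(c("D"), u)), "D")
  ab <- union_features(mk(c("A", "B"), u), mk(c("C", "D"), u))
  expect_gte(length(ab), 2)
  expect_lte(length(ab), 4)
  expect_error(union_features(mk("A", u), mk("A", c("A", "Z"))),
               "different candidate universes")
})

test_that("candidate equation enumeration counts match set algebra", {
  expect_length(build_candidate_equations(character(0)), 1)
  # 1 extra feature, linear only: baseline + 1
  specs1 <- build_candidate_equations("bmi", forms = "linear")
  expect_length(specs1, 2)
  # k features, linear only: 2^k specs including the baseline
  for (k in 2:4) {
    specs <- build_candidate_equations(paste0("f", 1:k), forms = "linear")
    expect_length(specs, 2^k)
  }
  expect_error(
    build_candidate_equations(paste0("f", 1:10), max_specs = 100),
    "restrict")
})

test_that("no covariate improves on CRL-only when GA depends on CRL alone", {
  coh <- generate_cohort(synthetic_config(n_participants = 1200, seed = 17,
                                          lmp_bias_days = 0))
  obs <- coh$observations[!is.na(coh$observations$crl_cm), ]
  split <- obs$participant_id <= "P00800"
  train <- obs[split, ]; test <- obs[!split, ]
  specs <- build_candidate_equations(c("bmi", "age_years", "weight_kg"),
                                     forms = c("linear", "log"))
  scores <- evaluate_candidates(specs, train, test)
  base <- scores$test_r2[scores$id == "crl_only"]
  expect_lt(max(scores$test_r2) - base, 0.01)
})
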