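# Covariate selection beyond CRL: Boruta-style shadow-feature selection
# on a random-forest regressor, GLM-based selection (L1 or stepwise),
# their union, and enumeration of candidate multivariate dating
# equations. On data whose GA depends on CRL alone, the expected outcome
# is that no covariate survives -- the qualitative conclusion the
# pipeline must be able to reproduce.

#' One-hot encode a covariate table
#'
#' Character and factor columns are expanded to 0/1 indicator columns
#' (full dummy coding, no reference level dropped — selection cares about
#' any informative indicator); logicals become 0/1; numerics pass
#' through.
#'
#' @param df Data frame of candidate covariates.
#' @return Numeric matrix with encoded columns.
#' @export
encode_features <- function(df) {
  stopifnot(is.data.frame(df))
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else if (is.logical(v)) {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
    } else {
      lev <- sort(unique(as.character(v)))
      m <- vapply(lev, function(l) as.numeric(v == l), numeric(length(v)))
      colnames(m) <- paste0(nm, ".", lev)
      m
    }
    m
  })
  do.call(cbind, cols)
}

#' Random-forest regression fit (importance + out-of-bag predictions)
#'
#' Thin wrapper over the compiled forest: bagged CART regression trees
#' with per-node feature subsampling and variance-reduction splits.
#' Two importance measures: `"permutation"` (default) is the mean
#' increase in out-of-bag MSE when a feature is permuted among the OOB
#' rows; `"variance"` is the total in-sample SSE decrease attributed to
#' the feature's splits. Permutation importance is the one safe for
#' shadow-feature comparisons — in-sample gain systematically rewards
#' chance correlations that deep splits overfit. Fully deterministic
#' given `seed`.
#'
#' @param X Numeric matrix.
#' @param y Numeric response.
#' @param num_trees Trees in the ensemble (default 500).
#' @param mtry Features tried per split; default `max(1, floor(p / 3))`,
#'   the regression-forest convention.
#' @param min_node Minimum node size (default 5).
#' @param seed Integer seed.
#' @param importance `"permutation"` or `"variance"`.
#' @return List with `importance` (named) and `oob_prediction`.
#' @export
rf_regression <- function(X, y, num_trees = 500, mtry = NULL, min_node = 5,
                          seed = 1L,
                          importance = c("permutation", "variance")) {
  importance <- match.arg(importance)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("X must be finite (impute upstream)")
  if (var(y) == 0) stop("constant response: nothing to regress on")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  res <- .rf_regression_cpp(X, as.numeric(y), as.integer(num_trees),
                            as.integer(mtry), as.integer(min_node),
                            as.numeric(seed),
                            if (importance == "permutation") 1L else 0L)
  names(res$importance) <- colnames(X)
  res
}

new_selection_result <- function(confirmed, rejected, tentative, history,
                                 method) {
  structure(list(confirmed = confirmed, rejected = rejected,
                 tentative = tentative, history = history, method = method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method:", x$method, "\n")
  cat("  confirmed:", if (length(x$confirmed)) paste(x$confirmed, collapse = ", ") else "(none)", "\n")
  cat("  tentative:", if (length(x$tentative)) paste(x$tentative, collapse = ", ") else "(none)", "\n")
  cat("  rejected: ", if (length(x$rejected)) paste(x$rejected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Boruta-style shadow-feature selection
#'
#' Classic Boruta loop on a random-forest regressor: each round appends a
#' shadow copy of every still-active feature (its values independently
#' permuted), fits the forest, and scores a "hit" for each undecided
#' feature whose importance exceeds the maximum shadow importance. After
#' each round, two-sided binomial tests at level `alpha` — Bonferroni-
#' corrected across the features still under test — confirm features
#' with significantly more than half hits and reject those with
#' significantly fewer. Stops when nothing is tentative or at `max_iter`.
#'
#' @param X Numeric matrix or covariate data frame (encoded via
#'   [encode_features()]); no missing values.
#' @param y Numeric response (GA in weeks).
#' @param max_iter Maximum decision rounds (default 50).
#' @param alpha Significance level of the binomial decisions.
#' @param seed Integer seed (drives both the permutations and the
#'   forests; same seed gives an identical result).
#' @param num_trees,mtry,min_node Forest settings, see [rf_regression()].
#' @param importance Importance measure; the default `"permutation"`
#'   (out-of-bag) is required for a calibrated shadow comparison.
#' @param shadow_mult Shadow replicates per active feature. With a
#'   single replicate the max-shadow benchmark is too easy for a
#'   chance-correlated noise feature to beat in a finite sample; extra
#'   independent permutations raise the bar without touching real
#'   features.
#' @return A `selection_result` with `confirmed` / `rejected` /
#'   `tentative` partitioning `colnames(X)`, plus the per-round
#'   importance history.
#' @export
boruta_select <- function(X, y, max_iter = 50, alpha = 0.05, seed = 1L,
                          num_trees = 500, mtry = NULL, min_node = 5,
                          importance = "permutation", shadow_mult = 3) {
  if (is.data.frame(X)) X <- encode_features(X)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X)) stop("X contains missing values; impute upstream")
  if (var(y) == 0) stop("constant response")

  feats <- colnames(X)
  status <- setNames(rep("tentative", length(feats)), feats)
  hits <- setNames(rep(0L, length(feats)), feats)
  history <- list()

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  for (iter in seq_len(max_iter)) {
    active <- feats[status != "rejected"]
    undecided <- feats[status == "tentative"]
    if (length(undecided) == 0) break

    Xa <- X[, active, drop = FALSE]
    # at least 5 shadows, as in classic Boruta: a thin shadow pool makes
    # the max-shadow benchmark too easy to beat in late rounds
    sh_src <- rep(active, shadow_mult)
    while (length(sh_src) < 5) sh_src <- c(sh_src, active)
    Xsh <- vapply(sh_src, function(f) sample(X[, f]), numeric(nrow(X)))
    sh_names <- paste0("shadow.", seq_along(sh_src))
    colnames(Xsh) <- sh_names
    fit <- rf_regression(cbind(Xa, Xsh), y, num_trees = num_trees,
                         mtry = mtry, min_node = min_node,
                         seed = participant_seed(seed, iter),
                         importance = importance)
    imp <- fit$importance
    shadow_max <- max(imp[sh_names])
    hit <- imp[undecided] > shadow_max
    hits[undecided] <- hits[undecided] + as.integer(hit)
    history[[iter]] <- imp

    # Bonferroni across the full candidate set (constant over rounds);
    # correcting only over the still-undecided set lets a lucky straggler
    # face almost no correction by the time it is the last one standing
    m <- length(feats)
    for (f in undecided) {
      p_conf <- pbinom(hits[[f]] - 1L, iter, 0.5, lower.tail = FALSE)
      p_rej <- pbinom(hits[[f]], iter, 0.5)
      if (p_conf * m < alpha) status[f] <- "confirmed"
      else if (p_rej * m < alpha) status[f] <- "rejected"
    }
  }

  new_selection_result(
    confirmed = feats[status == "confirmed"],
    rejected = feats[status == "rejected"],
    tentative = feats[status == "tentative"],
    history = history, method = "boruta")
}

#' GLM-based feature selection
#'
#' Default `"lasso"`: an L1-regularised linear model with the penalty
#' chosen by cross-validation (`lambda.1se`); confirmed features are
#' those with a nonzero coefficient. An explicit `penalty` bypasses the
#' cross-validation. Alternative `"stepwise"`: backward elimination from
#' the full linear model by AIC. Which GLM variant the original analysis
#' used is not recorded, so both modes are labelled assumptions.
#'
#' @param X Numeric matrix or covariate data frame; no missing values.
#' @param y Numeric response.
#' @param method `"lasso"` or `"stepwise"`.
#' @param penalty Optional fixed L1 penalty (lambda); `NULL` means CV.
#' @param seed Seed for the CV fold assignment.
#' @return A `selection_result` (no tentative set; this method decides
#'   every feature).
#' @export
glm_select <- function(X, y, method = c("lasso", "stepwise"), penalty = NULL,
                       seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(X)) X <- encode_features(X)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X)) stop("X contains missing values; impute upstream")
  feats <- colnames(X)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  if (method == "lasso") {
    if (is.null(penalty)) {
      cv <- glmnet::cv.glmnet(X, y, alpha = 1)
      lambda <- cv$lambda.1se
      co <- coef(cv, s = "lambda.1se")
    } else {
      # a strictly decreasing two-value path keeps coef(s = penalty)
      # well-defined even at penalty = 0
      fit <- glmnet::glmnet(X, y, alpha = 1,
                            lambda = c(2 * max(penalty, 1e-4), penalty))
      lambda <- penalty
      co <- coef(fit, s = penalty, exact = FALSE)
    }
    nz <- rownames(co)[as.vector(co != 0)]
    confirmed <- intersect(feats, nz)
    hist <- list(lambda = lambda, coef = setNames(as.vector(co), rownames(co)))
    tag <- "glm_lasso"
  } else {
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      stop("X is rank-deficient: drop collinear columns or use ",
           "method = 'lasso', which handles collinearity via shrinkage")
    }
    df <- data.frame(.y = y, X, check.names = TRUE)
    full <- lm(.y ~ ., data = df)
    red <- step(full, direction = "backward", trace = 0)
    kept_terms <- attr(stats::terms(red), "term.labels")
    confirmed <- feats[make.names(feats) %in% kept_terms]
    hist <- list(aic_full = AIC(full), aic_reduced = AIC(red))
    tag <- "glm_stepwise"
  }
  new_selection_result(confirmed = confirmed,
                       rejected = setdiff(feats, confirmed),
                       tentative = character(0),
                       history = hist, method = tag)
}

#' Union of two selection results
#'
#' Set union of the confirmed feature sets; requires the same candidate
#' universe on both sides.
#'
#' @param a,b `selection_result` objects.
#' @return Character vector of features confirmed by either method.
#' @export
union_features <- function(a, b) {
  stopifnot(inherits(a, "selection_result"), inherits(b, "selection_result"))
  ua <- sort(unique(c(a$confirmed, a$rejected, a$tentative)))
  ub <- sort(unique(c(b$confirmed, b$rejected, b$tentative)))
  if (!identical(ua, ub)) {
    stop("selection results cover different candidate universes")
  }
  sort(union(a$confirmed, b$confirmed))
}

#' Enumerate candidate multivariate dating equations
#'
#' Builds model specifications over all subsets of the selected
#' covariates crossed with the allowed per-feature functional forms,
#' with the CRL quadratic always included as the base. Forms: `linear`
#' (x), `log` (log x), `polynomial` (x + x^2), `fractional` (x^p for
#' each p in the fractional-polynomial power set). The empty subset
#' yields the CRL-only baseline.
#'
#' @param features Character vector of covariate names (may be empty).
#' @param forms Subset of `c("linear", "log", "polynomial", "fractional")`.
#' @param max_specs Combinatorial guard; exceeding it is an error
#'   advising form restriction.
#' @return List of specs; each spec has an `id` and a list of `terms`
#'   (`var`, `fun` in \{"pow", "log"\}, `power`).
#' @export
build_candidate_equations <- function(features,
                                      forms = c("linear", "log",
                                                "polynomial", "fractional"),
                                      max_specs = 1e5) {
  forms <- match.arg(forms, several.ok = TRUE)
  form_terms <- function(v) {
    out <- list()
    if ("linear" %in% forms) {
      out <- c(out, list(list(list(var = v, fun = "pow", power = 1))))
    }
    if ("log" %in% forms) {
      out <- c(out, list(list(list(var = v, fun = "log", power = NA))))
    }
    if ("polynomial" %in% forms) {
      out <- c(out, list(list(list(var = v, fun = "pow", power = 1),
                              list(var = v, fun = "pow", power = 2))))
    }
    if ("fractional" %in% forms) {
      for (p in setdiff(fp_power_set(), c(0, 1, 2))) {
        out <- c(out, list(list(list(var = v, fun = "pow", power = p))))
      }
    }
    out
  }
  per_feat <- lapply(features, form_terms)
  k <- length(features)
  n_forms <- if (k > 0) length(per_feat[[1]]) else 0
  total <- sum(choose(k, 0:k) * n_forms^(0:k))
  if (total > max_specs) {
    stop("candidate enumeration would produce ", total, " specs (> ",
         max_specs, "); restrict `forms` or the feature list")
  }

  base_terms <- list(list(var = "crl_cm", fun = "pow", power = 1),
                     list(var = "crl_cm", fun = "pow", power = 2))
  specs <- list()
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  if (k == 0) subsets <- data.frame(row.names = 1)
  for (s in seq_len(nrow(subsets))) {
    members <- if (ncol(subsets) == 0) integer(0) else
      which(unlist(subsets[s, , drop = TRUE]))
    if (length(members) == 0) {
      specs[[length(specs) + 1]] <- list(id = "crl_only", terms = base_terms)
      next
    }
    choice_grid <- expand.grid(lapply(members, function(m)
      seq_along(per_feat[[m]])))
    for (g in seq_len(nrow(choice_grid))) {
      terms <- base_terms
      label <- character(0)
      for (ci in seq_along(members)) {
        m <- members[ci]
        tt <- per_feat[[m]][[choice_grid[g, ci]]]
        terms <- c(terms, tt)
        label <- c(label, paste0(features[m], ":",
                                 paste(vapply(tt, function(t)
                                   if (t$fun == "log") "log"
                                   else paste0("p", t$power),
                                   character(1)), collapse = "+")))
      }
      specs[[length(specs) + 1]] <- list(id = paste(label, collapse = "|"),
                                         terms = terms)
    }
  }
  specs
}

spec_design <- function(spec, df) {
  cols <- lapply(spec$terms, function(t) {
    v <- df[[t$var]]
    if (is.null(v)) stop("spec references missing column '", t$var, "'")
    if (t$fun == "log") {
      if (any(v <= 0, na.rm = TRUE)) stop("log form on non-positive '", t$var, "'")
      log(v)
    } else {
      if (t$power < 1 && any(v <= 0, na.rm = TRUE)) {
        stop("fractional/negative power on non-positive '", t$var, "'")
      }
      v^t$power
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(spec$terms, function(t)
    if (t$fun == "log") paste0("log(", t$var, ")")
    else paste0(t$var, "^", t$power), character(1))
  X
}

#' Fit and score candidate equations
#'
#' Fits every spec by least squares on the training rows and reports
#' in-sample and held-out \eqn{R^2}, sorted by held-out performance.
#'
#' @param specs From [build_candidate_equations()].
#' @param train,test Data frames holding the response and every
#'   referenced covariate.
#' @param response Response column name (default `ga_lmp_weeks`).
#' @return Data frame: `id`, `n_terms`, `train_r2`, `test_r2`.
#' @export
evaluate_candidates <- function(specs, train, test,
                                response = "ga_lmp_weeks") {
  res <- lapply(specs, function(spec) {
    Xtr <- cbind(1, spec_design(spec, train))
    ytr <- train[[response]]
    fit <- lm.fit(Xtr, ytr)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    Xte <- cbind(1, spec_design(spec, test))
    yte <- test[[response]]
    data.frame(id = spec$id, n_terms = length(spec$terms),
               train_r2 = as.numeric(r_squared(ytr, drop(Xtr %*% beta))),
               test_r2 = as.numeric(r_squared(yte, drop(Xte %*% beta))))
  })
  out <- do.call(rbind, res)
  out[order(-out$test_r2), , drop = FALSE]
}
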