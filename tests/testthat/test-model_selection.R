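test_that("AICc follows the small-sample identity and its limits", {
  # intercept-only model on 5 tumours of 10: logL = 10 log(1/2), k = 1
  logL <- 10 * log(0.5)
  expect_equal(aicc(logL, 1, 10), -2 * logL + 2 + 0.5)
  expect_equal(aicc(logL, 1, 10), 16.363, tolerance = 1e-3)
  # correction vanishes as n grows
  expect_lt(abs(aicc(logL, 3, 1e8) - (-2 * logL + 6)), 1e-5)
  # undefined when n - k - 1 <= 0
  expect_true(is.na(aicc(logL, 9, 10)))
})

test_that("logistic fits reproduce saturated 2x2 closed forms", {
  # x=0: 1 tumour / 9 none; x=1: 9 tumours / 1 none -> OR = 81
  df <- tibble::tibble(x = rep(c(0, 1), each = 10))
  y <- c(rep(c(1, 0), c(1, 9)), rep(c(1, 0), c(9, 1)))
  fit <- fit_logistic(df, "x", y)
  expect_lt(abs(fit$coefficients["x"] - log(81)), 1e-8)
  expect_lt(abs(fit$coefficients["(Intercept)"] - log(1 / 9)), 1e-8)
  expect_false(fit$separation)

  # every saturated 2x2 with nonzero cells: coef = log OR, logL closed form
  set.seed(2)
  for (rep in 1:25) {
    counts <- sample(1:12, 4, replace = TRUE) # a,b = tumours; c,d = none
    df <- tibble::tibble(x = rep(c(0, 1), times = c(
      counts[1] + counts[3], counts[2] + counts[4]
    )))
    y <- c(
      rep(c(1, 0), c(counts[1], counts[3])),
      rep(c(1, 0), c(counts[2], counts[4]))
    )
    fit <- fit_logistic(df, "x", y)
    or <- (counts[2] * counts[3]) / (counts[1] * counts[4])
    expect_lt(abs(fit$coefficients["x"] - log(or)), 1e-8)
    p0 <- counts[1] / (counts[1] + counts[3])
    p1 <- counts[2] / (counts[2] + counts[4])
    ll <- counts[1] * log(p0) + counts[3] * log(1 - p0) +
      counts[2] * log(p1) + counts[4] * log(1 - p1)
    expect_lt(abs(fit$logL - ll), 1e-8)
  }
})

test_that("intercept-only fit on a balanced outcome is symmetric", {
  fit <- fit_logistic(tibble::tibble(), character(0), rep(c(0, 1), 5))
  expect_lt(abs(fit$coefficients["(Intercept)"]), 1e-10)
  expect_equal(fit$logL, 10 * log(0.5), tolerance = 1e-10)
  expect_equal(fit$k, 1)
})

test_that("degenerate designs are flagged, not silently fitted", {
  # perfect separation
  df <- tibble::tibble(x = c(1, 2, 3, 11, 12, 13))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(df, "x", y)
  expect_true(fit$separation)

  # single-class outcome
  expect_error(fit_logistic(df, "x", rep(1, 6)), "single class")

  # collinear subset -> infeasible, not an error
  df2 <- tibble::tibble(a = c(1, 2, 3, 4, 5, 6, 7, 8), b = 2 * c(1, 2, 3, 4, 5, 6, 7, 8))
  fit2 <- fit_logistic(df2, c("a", "b"), rep(c(0, 1), 4))
  expect_false(fit2$feasible)

  # too many parameters for n
  fit3 <- fit_logistic(
    tibble::tibble(a = rnorm(4), b = rnorm(4), c = rnorm(4)),
    c("a", "b", "c"), c(0, 1, 0, 1)
  )
  expect_false(fit3$feasible)
})

test_that("all-subsets selection enumerates 512 models with coherent weights", {
  sim <- generate_cohort(synthetic_config(n_acini = 40L, seed = 5L), with_end = FALSE)
  feats <- compute_features(sim$cohort, sim$assignments, outcomes = sim$outcomes)
  sel <- all_subsets_selection(feats)
  expect_equal(nrow(sel$models), 512)
  expect_equal(sum(sel$models$weight, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(min(sel$models$delta, na.rm = TRUE), 0)
  expect_true(all(sel$confidence_set$delta <= 3))
  expect_true(all(sel$importance$importance >= 0 & sel$importance$importance <= 1))
  expect_true("n_transduced_cluster" %in% sel$best_terms ||
    sel$importance$feature[1] == "n_transduced_cluster")
  # the generating feature dominates the importance ranking
  expect_equal(sel$importance$feature[1], "n_transduced_cluster")
  # odds ratio of the generating feature lands near exp(beta1) = 9
  or <- sel$odds_ratios
  expect_true("n_transduced_cluster" %in% or$term)
})

test_that("an irrelevant noise feature earns little importance", {
  set.seed(1234)
  means <- numeric(30)
  for (r in 1:30) {
    sim <- generate_cohort(
      synthetic_config(n_acini = 15L, seed = 3000L + r),
      with_end = FALSE
    )
    feats <- compute_features(sim$cohort, sim$assignments, outcomes = sim$outcomes)
    if (sum(feats$tumor) < 2 || sum(!feats$tumor) < 2) {
      means[r] <- NA
      next
    }
    feats$noise <- rnorm(nrow(feats))
    sel <- all_subsets_selection(
      feats,
      feature_cols = c(cluster_feature_names(), "noise")
    )
    means[r] <- sel$importance$importance[sel$importance$feature == "noise"]
  }
  expect_lt(mean(means, na.rm = TRUE), 0.4)
})

test_that("the transduced-cell coefficient is recovered at scale", {
  # ~150 clusters per cohort (50 acini); generating slope beta1 = ln 9
  cfg <- run_config(
    mode = "synthetic",
    synthetic = synthetic_config(n_acini = 50L, seed = 1L), seed = 1L
  )
  rec <- recover(cfg, n_replicates = 30L)
  s <- rec$summary
  expect_equal(s$n_effective, 30)
  expect_lt(abs(s$bias) / log(9), 0.2) # mean estimate within 20% of ln 9
  expect_gte(s$coverage, 0.9)
})

test_that("mixed model reduces to the ordinary fit at zero variance", {
  sim <- generate_cohort(synthetic_config(n_acini = 30L, seed = 11L), with_end = FALSE)
  feats <- compute_features(sim$cohort, sim$assignments, outcomes = sim$outcomes)
  top3 <- c("n_transduced_cluster", "n_cells_volume", "n_contacts_transduced")
  fixed <- fit_mixed_logistic(feats, top3, var_zero = TRUE)
  expect_equal(fixed$re_variance, 0)

  glm_terms <- paste0(
    ".y ~ (n_transduced_cluster + n_cells_volume + n_contacts_transduced) * .normal_c"
  )
  df <- feats
  df$.y <- as.numeric(df$tumor)
  df$.normal_c <- (df$n_cells_acinus - df$n_transduced_acinus) -
    mean(df$n_cells_acinus - df$n_transduced_acinus)
  ref <- glm(as.formula(glm_terms), family = binomial(), data = df)
  expect_equal(fixed$coefficients$estimate, unname(coef(ref)), tolerance = 1e-4)

  mixed <- fit_mixed_logistic(feats, top3)
  expect_gte(mixed$re_variance, 0)
  expect_true(all(c("estimate", "odds_ratio", "or_lower") %in% names(mixed$coefficients)))
})

test_that("the random-intercept variance tracks the simulated acinus effect", {
  # outcomes simulated with and without an acinus-level intercept
  simulate_fit <- function(seed, acinus_sd) {
    sim <- generate_cohort(synthetic_config(n_acini = 70L, seed = seed),
      with_end = FALSE
    )
    feats <- compute_features(sim$cohort, sim$assignments)
    set.seed(seed)
    u <- rnorm(length(unique(feats$acinus_id)), 0, acinus_sd)
    names(u) <- unique(feats$acinus_id)
    eta <- -3 * log(9) + log(9) * feats$n_transduced_cluster + u[feats$acinus_id]
    feats$tumor <- runif(nrow(feats)) < plogis(eta)
    if (sum(feats$tumor) < 2 || sum(!feats$tumor) < 2) {
      return(NULL)
    }
    list(
      mixed = fit_mixed_logistic(feats, "n_transduced_cluster"),
      fixed = fit_mixed_logistic(feats, "n_transduced_cluster", var_zero = TRUE)
    )
  }
  null_vars <- c()
  lrt_sig <- c()
  for (s in 1:12) {
    f0 <- simulate_fit(500L + s, 0)
    if (!is.null(f0)) null_vars <- c(null_vars, f0$mixed$re_variance)
    f2 <- simulate_fit(600L + s, 2)
    if (!is.null(f2)) {
      lrt <- 2 * (f2$mixed$logL - f2$fixed$logL)
      lrt_sig <- c(lrt_sig, lrt > qchisq(0.95, 1))
    }
  }
  # no acinus effect: the variance estimate sits at or near the zero
  # boundary in most replicates (boundary ML estimates overshoot in a
  # minority of binary-outcome samples, so the rate is below 1)
  expect_gte(mean(null_vars < 0.5), 0.7)
  expect_lt(median(null_vars), 0.05)
  # strong acinus effect: the likelihood ratio detects it in most replicates
  expect_gt(mean(lrt_sig), 0.5)
})
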