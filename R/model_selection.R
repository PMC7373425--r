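#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, defined only when
#' `n - k - 1 > 0`. The intercept counts as an estimated parameter.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of estimated parameters (intercept included).
#' @param n Number of observations (clusters).
#' @return The AICc, or `NA_real_` (infeasible) when `n - k - 1 <= 0`.
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) {
    return(NA_real_)
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a logistic regression for one feature subset
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm.fit`, convergence tolerance 1e-10, at most 100
#' iterations) of a binary outcome on an intercept plus the given feature
#' columns. Complete or quasi-complete separation is flagged when any
#' standardised coefficient exceeds 15 in absolute value or the fit fails
#' to converge with diverging coefficients. Rank-deficient designs and
#' subsets with `n - k - 1 <= 0` are returned flagged infeasible, not
#' fitted.
#'
#' @param features Data frame containing the feature columns.
#' @param subset Character vector of feature column names (possibly empty
#'   for the intercept-only model).
#' @param outcome Logical (or 0/1) outcome vector, one per row.
#' @return List of class `logit_fit`: `subset`, `coefficients`, `se`,
#'   `logL`, `k`, `n`, `aicc`, `converged`, `separation`, `feasible`.
#' @export
fit_logistic <- function(features, subset = character(0), outcome) {
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be binary with no missing values", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic fits are degenerate", call. = FALSE)
  }
  n <- length(y)
  x <- cbind(`(Intercept)` = rep(1, n))
  if (length(subset) > 0) {
    miss <- setdiff(subset, names(features))
    if (length(miss) > 0) {
      stop("unknown feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    x <- cbind(x, as.matrix(features[, subset, drop = FALSE]))
  }
  k <- ncol(x)
  out <- list(
    subset = subset, coefficients = stats::setNames(rep(NA_real_, k), colnames(x)),
    se = stats::setNames(rep(NA_real_, k), colnames(x)),
    logL = NA_real_, k = k, n = n, aicc = NA_real_,
    converged = FALSE, separation = FALSE, feasible = FALSE
  )
  class(out) <- "logit_fit"
  if (n - k - 1 <= 0) {
    return(out)
  }
  if (qr(x)$rank < k) {
    return(out)
  }
  fit <- suppressWarnings(stats::glm.fit(
    x, y,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  coefs <- fit$coefficients
  logL <- -fit$deviance / 2
  # Wald standard errors from the Fisher information X' W X
  se <- rep(NA_real_, k)
  info <- crossprod(x * sqrt(fit$weights))
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  sds <- apply(x, 2, stats::sd)
  sds[1] <- 1 # intercept on its own scale
  std_coefs <- abs(coefs * sds)
  separation <- any(std_coefs[-1] > 15) || (!fit$converged && any(std_coefs > 15))
  out$coefficients <- stats::setNames(coefs, colnames(x))
  out$se <- stats::setNames(se, colnames(x))
  out$logL <- logL
  out$aicc <- aicc(logL, k, n)
  out$converged <- fit$converged
  out$separation <- separation
  out$feasible <- TRUE
  out
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf(
    "<logit_fit> k = %d, n = %d, logL = %.4f, AICc = %.4f%s%s\n",
    x$k, x$n, x$logL, x$aicc,
    if (x$separation) " [separation]" else "",
    if (!x$feasible) " [infeasible]" else ""
  ))
  print(x$coefficients)
  invisible(x)
}

#' Exhaustive AICc model selection over the nine cluster features
#'
#' Fits a logistic regression of the tumour outcome on every subset of the
#' feature columns (2^9 = 512 models including the intercept-only model),
#' ranks them by AICc, and summarises the cross-model evidence: AICc
#' differences `delta_i = AICc_i - min AICc`, Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` over the retained
#' (feasible) models, the confidence set of models within `delta_window`
#' AICc units of the best, per-feature relative importance as the sum of
#' Akaike weights of the models containing the feature, and odds ratios
#' with Wald 95% confidence intervals from the best model. Features enter
#' untransformed, so odds ratios are per unit of each feature.
#'
#' Models rendered infeasible by `n - k - 1 <= 0` or rank deficiency are
#' excluded from the weight normalisation but listed (flagged) in the
#' model table; fit failures never abort the enumeration. A literal sum of
#' AICc values per feature is emitted as a diagnostic column of the
#' importance table (it is not a bounded importance measure; the Akaike
#' weight sum is the supported one).
#'
#' @param features Cluster feature table (e.g. [compute_features()]
#'   output) with a logical `tumor` column (or see `outcome`).
#' @param feature_cols Feature columns to search over; defaults to the
#'   nine of [cluster_feature_names()].
#' @param outcome Outcome column name, default `"tumor"`.
#' @param delta_window Width of the AICc confidence set, default 3.
#' @return Object of class `selection_result`: `models` (one row per
#'   candidate model), `best` (its [fit_logistic()] result),
#'   `best_terms`, `confidence_set`, `importance`, `odds_ratios`, `n`.
#' @export
all_subsets_selection <- function(features, feature_cols = cluster_feature_names(),
                                  outcome = "tumor", delta_window = 3) {
  stopifnot(all(feature_cols %in% names(features)))
  y <- features[[outcome]]
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need at least 2 clusters in each outcome class", call. = FALSE)
  }
  p <- length(feature_cols)
  n_models <- 2^p
  fits <- vector("list", n_models)
  for (m in seq_len(n_models) - 1L) {
    inc <- bitwAnd(m, 2^(seq_len(p) - 1L)) > 0
    fits[[m + 1L]] <- fit_logistic(features, feature_cols[inc], y)
  }
  models <- tibble::tibble(
    model_id = seq_len(n_models) - 1L,
    terms = vapply(
      fits, function(f) paste(f$subset, collapse = "+"),
      character(1)
    ),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    separation = vapply(fits, function(f) f$separation, logical(1)),
    feasible = vapply(fits, function(f) f$feasible, logical(1))
  )
  retained <- models$feasible & !is.na(models$aicc)
  if (!any(retained)) {
    stop("no feasible model could be fitted", call. = FALSE)
  }
  best_aicc <- min(models$aicc[retained])
  models$delta <- models$aicc - best_aicc
  w <- exp(-models$delta / 2)
  w[!retained] <- NA_real_
  models$weight <- w / sum(w, na.rm = TRUE)
  best_idx <- which(retained & models$delta == 0)[1]
  best <- fits[[best_idx]]

  # models and fits are both in model_id order here
  importance <- tibble::tibble(
    feature = feature_cols,
    importance = vapply(feature_cols, function(f) {
      has <- vapply(fits, function(fit) f %in% fit$subset, logical(1))
      sum(models$weight[has], na.rm = TRUE)
    }, numeric(1)),
    aicc_sum_literal = vapply(feature_cols, function(f) {
      has <- vapply(fits, function(fit) f %in% fit$subset, logical(1))
      sum(models$aicc[has], na.rm = TRUE)
    }, numeric(1))
  )
  models <- models[order(models$aicc), ]
  confidence_set <- models[!is.na(models$delta) & models$delta <= delta_window &
    models$feasible, , drop = FALSE]
  importance <- importance[order(-importance$importance), ]

  ors <- tibble::tibble(
    term = names(best$coefficients),
    estimate = unname(best$coefficients),
    se = unname(best$se),
    odds_ratio = exp(unname(best$coefficients)),
    or_lower = exp(unname(best$coefficients) - 1.96 * unname(best$se)),
    or_upper = exp(unname(best$coefficients) + 1.96 * unname(best$se)),
    p_value = 2 * stats::pnorm(-abs(unname(best$coefficients) / unname(best$se)))
  )

  structure(
    list(
      models = models, best = best, best_terms = best$subset,
      confidence_set = confidence_set, importance = importance,
      odds_ratios = ors, n = best$n, delta_window = delta_window
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d candidate models on n = %d clusters\n",
    nrow(x$models), x$n
  ))
  cat(
    "best model:",
    if (length(x$best_terms)) paste(x$best_terms, collapse = " + ") else "(intercept only)",
    sprintf("(AICc = %.3f)\n", x$best$aicc)
  )
  cat(sprintf(
    "confidence set (delta <= %g): %d models\n",
    x$delta_window, nrow(x$confidence_set)
  ))
  cat("feature importance (Akaike-weight sums):\n")
  print(x$importance[, c("feature", "importance")], n = Inf)
  invisible(x)
}

#' Random-intercept mixed logistic model of tumour outcome
#'
#' Fits, by the Laplace approximation to the marginal likelihood
#' (`lme4::glmer`, one quadrature point), a logistic model with the given
#' fixed-effect features, a main effect of the starting number of normal
#' cells in the acinus (centred, which conditions the design and makes the
#' feature main effects refer to the average acinus) plus its interactions
#' with each feature, and a random intercept per acinus of origin. With the random-intercept
#' variance constrained to zero (`var_zero = TRUE`) the model reduces to
#' the ordinary logistic fit on the same design.
#'
#' Non-convergence is reported through the `converged` flag and
#' `messages`, never as an exception.
#'
#' @param features Cluster feature table with outcome and acinus id.
#' @param fixed_terms Feature columns used as fixed effects (typically the
#'   three most important from [all_subsets_selection()]).
#' @param normal_col Column holding the starting number of normal cells of
#'   the acinus (derived as `n_cells_acinus - n_transduced_acinus` when
#'   absent).
#' @param acinus_col Acinus identifier column, default `"acinus_id"`.
#' @param outcome Outcome column name, default `"tumor"`.
#' @param var_zero Constrain the random-intercept variance to zero and fit
#'   the fixed design by ordinary logistic regression.
#' @return List of class `mixed_logit_fit`: `coefficients` tibble (term,
#'   estimate, se, odds_ratio, CI), `re_variance`, `converged`,
#'   `messages`, `formula`, `n`, `n_acini`.
#' @export
fit_mixed_logistic <- function(features, fixed_terms, normal_col = "n_normal_start",
                               acinus_col = "acinus_id", outcome = "tumor",
                               var_zero = FALSE) {
  df <- tibble::as_tibble(features)
  if (!normal_col %in% names(df)) {
    if (all(c("n_cells_acinus", "n_transduced_acinus") %in% names(df))) {
      df[[normal_col]] <- df$n_cells_acinus - df$n_transduced_acinus
    } else {
      stop("column '", normal_col, "' not found and not derivable", call. = FALSE)
    }
  }
  stopifnot(all(fixed_terms %in% names(df)), outcome %in% names(df))
  if (length(unique(df[[acinus_col]])) < 2) {
    stop("mixed model needs at least 2 acini", call. = FALSE)
  }
  df$.y <- as.numeric(df[[outcome]])
  if (length(unique(df$.y)) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  # centre the normal-cell count: keeps the interaction design well
  # conditioned and makes feature main effects refer to the average acinus
  df$.normal_c <- df[[normal_col]] - mean(df[[normal_col]])
  fixed <- paste0(
    "(", paste(fixed_terms, collapse = " + "), ") * .normal_c"
  )
  msgs <- character(0)
  if (var_zero) {
    f <- stats::as.formula(paste(".y ~", fixed))
    fit <- stats::glm(f, family = stats::binomial(), data = df)
    coefs <- stats::coef(summary(fit))
    re_var <- 0
    converged <- fit$converged
    formula_used <- f
    n_obs <- stats::nobs(fit)
    ll <- as.numeric(stats::logLik(fit))
  } else {
    f <- stats::as.formula(paste(".y ~", fixed, "+ (1 |", acinus_col, ")"))
    quiet <- function(expr) {
      withCallingHandlers(
        expr,
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          msgs <<- c(msgs, conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      )
    }
    fit <- quiet(lme4::glmer(f, family = stats::binomial(), data = df, nAGQ = 1L))
    coefs <- quiet(stats::coef(summary(fit)))
    re_var <- as.numeric(lme4::VarCorr(fit)[[acinus_col]][1, 1])
    cc <- fit@optinfo$conv$lme4
    converged <- length(cc) == 0 || is.null(cc$code) || cc$code == 0
    formula_used <- f
    n_obs <- stats::nobs(fit)
    ll <- as.numeric(stats::logLik(fit))
  }
  est <- coefs[, "Estimate"]
  se <- coefs[, "Std. Error"]
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(coefs),
        estimate = unname(est),
        se = unname(se),
        odds_ratio = exp(unname(est)),
        or_lower = exp(unname(est) - 1.96 * unname(se)),
        or_upper = exp(unname(est) + 1.96 * unname(se)),
        p_value = 2 * stats::pnorm(-abs(unname(est) / unname(se)))
      ),
      re_variance = re_var,
      logL = ll,
      converged = converged,
      messages = msgs,
      formula = formula_used,
      n = n_obs,
      n_acini = length(unique(df[[acinus_col]]))
    ),
    class = "mixed_logit_fit"
  )
}

#' @export
print.mixed_logit_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_logit_fit> n = %d clusters, %d acini, random-intercept variance = %.4g%s\n",
    x$n, x$n_acini, x$re_variance,
    if (!x$converged) " [not converged]" else ""
  ))
  print(x$coefficients)
  invisible(x)
}
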