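#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Wraps [lme4::lmer()] with `REML = FALSE`: likelihood-ratio and BIC
#' comparisons between models that differ in fixed effects require full
#' maximum likelihood.  The returned fit records the BIC with `n` equal
#' to the number of observations (rows), `BIC = k * log(n) - 2 * logLik`,
#' which is what downstream Bayes factors are built from.
#'
#' A constant outcome (zero variance) is handled as a degenerate fit with
#' the intercept equal to the constant and zero variance components.
#'
#' @param formula Fixed-effects formula, e.g. `y ~ group * condition`;
#'   the random intercept is added internally.
#' @param data Data.frame.
#' @param group Name of the grouping (participant) column.
#' @return An object of class `lmm_fit` with elements `coefficients`
#'   (data.frame `term`, `b`, `se`), `var_intercept`, `var_residual`,
#'   `logLik`, `k`, `n`, `BIC`, `converged`, `fitted_fixed` (fixed-effect
#'   predictions), and the underlying `model`.
#' @examples
#' d <- simulate_lmm_dataset(10, 10, 2, b = 1, seed = 1)
#' fit <- fit_random_intercept(y ~ group, d, group = "participant")
#' fit$BIC
#' @export
fit_random_intercept <- function(formula, data, group = "participant") {
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  if (length(unique(data[[group]])) < 2) {
    stop("need at least 2 grouping units")
  }
  yname <- all.vars(formula)[1]
  y <- data[[yname]]
  if (stats::var(y, na.rm = TRUE) < .Machine$double.eps) {
    n <- sum(is.finite(y))
    return(structure(list(
      coefficients = data.frame(term = "(Intercept)", b = y[1], se = 0,
                                stringsAsFactors = FALSE),
      var_intercept = 0, var_residual = 0,
      logLik = Inf, k = 3, n = n, BIC = -Inf, converged = TRUE,
      degenerate = TRUE, fitted_fixed = rep(y[1], n), model = NULL,
      formula = formula, group = group), class = "lmm_fit"))
  }
  f <- stats::update(formula,
                     stats::as.formula(paste0(". ~ . + (1 | ", group, ")")))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  warned <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(f, data = data, REML = FALSE, control = ctrl),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == group][1]
  var_res <- vc$vcov[vc$grp == "Residual"][1]
  ll <- as.numeric(stats::logLik(fit))
  n <- stats::nobs(fit)
  k <- attr(stats::logLik(fit), "df")
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(
    coefficients = data.frame(term = names(co), b = unname(co),
                              se = unname(se), stringsAsFactors = FALSE),
    var_intercept = var_int, var_residual = var_res,
    logLik = ll, k = k, n = n, BIC = k * log(n) - 2 * ll,
    converged = !warned, degenerate = FALSE,
    fitted_fixed = as.numeric(stats::model.matrix(fit) %*% co),
    model = fit, formula = formula, group = group), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> n = %d, k = %d, logLik = %.2f, BIC = %.2f\n",
              x$n, x$k, x$logLik, x$BIC))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("random-intercept var = %.4g, residual var = %.4g\n",
              x$var_intercept, x$var_residual))
  invisible(x)
}

#' Marginal R-squared of a mixed-model fit
#'
#' Nakagawa-Schielzeth marginal R2: the variance of the fixed-effect
#' predictions over the total outcome variance (fixed + random-intercept
#' + residual variance).
#'
#' @param fit An `lmm_fit`.
#' @return Marginal R2 in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  vf <- mean((fit$fitted_fixed - mean(fit$fitted_fixed))^2)
  tot <- vf + fit$var_intercept + fit$var_residual
  if (tot <= 0) return(0)
  vf / tot
}

#' Compare nested random-intercept models
#'
#' Likelihood-ratio chi-square with `df = k_full - k_null`, the BIC
#' Bayes factor `BF10 = exp((BIC_null - BIC_full) / 2)` (the Wagenmakers
#' BIC approximation), its reciprocal `BF01`, and the marginal f2 of the
#' effect of interest.
#'
#' @param full,null `lmm_fit` objects fitted by ML on identical data;
#'   `null` must be nested in `full`.
#' @return A one-row data.frame of class `lmm_comparison`: `chi2`, `df`,
#'   `p`, `b`, `se` (the coefficient(s) dropped from the null, collapsed
#'   to the first when several), `bf10`, `bf01`, `f2`, `converged`.
#' @examples
#' d <- simulate_lmm_dataset(20, 20, 2, b = 0.5, seed = 1)
#' full <- fit_random_intercept(y ~ group, d)
#' null <- fit_random_intercept(y ~ 1, d)
#' compare_models(full, null)
#' @export
compare_models <- function(full, null) {
  stopifnot(inherits(full, "lmm_fit"), inherits(null, "lmm_fit"))
  if (full$n != null$n) {
    stop("models were fitted on different numbers of observations")
  }
  if (full$k < null$k) stop("'null' must be nested in 'full' (fewer parameters)")
  df <- full$k - null$k
  chi2 <- max(0, 2 * (full$logLik - null$logLik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  bf10 <- exp((null$BIC - full$BIC) / 2)
  extra <- setdiff(full$coefficients$term, null$coefficients$term)
  if (length(extra) == 0) {
    b <- NA_real_; se <- NA_real_
  } else {
    i <- match(extra[1], full$coefficients$term)
    b <- full$coefficients$b[i]; se <- full$coefficients$se[i]
  }
  out <- data.frame(chi2 = chi2, df = df, p = p, b = b, se = se,
                    bf10 = bf10, bf01 = 1 / bf10,
                    f2 = marginal_f2(full, null),
                    converged = full$converged && null$converged)
  class(out) <- c("lmm_comparison", "data.frame")
  out
}

#' Marginal f2 effect size for a nested comparison
#'
#' `f2 = (R2m_full - R2m_null) / (1 - R2m_full)` with the
#' Nakagawa-Schielzeth marginal R2 of each model: the proportional
#' increase in explained variance contributed by the effect of interest.
#' Negative differences (the null explaining nominally more) are clamped
#' to 0.
#'
#' @param full,null `lmm_fit` objects.
#' @return Marginal f2 (>= 0).  `NA` with a warning if `R2m_full` is
#'   numerically 1.
#' @export
marginal_f2 <- function(full, null) {
  r2f <- marginal_r2(full)
  r2n <- marginal_r2(null)
  if (r2f >= 1 - 1e-12) {
    warning("marginal R2 of the full model is numerically 1; f2 undefined")
    return(NA_real_)
  }
  max(0, (r2f - r2n) / (1 - r2f))
}

#' Benjamini-Hochberg pass flags
#'
#' Step-up FDR control at level `q` via [stats::p.adjust()]: a p-value
#' passes when its BH-adjusted value is at most `q`.  The flags are
#' monotone: rejecting a p-value implies rejecting all smaller ones.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q False discovery rate (default 0.05).
#' @return Logical vector of pass flags (length of `p`).
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Group effect size calibrated to a target marginal f2
#'
#' For a two-group design with a participant random intercept, the
#' marginal R2 of the group effect is
#' `p * (1 - p) * b^2 / (p * (1 - p) * b^2 + var_b + var_e)` where `p` is
#' the fraction of observations in one group; against an intercept-only
#' null, `f2 = p * (1 - p) * b^2 / (var_b + var_e)`.  Inverting gives the
#' fixed-effect size that attains a requested f2.
#'
#' @param f2 Target marginal f2 (>= 0).
#' @param n_groups Two group sample sizes (participants).
#' @param var_intercept,var_residual Random-intercept and residual
#'   variances of the generating process.
#' @return The group fixed effect `b`.
#' @export
calibrate_group_effect <- function(f2, n_groups = c(37, 50),
                                   var_intercept = 0.5,
                                   var_residual = 0.5) {
  if (f2 < 0) stop("f2 must be non-negative")
  pfrac <- n_groups[1] / sum(n_groups)
  sqrt(f2 * (var_intercept + var_residual) / (pfrac * (1 - pfrac)))
}

#' Simulate a random-intercept dataset
#'
#' Two groups of participants with `m` repeated observations each:
#' `y = b * I(group 2) + u_participant + e`, with
#' `u ~ N(0, var_intercept)` and `e ~ N(0, var_residual)`.
#'
#' @param n1,n2 Participants per group.
#' @param m Observations per participant.
#' @param b Group fixed effect.
#' @param var_intercept,var_residual Variance components.
#' @param seed Optional seed.
#' @return Data.frame with `participant`, `group`, `condition` (the
#'   repeated-measure index, as a factor) and `y`.
#' @export
simulate_lmm_dataset <- function(n1, n2, m = 2, b = 0,
                                 var_intercept = 0.5, var_residual = 0.5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  grp <- rep(c("g1", "g2"), c(n1, n2))
  u <- stats::rnorm(n, 0, sqrt(var_intercept))
  d <- data.frame(
    participant = factor(rep(seq_len(n), each = m)),
    group = factor(rep(grp, each = m)),
    condition = factor(rep(seq_len(m), n))
  )
  d$y <- b * (d$group == "g2") + u[as.integer(d$participant)] +
    stats::rnorm(nrow(d), 0, sqrt(var_residual))
  d
}

#' Simulation-based power of the group comparison
#'
#' Generates `n_sims` random-intercept datasets with a group fixed effect
#' calibrated to the target marginal f2 (see
#' [calibrate_group_effect()]), fits the full (`y ~ group`) and null
#' (`y ~ 1`) ML mixed models, and records the proportion of
#' likelihood-ratio rejections at `alpha`.  With `f2 = 0` this estimates
#' the type-I error rate.  Refits use [lme4::refit()] on template
#' models, so each replicate costs two cheap refits.
#'
#' @param f2 Target marginal f2 of the group effect.
#' @param n_groups Two group sizes (participants); defaults to the study
#'   sample sizes 37 and 50.
#' @param m Repeated observations per participant (default 2, one per
#'   cueing condition).
#' @param n_sims Number of simulated datasets (>= 100).
#' @param alpha Significance level of the likelihood-ratio test.
#' @param var_intercept,var_residual Generating variance components.
#' @param seed Seed for the whole simulation.
#' @return List: `power`, `mc_se` (binomial Monte-Carlo SE), `n_sims`,
#'   `b` (calibrated effect), `alpha`.
#' @export
power_simulation <- function(f2 = 0.15, n_groups = c(37, 50), m = 2,
                             n_sims = 500, alpha = 0.05,
                             var_intercept = 0.5, var_residual = 0.5,
                             seed = 1) {
  if (n_sims < 100) stop("n_sims must be at least 100")
  b <- calibrate_group_effect(f2, n_groups, var_intercept, var_residual)
  set.seed(seed)
  d0 <- simulate_lmm_dataset(n_groups[1], n_groups[2], m, b,
                             var_intercept, var_residual)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  full0 <- lme4::lmer(y ~ group + (1 | participant), data = d0,
                      REML = FALSE, control = ctrl)
  null0 <- lme4::lmer(y ~ 1 + (1 | participant), data = d0,
                      REML = FALSE, control = ctrl)
  n <- sum(n_groups)
  rej <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    u <- stats::rnorm(n, 0, sqrt(var_intercept))
    y <- b * (d0$group == "g2") + u[as.integer(d0$participant)] +
      stats::rnorm(nrow(d0), 0, sqrt(var_residual))
    ff <- suppressWarnings(lme4::refit(full0, y))
    nf <- suppressWarnings(lme4::refit(null0, y))
    chi2 <- max(0, 2 * (as.numeric(stats::logLik(ff)) -
                          as.numeric(stats::logLik(nf))))
    rej[s] <- stats::pchisq(chi2, 1, lower.tail = FALSE) < alpha
  }
  pw <- mean(rej)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / n_sims),
       n_sims = n_sims, b = b, alpha = alpha)
}
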