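#' Satterthwaite degrees of freedom for the intervention effect
#'
#' Moment-matched degrees of freedom for the t-reference distribution of
#' the intervention contrast: with `v(sigma)` the contrast variance
#' `[(X'V(sigma)^-1 X)^-1]_{22}`, `g` its gradient with respect to the
#' variance parameters at the REML estimate, and `A` the asymptotic
#' covariance of the variance-parameter estimates (inverse observed
#' information),
#' \deqn{\nu = \frac{2\,v(\hat\sigma)^2}{g' A g}.}
#'
#' The gradient is computed by central finite differences (step
#' `1e-5 * max(estimate, 1)`). For the linear model the algebra collapses
#' exactly to the residual degrees of freedom `n - 2`, which is returned
#' directly. When the between-cluster variance sits on its zero boundary
#' and the corresponding information row is degenerate, the computation is
#' restricted to the interior parameters; if no usable information matrix
#' is available the residual df `n - 2` is returned with method
#' `"residual (fallback)"`.
#'
#' @param fit A converged [fit_pnrct()] object.
#' @return The degrees of freedom (positive scalar) with attribute
#'   `method` describing how it was obtained.
#' @examples
#' d <- generate_trial(scenario_config(12, 10, icc = 0.1))
#' satterthwaite_df(fit_pnrct(d, "pn-hom"))
#' @export
satterthwaite_df <- function(fit) {
  stopifnot(inherits(fit, "pnrct_fit"))
  if (!fit$converged) {
    stop("Satterthwaite df requires a converged fit", call. = FALSE)
  }
  if (fit$model == "linear") {
    return(structure(fit$n - 2, method = "residual (exact)"))
  }
  fallback <- structure(fit$n - 2, method = "residual (fallback)")
  A <- fit$varcomp_vcov
  if (is.null(A)) {
    warning("no usable variance-parameter covariance; using residual df",
            call. = FALSE)
    return(fallback)
  }
  bs <- fit$blockstats
  est <- fit$varcomp
  act <- match(colnames(A), names(est))
  h <- 1e-5 * pmax(abs(est[act]), 1)
  pts <- list()
  for (j in seq_along(act)) {
    for (s in c(1, -1)) {
      x <- est
      x[act[j]] <- x[act[j]] + s * h[j]
      pts[[length(pts) + 1L]] <- x
    }
  }
  ev <- reml_eval(bs, do.call(rbind, pts))
  if (any(!ev$ok)) {
    warning("contrast-variance gradient not computable; using residual df",
            call. = FALSE)
    return(fallback)
  }
  g <- (ev$v[seq_along(act) * 2 - 1] - ev$v[seq_along(act) * 2]) / (2 * h)
  v0 <- fit$se_theta^2
  denom <- drop(g %*% A %*% g)
  if (!is.finite(denom) || denom <= 0) {
    warning("degenerate variance-parameter covariance; using residual df",
            call. = FALSE)
    return(fallback)
  }
  structure(2 * v0^2 / denom, method = "satterthwaite")
}

#' t-based test and confidence interval for the intervention effect
#'
#' Two-sided Wald t-test of no intervention effect and the matching
#' confidence interval, both referred to a t distribution with `df`
#' degrees of freedom (normally the Satterthwaite value carried by the
#' fit).
#'
#' @param fit A converged [fit_pnrct()] object.
#' @param df Degrees of freedom (default: the fit's Satterthwaite df).
#' @param level Confidence level in (0, 1).
#' @return A list with `df`, `t_stat`, `p_value`, `ci_lower`, `ci_upper`
#'   and `level`.
#' @examples
#' d <- generate_trial(scenario_config(12, 10, effect = 0.5, icc = 0.1))
#' fit <- fit_pnrct(d, "pn-hom")
#' wald_test_ci(fit, level = 0.9)
#' @export
wald_test_ci <- function(fit, df = fit$df, level = 0.95) {
  stopifnot(inherits(fit, "pnrct_fit"))
  if (!fit$converged) {
    stop("inference requires a converged fit", call. = FALSE)
  }
  stopifnot(is.numeric(df), length(df) == 1L, df > 0,
            is.numeric(level), length(level) == 1L, level > 0, level < 1)
  t_stat <- fit$theta / fit$se_theta
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  crit <- stats::qt(1 - (1 - level) / 2, df = df)
  list(df = as.numeric(df), t_stat = t_stat, p_value = p,
       ci_lower = fit$theta - crit * fit$se_theta,
       ci_upper = fit$theta + crit * fit$se_theta,
       level = level)
}
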