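# Independent oracles used across the test files. These deliberately avoid
# the package's block closed forms: covariance matrices are built densely
# from the model definitions and factorised with base solve()/determinant().

# Dense marginal covariance implied by a model for a (coded) trial dataset.
dense_V <- function(trial, model, sigma_u2 = 0, sigma_e2 = 1,
                    sigma_r2 = NULL) {
  n <- nrow(trial)
  arm <- trial$arm
  V <- diag(if (model == "pn-het") {
    ifelse(arm == 1, sigma_e2, sigma_r2)
  } else {
    rep(sigma_e2, n)
  })
  if (model != "linear") {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        same <- !is.na(trial$cluster[i]) && !is.na(trial$cluster[j]) &&
          trial$cluster[i] == trial$cluster[j]
        share_u <- switch(model,
          "fully-clustered" = same,
          same && arm[i] == 1 && arm[j] == 1)
        if (share_u) V[i, j] <- V[i, j] + sigma_u2
      }
    }
  }
  V
}

# Dense evaluation of the restricted log-likelihood (full constants).
dense_reml_loglik <- function(trial, model, sigma_u2 = 0, sigma_e2 = 1,
                              sigma_r2 = NULL) {
  V <- dense_V(trial, model, sigma_u2, sigma_e2, sigma_r2)
  X <- cbind(1, trial$arm)
  y <- trial$y
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * ((nrow(trial) - 2) * log(2 * pi) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtViX, logarithm = TRUE)$modulus +
              t(r) %*% Vi %*% r)
  )
}

# Brute-force maximisation of the dense REML criterion by iterated grid
# refinement over the variance-parameter box. Independent of the package's
# profiled optimiser.
grid_refine_reml <- function(trial, model, lower, upper, rounds = 6,
                             pts = 11) {
  p <- length(lower)
  f <- function(par) {
    tryCatch(
      switch(model,
        "linear" = dense_reml_loglik(trial, model, sigma_e2 = par[1]),
        "pn-het" = dense_reml_loglik(trial, model, par[1], par[2], par[3]),
        dense_reml_loglik(trial, model, par[1], par[2])),
      error = function(e) -Inf)
  }
  lo <- lower
  hi <- upper
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = pts))
    pts_df <- as.matrix(expand.grid(grids))
    vals <- apply(pts_df, 1, f)
    best <- pts_df[which.max(vals), ]
    span <- (hi - lo) / (pts - 1)
    lo <- pmax(lower, best - span)
    hi <- pmin(upper, best + span)
  }
  list(par = best, loglik = max(vals))
}

# Welch-Satterthwaite two-sample degrees of freedom.
welch_df <- function(s1, n1, s0, n0) {
  (s1 / n1 + s0 / n0)^2 /
    ((s1 / n1)^2 / (n1 - 1) + (s0 / n0)^2 / (n0 - 1))
}

# Spec-style toy dataset: two intervention clusters of two, four control rows.
toy_trial <- function() {
  data.frame(
    participant_id = 1:8,
    arm = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    cluster = c(1L, 1L, 2L, 2L, NA, NA, NA, NA),
    y = c(1, 2, 3, 4, 0, 1, 2, 3)
  )
}

# Small random pnRCT dataset with labelled control clusters available.
random_small_trial <- function(seed, c_ = 3, m = 3, icc = 0.2,
                               var_ratio = 1.5, effect = 0.4) {
  cfg <- scenario_config(c_, m, effect = effect, icc = icc,
                         var_ratio = var_ratio, seed = seed)
  generate_trial(cfg, replicate = 1)
}

# One-way ANOVA moment estimators on the intervention arm (balanced).
anova_estimators <- function(trial) {
  d1 <- trial[trial$arm == 1, ]
  m <- as.numeric(table(d1$cluster)[1])
  cm <- tapply(d1$y, d1$cluster, mean)
  c_ <- length(cm)
  msb <- m * stats::var(cm)
  msw <- sum((d1$y - cm[as.character(d1$cluster)])^2) / (c_ * (m - 1))
  list(msb = msb, msw = msw,
       sigma_u2 = (msb - msw) / m, sigma_e2 = msw)
}
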