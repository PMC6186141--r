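test_that("marginal covariance blocks follow the model definitions", {
  d <- toy_trial()

  b1 <- marginal_covariance_blocks(d, "linear", sigma_e2 = 2)
  expect_true(all(b1$size == 1))
  expect_true(all(b1$resid_var == 2))
  expect_true(all(b1$cluster_var == 0))

  b3 <- marginal_covariance_blocks(d, "pn-hom", sigma_u2 = 0.5, sigma_e2 = 2)
  int <- b3$arm == 1
  expect_equal(b3$size[int], c(2, 2))
  expect_true(all(b3$cluster_var[int] == 0.5))
  expect_true(all(b3$size[!int] == 1 & b3$cluster_var[!int] == 0))

  b4 <- marginal_covariance_blocks(d, "pn-het", sigma_u2 = 0.5,
                                   sigma_e2 = 2, sigma_r2 = 3)
  expect_true(all(b4$resid_var[b4$arm == 0] == 3))
  expect_true(all(b4$resid_var[b4$arm == 1] == 2))

  # compound-symmetry determinant identity for one block of size m
  m <- 2; se2 <- 2; su2 <- 0.5
  blk <- diag(se2, m) + su2
  expect_equal(determinant(blk, logarithm = TRUE)$modulus[1],
               (m - 1) * log(se2) + log(se2 + m * su2))

  dc <- apply_control_coding(d, control_coding("one-cluster"))
  b2 <- marginal_covariance_blocks(dc, "fully-clustered", sigma_u2 = 0.5,
                                   sigma_e2 = 2)
  expect_true(all(b2$cluster_var == 0.5))
  expect_equal(sort(b2$size), c(2, 2, 4))
})

test_that("block closed-form REML loglik matches dense-matrix evaluation", {
  d <- toy_trial()
  pts <- list(c(0.3, 1.2), c(0.001, 0.5), c(2, 3), c(0, 1))
  for (p in pts) {
    expect_equal(reml_loglik(d, "pn-hom", p[1], p[2]),
                 dense_reml_loglik(d, "pn-hom", p[1], p[2]),
                 tolerance = 1e-6)
    expect_equal(reml_loglik(d, "pn-het", p[1], p[2], sigma_r2 = 0.8),
                 dense_reml_loglik(d, "pn-het", p[1], p[2], 0.8),
                 tolerance = 1e-6)
  }
  expect_equal(reml_loglik(d, "linear", sigma_e2 = 1.7),
               dense_reml_loglik(d, "linear", sigma_e2 = 1.7),
               tolerance = 1e-6)
  dc <- apply_control_coding(d, control_coding("pseudo", k = 2))
  expect_equal(reml_loglik(dc, "fully-clustered", 0.4, 1.1),
               dense_reml_loglik(dc, "fully-clustered", 0.4, 1.1),
               tolerance = 1e-6)
  # non-positive-definite variance components are rejected
  expect_error(reml_loglik(d, "pn-hom", 0.1, -1), "positive")
})

test_that("REML loglik is invariant to shifting all outcomes", {
  d <- random_small_trial(41)
  d2 <- d
  d2$y <- d$y + 5
  expect_equal(reml_loglik(d, "pn-hom", 0.2, 0.9),
               reml_loglik(d2, "pn-hom", 0.2, 0.9), tolerance = 1e-9)
  expect_equal(reml_loglik(d, "pn-het", 0.2, 0.9, sigma_r2 = 1.4),
               reml_loglik(d2, "pn-het", 0.2, 0.9, sigma_r2 = 1.4),
               tolerance = 1e-9)
})

test_that("fitted models match brute-force grid maximisation of the dense REML criterion", {
  seeds <- 101:106
  for (s in seeds) {
    d <- random_small_trial(s)
    dc <- apply_control_coding(d, control_coding("pseudo", k = 3,
                                                 seed = s))
    for (model in c("pn-hom", "pn-het", "fully-clustered")) {
      dd <- if (model == "fully-clustered") dc else d
      fit <- fit_pnrct(dd, model_spec(model, control_coding("pseudo", k = 3,
                                                            seed = s)))
      expect_true(fit$converged)
      oracle <- switch(model,
        "pn-het" = grid_refine_reml(dd, model, c(0, 0.05, 0.05),
                                    c(4, 6, 6)),
        grid_refine_reml(dd, model, c(0, 0.05), c(4, 6)))
      expect_gte(fit$loglik, oracle$loglik - 1e-4)
      ev_at_oracle <- switch(model,
        "pn-het" = reml_loglik(dd, model, oracle$par[1], oracle$par[2],
                               oracle$par[3]),
        reml_loglik(dd, model, oracle$par[1], oracle$par[2]))
      expect_equal(fit$loglik, ev_at_oracle, tolerance = 1e-3)
    }
  }
})

test_that("linear model reduces to OLS", {
  d <- random_small_trial(7, c_ = 4, m = 5)
  fit <- fit_pnrct(d, "linear")
  lmfit <- lm(y ~ arm, data = d)
  expect_equal(fit$theta,
               mean(d$y[d$arm == 1]) - mean(d$y[d$arm == 0]),
               tolerance = 1e-12)
  expect_equal(fit$sigma_e2, sum(residuals(lmfit)^2) / (nrow(d) - 2),
               tolerance = 1e-12)
  expect_equal(fit$se_theta, summary(lmfit)$coefficients["arm", "Std. Error"],
               tolerance = 1e-10)
})

test_that("heteroscedastic fit equals ANOVA estimators on balanced data", {
  d <- generate_trial(scenario_config(10, 6, icc = 0.3, var_ratio = 2,
                                      seed = 17), 1)
  fit <- fit_pnrct(d, "pn-het")
  an <- anova_estimators(d)
  skip_if(an$sigma_u2 < 0)  # boundary case exercised elsewhere
  expect_equal(fit$sigma_u2, an$sigma_u2, tolerance = 1e-10)
  expect_equal(fit$sigma_e2, an$sigma_e2, tolerance = 1e-10)
  y0 <- d$y[d$arm == 0]
  expect_equal(fit$sigma_r2, var(y0), tolerance = 1e-10)
})

test_that("fits agree with lme4/nlme reference implementations to 4 significant figures", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("nlme")
  d <- generate_trial(scenario_config(24, 30, effect = 0.5, icc = 0.1,
                                      var_ratio = 2, seed = 19), 1)
  dc <- apply_control_coding(d, control_coding("one-cluster"))
  dc$cluster <- factor(dc$cluster)

  f3 <- fit_pnrct(d, "pn-hom")
  m3 <- lme4::lmer(y ~ arm + (0 + arm | cluster), data = dc, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m3))
  expect_equal(f3$theta, lme4::fixef(m3)[["arm"]], tolerance = 1e-6)
  expect_equal(f3$se_theta, summary(m3)$coefficients["arm", "Std. Error"],
               tolerance = 1e-4)
  expect_equal(f3$sigma_u2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f3$sigma_e2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(f3$loglik, as.numeric(logLik(m3)), tolerance = 1e-8)

  f4 <- fit_pnrct(d, "pn-het")
  m4 <- nlme::lme(y ~ arm,
                  random = list(cluster = nlme::pdIdent(~ 0 + arm)),
                  weights = nlme::varIdent(form = ~ 1 | arm),
                  data = dc, method = "REML")
  expect_equal(f4$theta, nlme::fixef(m4)[["arm"]], tolerance = 1e-6)
  expect_equal(f4$se_theta, sqrt(vcov(m4)["arm", "arm"]), tolerance = 1e-4)
  expect_equal(f4$sigma_u2,
               as.numeric(nlme::VarCorr(m4)["arm", "Variance"]),
               tolerance = 1e-4)
  expect_equal(f4$loglik, as.numeric(logLik(m4)), tolerance = 1e-8)

  f2 <- fit_pnrct(d, model_spec("fully-clustered",
                                control_coding("one-cluster")))
  m2 <- lme4::lmer(y ~ arm + (1 | cluster), data = dc, REML = TRUE)
  vc2 <- as.data.frame(lme4::VarCorr(m2))
  expect_equal(f2$theta, lme4::fixef(m2)[["arm"]], tolerance = 1e-6)
  expect_equal(f2$sigma_u2, vc2$vcov[1], tolerance = 1e-4)
  expect_equal(f2$loglik, as.numeric(logLik(m2)), tolerance = 1e-8)
})

test_that("heteroscedastic model nests the homoscedastic model", {
  d <- random_small_trial(53, c_ = 5, m = 4)
  # constrained equal residual variances: identical criterion values
  for (su2 in c(0, 0.2, 1)) {
    for (s2 in c(0.5, 1, 2)) {
      expect_equal(reml_loglik(d, "pn-het", su2, s2, sigma_r2 = s2),
                   reml_loglik(d, "pn-hom", su2, s2), tolerance = 1e-10)
    }
  }
  # so the unconstrained heteroscedastic maximum can only be higher
  expect_gte(fit_pnrct(d, "pn-het")$loglik, fit_pnrct(d, "pn-hom")$loglik)
})

test_that("zero-ICC data attain the sigma_u2 = 0 boundary without error", {
  cfg <- scenario_config(6, 10, icc = 0, seed = 61)
  at_boundary <- vapply(1:20, function(r) {
    f <- fit_pnrct(generate_trial(cfg, r), "pn-hom")
    expect_true(f$converged)
    f$sigma_u2 == 0
  }, logical(1))
  expect_gt(mean(at_boundary), 0)
  expect_lt(mean(at_boundary), 1)
})

test_that("fitted loglik dominates the loglik at the generating values", {
  cfg <- scenario_config(8, 6, effect = 0.2, icc = 0.1, var_ratio = 2,
                         seed = 71)
  for (r in 1:10) {
    d <- generate_trial(cfg, r)
    f3 <- fit_pnrct(d, "pn-hom")
    expect_gte(f3$loglik,
               reml_loglik(d, "pn-hom", 0.1, 0.9) - 1e-8)
    f4 <- fit_pnrct(d, "pn-het")
    expect_gte(f4$loglik,
               reml_loglik(d, "pn-het", 0.1, 0.9, sigma_r2 = 2 * 0.9) - 1e-8)
  }
})

test_that("variance components are consistent at the generating values", {
  d <- generate_trial(scenario_config(60, 30, icc = 0, var_ratio = 4,
                                      seed = 81), 1)
  f <- fit_pnrct(d, "pn-het")
  expect_lt(abs(f$sigma_r2 / f$sigma_e2 - 4), 0.5)
})

test_that("ICC estimator maps variance components correctly", {
  expect_equal(estimate_icc(0, 1), 0)
  expect_equal(estimate_icc(1, 1), 0.5)
  expect_equal(estimate_icc(0.1, 0.9), 0.1)
  und <- estimate_icc(0, 0)
  expect_equal(as.numeric(und), 0)
  expect_true(attr(und, "undefined"))
  expect_error(estimate_icc(-0.1, 1))
})

test_that("degenerate data are flagged as non-converged, not an error", {
  d <- toy_trial()
  d$y <- rep(1, 8)
  f <- fit_pnrct(d, "pn-hom")
  expect_false(f$converged)
  expect_true(is.na(f$p_value))
})
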