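#' Specify an analysis model for a partially nested trial
#'
#' Four candidate analysis models are supported, all with fixed effects
#' intercept + intervention indicator and fitted by REML:
#'
#' * `"linear"`: linear regression ignoring clustering;
#' * `"fully-clustered"`: random cluster intercept in both arms, so the
#'   control arm must carry (artificial) cluster labels — see
#'   [control_coding()];
#' * `"pn-hom"`: partially nested homoscedastic model — random cluster
#'   intercept in the intervention arm only, common residual variance;
#' * `"pn-het"`: partially nested heteroscedastic model — random cluster
#'   intercept in the intervention arm only, arm-specific residual
#'   variances.
#'
#' @param model Model name (see above).
#' @param coding A [control_coding()] object; required for
#'   `"fully-clustered"` when the data carry no control-arm labels,
#'   immaterial for the partially nested models (default `"one-cluster"`).
#' @param label Optional short label used in study-runner output; defaults
#'   to the model name, plus the coding scheme for the fully clustered
#'   model.
#' @return An object of class `pnrct_model`.
#' @examples
#' model_spec("pn-het")
#' model_spec("fully-clustered", control_coding("pseudo"))
#' @export
model_spec <- function(model = c("linear", "fully-clustered",
                                 "pn-hom", "pn-het"),
                       coding = NULL, label = NULL) {
  model <- match.arg(model)
  if (!is.null(coding)) stopifnot(inherits(coding, "pnrct_coding"))
  if (is.null(coding) && model == "fully-clustered") {
    coding <- control_coding("one-cluster")
  }
  if (is.null(label)) {
    label <- if (model == "fully-clustered") {
      paste0(model, "/", coding$scheme)
    } else model
  }
  structure(list(model = model, coding = coding, label = label),
            class = "pnrct_model")
}

# ---- block structure -------------------------------------------------------

# Per-block marginal covariance layout. Every model's marginal covariance is
# block diagonal; a block of size n with cluster variance su2 and residual
# variance s2 is s2*I + su2*J, admitting closed-form determinant and inverse.
block_layout <- function(trial, model, coding = NULL) {
  check_trial(trial)
  if (!is.null(coding) && anyNA(trial$cluster)) {
    trial <- apply_control_coding(trial, coding)
  }
  if (model == "fully-clustered" && anyNA(trial$cluster)) {
    stop("the fully clustered model needs control-arm cluster labels; ",
         "supply a control_coding()", call. = FALSE)
  }
  arm <- trial$arm
  id <- switch(model,
    "linear" = seq_len(nrow(trial)),
    "fully-clustered" = trial$cluster,
    # partially nested: control rows are independent singleton blocks
    {
      blk <- trial$cluster
      ctl <- arm == 0L
      blk[ctl] <- max(trial$cluster[arm == 1L]) + seq_len(sum(ctl))
      blk
    })
  uid <- unique(id)
  idx <- match(id, uid)
  G <- length(uid)
  n_b <- tabulate(idx, G)
  t_b <- arm[match(seq_len(G), idx)]
  if (any(as.vector(rowsum(arm, idx)) != n_b * t_b)) {
    stop("a cluster label spans both arms; control labels must be disjoint ",
         "from intervention labels", call. = FALSE)
  }
  S_b <- as.vector(rowsum(trial$y, idx))
  Q_b <- as.vector(rowsum(trial$y^2, idx))
  u_b <- switch(model,
    "linear" = rep.int(0, G),
    "fully-clustered" = rep.int(1, G),
    as.numeric(t_b == 1L))
  r_b <- if (model == "pn-het") ifelse(t_b == 1L, 1L, 2L) else
    rep.int(1L, G)
  list(label = as.character(uid), n = n_b, t = t_b, u = u_b, r = r_b,
       S = S_b, Q = Q_b)
}

# Collapse blocks with identical (size, arm, cluster flag, residual group)
# into summary groups; all evaluation then runs over a handful of scalars.
# Singleton blocks (the linear model, and control rows under the partially
# nested models) are aggregated directly without enumerating them.
block_stats <- function(trial, model, coding = NULL) {
  check_trial(trial)
  arm <- trial$arm
  y <- trial$y
  collapse <- function(n_b, t_b, u_b, r_b, S_b, Q_b) {
    key <- ((n_b * 2L + t_b) * 2L + u_b) * 4L + r_b
    idx <- match(key, unique(key))
    G <- max(idx)
    take1 <- match(seq_len(G), idx)
    list(n = n_b[take1], t = t_b[take1], u = u_b[take1], r = r_b[take1],
         g = as.vector(tabulate(idx, G)),
         SS = as.vector(rowsum(S_b, idx)),
         SS2 = as.vector(rowsum(S_b^2, idx)),
         QQ = as.vector(rowsum(Q_b, idx)))
  }
  singleton_group <- function(rows, t_b, r_b) {
    yy <- y[rows]
    list(n = 1L, t = t_b, u = 0, r = r_b, g = length(yy),
         SS = sum(yy), SS2 = sum(yy^2), QQ = sum(yy^2))
  }
  cat_groups <- function(a, b) {
    Map(c, a, b)
  }
  if (model == "linear") {
    gs <- cat_groups(singleton_group(arm == 1L, 1L, 1L),
                     singleton_group(arm == 0L, 0L, 1L))
  } else if (model == "fully-clustered") {
    if (!is.null(coding) && anyNA(trial$cluster)) {
      trial <- apply_control_coding(trial, coding)
    }
    if (anyNA(trial$cluster)) {
      stop("the fully clustered model needs control-arm cluster labels; ",
           "supply a control_coding()", call. = FALSE)
    }
    uid <- unique(trial$cluster)
    idx <- match(trial$cluster, uid)
    n_b <- tabulate(idx, length(uid))
    t_b <- arm[match(seq_along(uid), idx)]
    if (any(as.vector(rowsum(arm, idx)) != n_b * t_b)) {
      stop("a cluster label spans both arms; control labels must be ",
           "disjoint from intervention labels", call. = FALSE)
    }
    gs <- collapse(n_b, t_b, rep.int(1, length(n_b)),
                   rep.int(1L, length(n_b)),
                   as.vector(rowsum(y, idx)), as.vector(rowsum(y^2, idx)))
  } else {
    int <- arm == 1L
    cl <- trial$cluster[int]
    uid <- unique(cl)
    idx <- match(cl, uid)
    n_b <- tabulate(idx, length(uid))
    gi <- collapse(n_b, rep.int(1L, length(uid)), rep.int(1, length(uid)),
                   rep.int(1L, length(uid)),
                   as.vector(rowsum(y[int], idx)),
                   as.vector(rowsum(y[int]^2, idx)))
    gs <- cat_groups(gi, singleton_group(!int, 0L,
                                         if (model == "pn-het") 2L else 1L))
  }
  ntot <- sum(gs$n * gs$g)
  structure(list(groups = gs, model = model, n = ntot,
                 n1 = sum(gs$n * gs$g * gs$t),
                 n0 = sum(gs$n * gs$g * (1 - gs$t)),
                 nvar = switch(model, "linear" = 1L, "pn-het" = 3L, 2L)),
            class = "pnrct_blocks")
}

#' Marginal covariance block description
#'
#' Describes the block-diagonal marginal covariance implied by a model and a
#' set of variance components: one row per independent block with its size,
#' arm, residual variance and cluster (compound-symmetry) variance. Each
#' block's covariance is `resid_var * I + cluster_var * J`.
#'
#' @inheritParams reml_loglik
#' @return A `data.frame` with columns `block`, `size`, `arm`, `resid_var`,
#'   `cluster_var`.
#' @examples
#' d <- generate_trial(scenario_config(3, 4))
#' marginal_covariance_blocks(d, "pn-het", sigma_u2 = 0.1,
#'                            sigma_e2 = 0.9, sigma_r2 = 1.2)
#' @export
marginal_covariance_blocks <- function(trial, model, sigma_u2 = 0,
                                       sigma_e2 = 1, sigma_r2 = NULL,
                                       coding = NULL) {
  model <- match.arg(model, c("linear", "fully-clustered", "pn-hom", "pn-het"))
  if (model == "pn-het" && is.null(sigma_r2)) {
    stop("`sigma_r2` is required for the heteroscedastic model",
         call. = FALSE)
  }
  bl <- block_layout(trial, model, coding)
  data.frame(
    block = bl$label,
    size = bl$n,
    arm = bl$t,
    resid_var = if (model == "pn-het") {
      ifelse(bl$r == 1L, sigma_e2, sigma_r2)
    } else rep.int(sigma_e2, length(bl$n)),
    cluster_var = bl$u * sigma_u2
  )
}

# ---- REML criterion --------------------------------------------------------

# Vectorised evaluation of the restricted log-likelihood and of the
# intervention-contrast variance v = [(X'V^-1 X)^-1]_{22} at a matrix of
# variance-parameter points (rows). Uses the compound-symmetry identities
#   log|s2*I + su2*J| = (n-1) log s2 + log(s2 + n*su2)
#   (s2*I + su2*J)^-1 = (1/s2) (I - su2/(s2 + n*su2) J)
# so each point costs a few scalar operations per block group.
reml_eval <- function(bs, par) {
  if (is.null(dim(par))) par <- matrix(par, nrow = 1L)
  K <- nrow(par)
  gs <- bs$groups
  su2 <- switch(bs$model, "linear" = numeric(K), par[, 1L])
  se2 <- switch(bs$model, "linear" = par[, 1L], par[, 2L])
  sr2 <- switch(bs$model, "pn-het" = par[, 3L], se2)

  logdetV <- A11 <- A12 <- A22 <- c1 <- c2 <- yy <- numeric(K)
  ok <- rep.int(TRUE, K)
  for (i in seq_along(gs$n)) {
    s2 <- if (gs$r[i] == 1L) se2 else sr2
    d <- s2 + gs$u[i] * gs$n[i] * su2
    ok <- ok & s2 > 0 & d > 0
    # clamp inside log only to silence warnings; invalid columns are
    # overwritten with -Inf below
    logdetV <- logdetV + gs$g[i] *
      ((gs$n[i] - 1) * log(pmax(s2, 1e-300)) + log(pmax(d, 1e-300)))
    w <- gs$g[i] * gs$n[i] / d
    A11 <- A11 + w
    if (gs$t[i] == 1L) A12 <- A12 + w
    cc <- gs$SS[i] / d
    c1 <- c1 + cc
    if (gs$t[i] == 1L) c2 <- c2 + cc
    yy <- yy + gs$QQ[i] / s2 - gs$u[i] * su2 / (s2 * d) * gs$SS2[i]
  }
  A22 <- A12
  det2 <- A11 * A22 - A12^2
  theta <- (A11 * c2 - A12 * c1) / det2
  beta0 <- (A22 * c1 - A12 * c2) / det2
  q <- yy - beta0 * c1 - theta * c2
  n <- bs$n
  ok <- ok & is.finite(det2) & det2 > 0
  ll <- -0.5 * ((n - 2) * log(2 * pi) + logdetV + log(pmax(det2, 1e-300)) + q)
  ll[!ok] <- -Inf
  list(loglik = ll, v = A11 / det2, beta0 = beta0, theta = theta, q = q,
       ok = ok)
}

#' Restricted log-likelihood of a pnRCT analysis model
#'
#' Evaluates the REML criterion (including constants)
#' \deqn{\ell_R = -\tfrac{1}{2}\left[(n-p)\log 2\pi + \log|V| +
#'   \log|X'V^{-1}X| + (y - X\hat\beta)'V^{-1}(y - X\hat\beta)\right]}
#' with the fixed effects (intercept and intervention effect, `p = 2`)
#' profiled out by generalised least squares at the supplied variance
#' components. The block-diagonal compound-symmetry structure of `V` is
#' exploited in closed form; no dense n-by-n factorisation is performed.
#'
#' @param trial A trial `data.frame`.
#' @param model Model name, see [model_spec()].
#' @param sigma_u2 Between-cluster variance (>= 0).
#' @param sigma_e2 Residual variance (intervention-arm residual variance
#'   under `"pn-het"`).
#' @param sigma_r2 Control-arm residual variance (`"pn-het"` only).
#' @param coding Optional [control_coding()] applied first if the control
#'   arm is unlabelled.
#' @return The restricted log-likelihood (a finite scalar), or an error if
#'   the implied covariance is not positive definite.
#' @examples
#' d <- generate_trial(scenario_config(4, 5, icc = 0.1))
#' reml_loglik(d, "pn-hom", sigma_u2 = 0.1, sigma_e2 = 0.9)
#' @export
reml_loglik <- function(trial, model, sigma_u2 = 0, sigma_e2 = 1,
                        sigma_r2 = NULL, coding = NULL) {
  model <- match.arg(model, c("linear", "fully-clustered", "pn-hom", "pn-het"))
  bs <- block_stats(trial, model, coding)
  par <- switch(model,
    "linear" = sigma_e2,
    "pn-het" = {
      if (is.null(sigma_r2)) {
        stop("`sigma_r2` is required for the heteroscedastic model",
             call. = FALSE)
      }
      c(sigma_u2, sigma_e2, sigma_r2)
    },
    c(sigma_u2, sigma_e2))
  ev <- reml_eval(bs, matrix(par, nrow = 1L))
  if (!ev$ok) {
    stop("variance components imply a covariance that is not positive ",
         "definite", call. = FALSE)
  }
  ev$loglik
}

# ---- fitting ---------------------------------------------------------------

# Profiled REML for models with a single variance ratio phi = sigma_u2 /
# sigma_e2: evaluate at unit residual variance, profile sigma_e2 in closed
# form. Returns negative profiled restricted log-likelihood (up to the
# constant (n-2)/2 * (log 2pi + 1), dropped inside the search).
prof_nll_ratio <- function(bs) {
  gs <- bs$groups
  n2 <- bs$n - 2
  nu <- gs$n * gs$u
  gn <- gs$g * gs$n
  i1 <- gs$t == 1L
  function(phi) {
    d <- 1 + nu * phi
    w <- gn / d
    A11 <- sum(w)
    A12 <- sum(w[i1])
    cc <- gs$SS / d
    c1 <- sum(cc)
    c2 <- sum(cc[i1])
    yy <- sum(gs$QQ - (gs$u * phi / d) * gs$SS2)
    det2 <- A12 * (A11 - A12)
    theta <- (A11 * c2 - A12 * c1) / det2
    beta0 <- (A12 * c1 - A12 * c2) / det2
    q <- yy - beta0 * c1 - theta * c2
    if (!is.finite(q) || q <= 0) return(Inf)
    0.5 * (n2 * log(q / n2) + sum(gs$g * log(d)) + log(det2))
  }
}

fit_ratio_model <- function(bs, phi_max = 1e3) {
  n_iter <- 0L
  nll0 <- prof_nll_ratio(bs)
  nll <- function(phi) {
    n_iter <<- n_iter + 1L
    nll0(phi)
  }
  opt <- stats::optimize(nll, c(0, phi_max), tol = 1e-8)
  phi <- opt$minimum
  if (nll(0) <= opt$objective + 1e-9) {
    phi <- 0
  }
  ev <- reml_eval(bs, matrix(c(phi, 1), nrow = 1L))
  se2 <- ev$q / (bs$n - 2)
  list(par = c(sigma_u2 = phi * se2, sigma_e2 = se2),
       n_iter = n_iter,
       converged = is.finite(se2) && se2 > 1e-10 &&
         phi < phi_max * (1 - 1e-6))
}

# Heteroscedastic partially nested model: the REML criterion separates into
# an intervention-arm one-way layout and an i.i.d. control sample, so the
# control residual variance is the control sample variance and the
# intervention components come from the balanced one-way closed form (ANOVA
# estimators, truncated at the sigma_u2 = 0 boundary) or, for unbalanced
# clusters, a one-dimensional profiled search.
fit_het_model <- function(bs, phi_max = 1e3) {
  gs <- bs$groups
  int <- gs$r == 1L
  ctl <- !int
  n0 <- bs$n0
  S0 <- sum(gs$SS[ctl])
  Q0 <- sum(gs$QQ[ctl])
  q0 <- Q0 - S0^2 / n0
  sr2 <- q0 / (n0 - 1)

  n1 <- bs$n1
  sizes <- gs$n[int]
  balanced <- length(sizes) == 1L
  n_iter <- 0L
  if (balanced && sizes[1L] > 1L) {
    m <- sizes[1L]
    cc <- gs$g[int]
    S1 <- gs$SS[int]
    ssb <- gs$SS2[int] / m - S1^2 / n1
    ssw <- gs$QQ[int] - gs$SS2[int] / m
    msb <- ssb / (cc - 1)
    msw <- ssw / (cc * (m - 1))
    if (msb > msw) {
      su2 <- (msb - msw) / m
      se2 <- msw
    } else {
      su2 <- 0
      se2 <- (ssb + ssw) / (n1 - 1)
    }
  } else {
    # one-way REML on the intervention arm alone, profiled over phi
    nll1 <- function(phi) {
      n_iter <<- n_iter + 1L
      d <- 1 + gs$n[int] * phi
      if (any(d <= 0)) return(Inf)
      logdetW <- sum(gs$g[int] * log(d))
      W1 <- sum(gs$g[int] * gs$n[int] / d)
      c1 <- sum(gs$SS[int] / d)
      yy <- sum(gs$QQ[int] - phi / d * gs$SS2[int])
      q <- yy - c1^2 / W1
      if (q <= 0) return(Inf)
      se2 <- q / (n1 - 1)
      0.5 * ((n1 - 1) * (log(2 * pi * se2) + 1) + logdetW + log(W1))
    }
    opt <- stats::optimize(nll1, c(0, phi_max), tol = 1e-8)
    phi <- if (nll1(0) <= opt$objective + 1e-9) 0 else opt$minimum
    d <- 1 + gs$n[int] * phi
    W1 <- sum(gs$g[int] * gs$n[int] / d)
    c1 <- sum(gs$SS[int] / d)
    yy <- sum(gs$QQ[int] - phi / d * gs$SS2[int])
    se2 <- (yy - c1^2 / W1) / (n1 - 1)
    su2 <- phi * se2
  }
  list(par = c(sigma_u2 = su2, sigma_e2 = se2, sigma_r2 = sr2),
       n_iter = n_iter,
       converged = is.finite(se2) && se2 > 1e-10 &&
         is.finite(sr2) && sr2 > 1e-10)
}

degenerate_fit <- function(bs, spec, level) {
  structure(list(
    model = spec$model, label = spec$label,
    coding = if (is.null(spec$coding)) NA_character_ else spec$coding$scheme,
    beta0 = NA_real_, theta = NA_real_, se_theta = NA_real_,
    sigma_u2 = NA_real_, sigma_e2 = NA_real_, sigma_r2 = NA_real_,
    icc = NA_real_, loglik = NA_real_, converged = FALSE, n_iter = 0L,
    varcomp_vcov = NULL, varcomp = NULL, active = NULL,
    n = bs$n, n1 = bs$n1, n0 = bs$n0, blockstats = bs,
    df = NA_real_, df_method = NA_character_, t_stat = NA_real_,
    p_value = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    level = level
  ), class = "pnrct_fit")
}

fit_linear_model <- function(bs) {
  gs <- bs$groups
  n1 <- bs$n1
  n0 <- bs$n0
  S1 <- sum(gs$SS[gs$t == 1L])
  S0 <- sum(gs$SS[gs$t == 0L])
  Q <- sum(gs$QQ)
  rss <- Q - S1^2 / n1 - S0^2 / n0
  se2 <- rss / (bs$n - 2)
  list(par = c(sigma_e2 = se2), n_iter = 0L,
       converged = is.finite(se2) && se2 > 1e-10)
}

# Observed information of the restricted log-likelihood on the variance
# scale, by central finite differences with step 1e-5 * max(estimate, 1).
# At the sigma_u2 = 0 boundary the small negative excursions remain inside
# the positive-definite domain for all but pathological data; if any
# evaluation fails the boundary parameter is dropped (attribute "active").
reml_hessian <- function(bs, est, active = NULL) {
  p <- length(est)
  h <- 1e-5 * pmax(abs(est), 1)
  if (is.null(active)) active <- rep.int(TRUE, p)
  build <- function(act) {
    ia <- which(act)
    pa <- length(ia)
    pts <- list(est)
    for (j in ia) {
      for (s in c(1, -1)) {
        x <- est; x[j] <- x[j] + s * h[j]; pts[[length(pts) + 1L]] <- x
      }
    }
    if (pa > 1L) {
      for (a in seq_len(pa - 1L)) {
        for (b in (a + 1L):pa) {
          for (sa in c(1, -1)) for (sb in c(1, -1)) {
            x <- est
            x[ia[a]] <- x[ia[a]] + sa * h[ia[a]]
            x[ia[b]] <- x[ia[b]] + sb * h[ia[b]]
            pts[[length(pts) + 1L]] <- x
          }
        }
      }
    }
    f <- reml_eval(bs, do.call(rbind, pts))$loglik
    if (any(!is.finite(f))) return(NULL)
    H <- matrix(0, pa, pa)
    k <- 2L
    for (a in seq_len(pa)) {
      H[a, a] <- (f[k] + f[k + 1L] - 2 * f[1L]) / h[ia[a]]^2
      k <- k + 2L
    }
    if (pa > 1L) {
      for (a in seq_len(pa - 1L)) {
        for (b in (a + 1L):pa) {
          H[a, b] <- H[b, a] <-
            (f[k] - f[k + 1L] - f[k + 2L] + f[k + 3L]) /
            (4 * h[ia[a]] * h[ia[b]])
          k <- k + 4L
        }
      }
    }
    H
  }
  H <- build(active)
  if (is.null(H) && p > 1L && active[1L] && est[1L] <= 1e-8) {
    active[1L] <- FALSE
    H <- build(active)
  }
  list(H = H, active = active, h = h)
}

#' Fit a pnRCT analysis model by REML
#'
#' Fits one of the four candidate models (see [model_spec()]) by restricted
#' maximum likelihood using closed-form block compound-symmetry algebra,
#' then computes the Satterthwaite degrees of freedom and a t-based test and
#' confidence interval for the intervention effect.
#'
#' The variance components are optimised on the variance scale with the
#' between-cluster variance bounded below by zero, so the boundary estimate
#' `sigma_u2 = 0` is attainable (it occurs with positive probability when
#' the true ICC is zero and drives the conservative behaviour of the
#' partially nested models there). Optimiser failure is reported via
#' `converged = FALSE`, never as an error.
#'
#' @param trial A trial `data.frame` ([generate_trial()] or [read_trial()]).
#' @param model Model name or a [model_spec()] object.
#' @param coding Optional [control_coding()]; see [model_spec()].
#' @param level Confidence level for the interval (default 0.95).
#' @return An object of class `pnrct_fit`: a list with the fixed-effect
#'   estimates (`beta0`, `theta`, `se_theta`), variance components
#'   (`sigma_u2`, `sigma_e2`, `sigma_r2`), `icc`, `loglik`, `converged`,
#'   `n_iter`, the variance-parameter covariance `varcomp_vcov`, and the
#'   inference fields `df`, `df_method`, `t_stat`, `p_value`, `ci_lower`,
#'   `ci_upper`, `level`.
#' @examples
#' d <- generate_trial(scenario_config(12, 10, effect = 0.5, icc = 0.1))
#' fit_pnrct(d, "pn-het")
#' @export
fit_pnrct <- function(trial, model = "pn-het", coding = NULL, level = 0.95) {
  if (inherits(model, "pnrct_model")) {
    spec <- model
  } else {
    spec <- model_spec(model, coding)
  }
  bs <- block_stats(trial, spec$model, spec$coding)
  if (fit_linear_model(bs)$par[["sigma_e2"]] <= 1e-12) {
    # zero residual variation: REML surface degenerate, flag and return
    return(degenerate_fit(bs, spec, level))
  }
  fitted <- switch(spec$model,
    "linear" = fit_linear_model(bs),
    "pn-het" = fit_het_model(bs),
    fit_ratio_model(bs))
  est <- fitted$par
  ev <- reml_eval(bs, matrix(est, nrow = 1L))

  su2 <- if (spec$model == "linear") NA_real_ else unname(est["sigma_u2"])
  se2 <- unname(est["sigma_e2"])
  sr2 <- if (spec$model == "pn-het") unname(est["sigma_r2"]) else NA_real_
  icc <- if (spec$model == "linear") NA_real_ else estimate_icc(su2, se2)

  # At the sigma_u2 = 0 boundary the REML estimator is not interior and its
  # information row is unusable for the Satterthwaite moment match; treat the
  # boundary component as fixed and take the information over the interior
  # parameters (this reproduces the Welch-Satterthwaite df in the
  # heteroscedastic no-clustering case).
  act0 <- rep.int(TRUE, length(est))
  if (spec$model != "linear" && length(est) > 1L &&
      est["sigma_u2"] <= 1e-10) {
    act0[1L] <- FALSE
  }
  vcov_info <- if (fitted$converged) reml_hessian(bs, est, act0) else
    list(H = NULL, active = act0)
  varcomp_vcov <- NULL
  if (!is.null(vcov_info$H)) {
    A <- tryCatch(solve(-vcov_info$H), error = function(e) NULL)
    if (!is.null(A) && all(is.finite(A))) {
      nm <- names(est)[vcov_info$active]
      dimnames(A) <- list(nm, nm)
      varcomp_vcov <- A
    }
  }

  fit <- structure(list(
    model = spec$model, label = spec$label,
    coding = if (is.null(spec$coding)) NA_character_ else spec$coding$scheme,
    beta0 = ev$beta0, theta = ev$theta,
    se_theta = sqrt(ev$v),
    sigma_u2 = su2, sigma_e2 = se2, sigma_r2 = sr2,
    icc = icc, loglik = ev$loglik,
    converged = fitted$converged && is.finite(ev$loglik),
    n_iter = fitted$n_iter,
    varcomp_vcov = varcomp_vcov,
    varcomp = est,
    active = vcov_info$active,
    n = bs$n, n1 = bs$n1, n0 = bs$n0,
    blockstats = bs
  ), class = "pnrct_fit")

  fit$df <- NA_real_
  fit$df_method <- NA_character_
  if (fit$converged) {
    df <- satterthwaite_df(fit)
    fit$df <- as.numeric(df)
    fit$df_method <- attr(df, "method")
    inf <- wald_test_ci(fit, df = fit$df, level = level)
    fit[c("t_stat", "p_value", "ci_lower", "ci_upper", "level")] <-
      inf[c("t_stat", "p_value", "ci_lower", "ci_upper", "level")]
  } else {
    fit[c("t_stat", "p_value", "ci_lower", "ci_upper")] <- NA_real_
    fit$level <- level
  }
  fit
}

#' @export
print.pnrct_fit <- function(x, digits = 4, ...) {
  cat("pnRCT REML fit:", x$label, "model",
      if (!is.na(x$coding)) paste0("(control coding: ", x$coding, ")"), "\n")
  cat(sprintf("  intervention effect: %.*g (SE %.*g), %d%% CI [%.*g, %.*g]\n",
              digits, x$theta, digits, x$se_theta,
              round(100 * x$level), digits, x$ci_lower, digits, x$ci_upper))
  cat(sprintf("  t = %.*g on Satterthwaite df = %.*g, p = %.*g\n",
              digits, x$t_stat, digits, x$df, digits, x$p_value))
  vc <- c("cluster" = x$sigma_u2, "residual" = x$sigma_e2,
          "residual (control)" = x$sigma_r2)
  vc <- vc[!is.na(vc)]
  cat("  variance components:",
      paste(sprintf("%s = %.*g", names(vc), digits, vc), collapse = ", "),
      "\n")
  if (!is.na(x$icc)) cat(sprintf("  ICC = %.*g\n", digits, x$icc))
  cat(sprintf("  REML log-likelihood = %.*g; converged: %s\n",
              digits + 2, x$loglik, x$converged))
  invisible(x)
}

#' Intracluster correlation from variance components
#'
#' The ICC is the proportion of total variance attributable to
#' between-cluster variation, `sigma_u2 / (sigma_u2 + sigma_e2)`. Under the
#' heteroscedastic model the residual variance is that of the clustered
#' intervention arm.
#'
#' @param sigma_u2 Between-cluster variance (>= 0).
#' @param sigma_e2 Individual-level (residual) variance.
#' @return The ICC in `[0, 1]`. When both components are zero the ICC is
#'   undefined; 0 is returned with attribute `undefined = TRUE`.
#' @examples
#' estimate_icc(0.1, 0.9)
#' @export
estimate_icc <- function(sigma_u2, sigma_e2) {
  stopifnot(sigma_u2 >= 0, sigma_e2 >= 0)
  tot <- sigma_u2 + sigma_e2
  if (tot == 0) {
    return(structure(0, undefined = TRUE))
  }
  sigma_u2 / tot
}
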