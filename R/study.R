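#' Monte Carlo error of a simulated proportion
#'
#' Binomial standard error `sqrt(p * (1 - p) / nsim)` of a proportion
#' estimated from `nsim` independent replicates. For a 5% significance
#' level and 1000 replicates this is 0.0069, i.e. about 0.7%.
#'
#' @param p Proportion in `[0, 1]`.
#' @param nsim Number of replicates (>= 1).
#' @return The Monte Carlo standard error.
#' @examples
#' mc_error(0.05, 1000)
#' @export
mc_error <- function(p, nsim) {
  stopifnot(all(p >= 0 & p <= 1), all(nsim >= 1))
  sqrt(p * (1 - p) / nsim)
}

normalize_models <- function(models) {
  if (inherits(models, "pnrct_model")) models <- list(models)
  lapply(models, function(mo) {
    if (inherits(mo, "pnrct_model")) mo else model_spec(mo)
  })
}

#' Run all replicates of one scenario
#'
#' Generates `config$n_reps` trial datasets and fits every requested model
#' to each of them (a paired comparison: all models see the same data).
#' Non-converged fits are recorded with missing inference fields, never
#' dropped.
#'
#' @param config A [scenario_config()].
#' @param models A list of [model_spec()] objects (or model-name strings).
#' @return A `data.frame` with one row per (replicate, model): scenario
#'   identifiers, `replicate`, `model`, `theta_hat`, `se`, `df`, `p_value`,
#'   `ci_lower`, `ci_upper`, `icc_hat`, `converged`.
#' @examples
#' cfg <- scenario_config(6, 5, icc = 0.05, n_reps = 3)
#' run_scenario(cfg, list(model_spec("linear"), model_spec("pn-het")))
#' @export
run_scenario <- function(config, models) {
  stopifnot(inherits(config, "pnrct_scenario"))
  models <- normalize_models(models)
  R <- config$n_reps
  M <- length(models)
  rep_seeds <- substream_seeds(config$seed, R)

  nrec <- R * M
  theta_hat <- se <- df <- p_value <- ci_lo <- ci_hi <- icc_hat <-
    rep.int(NA_real_, nrec)
  converged <- rep.int(FALSE, nrec)
  for (r in seq_len(R)) {
    d <- generate_trial_seeded(config, rep_seeds[r])
    for (k in seq_len(M)) {
      i <- (r - 1L) * M + k
      fit <- fit_pnrct(d, models[[k]])
      theta_hat[i] <- fit$theta
      se[i] <- fit$se_theta
      icc_hat[i] <- fit$icc
      converged[i] <- fit$converged
      if (fit$converged) {
        df[i] <- fit$df
        p_value[i] <- fit$p_value
        ci_lo[i] <- fit$ci_lower
        ci_hi[i] <- fit$ci_upper
      }
    }
  }
  data.frame(
    n_clusters = config$n_clusters, cluster_size = config$cluster_size,
    effect = config$effect, icc = config$icc, var_ratio = config$var_ratio,
    replicate = rep(seq_len(R), each = M),
    model = rep.int(vapply(models, `[[`, "", "label"), R),
    theta_hat = theta_hat, se = se, df = df, p_value = p_value,
    ci_lower = ci_lo, ci_upper = ci_hi, icc_hat = icc_hat,
    converged = converged
  )
}

#' Summarise replicate records into operating characteristics
#'
#' Computes, per model, the performance measures of a simulation scenario:
#' bias and MSE of the intervention effect estimate, coverage of the
#' confidence interval, rejection rate of the 5% test (the Type I error
#' rate under the null, power otherwise), mean estimated ICC, convergence
#' rate, and Monte Carlo standard errors for the proportions.
#'
#' @param records Replicate records from [run_scenario()] for a single
#'   scenario.
#' @param effect True intervention effect (defaults to the value recorded
#'   in `records`).
#' @param alpha Significance level for the rejection rate (default 0.05).
#' @param denominator `"converged"` (default) computes all measures over
#'   converged fits only; `"all"` uses every replicate.
#' @return A `data.frame` with one row per model.
#' @examples
#' cfg <- scenario_config(6, 5, icc = 0.05, n_reps = 20)
#' summarize_scenario(run_scenario(cfg, list(model_spec("pn-hom"))))
#' @export
summarize_scenario <- function(records, effect = NULL, alpha = 0.05,
                               denominator = c("converged", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(records) > 0)
  if (is.null(effect)) effect <- records$effect[1L]
  one <- function(rec) {
    keep <- if (denominator == "converged") rec$converged else
      rep.int(TRUE, nrow(rec))
    nk <- sum(keep)
    if (nk == 0L) {
      return(data.frame(
        model = rec$model[1L], n_reps = nrow(rec), n_converged = 0L,
        convergence_rate = 0, bias = NA_real_, mse = NA_real_,
        coverage = NA_real_, rejection_rate = NA_real_,
        mean_icc = NA_real_, mc_se_rejection = NA_real_,
        mc_se_coverage = NA_real_, empty = TRUE
      ))
    }
    th <- rec$theta_hat[keep]
    rej <- mean(rec$p_value[keep] < alpha, na.rm = TRUE)
    cov <- mean(rec$ci_lower[keep] <= effect & effect <= rec$ci_upper[keep],
                na.rm = TRUE)
    data.frame(
      model = rec$model[1L], n_reps = nrow(rec), n_converged = sum(rec$converged),
      convergence_rate = mean(rec$converged),
      bias = mean(th) - effect,
      mse = mean((th - effect)^2),
      coverage = cov,
      rejection_rate = rej,
      mean_icc = mean(rec$icc_hat[keep]),
      mc_se_rejection = mc_error(rej, nk),
      mc_se_coverage = mc_error(cov, nk),
      empty = FALSE
    )
  }
  out <- do.call(rbind, lapply(split(records, records$model), one))
  scen <- records[1L, c("n_clusters", "cluster_size", "effect", "icc",
                        "var_ratio")]
  rownames(out) <- NULL
  cbind(scen, out, row.names = NULL)
}

#' Define a scenario grid
#'
#' The Cartesian product of the supplied design values defines the scenario
#' set. The defaults reproduce the full factorial investigated in the
#' simulation study: 4 cluster numbers x 4 cluster sizes x 3 effects x
#' 6 ICCs x 5 variance ratios = 1440 scenarios.
#'
#' @param n_clusters,cluster_size,effect,icc,var_ratio Vectors of admissible
#'   design values (see [scenario_config()]).
#' @param n_reps Replicates per scenario.
#' @param seed Master seed; every scenario receives its own substream, so
#'   results do not depend on execution order.
#' @return An object of class `pnrct_grid` wrapping the scenario table.
#' @examples
#' nrow(scenario_grid()$scenarios)  # 1440
#' @export
scenario_grid <- function(n_clusters = c(3, 6, 12, 24),
                          cluster_size = c(5, 10, 20, 30),
                          effect = c(0, 0.2, 0.5),
                          icc = c(0, 0.01, 0.05, 0.1, 0.2, 0.3),
                          var_ratio = c(0.25, 0.5, 1, 2, 4),
                          n_reps = 1000L, seed = 1L) {
  scen <- expand.grid(
    n_clusters = n_clusters, cluster_size = cluster_size, effect = effect,
    icc = icc, var_ratio = var_ratio,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  structure(list(scenarios = scen, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "pnrct_grid")
}

#' @export
print.pnrct_grid <- function(x, ...) {
  cat("pnRCT scenario grid:", nrow(x$scenarios), "scenarios,",
      x$n_reps, "replicates each, seed", x$seed, "\n")
  invisible(x)
}

#' Run a scenario grid
#'
#' Runs every scenario of the grid for every model and returns one
#' performance-summary row per (scenario, model). Each scenario draws its
#' random substream from the grid seed and its own index, so the result is
#' deterministic and independent of execution order. When `out` is given,
#' rows are appended to a CSV file as each scenario completes, and
#' `resume = TRUE` skips scenarios already present in that file.
#'
#' @param grid A [scenario_grid()].
#' @param models A list of [model_spec()] objects (or model-name strings).
#' @param out Optional CSV path for incremental (resumable) output.
#' @param resume Resume from an existing `out` file.
#' @param verbose Print a progress line per scenario.
#' @return A `data.frame` of performance summaries.
#' @examples
#' g <- scenario_grid(n_clusters = 6, cluster_size = 5, effect = 0,
#'                    icc = 0.1, var_ratio = 1, n_reps = 10)
#' run_grid(g, list(model_spec("linear")))
#' @export
run_grid <- function(grid, models, out = NULL, resume = FALSE,
                     verbose = FALSE) {
  stopifnot(inherits(grid, "pnrct_grid"))
  models <- normalize_models(models)
  scen <- grid$scenarios
  scen_seeds <- substream_seeds(grid$seed, nrow(scen))
  done <- NULL
  if (resume && !is.null(out) && file.exists(out)) {
    done <- utils::read.csv(out)
  }
  keys <- c("n_clusters", "cluster_size", "effect", "icc", "var_ratio")
  res <- if (is.null(done)) list() else list(done)
  for (i in seq_len(nrow(scen))) {
    if (!is.null(done)) {
      hit <- rep.int(TRUE, nrow(done))
      for (k in keys) hit <- hit & done[[k]] == scen[[k]][i]
      if (any(hit)) next
    }
    cfg <- scenario_config(
      n_clusters = scen$n_clusters[i], cluster_size = scen$cluster_size[i],
      effect = scen$effect[i], icc = scen$icc[i],
      var_ratio = scen$var_ratio[i],
      n_reps = grid$n_reps, seed = scen_seeds[i]
    )
    summ <- summarize_scenario(run_scenario(cfg, models))
    res[[length(res) + 1L]] <- summ
    if (!is.null(out)) {
      utils::write.table(summ, out, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out), append = file.exists(out))
    }
    if (verbose) {
      cat(sprintf("[%d/%d] c=%d m=%d effect=%g icc=%g gamma=%g\n",
                  i, nrow(scen), cfg$n_clusters, cfg$cluster_size,
                  cfg$effect, cfg$icc, cfg$var_ratio))
    }
  }
  out_df <- do.call(rbind, res)
  rownames(out_df) <- NULL
  out_df
}

#' Aggregate a performance measure across scenarios
#'
#' Unweighted mean and standard deviation of a per-scenario measure over a
#' filtered set of scenarios, matching the "mean (SD)" convention used to
#' summarise grid results (the SD is across scenario means, not across
#' replicates).
#'
#' @param results A summary `data.frame` from [run_grid()].
#' @param measure Column name to aggregate (e.g. `"rejection_rate"`).
#' @param where Optional filter expression evaluated in `results`, e.g.
#'   `icc == 0.01 & model == "linear"`.
#' @return A list with `mean`, `sd` and `n_scenarios`.
#' @examples
#' g <- scenario_grid(n_clusters = c(3, 6), cluster_size = 5, effect = 0,
#'                    icc = 0.1, var_ratio = 1, n_reps = 10)
#' res <- run_grid(g, list(model_spec("linear")))
#' aggregate_measure(res, "rejection_rate")
#' @export
aggregate_measure <- function(results, measure, where = NULL) {
  stopifnot(measure %in% names(results))
  pred <- substitute(where)
  keep <- if (is.null(pred)) rep.int(TRUE, nrow(results)) else
    eval(pred, results, parent.frame())
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop("no scenarios match filter: ", deparse(pred), call. = FALSE)
  }
  x <- results[[measure]][keep]
  list(mean = mean(x, na.rm = TRUE),
       sd = stats::sd(x),
       n_scenarios = sum(keep))
}
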