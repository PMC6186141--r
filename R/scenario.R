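#' Define a simulation scenario for a partially nested trial
#'
#' A scenario fixes one design point of a two-arm partially nested randomised
#' controlled trial (pnRCT): a clustered intervention arm of `n_clusters`
#' clusters each of `cluster_size` participants, and a non-clustered control
#' arm of the same total size (1:1 randomisation).
#'
#' @param n_clusters Number of clusters in the intervention arm (c >= 1).
#' @param cluster_size Participants per intervention-arm cluster (m >= 1).
#' @param effect True intervention effect (outcome units); 0 gives data under
#'   the null hypothesis.
#' @param icc True intracluster correlation coefficient in the intervention
#'   arm, in `[0, 1)`. The intervention-arm marginal variance is fixed at 1,
#'   so `icc` is also the between-cluster variance.
#' @param var_ratio Ratio of individual-level (residual) variance in the
#'   control arm to that in the intervention arm (> 0); 1 means
#'   homoscedasticity across arms.
#' @param n_reps Number of Monte Carlo replicates when the scenario is run.
#' @param seed Master seed (non-negative integer) from which per-replicate
#'   random substreams are derived.
#'
#' @return An object of class `pnrct_scenario`: a list with elements
#'   `n_clusters`, `cluster_size`, `effect`, `icc`, `var_ratio`, `n_reps`,
#'   `seed`, and the implied arm sizes `n_intervention` and `n_control`.
#' @examples
#' scenario_config(n_clusters = 12, cluster_size = 10, icc = 0.1)
#' @export
scenario_config <- function(n_clusters, cluster_size, effect = 0,
                            icc = 0, var_ratio = 1,
                            n_reps = 1000L, seed = 1L) {
  stopifnot(
    is.numeric(n_clusters), length(n_clusters) == 1L,
    n_clusters >= 1, n_clusters == as.integer(n_clusters),
    is.numeric(cluster_size), length(cluster_size) == 1L,
    cluster_size >= 1, cluster_size == as.integer(cluster_size),
    is.numeric(effect), length(effect) == 1L, is.finite(effect),
    is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1,
    is.numeric(seed), length(seed) == 1L, seed >= 0
  )
  if (!is.numeric(icc) || length(icc) != 1L || icc < 0 || icc >= 1) {
    stop("`icc` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(var_ratio) || length(var_ratio) != 1L || var_ratio <= 0) {
    stop("`var_ratio` must be positive", call. = FALSE)
  }
  n1 <- as.integer(n_clusters) * as.integer(cluster_size)
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      cluster_size = as.integer(cluster_size),
      effect = as.numeric(effect),
      icc = as.numeric(icc),
      var_ratio = as.numeric(var_ratio),
      n_reps = as.integer(n_reps),
      seed = as.integer(seed),
      n_intervention = n1,
      n_control = n1
    ),
    class = "pnrct_scenario"
  )
}

#' @export
print.pnrct_scenario <- function(x, ...) {
  cat("pnRCT scenario: c =", x$n_clusters, "clusters of m =", x$cluster_size,
      "| effect =", x$effect, "| ICC =", x$icc,
      "| variance ratio =", x$var_ratio, "\n")
  cat("  arms: intervention n =", x$n_intervention,
      ", control n =", x$n_control,
      "| reps =", x$n_reps, "| seed =", x$seed, "\n")
  invisible(x)
}

# Distinct substream seeds derived from a master seed. Used so that each
# replicate (or each scenario of a grid) gets its own reproducible stream
# regardless of execution order. Restores the caller's RNG state.
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  sample.int(.Machine$integer.max, n, replace = FALSE)
}
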