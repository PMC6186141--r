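#' Generate one partially nested trial dataset
#'
#' Simulates a two-arm pnRCT with a clustered intervention arm and a
#' non-clustered control arm. With `u_j ~ N(0, 1)` cluster effects and
#' `z_ij ~ N(0, 1)` individual deviates, outcomes are
#' \deqn{y_{ij} = \theta + u_j \sqrt{\rho} + z_{ij} \sqrt{1 - \rho}}{
#'       y = theta + u * sqrt(icc) + z * sqrt(1 - icc)}
#' in the intervention arm and
#' \deqn{y_{ij} = z_{ij} \sqrt{\gamma (1 - \rho)}}{
#'       y = z * sqrt(var_ratio * (1 - icc))}
#' in the control arm, with the intercept fixed at zero. The intervention-arm
#' marginal variance is therefore 1, the within-cluster correlation is the
#' ICC, and the control-arm variance is `var_ratio * (1 - icc)`.
#'
#' Replicates are drawn from independent substreams derived from
#' `config$seed`, so the same `(seed, replicate)` pair always reproduces the
#' same dataset and different replicates are independent.
#'
#' @param config A [scenario_config()] object.
#' @param replicate Replicate index (>= 1) selecting the substream.
#'
#' @return A `data.frame` with one row per participant and columns
#'   `participant_id` (1..2cm; intervention rows first), `arm` (1 =
#'   intervention, 0 = control), `cluster` (integer 1..c for intervention
#'   rows, `NA` for control rows until a control coding is applied) and `y`.
#' @seealso [apply_control_coding()], [fit_pnrct()]
#' @examples
#' cfg <- scenario_config(n_clusters = 12, cluster_size = 10, icc = 0.1)
#' d <- generate_trial(cfg, replicate = 1)
#' table(d$arm)
#' @export
generate_trial <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "pnrct_scenario"),
            is.numeric(replicate), length(replicate) == 1L, replicate >= 1)
  replicate <- as.integer(replicate)
  rep_seed <- substream_seeds(config$seed, replicate)[replicate]
  generate_trial_seeded(config, rep_seed)
}

# Draw one dataset from an explicit substream seed (shared by
# generate_trial() and the study runner, which pre-computes the seeds).
generate_trial_seeded <- function(config, rep_seed) {
  c_ <- config$n_clusters
  m <- config$cluster_size
  n1 <- config$n_intervention
  n0 <- config$n_control
  rho <- config$icc
  gam <- config$var_ratio

  set.seed(rep_seed, kind = "Mersenne-Twister")
  u <- stats::rnorm(c_)
  z1 <- stats::rnorm(n1)
  z0 <- stats::rnorm(n0)

  cluster1 <- rep.int(seq_len(c_), rep.int(m, c_))
  y1 <- config$effect + u[cluster1] * sqrt(rho) + z1 * sqrt(1 - rho)
  y0 <- z0 * sqrt(gam * (1 - rho))

  data.frame(
    participant_id = seq_len(n1 + n0),
    arm = rep.int(c(1L, 0L), c(n1, n0)),
    cluster = c(cluster1, rep.int(NA_integer_, n0)),
    y = c(y1, y0)
  )
}

# Validate the participant-level layout shared by the fitting and coding
# functions; used on user-supplied as well as generated data.
check_trial <- function(trial) {
  required <- c("participant_id", "arm", "cluster", "y")
  missing <- setdiff(required, names(trial))
  if (length(missing)) {
    stop("trial dataset is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(trial$y)) {
    stop("column `y` must be numeric", call. = FALSE)
  }
  if (anyNA(trial$y)) {
    stop("column `y` contains missing values", call. = FALSE)
  }
  bad_arm <- !trial$arm %in% c(0L, 1L)
  if (any(bad_arm)) {
    stop("column `arm` must be 0 or 1; offending row(s): ",
         paste(utils::head(which(bad_arm), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(trial$participant_id)) {
    stop("column `participant_id` contains duplicate id(s): ",
         paste(utils::head(
           unique(trial$participant_id[duplicated(trial$participant_id)]), 5L),
           collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(trial$cluster[trial$arm == 1L])) {
    stop("intervention-arm rows must carry a cluster label", call. = FALSE)
  }
  invisible(trial)
}
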