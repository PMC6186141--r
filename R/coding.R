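#' Control-arm cluster codings
#'
#' Mixed-model software requires every row to carry a cluster label, so the
#' non-clustered control arm of a pnRCT must be given artificial labels
#' before a clustered model can be fitted. Three conventions are in use:
#'
#' * `"one-cluster"`: the whole control arm forms one large cluster;
#' * `"singleton"`: each control participant is their own cluster of size 1;
#' * `"pseudo"`: the control arm is split at random into `k` equally sized
#'   pseudo clusters (default `k` equal to the number of intervention-arm
#'   clusters, so cluster structure matches across arms).
#'
#' For the partially nested models the choice is immaterial beyond the
#' fourth decimal place of p-values, confidence limits and ICC estimates;
#' for the fully clustered model it changes the model being fitted.
#'
#' @param scheme One of `"one-cluster"`, `"singleton"`, `"pseudo"`.
#' @param k Number of pseudo clusters (`"pseudo"` only); defaults to the
#'   number of intervention-arm clusters at application time.
#' @param seed Seed for the random assignment of control participants to
#'   pseudo clusters (`"pseudo"` only). Control outcomes are exchangeable,
#'   so the assignment affects individual replicates but no distributional
#'   property.
#' @return An object of class `pnrct_coding`.
#' @examples
#' control_coding("pseudo", k = 12)
#' @export
control_coding <- function(scheme = c("one-cluster", "singleton", "pseudo"),
                           k = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is.null(k)) {
    stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == as.integer(k))
    k <- as.integer(k)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  structure(list(scheme = scheme, k = k, seed = as.integer(seed)),
            class = "pnrct_coding")
}

#' @export
print.pnrct_coding <- function(x, ...) {
  cat("control-arm coding:", x$scheme,
      if (x$scheme == "pseudo") {
        paste0("(k = ", if (is.null(x$k)) "c (matched)" else x$k,
               ", seed = ", x$seed, ")")
      } else "", "\n")
  invisible(x)
}

#' Apply a control-arm coding to a trial dataset
#'
#' Replaces the missing cluster labels of control-arm rows according to the
#' chosen scheme. Intervention-arm labels are untouched and the new control
#' labels are disjoint from them (numbered from `max(intervention) + 1`).
#'
#' @param trial A trial `data.frame` with unlabelled control rows.
#' @param coding A [control_coding()] object.
#' @return The trial `data.frame` with every row labelled.
#' @examples
#' d <- generate_trial(scenario_config(12, 10))
#' d2 <- apply_control_coding(d, control_coding("pseudo"))
#' table(d2$cluster[d2$arm == 0])
#' @export
apply_control_coding <- function(trial, coding) {
  check_trial(trial)
  stopifnot(inherits(coding, "pnrct_coding"))
  ctl <- which(trial$arm == 0L)
  l <- length(ctl)
  if (l == 0L) return(trial)
  base <- max(trial$cluster[trial$arm == 1L], 0L)
  labels <- switch(coding$scheme,
    "one-cluster" = rep.int(base + 1L, l),
    "singleton" = base + seq_len(l),
    "pseudo" = {
      k <- coding$k
      if (is.null(k)) k <- length(unique(trial$cluster[trial$arm == 1L]))
      if (l %% k != 0L) {
        stop("pseudo-cluster coding with k = ", k,
             " does not divide the control-arm size l = ", l, call. = FALSE)
      }
      set.seed(coding$seed, kind = "Mersenne-Twister")
      base + sample(rep.int(seq_len(k), rep.int(l %/% k, k)))
    })
  trial$cluster[ctl] <- as.integer(labels)
  trial
}
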