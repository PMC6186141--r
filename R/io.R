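#' Read and write trial datasets
#'
#' Trial datasets are stored as comma-separated text with header
#' `participant_id,arm,cluster,y`. The `cluster` field is empty for control
#' rows to which no control coding has been applied. Outcomes are written at
#' full double precision so that a write/read round trip is exact.
#'
#' @param trial A trial `data.frame` as returned by [generate_trial()].
#' @param path File path to write to or read from.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   the trial `data.frame`.
#' @examples
#' cfg <- scenario_config(3, 2)
#' f <- tempfile(fileext = ".csv")
#' write_trial(generate_trial(cfg), f)
#' head(read_trial(f))
#' @export
write_trial <- function(trial, path) {
  check_trial(trial)
  out <- trial[c("participant_id", "arm", "cluster", "y")]
  out$y <- sprintf("%.17g", out$y)
  utils::write.table(out, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  required <- c("participant_id", "arm", "cluster", "y")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- suppressWarnings(as.numeric(raw$y))
  if (anyNA(y)) {
    stop("non-numeric outcome `y` at row(s): ",
         paste(utils::head(which(is.na(y)), 5L), collapse = ", "),
         call. = FALSE)
  }
  cluster <- raw$cluster
  cluster[!nzchar(cluster)] <- NA_character_
  cluster_int <- suppressWarnings(as.integer(cluster))
  if (any(is.na(cluster_int) & !is.na(cluster))) {
    stop("non-integer cluster label at row(s): ",
         paste(utils::head(which(is.na(cluster_int) & !is.na(cluster)), 5L),
               collapse = ", "),
         call. = FALSE)
  }
  trial <- data.frame(
    participant_id = as.integer(raw$participant_id),
    arm = suppressWarnings(as.integer(raw$arm)),
    cluster = cluster_int,
    y = y
  )
  check_trial(trial)
  trial
}
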