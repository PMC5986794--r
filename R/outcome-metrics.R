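# Short-term performance metrics on trial logs: Manhattan path efficiency
# and normalized accuracy, split by on-/off-axis targets.

#' Optimal Manhattan path length to a target
#'
#' `|x| + |y|` of the target center from the trial start (the origin).
#'
#' @param target A [task_target()] (or length-2 center vector).
#' @return Distance in pixels.
#' @export
manhattan_optimal <- function(target) {
  center <- if (inherits(target, "task_target")) target$center else target
  stopifnot(length(center) == 2L, all(is.finite(center)))
  d <- sum(abs(center))
  if (d == 0) stop("zero-distance target has no optimal path", call. = FALSE)
  d
}

#' Manhattan path efficiency of a trial
#'
#' 100 times the ratio of the optimal Manhattan path to the cumulative
#' Manhattan (L1) length of the sampled trajectory, capped at 100. Under the
#' L1 length any monotone path (straight or L-shaped) scores exactly 100;
#' overshoots and off-axis wander lengthen the path and lower the score. The
#' cap is a numerical safeguard for trials acquired just inside the target
#' radius, where the traveled path can be marginally shorter than the
#' center-to-center optimum.
#'
#' @param log A `trial_log` with at least 2 samples.
#' @return Efficiency in percent. A trial that never moved returns 0 with
#'   attribute `flagged = TRUE`.
#' @export
path_efficiency <- function(log) {
  stopifnot(inherits(log, "trial_log"))
  s <- log$samples
  if (nrow(s) < 2L) {
    stop("need at least 2 samples to measure a path", call. = FALSE)
  }
  traveled <- sum(abs(diff(s$x))) + sum(abs(diff(s$y)))
  if (traveled == 0) {
    return(structure(0, flagged = TRUE, reason = "no movement"))
  }
  min(100, 100 * manhattan_optimal(log$target) / traveled)
}

#' Normalized target-acquisition accuracy of a trial
#'
#' 100 times one minus the ratio of the final Manhattan error (distance
#' between the target center and the last point reached) to the optimal
#' Manhattan path, floored at 0.
#'
#' @param log A `trial_log` with at least 1 sample.
#' @return Accuracy in percent.
#' @export
accuracy <- function(log) {
  stopifnot(inherits(log, "trial_log"))
  s <- log$samples
  final <- c(s$x[nrow(s)], s$y[nrow(s)])
  err <- sum(abs(log$target$center - final))
  max(0, 100 * (1 - err / manhattan_optimal(log$target)))
}

#' Per-trial performance metrics table
#'
#' @param logs List of `trial_log`s.
#' @param subject,strategy Optional labels attached to every row.
#' @return Data frame with one row per trial: `subject`, `strategy`,
#'   `axis_class`, `outcome`, `path_efficiency`, `accuracy`, `duration`.
#' @export
trial_metrics <- function(logs, subject = NA, strategy = NA) {
  rows <- lapply(logs, function(log) {
    data.frame(
      subject = subject,
      strategy = if (is.na(strategy)) log$strategy else strategy,
      axis_class = log$target$axis_class,
      outcome = log$outcome,
      path_efficiency = if (nrow(log$samples) >= 2) {
        as.numeric(path_efficiency(log))
      } else {
        NA_real_
      },
      accuracy = accuracy(log),
      duration = log$duration
    )
  })
  do.call(rbind, rows)
}

#' Summarize performance by subject, strategy and axis class
#'
#' Aggregates the per-trial metrics into means, SDs and SEMs, computed only
#' over trials with at least 2 samples. Groups with no usable trials are
#' omitted with a warning.
#'
#' @param metrics Data frame from [trial_metrics()] (possibly row-bound over
#'   subjects/strategies).
#' @return Tidy data frame: `subject`, `strategy`, `axis_class`, `metric`,
#'   `mean`, `sd`, `sem`, `n`.
#' @export
summarize_performance <- function(metrics) {
  metrics <- metrics[!is.na(metrics$path_efficiency), , drop = FALSE]
  if (nrow(metrics) == 0L) {
    warning("no usable trials to summarize")
    return(data.frame(subject = character(0), strategy = character(0),
                      axis_class = character(0), metric = character(0),
                      mean = numeric(0), sd = numeric(0), sem = numeric(0),
                      n = integer(0)))
  }
  long <- rbind(
    data.frame(metrics[c("subject", "strategy", "axis_class")],
               metric = "path_efficiency", value = metrics$path_efficiency),
    data.frame(metrics[c("subject", "strategy", "axis_class")],
               metric = "accuracy", value = metrics$accuracy)
  )
  agg <- stats::aggregate(value ~ subject + strategy + axis_class + metric,
                          data = long,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[c("subject", "strategy", "axis_class", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out$sem <- out$sd / sqrt(out$n)
  out[order(out$subject, out$strategy, out$axis_class, out$metric),
      c("subject", "strategy", "axis_class", "metric", "mean", "sd", "sem",
        "n")]
}
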