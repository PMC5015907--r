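#' Classify a target-acquisition attempt
#'
#' Scores one goal-reaching attempt from the trajectory of predicted DOF
#' activations. The controller is "on target" at a sample when *every* DOF's
#' prediction lies within `tolerance` of its commanded level, inactive DOFs
#' included -- the conjunction over DOFs is what makes the attempt a single
#' multi-dimensional reaching task. In-target status is held between two
#' consecutive samples when both endpoints are in target, so a dwell is the
#' time spanned by a contiguous in-target run (a single isolated in-target
#' sample has dwell 0).
#'
#' The attempt is a **success** when some dwell reaches the success time
#' `t_s`; an **overshoot** when the target was touched but never held long
#' enough (longest dwell strictly between 0 and `t_s`); **unreachable** when
#' the longest dwell is 0. The task completion time (TCT) of a success runs
#' from the start of the attempt to the moment the first qualifying dwell
#' reaches `t_s`; the longest stable time (LST) is the longest dwell, capped
#' at `t_s`.
#'
#' @param times numeric vector of strictly increasing timestamps in seconds,
#'   starting at the appearance of the stimulus.
#' @param predictions numeric matrix (samples x K) of predicted activations.
#' @param target numeric K-vector of commanded activation levels.
#' @param tolerance half-width of the target box per DOF (default 0.25).
#' @param t_s success (dwell) time in seconds (default 1.5).
#' @param t_d attempt duration limit in seconds (default 30).
#' @return An object of class `attempt_outcome`: `status` (`"success"`,
#'   `"overshoot"` or `"unreachable"`), `tct` (seconds, `NA` unless success),
#'   `lst` (seconds in `[0, t_s]`) and `dwells` (data.frame of in-target
#'   intervals).
#' @export
classify_attempt <- function(times, predictions, target, tolerance = 0.25,
                             t_s = 1.5, t_d = 30) {
  if (is.null(dim(predictions))) predictions <- matrix(predictions, ncol = 1)
  predictions <- as.matrix(predictions)
  if (length(times) != nrow(predictions))
    stop("one timestamp per prediction row required", call. = FALSE)
  if (length(times) == 0) stop("empty trajectory", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (ncol(predictions) != length(target))
    stop("prediction dimensionality does not match the target", call. = FALSE)
  if (times[length(times)] - times[1] > t_d + 1e-9)
    stop("trajectory exceeds the attempt duration limit t_d", call. = FALSE)
  dev <- abs(sweep(predictions, 2, target))
  in_tgt <- apply(dev <= tolerance + 1e-12, 1, all)
  runs <- rle(in_tgt)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  dwells <- data.frame(start = times[starts[keep]], end = times[ends[keep]])
  dwells$duration <- dwells$end - dwells$start
  longest <- if (nrow(dwells)) max(dwells$duration) else 0
  qual <- which(dwells$duration >= t_s)
  if (length(qual)) {
    status <- "success"
    tct <- (dwells$start[qual[1]] - times[1]) + t_s
  } else {
    status <- if (longest > 0) "overshoot" else "unreachable"
    tct <- NA_real_
  }
  structure(list(status = status, tct = tct, lst = min(longest, t_s),
                 dwells = dwells, t_s = t_s, tolerance = tolerance),
            class = "attempt_outcome")
}

#' @export
print.attempt_outcome <- function(x, ...) {
  cat(sprintf("<attempt_outcome> %s: TCT %s, LST %.2f s\n", x$status,
              if (is.na(x$tct)) "-" else sprintf("%.2f s", x$tct), x$lst))
  invisible(x)
}

#' Summarise attempt outcomes into session rates
#'
#' Success rate `SR = n_s / n_total * 100%` and unreachable rate
#' `UA = n_u / n_total * 100%`; the overshoot percentage completes the total
#' to 100. Task completion time is averaged over successes only (it is
#' undefined otherwise); the longest stable time is averaged over overshoots
#' (`mean_lst`), and over all attempts with the success cap applied
#' (`mean_lst_all`) for completeness.
#'
#' @param outcomes list of [classify_attempt()] results.
#' @param group optional vector (same length) of grouping keys, e.g.
#'   activation cardinality or repetition; when given, one summary row per
#'   group is returned in addition to the overall row.
#' @return A data.frame with columns `group`, `n`, `sr`, `ua`,
#'   `overshoot_rate`, `mean_tct`, `mean_lst`, `mean_lst_all`.
#' @export
summarize_attempts <- function(outcomes, group = NULL) {
  if (length(outcomes) == 0) stop("no outcomes to summarise", call. = FALSE)
  status <- vapply(outcomes, `[[`, "", "status")
  tct <- vapply(outcomes, `[[`, numeric(1), "tct")
  lst <- vapply(outcomes, `[[`, numeric(1), "lst")
  one <- function(idx, label) {
    s <- status[idx]
    data.frame(group = label, n = length(idx),
               sr = 100 * mean(s == "success"),
               ua = 100 * mean(s == "unreachable"),
               overshoot_rate = 100 * mean(s == "overshoot"),
               mean_tct = if (any(s == "success"))
                 mean(tct[idx][s == "success"]) else NA_real_,
               mean_lst = if (any(s == "overshoot"))
                 mean(lst[idx][s == "overshoot"]) else NA_real_,
               mean_lst_all = mean(lst[idx]))
  }
  res <- one(seq_along(outcomes), "all")
  if (!is.null(group)) {
    stopifnot(length(group) == length(outcomes))
    for (g in unique(group))
      res <- rbind(res, one(which(group == g), as.character(g)))
  }
  rownames(res) <- NULL
  res
}

#' Write a trajectory log to CSV
#'
#' Dialect: `time,pred_<dof1>..,target_<dof1>..,attempt_id`.
#'
#' @param log data.frame in that layout (as produced by the online layer).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Read and classify a trajectory log
#'
#' Reads a CSV written in the [write_trajectory_csv()] dialect and classifies
#' every attempt it contains.
#'
#' @param path CSV path.
#' @param tolerance,t_s,t_d see [classify_attempt()].
#' @return List with `outcomes` (list of `attempt_outcome`, named by attempt
#'   id) and `targets` (matrix of per-attempt targets).
#' @export
classify_trajectory_log <- function(path, tolerance = 0.25, t_s = 1.5,
                                    t_d = 30) {
  if (!file.exists(path)) stop("trajectory log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  pred_cols <- grep("^pred_", names(df), value = TRUE)
  tgt_cols <- grep("^target_", names(df), value = TRUE)
  if (length(pred_cols) == 0 || nrow(df) == 0)
    stop("empty or malformed trajectory log", call. = FALSE)
  ids <- unique(df$attempt_id)
  outcomes <- stats::setNames(vector("list", length(ids)), as.character(ids))
  targets <- matrix(NA_real_, length(ids), length(tgt_cols),
                    dimnames = list(as.character(ids), sub("^target_", "", tgt_cols)))
  for (i in seq_along(ids)) {
    a <- df[df$attempt_id == ids[i], ]
    target <- as.numeric(a[1, tgt_cols])
    outcomes[[i]] <- classify_attempt(a$time, as.matrix(a[pred_cols]), target,
                                      tolerance = tolerance, t_s = t_s, t_d = t_d)
    targets[i, ] <- target
  }
  list(outcomes = outcomes, targets = targets)
}
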