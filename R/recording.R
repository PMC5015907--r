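#' Construct an sEMG envelope recording
#'
#' A recording holds a multi-channel rectified/low-pass-filtered sEMG envelope
#' together with the stimulus track that was presented to the subject: the
#' commanded activation level of every degree of freedom (DOF) at every sample.
#' The stimulus track is what turns a raw recording into labelled activation
#' clusters, see [segment_clusters()].
#'
#' @param signals numeric matrix, one row per sample and one column per
#'   electrode channel. Values are nonnegative arbitrary units (an envelope).
#' @param stimulus numeric matrix with the same number of rows as `signals`
#'   and one column per DOF; entries are commanded activation levels in
#'   `[0, 1]` (0 = rest, 1 = full activation).
#' @param sample_rate sampling rate in Hz (default 62).
#' @param dof_order character vector naming the DOFs; defaults to the column
#'   names of `stimulus`.
#' @param repetition integer repetition identifier.
#' @param subject subject identifier string.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, stimulus, sample_rate = 62,
                          dof_order = colnames(stimulus),
                          repetition = 1L, subject = "S01") {
  signals <- as.matrix(signals)
  stimulus <- as.matrix(stimulus)
  if (!is.numeric(signals) || !is.numeric(stimulus))
    stop("signals and stimulus must be numeric", call. = FALSE)
  if (nrow(signals) != nrow(stimulus))
    stop("stimulus must have one row per sample", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  if (is.null(dof_order))
    dof_order <- paste0("dof", seq_len(ncol(stimulus)))
  if (length(dof_order) != ncol(stimulus))
    stop("dof_order must name every stimulus column", call. = FALSE)
  if (!all(is.finite(signals)))
    stop("signals must be finite", call. = FALSE)
  colnames(stimulus) <- dof_order
  structure(list(signals = signals, stimulus = stimulus,
                 sample_rate = sample_rate, dof_order = dof_order,
                 repetition = as.integer(repetition), subject = subject),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, repetition %d\n", x$subject, x$repetition))
  cat(sprintf("  %d samples x %d channels at %.4g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate,
              nrow(x$signals) / x$sample_rate))
  cat(sprintf("  DOFs: %s\n", paste(x$dof_order, collapse = ", ")))
  invisible(x)
}

#' Causal low-pass envelope filter
#'
#' Applies a causal Butterworth low-pass filter channel by channel, the
#' standard smoothing step that turns rectified sEMG into a slowly varying
#' envelope usable as a regression input. The filter state is initialised at
#' steady state for the first sample, so short recordings carry no startup
#' transient: for a unity-DC-gain filter this is achieved exactly by filtering
#' the deviation from the first sample from rest and adding it back.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param sample_rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 1.5).
#' @param order filter order (default 1).
#' @param rectify if `TRUE`, take `abs(x)` first, so raw signed signals can be
#'   fed through the same code path as pre-rectified envelopes.
#' @return Filtered object of the same shape as `x`.
#' @export
lowpass_envelope <- function(x, sample_rate, cutoff = 1.5, order = 1,
                             rectify = FALSE) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (cutoff >= sample_rate / 2)
    stop("cutoff must lie below the Nyquist frequency sample_rate/2",
         call. = FALSE)
  if (cutoff <= 0 || order < 1)
    stop("cutoff must be positive and order >= 1", call. = FALSE)
  if (rectify) x <- abs(x)
  bf <- signal::butter(order, W = cutoff / (sample_rate / 2), type = "low")
  out <- x
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    out[, j] <- as.numeric(signal::filter(bf, xj - xj[1])) + xj[1]
  }
  if (vec) out <- drop(out)
  out
}

#' Construct an activation cluster
#'
#' An activation cluster is the block of envelope samples gathered while one
#' labelled activation was held: `data` is an n x d matrix whose rows are
#' points in the d-dimensional sEMG space. An empty `dofs` set denotes rest.
#'
#' @param data numeric n x d matrix of envelope samples.
#' @param dofs character vector of active DOFs (empty for rest).
#' @param levels named numeric vector of commanded levels per active DOF;
#'   defaults to 1 for every member of `dofs`.
#' @param repetition integer repetition id the samples came from.
#' @param subject subject identifier.
#' @return An object of class `activation_cluster`.
#' @export
activation_cluster <- function(data, dofs = character(), levels = NULL,
                               repetition = 1L, subject = "S01") {
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("cluster must contain at least one sample", call. = FALSE)
  if (!all(is.finite(data))) stop("cluster samples must be finite", call. = FALSE)
  dofs <- as.character(dofs)
  if (is.null(levels)) levels <- stats::setNames(rep(1, length(dofs)), dofs)
  structure(list(data = data, dofs = dofs, levels = levels,
                 repetition = as.integer(repetition), subject = subject),
            class = "activation_cluster")
}

#' @export
print.activation_cluster <- function(x, ...) {
  cat(sprintf("<activation_cluster> %s: %d x %d (rep %d, %s)\n",
              if (length(x$dofs)) cluster_key(x) else "rest",
              nrow(x$data), ncol(x$data), x$repetition, x$subject))
  invisible(x)
}

#' Canonical label key of a cluster
#'
#' DOF names joined with `+` in the order given by `dof_order` (or the
#' cluster's own order when `dof_order` is `NULL`); `"rest"` for the empty set.
#'
#' @param cluster an `activation_cluster` or character vector of DOFs.
#' @param dof_order optional reference ordering of DOF names.
#' @return A single string.
#' @export
cluster_key <- function(cluster, dof_order = NULL) {
  dofs <- if (inherits(cluster, "activation_cluster")) cluster$dofs else as.character(cluster)
  if (length(dofs) == 0) return("rest")
  if (!is.null(dof_order)) dofs <- dof_order[dof_order %in% dofs]
  paste(dofs, collapse = "+")
}

#' Centroid of an activation cluster
#'
#' The centre point of the cluster: the arithmetic mean of its samples,
#' one value per channel. Centroids are the sufficient statistic used by the
#' closed-form combination-weight estimators [fit_alpha_single()] and
#' [fit_alpha_multi()].
#'
#' @param cluster an `activation_cluster` or a bare numeric matrix.
#' @return Numeric vector of length d.
#' @export
cluster_centroid <- function(cluster) {
  data <- if (inherits(cluster, "activation_cluster")) cluster$data else as.matrix(cluster)
  if (nrow(data) < 1) stop("cannot take the centroid of an empty cluster", call. = FALSE)
  colMeans(data)
}

#' Segment a recording into activation clusters along the stimulus track
#'
#' Finds contiguous plateaus of the stimulus track (runs of identical
#' commanded-level rows) and cuts the corresponding envelope samples into one
#' cluster each. Samples within `guard` seconds of an active plateau's edges
#' are discarded to exclude ramp transients; resting phases, which have no
#' fixed duration, are kept in full.
#'
#' @param recording an [emg_recording()].
#' @param guard guard margin in seconds trimmed from each edge of active
#'   plateaus (default 0.5).
#' @return A list of [activation_cluster()] objects in temporal order. A
#'   recording whose stimulus never moves yields a single rest cluster.
#' @export
segment_clusters <- function(recording, guard = 0.5) {
  stopifnot(inherits(recording, "emg_recording"))
  stim <- recording$stimulus
  if (nrow(stim) != nrow(recording$signals))
    stop("stimulus and samples have different lengths", call. = FALSE)
  key <- apply(stim, 1, paste, collapse = "\r")
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  g <- round(guard * recording$sample_rate)
  out <- list()
  for (k in seq_along(starts)) {
    row <- stim[starts[k], ]
    active <- which(row > 0)
    i0 <- starts[k]; i1 <- ends[k]
    if (length(active) > 0) {        # active plateau: trim guard margin
      i0 <- i0 + g; i1 <- i1 - g
      if (i0 > i1) next
    }
    out[[length(out) + 1L]] <- activation_cluster(
      recording$signals[i0:i1, , drop = FALSE],
      dofs = recording$dof_order[active],
      levels = stats::setNames(row[active], recording$dof_order[active]),
      repetition = recording$repetition, subject = recording$subject)
  }
  out
}

#' Write a recording to CSV
#'
#' Plain-text dialect with header
#' `time,ch01..chNN,stim_<dof1>..stim_<dofK>,repetition,subject`, one row per
#' sample, time in seconds.
#'
#' @param recording an [emg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- nrow(recording$signals)
  d <- ncol(recording$signals)
  df <- data.frame(time = (seq_len(n) - 1) / recording$sample_rate)
  sig <- as.data.frame(recording$signals)
  names(sig) <- sprintf("ch%02d", seq_len(d))
  stim <- as.data.frame(recording$stimulus)
  names(stim) <- paste0("stim_", recording$dof_order)
  df <- cbind(df, sig, stim,
              repetition = recording$repetition, subject = recording$subject)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording_csv()]. The sample rate is recovered from the
#' median time step.
#'
#' @param path CSV file path.
#' @return An [emg_recording()].
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  stim_cols <- grep("^stim_", names(df), value = TRUE)
  if (length(ch_cols) == 0 || length(stim_cols) == 0)
    stop("not a recording CSV: expected ch* and stim_* columns", call. = FALSE)
  dt <- stats::median(diff(df$time))
  emg_recording(as.matrix(df[ch_cols]), as.matrix(df[stim_cols]),
                sample_rate = 1 / dt,
                dof_order = sub("^stim_", "", stim_cols),
                repetition = df$repetition[1], subject = as.character(df$subject[1]))
}
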