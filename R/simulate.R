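#' Describe one commanded activation
#'
#' @param dofs character vector of active DOFs (empty = rest).
#' @param level commanded activation level in `[0, 1]` shared by all active
#'   DOFs (1 = full activation).
#' @return An object of class `activation_label`.
#' @export
activation_label <- function(dofs = character(), level = 1) {
  if (level < 0 || level > 1) stop("level must lie in [0, 1]", call. = FALSE)
  structure(list(dofs = as.character(dofs), level = level),
            class = "activation_label")
}

#' Describe an acquisition routine
#'
#' An ordered sequence of commanded activations, each held as a plateau of
#' fixed duration and separated by rest gaps, repeated a number of times.
#'
#' @param labels list of [activation_label()]s in chronological order.
#' @param plateau plateau duration in seconds (default 4).
#' @param rest_gap rest duration between plateaus in seconds (default 2).
#' @param repetitions number of repetitions of the whole sequence (default 4).
#' @return An object of class `routine_spec`.
#' @export
routine_spec <- function(labels, plateau = 4, rest_gap = 2, repetitions = 4) {
  if (plateau <= 0 || rest_gap <= 0 || repetitions < 1)
    stop("durations must be positive and repetitions >= 1", call. = FALSE)
  structure(list(labels = labels, plateau = plateau, rest_gap = rest_gap,
                 repetitions = as.integer(repetitions)),
            class = "routine_spec")
}

#' The 13-activation calibration routine
#'
#' Four single-finger activations (thumb opposition, thumb flexion, index
#' flexion, little-finger flexion), the six pairs, two triples
#' (ThOp+ThFl+InFl and ThFl+InFl+LiFl) and the quadruple, in increasing
#' complexity, all at full activation.
#'
#' @param repetitions repetitions of the sequence (default 4).
#' @return A [routine_spec()].
#' @export
routine_calibration <- function(repetitions = 4) {
  d <- c("ThOp", "ThFl", "InFl", "LiFl")
  acts <- list(d[1], d[2], d[3], d[4],
               d[c(1, 2)], d[c(1, 3)], d[c(1, 4)],
               d[c(2, 3)], d[c(2, 4)], d[c(3, 4)],
               d[c(1, 2, 3)], d[c(2, 3, 4)],
               d)
  routine_spec(lapply(acts, activation_label), repetitions = repetitions)
}

#' The single-finger training routine of the online protocol
#'
#' Full activations of thumb, index and little-finger flexion only -- the
#' material LET needs to synthesize the pairwise combinations.
#'
#' @param repetitions repetitions of the sequence (default 3).
#' @return A [routine_spec()].
#' @export
routine_online_training <- function(repetitions = 3) {
  d <- c("ThFl", "InFl", "LiFl")
  routine_spec(lapply(d, activation_label), repetitions = repetitions)
}

#' Target set of the online goal-reaching task
#'
#' All 18 single- and double-finger targets over thumb, index and
#' little-finger flexion at the two intensity levels 0.5 and 1.0.
#'
#' @return A data.frame with columns `ThFl`, `InFl`, `LiFl`.
#' @export
online_targets <- function() {
  lv <- c(0.5, 1.0)
  rows <- list()
  for (j in 1:3) for (l in lv) {
    r <- c(0, 0, 0); r[j] <- l
    rows[[length(rows) + 1L]] <- r
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    for (l1 in lv) for (l2 in lv) {
      r <- c(0, 0, 0); r[pair[1]] <- l1; r[pair[2]] <- l2
      rows[[length(rows) + 1L]] <- r
    }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("ThFl", "InFl", "LiFl")
  out
}

all_combos <- function(dofs, max_card = 4) {
  out <- list()
  for (k in 2:min(length(dofs), max_card))
    out <- c(out, utils::combn(dofs, k, simplify = FALSE))
  out
}

#' Build a synthetic subject model
#'
#' A subject is a rest centroid, one nonnegative direction in d-dimensional
#' signal space per DOF, and ground-truth combination weights. The model
#' encodes the central structural assumption under test: a multi-DOF
#' activation lies near a sub-unit-weight linear combination of the single-DOF
#' ones, with the weight shrinking as more DOFs join (the force-deficit
#' effect). Per-combination true weights are drawn around the per-cardinality
#' means with a between-subject spread, so population ("general") weights are
#' a genuine approximation for any individual subject.
#'
#' @param seed integer seed; the whole subject is reproducible from it.
#' @param d number of channels (default 10).
#' @param dofs DOF names (default the four calibration DOFs).
#' @param true_alpha named per-cardinality mean combination weights
#'   (defaults 0.53, 0.37, 0.29 for pairs/triples/quadruples).
#' @param alpha_spread sd of the per-subject, per-cardinality deviation from
#'   the population means (default 0.04); all combinations of one cardinality
#'   share their subject's weight, mirroring the across-subject uniformity of
#'   the weights that makes a population model usable at all.
#' @param noise_sd per-channel envelope noise scale (default 0.1, i.e. 10% of
#'   the unit direction magnitude).
#' @param crosstalk mixing factor in `[0, 1)` pulling DOF directions towards
#'   their common mean, emulating electrode crosstalk (default 0.1).
#' @param rep_variability sd of the multiplicative per-repetition gain jitter
#'   (default 0.05).
#' @param rest_level magnitude scale of the rest centroid (default 0.1).
#' @param orthogonal use one coordinate axis per DOF instead of random
#'   rectified directions (useful for exactness tests).
#' @param max_condition upper bound enforced on the condition number of the
#'   stacked direction matrix.
#' @return An object of class `subject_model`.
#' @export
make_subject <- function(seed, d = 10, dofs = c("ThOp", "ThFl", "InFl", "LiFl"),
                         true_alpha = c("2" = 0.53, "3" = 0.37, "4" = 0.29),
                         alpha_spread = 0.04, noise_sd = 0.1, crosstalk = 0.1,
                         rep_variability = 0.05, rest_level = 0.1,
                         orthogonal = FALSE, max_condition = 50) {
  K <- length(dofs)
  if (d < K) stop("need at least as many channels as DOFs", call. = FALSE)
  if (crosstalk < 0 || crosstalk >= 1) stop("crosstalk must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0 || alpha_spread < 0 || rep_variability < 0)
    stop("noise_sd, alpha_spread and rep_variability must be nonnegative", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rest <- stats::runif(d, 0.5, 1.5) * rest_level
  if (orthogonal) {
    dirs <- diag(1, K, d)
  } else {
    dirs <- abs(matrix(stats::rnorm(K * d), K, d))
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  if (crosstalk > 0) {
    common <- colMeans(dirs)
    dirs <- (1 - crosstalk) * dirs +
      crosstalk * matrix(common, K, d, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  rownames(dirs) <- dofs
  if (kappa(dirs, exact = TRUE) > max_condition)
    stop("DOF directions too collinear (condition number bound exceeded)",
         call. = FALSE)
  combos <- all_combos(dofs)
  keys <- vapply(combos, paste, "", collapse = "+")
  cards <- as.character(sort(unique(lengths(combos))))
  subject_alpha <- stats::setNames(vapply(cards, function(k) {
    min(max(true_alpha[[k]] + stats::rnorm(1, 0, alpha_spread), 0.05), 1)
  }, numeric(1)), cards)
  combo_alpha <- stats::setNames(
    subject_alpha[as.character(lengths(combos))], keys)
  structure(list(seed = seed, d = d, dofs = dofs, rest_centroid = rest,
                 dof_directions = dirs, true_alpha = true_alpha,
                 subject_alpha = subject_alpha,
                 combo_alpha = combo_alpha, alpha_spread = alpha_spread,
                 noise_sd = noise_sd, crosstalk = crosstalk,
                 rep_variability = rep_variability),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model> seed %d: %d channels, DOFs %s\n",
              x$seed, x$d, paste(x$dofs, collapse = ", ")))
  cat(sprintf("  noise_sd %.3g, crosstalk %.3g, rep_variability %.3g\n",
              x$noise_sd, x$crosstalk, x$rep_variability))
  invisible(x)
}

#' Simulate one repetition of a routine for a subject
#'
#' Emits the envelope recording of the routine: for every plateau the
#' noiseless signal is `rest + scale * sum(level * gain_dof * direction_dof)`,
#' where `scale` is the subject's true combination weight for multi-DOF
#' plateaus and 1 for single-DOF ones, and `gain_dof` is the repetition's
#' multiplicative jitter. Channel noise is generated white, smoothed with the
#' same 1.5 Hz first-order envelope filter used for real signals (so the
#' synthetic data carry the temporal correlation that motivates
#' repetition-wise cross-validation), rescaled to `noise_sd` per channel,
#' added, and clipped at zero to keep the envelope nonnegative. The stimulus
#' track records the commanded levels; the attached sidecar records the exact
#' segment boundaries and the ground-truth weights.
#'
#' @param subject a [make_subject()] model.
#' @param routine a [routine_spec()].
#' @param repetition repetition id (drives the jitter and noise seed).
#' @param sample_rate sampling rate in Hz (default 62).
#' @return An [emg_recording()] with a `sidecar` attribute: a list with
#'   `segments` (data.frame of start/end sample, label key, level,
#'   cardinality), `true_alpha` and `seed`.
#' @export
simulate_recording <- function(subject, routine, repetition = 1,
                               sample_rate = 62) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((subject$seed + 1009L * as.integer(repetition)) %% 2147483647L)
  K <- length(subject$dofs)
  d <- subject$d
  gains <- 1 + stats::rnorm(K, 0, subject$rep_variability)
  names(gains) <- subject$dofs
  n_p <- as.integer(round(routine$plateau * sample_rate))
  n_r <- as.integer(round(routine$rest_gap * sample_rate))
  blocks <- list(list(label = activation_label(), n = n_r))   # lead-in rest
  for (lab in routine$labels) {
    blocks[[length(blocks) + 1L]] <- list(label = lab, n = n_p)
    blocks[[length(blocks) + 1L]] <- list(label = activation_label(), n = n_r)
  }
  n_total <- sum(vapply(blocks, `[[`, integer(1), "n"))
  signals <- matrix(0, n_total, d)
  stimulus <- matrix(0, n_total, K)
  colnames(stimulus) <- subject$dofs
  seg <- list()
  at <- 1L
  for (b in blocks) {
    idx <- at:(at + b$n - 1L)
    base <- subject$rest_centroid
    card <- length(b$label$dofs)
    if (card > 0) {
      contrib <- colSums(subject$dof_directions[b$label$dofs, , drop = FALSE] *
                           (b$label$level * gains[b$label$dofs]))
      scale <- if (card >= 2)
        subject$combo_alpha[[paste(b$label$dofs, collapse = "+")]] else 1
      base <- base + scale * contrib
      stimulus[idx, b$label$dofs] <- b$label$level
    }
    signals[idx, ] <- matrix(base, b$n, d, byrow = TRUE)
    seg[[length(seg) + 1L]] <- data.frame(
      start = at, end = at + b$n - 1L,
      label = cluster_key(b$label$dofs), level = b$label$level,
      cardinality = card)
    at <- at + b$n
  }
  if (subject$noise_sd > 0) {
    noise <- matrix(stats::rnorm(n_total * d), n_total, d)
    noise <- lowpass_envelope(noise, sample_rate)
    sds <- apply(noise, 2, stats::sd)
    noise <- sweep(noise, 2, subject$noise_sd / pmax(sds, 1e-12), `*`)
    signals <- pmax(signals + noise, 0)
  }
  rec <- emg_recording(signals, stimulus, sample_rate = sample_rate,
                       dof_order = subject$dofs,
                       repetition = repetition,
                       subject = subject$label %||% sprintf("seed%d", subject$seed))
  attr(rec, "sidecar") <- list(segments = do.call(rbind, seg),
                               true_alpha = as.list(subject$combo_alpha),
                               grouped_true_alpha = as.list(subject$true_alpha),
                               seed = subject$seed, repetition = repetition)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording's ground-truth sidecar to JSON
#'
#' @param recording a recording produced by [simulate_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sidecar_json <- function(recording, path) {
  sc <- attr(recording, "sidecar")
  if (is.null(sc)) stop("recording carries no sidecar", call. = FALSE)
  jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a multi-subject cohort
#'
#' Generates `n_subjects` independent synthetic subjects and all repetitions
#' of the given routine for each. Per-subject seeds are derived
#' deterministically from the master seed, so each subject's data is
#' unaffected by how many other subjects exist or in which order they are
#' generated.
#'
#' @param n_subjects number of subjects (default 10).
#' @param seed master integer seed.
#' @param routine a [routine_spec()] (default [routine_calibration()]).
#' @param sample_rate sampling rate in Hz (default 62).
#' @param ... further arguments passed to [make_subject()].
#' @return A named list (`S01`, `S02`, ...) of lists with elements `model`
#'   (the [make_subject()] result) and `recordings` (one
#'   [simulate_recording()] per repetition).
#' @export
make_cohort <- function(n_subjects = 10, seed = 1,
                        routine = routine_calibration(),
                        sample_rate = 62, ...) {
  if (n_subjects < 1) stop("n_subjects must be at least 1", call. = FALSE)
  out <- stats::setNames(vector("list", n_subjects),
                         sprintf("S%02d", seq_len(n_subjects)))
  for (i in seq_len(n_subjects)) {
    sseed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    model <- make_subject(sseed, ...)
    model$label <- names(out)[i]
    recs <- lapply(seq_len(routine$repetitions), function(r)
      simulate_recording(model, routine, repetition = r,
                         sample_rate = sample_rate))
    out[[i]] <- list(model = model, recordings = recs)
  }
  out
}

#' Segment every recording of a cohort into clusters
#'
#' @param cohort result of [make_cohort()].
#' @param guard guard margin in seconds (default 0: the generator emits ideal
#'   step plateaus with no ramp transients).
#' @return Named list: per subject, a flat list of [activation_cluster()]s
#'   across all repetitions.
#' @export
cohort_clusters <- function(cohort, guard = 0) {
  lapply(cohort, function(s) {
    unlist(lapply(s$recordings, segment_clusters, guard = guard),
           recursive = FALSE)
  })
}
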