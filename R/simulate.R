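#' Per-beat recording of heart and torso potentials
#'
#' Container for one heartbeat: heart-surface potentials `x` (nodes x time,
#' mV), torso-surface potentials `y` (electrodes x time, mV), sampling rate,
#' the QRS window (sample indices used for fitting), and — for synthetic data
#' — the true generating pose.
#'
#' @param x heart potentials, nodes x time.
#' @param y torso potentials, electrodes x time.
#' @param fs sampling rate in Hz.
#' @param qrs_window integer pair `(start, end)` of sample indices.
#' @param beat_id beat index.
#' @param rep noise-realization index (synthetic data).
#' @param true_pose generating [pose_params], or `NULL` for real data.
#' @return object of class `beat_recording`.
#' @export
beat_recording <- function(x, y, fs, qrs_window = c(1L, ncol(x)), beat_id = 1L,
                           rep = 1L, true_pose = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("x and y must have the same number of samples")
  if (fs <= 0) stop("sampling rate must be positive")
  qrs_window <- as.integer(qrs_window)
  if (length(qrs_window) != 2 || qrs_window[1] < 1 ||
      qrs_window[2] > ncol(x) || qrs_window[1] > qrs_window[2])
    stop("qrs_window outside the signal")
  structure(list(x = x, y = y, fs = fs, qrs_window = qrs_window,
                 beat_id = as.integer(beat_id), rep = as.integer(rep),
                 true_pose = if (!is.null(true_pose)) as_pose(true_pose)),
            class = "beat_recording")
}

#' @export
print.beat_recording <- function(x, ...) {
  cat(sprintf("beat %d (rep %d): %d heart nodes, %d electrodes, %d samples @ %g Hz, QRS [%d, %d]\n",
              x$beat_id, x$rep, nrow(x$x), nrow(x$y), ncol(x$x), x$fs,
              x$qrs_window[1], x$qrs_window[2]))
  if (!is.null(x$true_pose)) cat("  true ", format_pose(x$true_pose), "\n", sep = "")
  invisible(x)
}

format_pose <- function(p) {
  sprintf("pose: t = (%.2f, %.2f, %.2f) mm, angles (%.3f, %.3f, %.3f) rad",
          p[1], p[2], p[3], p[4], p[5], p[6])
}

#' Respiratory-like pose trajectory
#'
#' Poses along a breathing cycle parameterized by normalized respiratory
#' phase on [-1, 1]: the heart translates vertically and pitches about the
#' atrial anchor, both scaling as a half-cosine of the phase — zero (nominal
#' pose) at phase 0 and maximal displacement at phase +/- 1, so displacement
#' magnitude is even in phase and nondecreasing in |phase|.
#'
#' @param n_beats number of beats (poses); ignored if `phases` is given.
#' @param z_amplitude vertical translation at maximal phase, mm.
#' @param pitch_amplitude pitch at maximal phase, rad.
#' @param phases respiratory phases in [-1, 1] (default: `n_beats` values
#'   equally spaced over [-1, 1]).
#' @param bounds optional `pose_bounds`; an out-of-bounds pose is an error.
#' @return list of [pose_params], one per beat, with attribute `"phases"`.
#' @export
respiratory_trajectory <- function(n_beats = 10, z_amplitude = 20,
                                   pitch_amplitude = 10 * pi / 180,
                                   phases = seq(-1, 1, length.out = n_beats),
                                   bounds = NULL) {
  if (any(abs(phases) > 1)) stop("phases must lie in [-1, 1]")
  scale <- (1 - cos(pi * phases)) / 2
  poses <- lapply(scale, function(s)
    pose_params(tz = z_amplitude * s, theta = pitch_amplitude * s))
  if (!is.null(bounds)) {
    ok <- vapply(poses, in_bounds, logical(1), bounds = bounds)
    if (!all(ok))
      stop("trajectory amplitudes leave the feasible bounds at phase(s) ",
           paste(round(phases[!ok], 3), collapse = ", "))
  }
  attr(poses, "phases") <- phases
  poses
}

#' Synthetic epicardial source potentials
#'
#' A traveling-depolarization surrogate for recorded electrograms: every node
#' carries the same smooth biphasic waveform, delayed by the node's
#' geodesic distance (shortest path along mesh edges; Euclidean fallback when
#' the edge graph is unavailable) from a pacing node divided by the
#' conduction speed. Amplitudes are a few mV with small deterministic
#' per-node variation controlled by `seed`.
#'
#' @param heart heart [trimesh].
#' @param fs sampling rate, Hz.
#' @param duration_ms signal length, ms.
#' @param pacing_node index of the earliest-activated node (default: the node
#'   of minimal Z — an apical pacing site).
#' @param speed conduction speed, mm/ms.
#' @param width_ms waveform half-width, ms.
#' @param amplitude_mv peak amplitude scale, mV.
#' @param seed integer seed for the per-node amplitude jitter.
#' @return nodes x time matrix with attributes `"activation_ms"` (per-node
#'   delays) and `"qrs_window"` (samples spanning the depolarization).
#' @export
synth_epicardial_potentials <- function(heart, fs = 2000, duration_ms = 200,
                                        pacing_node = which.min(heart$nodes[, 3]),
                                        speed = 1.0, width_ms = 5,
                                        amplitude_mv = 2, seed = 1) {
  n <- nrow(heart$nodes)
  if (pacing_node < 1 || pacing_node > n) stop("invalid pacing node")
  dist <- mesh_geodesic(heart, pacing_node)
  delay <- dist / speed
  nt <- round(duration_ms * fs / 1000)
  tms <- (seq_len(nt) - 1) * 1000 / fs
  set.seed(seed %% .Machine$integer.max)
  amp <- amplitude_mv * (1 + 0.15 * stats::rnorm(n))
  onset <- 3 * width_ms  # lead-in so the earliest waveform is fully captured
  x <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    u <- (tms - onset - delay[i]) / width_ms
    x[i, ] <- -amp[i] * u * exp(-u^2 / 2)  # biphasic (derivative-of-Gaussian)
  }
  lo <- max(1L, floor((onset - 3 * width_ms) * fs / 1000) + 1L)
  hi <- min(nt, ceiling((onset + max(delay) + 3 * width_ms) * fs / 1000))
  attr(x, "activation_ms") <- delay
  attr(x, "qrs_window") <- c(lo, hi)
  x
}

# shortest-path distance from one node to all nodes along mesh edges
mesh_geodesic <- function(mesh, from) {
  f <- mesh$faces
  e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                    f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)]))
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  w <- sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                       mesh$nodes[e[, 2], , drop = FALSE])^2))
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    as.numeric(igraph::distances(g, v = from, weights = w))
  } else {
    euclid <- sweep(mesh$nodes, 2, mesh$nodes[from, ])
    sqrt(rowSums(euclid^2))
  }
}

# derive a per-(beat, rep) integer seed below 2^31 from the master seed
derive_seed <- function(seed, beat, rep) {
  as.integer((as.numeric(seed) * 48271 + beat * 9973 + rep * 101) %%
               2147483629)
}

#' Synthesize body-surface beats through the forward model
#'
#' For each pose along a trajectory and each noise realization, computes the
#' noiseless torso potentials `y = A(pose) x` through the BEM transfer matrix
#' of the displaced heart and adds independent Gaussian noise calibrated so
#' the realized signal-to-noise ratio over the QRS window (all electrodes
#' jointly) equals `snr_db` exactly; `snr_db = Inf` disables noise. Seeds for
#' each (beat, repetition) derive deterministically from `seed`, so identical
#' calls give bit-identical datasets.
#'
#' @param heart,torso closed [trimesh] objects (nominal geometry).
#' @param frame an [anatomical_frame].
#' @param poses list of [pose_params] (e.g. [respiratory_trajectory()]).
#' @param x heart potentials, nodes x time (e.g.
#'   [synth_epicardial_potentials()]).
#' @param fs sampling rate, Hz.
#' @param qrs_window integer pair of sample indices (defaults to the
#'   `"qrs_window"` attribute of `x`, else the full signal).
#' @param snr_db signal-to-noise ratio in dB (default 30).
#' @param n_reps noise realizations per pose (default 10).
#' @param seed master integer seed.
#' @param bounds optional `pose_bounds` checked for every pose.
#' @param cache optional [forward_cache()].
#' @return list of [beat_recording] objects, ordered by beat then repetition.
#' @export
synthesize_beats <- function(heart, torso, frame, poses, x, fs = 2000,
                             qrs_window = NULL, snr_db = 30, n_reps = 10,
                             seed = 1, bounds = NULL, cache = NULL) {
  x <- as.matrix(x)
  if (is.null(qrs_window))
    qrs_window <- attr(x, "qrs_window") %||% c(1L, ncol(x))
  if (is.null(cache)) cache <- forward_cache(torso)
  beats <- vector("list", length(poses) * n_reps)
  k <- 1L
  for (b in seq_along(poses)) {
    model <- transfer_at_pose(heart, torso, frame, poses[[b]], bounds = bounds,
                              cache = cache)
    y0 <- forward_map(model, x)
    qrs_idx <- qrs_window[1]:qrs_window[2]
    psig <- mean(y0[, qrs_idx]^2)
    for (r in seq_len(n_reps)) {
      if (is.finite(snr_db)) {
        set.seed(derive_seed(seed, b, r))
        eps <- matrix(stats::rnorm(length(y0)), nrow(y0), ncol(y0))
        target <- psig / 10^(snr_db / 10)
        eps <- eps * sqrt(target / mean(eps[, qrs_idx]^2))
        y <- y0 + eps
      } else {
        y <- y0
      }
      beats[[k]] <- beat_recording(x, y, fs, qrs_window, beat_id = b, rep = r,
                                   true_pose = poses[[b]])
      k <- k + 1L
    }
  }
  beats
}

`%||%` <- function(a, b) if (is.null(a)) b else a
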