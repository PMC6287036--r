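#' Centered moving-average filter
#'
#' Boxcar mean per channel with a centered window; at the edges the window
#' shrinks to the available samples (the mean is taken over fewer points), so
#' constant signals pass through unchanged everywhere. The default 20 ms
#' window is the denoising filter applied to both heart and torso recordings
#' before fitting.
#'
#' @param signals channels x time matrix.
#' @param window_ms window length in ms.
#' @param fs sampling rate in Hz.
#' @return filtered matrix, same shape.
#' @export
moving_average <- function(signals, window_ms = 20, fs = 1000) {
  signals <- as.matrix(signals)
  nt <- ncol(signals)
  w <- round(window_ms * fs / 1000)
  if (window_ms <= 0 || w < 1) stop("window must be at least one sample")
  if (w > nt) stop("window (", w, " samples) longer than the signal (", nt, ")")
  hl <- floor((w - 1) / 2)
  hr <- w - 1 - hl
  lo <- pmax(seq_len(nt) - hl, 1L)
  hi <- pmin(seq_len(nt) + hr, nt)
  cs <- cbind(0, t(apply(signals, 1, cumsum)))
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(signals))
  dimnames(out) <- dimnames(signals)
  out
}

#' Restrict a beat to its QRS window
#'
#' Truncates heart and torso signals to the annotated QRS complex — the
#' high-amplitude ventricular depolarization segment used for fitting — and
#' resets the window metadata to span the truncated signal.
#'
#' @param beat a [beat_recording] with `qrs_window` set.
#' @return a [beat_recording] restricted to the QRS samples.
#' @export
extract_qrs <- function(beat) {
  w <- beat$qrs_window
  if (w[2] < w[1]) stop("empty QRS window")
  idx <- w[1]:w[2]
  beat_recording(beat$x[, idx, drop = FALSE], beat$y[, idx, drop = FALSE],
                 beat$fs, c(1L, length(idx)), beat$beat_id, beat$rep,
                 beat$true_pose)
}

#' Preprocess a beat for fitting
#'
#' QRS extraction followed by moving-average smoothing of both heart and
#' torso signals.
#'
#' @param beat a [beat_recording].
#' @param window_ms moving-average window, ms (default 20).
#' @return the preprocessed [beat_recording].
#' @export
preprocess_beat <- function(beat, window_ms = 20) {
  beat <- extract_qrs(beat)
  beat$x <- moving_average(beat$x, window_ms, beat$fs)
  beat$y <- moving_average(beat$y, window_ms, beat$fs)
  beat
}

#' Relative error between measured and synthesized potentials
#'
#' Sum of squared differences over all channels and time instances divided by
#' the sum of squares of the measured signal:
#' `sum((y - yhat)^2) / sum(y^2)`. Scale-invariant under joint scaling of
#' both signals. Any referencing must be applied to both inputs beforehand.
#'
#' @param y measured potentials, channels x time.
#' @param yhat synthesized potentials, same shape.
#' @return nonnegative scalar.
#' @export
relative_error <- function(y, yhat) {
  y <- as.matrix(y)
  yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("y and yhat must have the same shape")
  den <- sum(y^2)
  if (den == 0) stop("measured signal is identically zero")
  sum((y - yhat)^2) / den
}

#' Evaluate an experiment: forward and inverse errors, geometry RMSD
#'
#' For every beat, compares measured torso potentials with potentials
#' synthesized through the nominal and the corrected forward matrices
#' (forward relative error), reconstructs heart potentials from the torso
#' potentials with zero-order Tikhonov regularization and per-beat L-curve
#' selection under both matrices and scores them against the known heart
#' potentials (inverse relative error), and — when true poses are available —
#' reports the node RMSD of the nominal and corrected heart geometries
#' against the true one. All potential comparisons are zero-mean referenced
#' per time instant. Improvements are nominal minus corrected.
#'
#' @param beats list of [beat_recording] (preprocessed the same way as during
#'   fitting).
#' @param fits [correct_all_beats()] result (or list of `pose_fit`).
#' @param heart,torso,frame nominal geometry and [anatomical_frame].
#' @param grid lambda grid for the inverse solutions.
#' @param channels optional subset of heart nodes treated as measured
#'   channels for the inverse error (default: all).
#' @param nominal_model optional precomputed nominal `transfer_model`.
#' @return object of class `error_report`: `per_beat` data.frame and `summary`
#'   (mean and sd of each error column).
#' @export
evaluate_experiment <- function(beats, fits, heart, torso, frame,
                                grid = lambda_grid(), channels = NULL,
                                nominal_model = NULL) {
  if (inherits(fits, "pose_fit")) fits <- list(fits)
  if (length(fits) != length(beats))
    stop("one fit per beat is required (", length(beats), " beats, ",
         length(fits), " fits)")
  if (is.null(nominal_model))
    nominal_model <- assemble_transfer_matrix(heart, torso)
  if (is.null(channels)) channels <- seq_len(nrow(heart$nodes))
  rows <- vector("list", length(beats))
  for (i in seq_along(beats)) {
    beat <- beats[[i]]
    fit <- fits[[i]]
    row <- data.frame(beat_id = beat$beat_id, rep = beat$rep)
    if (inherits(fit, "pose_fit")) {
      A0 <- nominal_model$matrix
      Ac <- fit$corrected_model$matrix
      ym <- zero_reference(beat$y)
      row$bsp_rel_err_nominal <- relative_error(ym, zero_reference(A0 %*% beat$x))
      row$bsp_rel_err_corrected <- relative_error(ym, zero_reference(Ac %*% beat$x))
      x_true <- zero_reference(beat$x[channels, , drop = FALSE])
      x0 <- tikhonov_inverse(A0, ym, grid)$X
      xc <- tikhonov_inverse(Ac, ym, grid)$X
      row$egm_rel_err_nominal <-
        relative_error(x_true, zero_reference(x0[channels, , drop = FALSE]))
      row$egm_rel_err_corrected <-
        relative_error(x_true, zero_reference(xc[channels, , drop = FALSE]))
      row$bsp_improvement <- row$bsp_rel_err_nominal - row$bsp_rel_err_corrected
      row$egm_improvement <- row$egm_rel_err_nominal - row$egm_rel_err_corrected
      if (!is.null(beat$true_pose)) {
        true_heart <- apply_pose(heart, frame, beat$true_pose)
        row$rmsd_nominal <- mesh_rmsd(heart, true_heart)
        row$rmsd_corrected <-
          mesh_rmsd(apply_pose(heart, frame, fit$pose), true_heart)
      }
      row$objective_initial <- fit$value0
      row$objective_final <- fit$value
      row$converged <- fit$converged
    } else {
      row$error <- paste(conditionMessage(attr(fit, "condition") %||%
                                            simpleCondition("fit failed")),
                         collapse = " ")
    }
    rows[[i]] <- row
  }
  per_beat <- do.call(rbind_fill, list(rows))
  num <- per_beat[vapply(per_beat, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("beat_id", "rep"))]
  summ <- data.frame(metric = names(num),
                     mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
                     sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0),
                     row.names = NULL)
  structure(list(per_beat = per_beat, summary = summ), class = "error_report")
}

rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  }))
}

#' @export
print.error_report <- function(x, ...) {
  cat("error report over", nrow(x$per_beat), "beats\n")
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 4)),
        row.names = FALSE)
  invisible(x)
}
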