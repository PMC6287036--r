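#' Pose-fit objective: residual power of the pose-parameterized forward model
#'
#' The sum over time of squared differences between measured torso potentials
#' and potentials synthesized through the transfer matrix of the heart moved
#' to pose `p`: `sum_t || y(t) - A(p) x(t) ||^2`, with both signals zero-mean
#' referenced per time instant so the additive-constant ambiguity of the
#' volume conductor cannot enter the residual. Deterministic given the beat
#' and meshes; minimized over the feasible hyper-rectangle by
#' [correct_pose()].
#'
#' @param p a [pose_params].
#' @param beat a (preprocessed) [beat_recording].
#' @param heart,torso nominal geometry.
#' @param frame an [anatomical_frame].
#' @param bounds optional `pose_bounds`; poses outside are an error.
#' @param cache optional [forward_cache()].
#' @return nonnegative scalar.
#' @export
pose_objective <- function(p, beat, heart, torso, frame, bounds = NULL,
                           cache = NULL) {
  model <- transfer_at_pose(heart, torso, frame, p, bounds = bounds,
                            cache = cache)
  yhat <- forward_map(model, beat$x)
  sum((zero_reference(beat$y) - zero_reference(yhat))^2)
}

#' Optimizer control settings for pose correction
#'
#' @param max_evals cap on objective evaluations per beat (default 300;
#'   gradient evaluations by finite differences count toward it).
#' @param step_mm,step_deg central finite-difference steps for translations
#'   (mm) and angles (degrees).
#' @param factr,pgtol L-BFGS-B convergence controls (see [stats::optim()]).
#' @param n_restarts number of additional random feasible starting poses
#'   (default 0: start from the nominal pose only).
#' @param restart_seed seed for the restart draws.
#' @return list of class `correct_control`.
#' @export
correct_control <- function(max_evals = 300, step_mm = 0.5, step_deg = 0.5,
                            factr = 1e7, pgtol = 0, n_restarts = 0,
                            restart_seed = 1) {
  structure(list(max_evals = max_evals, step_mm = step_mm,
                 step_deg = step_deg, factr = factr, pgtol = pgtol,
                 n_restarts = n_restarts, restart_seed = restart_seed),
            class = "correct_control")
}

#' Estimate the heart pose for one beat
#'
#' The core estimator: finds the six rigid pose parameters (translation,
#' pitch, yaw, roll) that minimize the residual between measured torso
#' potentials and potentials synthesized through the pose-parameterized BEM
#' forward model, subject to the hyper-rectangle bounds that keep the heart
#' from intersecting the torso. A bound-constrained quasi-Newton local method
#' (L-BFGS-B with central finite-difference gradients) runs from the nominal
#' (zero)
#' pose on parameters rescaled to a common [-1, 1] box; optional seeded
#' random restarts guard against local minima. The returned pose never
#' increases the objective relative to the start.
#'
#' @param beat a preprocessed [beat_recording] (see [preprocess_beat()]).
#' @param heart,torso nominal geometry ([trimesh]).
#' @param frame an [anatomical_frame].
#' @param bounds a `pose_bounds` feasible box containing the nominal pose.
#' @param control a [correct_control()] list.
#' @param cache optional [forward_cache()]; created internally if missing.
#' @return object of class `pose_fit`: `pose` (the estimate), `value` /
#'   `value0` (objective at estimate / at the nominal pose), `n_evals`,
#'   `converged`, `corrected_model` (freshly assembled transfer matrix at the
#'   estimate), plus the beat and frame for the methods.
#' @seealso [correct_all_beats()] for batch fitting;
#'   [coef.pose_fit()], [predict.pose_fit()], [residuals.pose_fit()].
#' @export
correct_pose <- function(beat, heart, torso, frame, bounds,
                         control = correct_control(), cache = NULL) {
  if (!in_bounds(pose_zero(), bounds))
    stop("the nominal (zero) pose must lie inside the bounds")
  if (is.null(cache)) cache <- forward_cache(torso)
  lo <- as.numeric(unclass(bounds$lower))
  hi <- as.numeric(unclass(bounds$upper))
  center <- (lo + hi) / 2
  half <- (hi - lo) / 2
  free <- half > 1e-12

  n_evals <- 0L
  evals_exceeded <- FALSE
  best_seen <- list(u = NULL, f = Inf)
  fn <- function(u) {
    if (n_evals >= control$max_evals) {
      evals_exceeded <<- TRUE
      stop("evaluation budget exhausted")
    }
    n_evals <<- n_evals + 1L
    p <- center
    p[free] <- center[free] + u * half[free]
    # clamp floating-point boundary overshoot
    p <- pmin(pmax(p, lo), hi)
    f <- pose_objective(as_pose(p), beat, heart, torso, frame, cache = cache)
    if (f < best_seen$f) best_seen <<- list(u = u, f = f)
    f
  }
  u0 <- ((0 - center) / ifelse(free, half, 1))[free]
  f0 <- fn(u0)
  ndeps <- (c(rep(control$step_mm, 3),
              rep(control$step_deg * pi / 180, 3)) / ifelse(free, half, 1))[free]

  signal_power <- sum(zero_reference(beat$y)^2)
  if (f0 <= 1e-14 * max(signal_power, .Machine$double.xmin)) {
    # nominal geometry already explains the data to numerical precision
    corrected <- transfer_at_pose(heart, torso, frame, pose_zero())
    return(structure(list(pose = pose_zero(), value = f0, value0 = f0,
                          n_evals = n_evals, converged = TRUE,
                          message = "nominal pose already optimal",
                          corrected_model = corrected, beat = beat,
                          frame = frame, bounds = bounds,
                          call = match.call()),
                     class = "pose_fit"))
  }

  starts <- list(u0)
  if (control$n_restarts > 0) {
    set.seed(control$restart_seed)
    for (k in seq_len(control$n_restarts))
      starts[[k + 1]] <- stats::runif(sum(free), -1, 1)
  }
  best <- list(par = u0, value = f0, convergence = 1L,
               message = "no improvement over the nominal pose")
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, fn, method = "L-BFGS-B", lower = -1, upper = 1,
                   control = list(maxit = 200, factr = control$factr,
                                  pgtol = control$pgtol, ndeps = ndeps,
                                  fnscale = max(f0, .Machine$double.xmin))),
      error = function(e) {
        if (evals_exceeded) NULL else stop(e)
      })
    if (!is.null(res) && res$value < best$value) best <- res
    if (evals_exceeded) break
  }
  if (is.finite(best_seen$f) && best_seen$f < best$value) {
    # keep the best evaluated point when a run was cut off mid-iteration
    best <- list(par = best_seen$u, value = best_seen$f, convergence = 1L,
                 message = "evaluation budget reached")
  }

  p_hat <- center
  p_hat[free] <- center[free] + best$par * half[free]
  p_hat <- as_pose(pmin(pmax(p_hat, lo), hi))
  # fresh (uncached) assembly at the estimate; its objective is the reported one
  corrected <- transfer_at_pose(heart, torso, frame, p_hat)
  yhat <- forward_map(corrected, beat$x)
  value <- sum((zero_reference(beat$y) - zero_reference(yhat))^2)
  structure(list(pose = p_hat, value = value, value0 = f0, n_evals = n_evals,
                 converged = !is.null(best$convergence) && best$convergence == 0,
                 message = best$message %||% "",
                 corrected_model = corrected, beat = beat, frame = frame,
                 bounds = bounds, call = match.call()),
            class = "pose_fit")
}

#' @export
print.pose_fit <- function(x, ...) {
  cat("heart pose fit (beat ", x$beat$beat_id, ", rep ", x$beat$rep, ")\n",
      sep = "")
  cat("  ", format_pose(x$pose), "\n", sep = "")
  cat(sprintf("  objective: %.4g -> %.4g (%d evaluations, %s)\n", x$value0,
              x$value, x$n_evals,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.pose_fit <- function(object, ...) {
  ym <- zero_reference(object$beat$y)
  rel <- relative_error(ym, zero_reference(fitted(object)))
  out <- list(pose = object$pose, value = object$value, value0 = object$value0,
              n_evals = object$n_evals, converged = object$converged,
              bsp_rel_err = rel,
              true_pose = object$beat$true_pose)
  if (!is.null(object$beat$true_pose))
    out$pose_error <- unclass(object$pose) - unclass(object$beat$true_pose)
  structure(out, class = "summary.pose_fit")
}

#' @export
print.summary.pose_fit <- function(x, ...) {
  cat("estimated ", format_pose(x$pose), "\n", sep = "")
  if (!is.null(x$true_pose)) {
    cat("true      ", format_pose(x$true_pose), "\n", sep = "")
    cat("  parameter error:",
        paste(signif(x$pose_error, 3), collapse = " "), "\n")
  }
  cat(sprintf("objective %.4g -> %.4g in %d evaluations; BSP relative error %.4g\n",
              x$value0, x$value, x$n_evals, x$bsp_rel_err))
  invisible(x)
}

#' @export
coef.pose_fit <- function(object, ...) object$pose

#' Predicted torso potentials from a pose fit
#'
#' @param object a `pose_fit`.
#' @param x heart potentials (nodes x time); default: the fitted beat's own.
#' @param ... unused.
#' @return electrodes x time matrix `A(p_hat) x`.
#' @export
predict.pose_fit <- function(object, x = object$beat$x, ...) {
  forward_map(object$corrected_model, x)
}

#' @export
fitted.pose_fit <- function(object, ...) predict(object)

#' @export
residuals.pose_fit <- function(object, ...) {
  zero_reference(object$beat$y) - zero_reference(fitted(object))
}

#' @export
plot.pose_fit <- function(x, ...) {
  r <- residuals(x)
  ym <- zero_reference(x$beat$y)
  t <- seq_len(ncol(r)) / x$beat$fs * 1000
  graphics::plot(t, sqrt(colMeans(ym^2)), type = "l", xlab = "time (ms)",
                 ylab = "RMS potential (mV)",
                 main = "measured torso signal and fit residual", ...)
  graphics::lines(t, sqrt(colMeans(r^2)), lty = 2)
  graphics::legend("topright", legend = c("measured", "residual"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Estimate poses for a sequence of beats
#'
#' Runs [correct_pose()] independently on every beat (the heart may move
#' between beats), sharing the torso self-interaction blocks across beats and
#' clearing the pose-keyed cache between them. A failing beat is recorded and
#' does not abort the batch.
#'
#' @inheritParams correct_pose
#' @param beats list of preprocessed [beat_recording] objects.
#' @return object of class `pose_fit_list` (a list of `pose_fit`, with
#'   try-errors in place of failed beats).
#' @export
correct_all_beats <- function(beats, heart, torso, frame, bounds,
                              control = correct_control()) {
  if (!length(beats)) stop("at least one beat is required")
  cache <- forward_cache(torso)
  fits <- vector("list", length(beats))
  for (i in seq_along(beats)) {
    reset_pose_cache(cache)
    fits[[i]] <- tryCatch(
      correct_pose(beats[[i]], heart, torso, frame, bounds, control, cache),
      error = function(e) structure(conditionMessage(e), class = "try-error",
                                    condition = e))
  }
  structure(fits, class = "pose_fit_list")
}

#' @export
print.pose_fit_list <- function(x, ...) {
  cat("pose fits for", length(x), "beats\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.pose_fit_list <- function(object, ...) {
  t(vapply(object, function(f) {
    if (inherits(f, "pose_fit")) as.numeric(unclass(f$pose)) else rep(NA_real_, 6)
  }, numeric(6), USE.NAMES = FALSE)) |>
    `colnames<-`(c("tx", "ty", "tz", "theta", "phi", "rho"))
}

#' @export
summary.pose_fit_list <- function(object, ...) {
  ok <- vapply(object, inherits, logical(1), "pose_fit")
  tab <- data.frame(
    beat_id = vapply(object[ok], function(f) f$beat$beat_id, 0L),
    rep = vapply(object[ok], function(f) f$beat$rep, 0L),
    coef(object)[ok, , drop = FALSE],
    objective_initial = vapply(object[ok], function(f) f$value0, 0),
    objective_final = vapply(object[ok], function(f) f$value, 0),
    n_evals = vapply(object[ok], function(f) f$n_evals, 0L),
    converged = vapply(object[ok], function(f) f$converged, TRUE))
  structure(list(table = tab, n_failed = sum(!ok)),
            class = "summary.pose_fit_list")
}

#' @export
print.summary.pose_fit_list <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (x$n_failed) cat(x$n_failed, "beat(s) failed\n")
  invisible(x)
}

#' @export
plot.pose_fit_list <- function(x, ...) {
  co <- coef(x)
  beat <- vapply(x, function(f)
    if (inherits(f, "pose_fit")) f$beat$beat_id else NA_integer_, 0L)
  graphics::plot(beat, co[, "tz"], xlab = "beat", ylab = "tz (mm)",
                 main = "estimated vertical translation per beat", ...)
  invisible(x)
}
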