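#' Synthetic heart and torso geometry
#'
#' Default closed surfaces for the synthetic respiration experiment:
#' ellipsoidal meshes. Coordinates follow the X-left, Y-posterior, Z-superior
#' convention. The heart is a prolate ellipsoid (semi-axes 35, 30, 50 mm)
#' whose long (septal) axis is tilted obliquely so the apex points left,
#' anterior and inferior — the usual anatomical attitude, which also keeps
#' the axis far from the poles of the spherical pitch/yaw parameterization;
#' the heart sits left, anterior and superior of the center of the larger
#' torso ellipsoid (semi-axes 170, 120, 230 mm). At the default `level = 2`
#' the heart has 194 nodes (384 faces) and the torso 290 nodes (576 faces),
#' every torso node acting as an electrode; `level = 1` gives coarser meshes
#' (98 / 147 nodes) for quick experiments.
#'
#' @param level mesh resolution (1 = coarse, 2 = default study size).
#' @return a [trimesh].
#' @export
synthetic_heart_mesh <- function(level = 2) {
  m <- if (level >= 2) mesh_uvsphere(12, 16, name = "synthetic-heart")
  else mesh_uvsphere(8, 12, name = "synthetic-heart")
  m$nodes <- sweep(m$nodes, 2, c(35, 30, 50), "*")
  axis_dir <- c(0.5, -0.4, -0.77)  # apex toward left-anterior-inferior
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  R <- rotation_between(c(0, 0, -1), axis_dir)
  m$nodes <- m$nodes %*% t(R)
  m$nodes <- sweep(m$nodes, 2, c(25, -20, 30), "+")
  m
}

#' @rdname synthetic_heart_mesh
#' @export
synthetic_torso_mesh <- function(level = 2) {
  m <- if (level >= 2) mesh_uvsphere(16, 18, name = "synthetic-torso")
  else mesh_uvsphere(10, 14, name = "synthetic-torso")
  m$nodes <- sweep(m$nodes, 2, c(170, 120, 230), "*")
  m
}

#' Default anatomical frame for the synthetic heart
#'
#' The long axis of the heart is taken as the first principal axis of the
#' node cloud, signed so the apex points inferior. The basal cap — nodes in
#' the top 15% of the extent along that axis, standing in for the atrial
#' region — defines the anchor centroid; the node of largest apical
#' projection is the apex, so the septal axis runs base to apex.
#'
#' @param heart heart [trimesh].
#' @return an [anatomical_frame].
#' @export
synthetic_frame <- function(heart) {
  pc <- stats::prcomp(heart$nodes)
  axis <- pc$rotation[, 1]
  if (axis[3] > 0) axis <- -axis  # apex end points downward
  proj <- heart$nodes %*% axis
  base_ids <- which(proj <= min(proj) + 0.15 * (max(proj) - min(proj)))
  anatomical_frame(heart, base_ids, which.max(proj))
}

#' Run the synthetic respiration experiment end to end
#'
#' The full validation pipeline: build the synthetic geometry, move the heart
#' through a respiratory-like trajectory, synthesize body-surface potentials
#' through the BEM forward model for every pose, add Gaussian noise at the
#' requested SNR for each realization, estimate the pose of every beat back
#' from the potentials starting at the nominal geometry, and score forward,
#' inverse and geometric errors.
#'
#' @param n_beats trajectory poses (default 10).
#' @param n_reps noise realizations per pose (default 10).
#' @param snr_db signal-to-noise ratio, dB (default 30; `Inf` for noiseless).
#' @param seed master seed for noise realizations.
#' @param level mesh resolution (default 2: 194-node heart, 290-node torso).
#' @param fs sampling rate of the synthetic recordings, Hz.
#' @param z_amplitude,pitch_amplitude trajectory amplitudes (mm, rad).
#' @param control optimizer settings ([correct_control()]).
#' @param lambda_grid_n L-curve grid size for the evaluation step.
#' @param evaluate if `FALSE`, skip the forward/inverse error report (the
#'   geometry RMSD columns are still computed from the fits).
#' @return list with `heart`, `torso`, `frame`, `bounds`, `poses`, `beats`
#'   (preprocessed), `fits` (a `pose_fit_list`), and `report` (an
#'   `error_report`, when `evaluate = TRUE`) or `rmsd` (data.frame otherwise).
#' @export
run_synthetic_experiment <- function(n_beats = 10, n_reps = 10, snr_db = 30,
                                     seed = 1, level = 2, fs = 2000,
                                     z_amplitude = 20,
                                     pitch_amplitude = 10 * pi / 180,
                                     control = correct_control(),
                                     lambda_grid_n = 100,
                                     evaluate = TRUE) {
  heart <- synthetic_heart_mesh(level)
  torso <- synthetic_torso_mesh(level)
  frame <- synthetic_frame(heart)
  bounds <- compute_bounds(heart, torso, frame)
  poses <- respiratory_trajectory(n_beats, z_amplitude, pitch_amplitude,
                                  bounds = bounds)
  x <- synth_epicardial_potentials(heart, fs = fs, seed = seed)
  cache <- forward_cache(torso, heart)
  beats <- synthesize_beats(heart, torso, frame, poses, x, fs = fs,
                            snr_db = snr_db,
                            n_reps = n_reps, seed = seed, bounds = bounds,
                            cache = cache)
  beats <- lapply(beats, preprocess_beat)
  fits <- correct_all_beats(beats, heart, torso, frame, bounds, control)
  out <- list(heart = heart, torso = torso, frame = frame, bounds = bounds,
              poses = poses, beats = beats, fits = fits)
  if (evaluate) {
    out$report <- evaluate_experiment(beats, fits, heart, torso, frame,
                                      grid = lambda_grid(lambda_grid_n))
  } else {
    out$rmsd <- geometry_rmsd(beats, fits, heart, frame)
  }
  out
}

#' Corrected- and nominal-geometry RMSD per beat
#'
#' Node RMSD of the corrected and the nominal heart against the true heart
#' geometry for every synthetic beat with a known generating pose.
#'
#' @param beats list of [beat_recording] with `true_pose` set.
#' @param fits matching `pose_fit_list`.
#' @param heart nominal heart [trimesh].
#' @param frame an [anatomical_frame].
#' @return data.frame with `beat_id`, `rep`, `rmsd_nominal`, `rmsd_corrected`.
#' @export
geometry_rmsd <- function(beats, fits, heart, frame) {
  rows <- lapply(seq_along(beats), function(i) {
    beat <- beats[[i]]
    fit <- fits[[i]]
    if (is.null(beat$true_pose) || !inherits(fit, "pose_fit")) return(NULL)
    true_heart <- apply_pose(heart, frame, beat$true_pose)
    data.frame(beat_id = beat$beat_id, rep = beat$rep,
               rmsd_nominal = mesh_rmsd(heart, true_heart),
               rmsd_corrected = mesh_rmsd(apply_pose(heart, frame, fit$pose),
                                          true_heart))
  })
  do.call(rbind, rows)
}

#' Write / read a synthetic dataset bundle
#'
#' Serializes meshes (OFF), per-beat potentials (delimited text, one file per
#' beat and surface) and a YAML manifest carrying the sampling rate, QRS
#' windows, seeds and true poses, so a dataset can be regenerated, shared and
#' re-read without recomputation.
#'
#' @param bundle list with `heart`, `torso`, `frame`, `beats`, and optionally
#'   `seed` (as produced by [run_synthetic_experiment()]).
#' @param dir output directory (created if missing).
#' @return `dir` (write) / a bundle list (read), invisibly for the writer.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(bundle$heart, file.path(dir, "heart.off"))
  write_mesh(bundle$torso, file.path(dir, "torso.off"))
  beats_meta <- list()
  for (i in seq_along(bundle$beats)) {
    b <- bundle$beats[[i]]
    xf <- sprintf("beat%03d_x.tsv", i)
    yf <- sprintf("beat%03d_y.tsv", i)
    utils::write.table(b$x, file.path(dir, xf), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(b$y, file.path(dir, yf), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    beats_meta[[i]] <- list(beat_id = b$beat_id, rep = b$rep, fs = b$fs,
                            qrs_window = as.integer(b$qrs_window),
                            x_file = xf, y_file = yf,
                            true_pose = if (!is.null(b$true_pose))
                              sprintf("%.17g", unclass(b$true_pose)))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ecgpose")),
    seed = bundle$seed,
    heart = "heart.off", torso = "torso.off",
    frame = list(base_node_ids = bundle$frame$base_node_ids,
                 apex_node_id = bundle$frame$apex_node_id),
    beats = beats_meta)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  heart <- read_mesh(file.path(dir, manifest$heart))
  torso <- read_mesh(file.path(dir, manifest$torso))
  frame <- anatomical_frame(heart, unlist(manifest$frame$base_node_ids),
                            manifest$frame$apex_node_id)
  beats <- lapply(manifest$beats, function(m) {
    x <- as.matrix(utils::read.table(file.path(dir, m$x_file), sep = "\t"))
    y <- as.matrix(utils::read.table(file.path(dir, m$y_file), sep = "\t"))
    dimnames(x) <- dimnames(y) <- NULL
    beat_recording(x, y, m$fs, unlist(m$qrs_window), m$beat_id, m$rep,
                   true_pose = if (!is.null(m$true_pose))
                     as.numeric(unlist(m$true_pose)))
  })
  list(heart = heart, torso = torso, frame = frame, beats = beats,
       seed = manifest$seed)
}
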