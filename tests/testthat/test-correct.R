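# End-to-end behaviour of the pose estimator on small (level-1) geometry.

make_beats <- function(poses, snr_db = Inf, n_reps = 1, seed = 1) {
  g <- get_small_geometry()
  x <- synth_epicardial_potentials(g$heart, seed = seed)
  cache <- forward_cache(g$torso, g$heart)
  beats <- synthesize_beats(g$heart, g$torso, g$frame, poses, x,
                            snr_db = snr_db, n_reps = n_reps, seed = seed,
                            cache = cache)
  lapply(beats, preprocess_beat)
}

test_that("objective is zero at the generating pose and positive elsewhere", {
  g <- get_small_geometry()
  p_star <- pose_params(tz = 12, theta = 0.15)
  beat <- make_beats(list(p_star))[[1]]
  cache <- forward_cache(g$torso, g$heart)
  f_star <- pose_objective(p_star, beat, g$heart, g$torso, g$frame,
                           cache = cache)
  expect_lt(f_star, 1e-10 * sum(beat$y^2))
  f0 <- pose_objective(pose_zero(), beat, g$heart, g$torso, g$frame,
                       cache = cache)
  expect_gt(f0, 0)
  expect_error(pose_objective(pose_params(tx = 1e3), beat, g$heart, g$torso,
                              g$frame, bounds = g$bounds), "outside")
})

test_that("objective at the true pose equals the residual noise power", {
  g <- get_small_geometry()
  p_star <- pose_params(tz = 10)
  raw <- {
    x <- synth_epicardial_potentials(g$heart, seed = 1)
    cache <- forward_cache(g$torso, g$heart)
    synthesize_beats(g$heart, g$torso, g$frame, list(p_star), x, snr_db = 30,
                     n_reps = 1, seed = 1, cache = cache)[[1]]
  }
  cache <- forward_cache(g$torso, g$heart)
  y0 <- forward_map(transfer_at_pose(g$heart, g$torso, g$frame, p_star,
                                     cache = cache), raw$x)
  # push the actual noise realization through the identical preprocessing
  noise_beat <- beat_recording(raw$x, raw$y - y0, raw$fs, raw$qrs_window)
  noise_proc <- preprocess_beat(noise_beat)
  expected <- sum(zero_reference(noise_proc$y)^2)
  beat <- preprocess_beat(raw)
  f_star <- pose_objective(p_star, beat, g$heart, g$torso, g$frame,
                           cache = cache)
  expect_equal(f_star, expected, tolerance = 0.2)
})

test_that("noiseless displaced pose is recovered to 0.1 mm / 0.1 degree", {
  g <- get_small_geometry()
  p_star <- pose_params(tz = 15, theta = 10 * pi / 180)
  beat <- make_beats(list(p_star))[[1]]
  fit <- correct_pose(beat, g$heart, g$torso, g$frame, g$bounds)
  err <- unclass(fit$pose) - unclass(p_star)
  expect_lt(max(abs(err[1:3])), 0.1)                 # mm
  expect_lt(max(abs(err[4:6])), 0.1 * pi / 180)      # rad
  true_heart <- apply_pose(g$heart, g$frame, p_star)
  expect_lt(mesh_rmsd(apply_pose(g$heart, g$frame, fit$pose), true_heart),
            0.05)
  # monotone improvement and feasibility
  expect_lte(fit$value, fit$value0)
  expect_true(in_bounds(fit$pose, g$bounds))
  expect_false(surfaces_intersect(apply_pose(g$heart, g$frame, fit$pose),
                                  g$torso))
})

test_that("objective at the returned pose matches a fresh uncached assembly", {
  g <- get_small_geometry()
  beat <- make_beats(list(pose_params(tz = 8)), snr_db = 30)[[1]]
  fit <- correct_pose(beat, g$heart, g$torso, g$frame, g$bounds)
  fresh <- pose_objective(fit$pose, beat, g$heart, g$torso, g$frame)
  expect_equal(fit$value, fresh, tolerance = 1e-9)
})

test_that("data from the nominal geometry leaves the pose near nominal", {
  g <- get_small_geometry()
  beat <- make_beats(list(pose_zero()), snr_db = 30)[[1]]
  fit <- correct_pose(beat, g$heart, g$torso, g$frame, g$bounds)
  expect_lt(mesh_rmsd(apply_pose(g$heart, g$frame, fit$pose), g$heart), 0.5)
  # noiseless nominal data short-circuits to the zero pose
  clean <- make_beats(list(pose_zero()))[[1]]
  fit0 <- correct_pose(clean, g$heart, g$torso, g$frame, g$bounds)
  expect_equal(as.numeric(fit0$pose), rep(0, 6))
})

test_that("batch correction preserves order, determinism, and isolates failures", {
  g <- get_small_geometry()
  poses <- list(pose_params(tz = 6), pose_params(tz = 6))
  beats <- make_beats(poses, snr_db = 30, n_reps = 1, seed = 2)
  single <- correct_pose(beats[[1]], g$heart, g$torso, g$frame, g$bounds)
  fits <- correct_all_beats(beats, g$heart, g$torso, g$frame, g$bounds)
  expect_s3_class(fits, "pose_fit_list")
  expect_equal(coef(fits)[1, ], unclass(coef(single)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical copies of one beat yield identical poses
  same <- correct_all_beats(beats[c(1, 1)], g$heart, g$torso, g$frame,
                            g$bounds)
  expect_identical(coef(same)[1, ], coef(same)[2, ])
  # a corrupt beat is recorded as a failure without aborting the batch
  bad <- beats[[1]]
  bad$x <- bad$x[-1, ]
  mixed <- correct_all_beats(list(beats[[1]], bad), g$heart, g$torso, g$frame,
                             g$bounds)
  expect_s3_class(mixed[[1]], "pose_fit")
  expect_s3_class(mixed[[2]], "try-error")
  expect_equal(summary(mixed)$n_failed, 1)
})

test_that("estimated vertical translations track a noiseless trajectory", {
  g <- get_small_geometry()
  poses <- respiratory_trajectory(6, z_amplitude = 15,
                                  pitch_amplitude = 5 * pi / 180,
                                  bounds = g$bounds)
  beats <- make_beats(poses)
  fits <- correct_all_beats(beats, g$heart, g$torso, g$frame, g$bounds)
  tz_true <- vapply(poses, function(p) p[["tz"]], 0)
  tz_hat <- coef(fits)[, "tz"]
  expect_gt(stats::cor(tz_true, tz_hat), 0.95)
})

test_that("pose_fit methods expose coefficients, predictions and residuals", {
  g <- get_small_geometry()
  beat <- make_beats(list(pose_params(tz = 10)), snr_db = 30)[[1]]
  fit <- correct_pose(beat, g$heart, g$torso, g$frame, g$bounds)
  expect_s3_class(coef(fit), "pose_params")
  expect_equal(dim(predict(fit)), dim(beat$y))
  expect_equal(residuals(fit),
               zero_reference(beat$y) - zero_reference(fitted(fit)))
  s <- summary(fit)
  expect_s3_class(s, "summary.pose_fit")
  expect_lt(s$bsp_rel_err, 0.05)
  expect_output(print(fit), "objective")
})
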