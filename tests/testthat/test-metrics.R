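test_that("moving average matches hand values and a naive loop oracle", {
  # constant signal is unchanged, including at the edges
  const <- matrix(2.5, 3, 50)
  expect_equal(moving_average(const, 20, 1000), const)
  # unit impulse at 1000 Hz spreads into a 20-sample boxcar of height 1/20
  imp <- matrix(0, 1, 100)
  imp[1, 50] <- 1
  sm <- moving_average(imp, 20, 1000)
  expect_equal(sum(sm > 0), 20)
  expect_equal(max(sm), 1 / 20)
  expect_equal(sum(sm), 1)
  # random signal against an explicit sliding-window mean
  set.seed(13)
  s <- matrix(rnorm(2 * 40), 2, 40)
  out <- moving_average(s, 7, 1000)
  w <- 7; hl <- floor((w - 1) / 2); hr <- w - 1 - hl
  for (ch in 1:2) for (t in 1:40) {
    idx <- max(1, t - hl):min(40, t + hr)
    expect_equal(out[ch, t], mean(s[ch, idx]), tolerance = 1e-12)
  }
  # invariances: channel permutation and additive constants commute
  expect_equal(moving_average(s[2:1, ], 7, 1000), out[2:1, ])
  expect_equal(moving_average(s + 3, 7, 1000), out + 3, tolerance = 1e-12)
  expect_error(moving_average(s, 100, 1000), "longer than the signal")
  expect_error(moving_average(s, 0, 1000), "at least one sample")
})

test_that("QRS extraction truncates both signals and preserves metadata", {
  b <- beat_recording(matrix(rnorm(40), 4, 10), matrix(rnorm(60), 6, 10),
                      fs = 500, qrs_window = c(3, 8), beat_id = 2, rep = 3,
                      true_pose = pose_params(tz = 1))
  q <- extract_qrs(b)
  expect_equal(ncol(q$x), 6)
  expect_equal(q$x, b$x[, 3:8])
  expect_equal(q$y, b$y[, 3:8])
  expect_equal(q$beat_id, 2L)
  expect_equal(q$true_pose, b$true_pose)
  # full-signal window is the identity
  full <- beat_recording(b$x, b$y, 500)
  expect_equal(extract_qrs(full)$x, b$x)
})

test_that("relative error matches its defining arithmetic and invariances", {
  y <- matrix(c(1, 0), 1, 2)
  expect_equal(relative_error(y, y), 0)
  expect_equal(relative_error(y, 0 * y), 1)
  expect_equal(relative_error(y, matrix(c(0, 1), 1, 2)), 2)
  set.seed(2)
  a <- matrix(rnorm(20), 4, 5)
  b <- matrix(rnorm(20), 4, 5)
  expect_equal(relative_error(3.7 * a, 3.7 * b), relative_error(a, b))
  expect_error(relative_error(a, b[, 1:3]), "shape")
  expect_error(relative_error(0 * a, b), "zero")
})

test_that("experiment evaluation scores forward, inverse and geometric errors", {
  g <- get_small_geometry()
  x <- synth_epicardial_potentials(g$heart, seed = 3)
  poses <- respiratory_trajectory(2, phases = c(0.4, 1))
  cache <- forward_cache(g$torso, g$heart)
  beats <- synthesize_beats(g$heart, g$torso, g$frame, poses, x,
                            snr_db = Inf, n_reps = 1, seed = 1, cache = cache)
  beats <- lapply(beats, preprocess_beat)
  # fits that recover the generating pose exactly
  fits <- structure(lapply(beats, function(b) {
    model <- transfer_at_pose(g$heart, g$torso, g$frame, b$true_pose,
                              cache = cache)
    structure(list(pose = b$true_pose, value = 0, value0 = 1, n_evals = 1L,
                   converged = TRUE, corrected_model = model, beat = b,
                   frame = g$frame, bounds = g$bounds),
              class = "pose_fit")
  }), class = "pose_fit_list")
  rep <- evaluate_experiment(beats, fits, g$heart, g$torso, g$frame,
                             grid = lambda_grid(30))
  pb <- rep$per_beat
  # corrected model equals the generating model with no noise
  expect_true(all(pb$bsp_rel_err_corrected < 1e-12))
  expect_true(all(pb$bsp_rel_err_nominal > pb$bsp_rel_err_corrected))
  # improvements are nominal minus corrected by definition
  expect_equal(pb$bsp_improvement,
               pb$bsp_rel_err_nominal - pb$bsp_rel_err_corrected)
  expect_equal(pb$egm_improvement,
               pb$egm_rel_err_nominal - pb$egm_rel_err_corrected)
  # geometric columns: corrected RMSD is zero, nominal reflects the pose
  expect_true(all(pb$rmsd_corrected < 1e-9))
  expect_true(all(pb$rmsd_nominal > 1))
  # summary is the arithmetic mean/sd of the per-beat rows
  m <- rep$summary
  expect_equal(m$mean[m$metric == "bsp_rel_err_nominal"],
               mean(pb$bsp_rel_err_nominal))
})
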