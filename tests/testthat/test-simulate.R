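test_that("respiratory trajectory is nominal at phase 0 and maximal at the ends", {
  poses <- respiratory_trajectory(5, z_amplitude = 20,
                                  pitch_amplitude = 0.2,
                                  phases = c(-1, -0.5, 0, 0.5, 1))
  expect_equal(as.numeric(poses[[3]]), rep(0, 6))
  expect_equal(poses[[5]][["tz"]], 20)
  expect_equal(poses[[5]][["theta"]], 0.2)
  # even in phase
  expect_equal(unclass(poses[[1]]), unclass(poses[[5]]))
  # displacement nondecreasing in |phase|
  tz <- vapply(poses, function(p) p[["tz"]], 0)
  expect_true(all(diff(tz[3:5]) >= 0))
  expect_error(respiratory_trajectory(3, phases = c(0, 0.5, 1.2)), "phases")
})

test_that("epicardial source surrogate activates along geodesic delays", {
  g <- get_small_geometry()
  pac <- 7L
  x <- synth_epicardial_potentials(g$heart, pacing_node = pac, speed = 1.2,
                                   seed = 4)
  delay <- attr(x, "activation_ms")
  expect_equal(delay[pac], 0)  # pacing node is earliest
  expect_true(all(delay >= 0))
  # 1-Lipschitz in graph distance / speed: independent igraph recomputation
  f <- g$heart$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  w <- sqrt(rowSums((g$heart$nodes[e[, 1], ] - g$heart$nodes[e[, 2], ])^2))
  gr <- igraph::graph_from_edgelist(e, directed = FALSE)
  D <- igraph::distances(gr, weights = w)
  for (k in 1:50) {
    ij <- sample(nrow(g$heart$nodes), 2)
    expect_lte(abs(delay[ij[1]] - delay[ij[2]]),
               D[ij[1], ij[2]] / 1.2 + 1e-9)
  }
  # deterministic given the seed
  x2 <- synth_epicardial_potentials(g$heart, pacing_node = pac, speed = 1.2,
                                    seed = 4)
  expect_identical(x, x2)
})

test_that("noise calibration hits the requested SNR exactly", {
  g <- get_small_geometry()
  x <- synth_epicardial_potentials(g$heart, seed = 2)
  poses <- respiratory_trajectory(2, phases = c(-1, 0.5))
  cache <- forward_cache(g$torso, g$heart)
  beats <- synthesize_beats(g$heart, g$torso, g$frame, poses, x, snr_db = 30,
                            n_reps = 3, seed = 9, cache = cache)
  expect_length(beats, 6)
  for (b in beats) {
    y0 <- forward_map(transfer_at_pose(g$heart, g$torso, g$frame, b$true_pose,
                                       cache = cache), b$x)
    idx <- b$qrs_window[1]:b$qrs_window[2]
    snr <- 10 * log10(mean(y0[, idx]^2) / mean((b$y - y0)[, idx]^2))
    expect_equal(snr, 30, tolerance = 0.1)
  }
  # infinite SNR disables noise entirely
  clean <- synthesize_beats(g$heart, g$torso, g$frame, poses, x,
                            snr_db = Inf, n_reps = 1, seed = 9, cache = cache)
  y0 <- forward_map(transfer_at_pose(g$heart, g$torso, g$frame,
                                     poses[[1]], cache = cache), x)
  expect_identical(clean[[1]]$y, y0)
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  g <- get_small_geometry()
  x <- synth_epicardial_potentials(g$heart, seed = 2)
  poses <- respiratory_trajectory(2, phases = c(0, 1))
  cache <- forward_cache(g$torso, g$heart)
  b1 <- synthesize_beats(g$heart, g$torso, g$frame, poses, x, n_reps = 2,
                         seed = 5, cache = cache)
  b2 <- synthesize_beats(g$heart, g$torso, g$frame, poses, x, n_reps = 2,
                         seed = 5, cache = cache)
  expect_identical(lapply(b1, `[[`, "y"), lapply(b2, `[[`, "y"))
  b3 <- synthesize_beats(g$heart, g$torso, g$frame, poses, x, n_reps = 2,
                         seed = 6, cache = cache)
  expect_false(identical(b1[[1]]$y, b3[[1]]$y))
  # repetitions within a dataset are independent draws
  expect_false(identical(b1[[1]]$y, b1[[2]]$y))
})

test_that("beat_recording validates its window and dimensions", {
  x <- matrix(0, 4, 10)
  y <- matrix(0, 6, 10)
  b <- beat_recording(x, y, fs = 1000)
  expect_equal(b$qrs_window, c(1L, 10L))
  expect_error(beat_recording(x, y[, 1:5], 1000), "same number")
  expect_error(beat_recording(x, y, 1000, qrs_window = c(0, 10)), "window")
  expect_error(beat_recording(x, y, -1), "positive")
})
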