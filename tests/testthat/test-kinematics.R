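test_that("anatomical_frame computes anchor centroid and unit septal axis", {
  nodes <- rbind(c(0, 0, 10), c(0, 0, -10), c(1, 0, 0), c(-1, 0, 0),
                 c(0, 2, 0), c(0, 0, 0), c(2, 0, 0), c(0, 2, 0.5),
                 c(1, 1, -3), c(0, 0, -5))
  faces <- tetra_mesh()$faces  # frame construction does not need a closed mesh
  mk <- function(base, apex) {
    heart <- structure(list(nodes = nodes, faces = faces, name = "pts"),
                       class = "trimesh")
    anatomical_frame(heart, base, apex)
  }
  f1 <- mk(1, 2)
  expect_equal(f1$anchor, c(0, 0, 10))
  expect_equal(f1$septal_axis, c(0, 0, -1))
  f2 <- mk(c(3, 4), 10)
  expect_equal(f2$anchor, c(0, 0, 0))
  expect_equal(f2$septal_axis, c(0, 0, -1))
  f3 <- mk(c(6, 7, 5), 9)  # centroid (2/3, 2/3, 0), arithmetic-mean oracle
  expect_equal(f3$anchor, colMeans(nodes[c(6, 7, 5), ]))
  expect_equal(f3$anchor[1:2], c(2 / 3, 2 / 3))
  expect_error(mk(6, 6), "coincides")
})

test_that("pose_to_transform: identity, half-turn, and quaternion oracle", {
  heart <- mesh_icosphere(1, 10, center = c(0, 0, 5))
  frame <- anatomical_frame(heart, which.max(heart$nodes[, 3]),
                            which.min(heart$nodes[, 3]))
  # zero pose (axis at its own nominal spherical angles) -> identity
  tr0 <- pose_to_transform(pose_zero(), frame)
  expect_equal(tr0$R, diag(3))
  expect_equal(tr0$t, c(0, 0, 0))

  # half-turn roll about nominal axis (0,0,-1) through the origin
  frame2 <- structure(list(anchor = c(0, 0, 0), apex = c(0, 0, -1),
                           septal_axis = c(0, 0, -1)),
                      class = "anatomical_frame")
  tr <- pose_to_transform(pose_params(rho = pi), frame2)
  expect_equal(as.numeric(tr$R %*% c(1, 0, 0)), c(-1, 0, 0), tolerance = 1e-12)

  # arbitrary poses against an independent quaternion composition
  set.seed(7)
  for (k in 1:100) {
    p <- pose_params(theta = runif(1, -1, 1), phi = runif(1, -1, 1),
                     rho = runif(1, -pi, pi))
    u <- frame$septal_axis
    tr <- pose_to_transform(p, frame)
    # oracle: q_align * q_roll
    q_roll <- quat_from_axis_angle(u, p[["rho"]])
    sa <- acos(min(1, max(-1, u[3]))); az <- atan2(u[2], u[1])
    v <- c(sin(sa + p[["theta"]]) * cos(az + p[["phi"]]),
           sin(sa + p[["theta"]]) * sin(az + p[["phi"]]),
           cos(sa + p[["theta"]]))
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    q_align <- quat_from_axis_angle(cr, atan2(sqrt(sum(cr^2)), sum(u * v)))
    q <- quat_mult(q_align, q_roll)
    w <- rnorm(3)
    expect_equal(as.numeric(tr$R %*% w), quat_rotate(q, w), tolerance = 1e-9)
    # orthonormality and orientation
    expect_lt(max(abs(crossprod(tr$R) - diag(3))), 1e-12)
    expect_equal(det(tr$R), 1, tolerance = 1e-12)
  }
})

test_that("transformed septal axis lands at the offset spherical angles", {
  g <- get_small_geometry()
  sa0 <- acos(g$frame$septal_axis[3])
  az0 <- atan2(g$frame$septal_axis[2], g$frame$septal_axis[1])
  set.seed(11)
  for (k in 1:20) {
    p <- pose_params(tx = runif(1, -5, 5), tz = runif(1, -5, 5),
                     theta = runif(1, -0.4, 0.4), phi = runif(1, -0.4, 0.4),
                     rho = runif(1, -0.4, 0.4))
    fr2 <- ecgpose:::apply_pose_frame(g$frame, p)
    expect_equal(acos(fr2$septal_axis[3]), sa0 + p[["theta"]],
                 tolerance = 1e-9)
    expect_equal(atan2(fr2$septal_axis[2], fr2$septal_axis[1]),
                 az0 + p[["phi"]], tolerance = 1e-9)
  }
})

test_that("apply_pose is rigid and roll composes to identity", {
  g <- get_small_geometry()
  heart <- g$heart
  p <- pose_params(tx = 3, ty = -4, tz = 10, theta = 0.2, phi = -0.3,
                   rho = 0.5)
  moved <- apply_pose(heart, g$frame, p)
  # edge lengths preserved
  e <- heart$faces[, 1:2]
  len0 <- sqrt(rowSums((heart$nodes[e[, 1], ] - heart$nodes[e[, 2], ])^2))
  len1 <- sqrt(rowSums((moved$nodes[e[, 1], ] - moved$nodes[e[, 2], ])^2))
  expect_equal(len1, len0, tolerance = 1e-9)
  # enclosed volume preserved (signed-volume oracle)
  expect_equal(oracle_signed_volume(moved$nodes, moved$faces),
               oracle_signed_volume(heart$nodes, heart$faces),
               tolerance = 1e-9)
  # pure vertical translation moves RMSD by exactly its magnitude
  shifted <- apply_pose(heart, g$frame, pose_params(tz = 22.7))
  expect_equal(mesh_rmsd(shifted, heart), 22.7, tolerance = 1e-9)
  # roll then -roll is the identity
  back <- apply_pose(apply_pose(heart, g$frame, pose_params(rho = 0.7)),
                     g$frame, pose_params(rho = -0.7))
  expect_lt(mesh_rmsd(back, heart), 1e-9)
  # identity pose returns the very same geometry
  expect_identical(apply_pose(heart, g$frame, pose_zero())$nodes, heart$nodes)
})

test_that("compute_bounds certifies a feasible box and honors preconditions", {
  torso <- mesh_icosphere(1, 100, name = "outer")
  heart <- mesh_icosphere(1, 10, name = "inner")
  # anchor at the sphere center (centroid of two antipodal nodes), so
  # rotations leave the sphere invariant
  frame <- anatomical_frame(heart, c(which.max(heart$nodes[, 3]),
                                     which.min(heart$nodes[, 3])),
                            which.min(heart$nodes[, 3]))
  b <- compute_bounds(heart, torso, frame,
                      candidate_lower = c(rep(-200, 3), rep(-pi, 3)),
                      candidate_upper = c(rep(200, 3), rep(pi, 3)),
                      margin_mm = 2)
  # identity pose is inside
  expect_true(in_bounds(pose_zero(), b))
  # translations shrink below the analytic clearance (90 mm center shift)
  expect_true(all(b$upper[1:3] < 90))
  expect_true(all(b$lower[1:3] > -90))
  expect_gt(b$upper["tz"], 10)
  # rotations of a sphere are unconstrained within the candidate
  expect_equal(unname(b$upper[4:6]), rep(pi, 3))
  expect_equal(unname(b$lower[4:6]), rep(-pi, 3))
  # every corner of the certified box is intersection-free
  corners <- as.matrix(expand.grid(rep(list(c(1, 2)), 6)))
  for (i in seq_len(nrow(corners))) {
    p <- ifelse(corners[i, ] == 1, b$lower, b$upper)
    expect_false(surfaces_intersect(apply_pose(heart, frame, as_pose(p)),
                                    torso))
  }
  # nominal heart touching the wall is an error
  touching <- heart
  touching$nodes <- sweep(heart$nodes, 2, c(91, 0, 0), "+")
  expect_error(compute_bounds(touching, torso, frame), "intersects")
})
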