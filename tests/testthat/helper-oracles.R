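# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately naive (loops, brute force, alternative
# formulations) and never call the code paths they check.

tetra_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
          name = "tetra")
}

# 12-triangle unit cube surface (closed, outward)
cube_faces <- rbind(
  c(1, 3, 2), c(1, 4, 3),  # bottom (z = 0)
  c(5, 6, 7), c(5, 7, 8),  # top (z = 1)
  c(1, 2, 6), c(1, 6, 5),  # front (y = 0)
  c(2, 3, 7), c(2, 7, 6),  # right
  c(3, 4, 8), c(3, 8, 7),  # back
  c(4, 1, 5), c(4, 5, 8))  # left
cube_nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

cube_mesh <- function() trimesh(cube_nodes, cube_faces, name = "cube")

# signed volume by explicit determinant sum (oracle for orientation checks)
oracle_signed_volume <- function(nodes, faces) {
  s <- 0
  for (k in seq_len(nrow(faces))) {
    m <- t(nodes[faces[k, ], ])
    s <- s + det(m) / 6
  }
  s
}

# naive parity ray casting with a fixed irrational direction (oracle for
# point-in-mesh; assumes no degenerate hits for the meshes used in tests)
oracle_point_inside <- function(p, nodes, faces,
                                dir = c(0.57735, 0.311, 0.754)) {
  dir <- dir / sqrt(sum(dir^2))
  hits <- 0
  for (k in seq_len(nrow(faces))) {
    v0 <- nodes[faces[k, 1], ]; v1 <- nodes[faces[k, 2], ]
    v2 <- nodes[faces[k, 3], ]
    e1 <- v1 - v0; e2 <- v2 - v0
    h <- c(dir[2] * e2[3] - dir[3] * e2[2], dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    s <- p - v0
    u <- sum(s * h) / a
    if (u < 0 || u > 1) next
    q <- c(s[2] * e1[3] - s[3] * e1[2], s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    v <- sum(dir * q) / a
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * q) / a
    if (t > 1e-12) hits <- hits + 1
  }
  hits %% 2 == 1
}

# quaternion utilities (oracle for rotation composition)
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}
quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3], a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}
quat_rotate <- function(q, v) {
  qv <- c(0, v)
  r <- quat_mult(quat_mult(q, qv), c(q[1], -q[2:4]))
  r[2:4]
}

# small synthetic geometry for fast end-to-end tests
small_geometry <- function() {
  heart <- synthetic_heart_mesh(1)
  torso <- synthetic_torso_mesh(1)
  frame <- synthetic_frame(heart)
  bounds <- compute_bounds(heart, torso, frame)
  list(heart = heart, torso = torso, frame = frame, bounds = bounds)
}

# memoized across tests within a file run
.small_geom_env <- new.env()
get_small_geometry <- function() {
  if (is.null(.small_geom_env$g)) .small_geom_env$g <- small_geometry()
  .small_geom_env$g
}

sort_faces <- function(f) f[do.call(order, as.data.frame(f)), ]
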