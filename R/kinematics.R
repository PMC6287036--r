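#' Six-parameter rigid heart pose
#'
#' A pose is the six-vector `(tx, ty, tz, theta, phi, rho)`: translation of
#' the atrial anchor point in mm along the X (left), Y (posterior) and Z
#' (superior) axes, and three angles in radians. `theta` (pitch) and `phi`
#' (yaw) move the septal axis: the axis is rotated so that its inclination
#' from +Z changes by `theta` and its azimuth from +X in the axial (X/Y)
#' plane changes by `phi`, relative to the nominal axis of the anatomical
#' frame. `rho` (roll) spins the heart about its nominal septal axis. The
#' all-zero pose is therefore the identity (the nominal geometry). Angles are
#' wrapped to (-pi, pi].
#'
#' @param tx,ty,tz translation in mm.
#' @param theta,phi,rho pitch/yaw/roll offsets in radians.
#' @return named numeric vector of class `pose_params`.
#' @export
pose_params <- function(tx = 0, ty = 0, tz = 0, theta = 0, phi = 0, rho = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, theta = theta, phi = phi, rho = rho)
  p[4:6] <- wrap_angle(p[4:6])
  structure(p, class = "pose_params")
}

#' @rdname pose_params
#' @export
pose_zero <- function() pose_params()

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

as_pose <- function(p) {
  if (inherits(p, "pose_params")) return(p)
  p <- as.numeric(p)
  if (length(p) != 6) stop("a pose has exactly 6 parameters")
  do.call(pose_params, as.list(p))
}

#' @export
print.pose_params <- function(x, ...) {
  cat(sprintf("pose: t = (%.3f, %.3f, %.3f) mm, pitch %.3f, yaw %.3f, roll %.3f rad\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

#' Anatomical reference frame of the heart
#'
#' The frame anchors the pose parameterization: the anchor point is the
#' centroid of a designated set of atrial/base nodes, and the septal axis is
#' the unit vector from that anchor through the septum to the apex node.
#' Rotations are applied about the anchor; roll spins about the septal axis.
#'
#' @param heart heart [trimesh].
#' @param base_node_ids nonempty vector of node indices whose centroid defines
#'   the anchor (atrial/base region).
#' @param apex_node_id index of the apex node.
#' @return object of class `anatomical_frame` with `anchor`, `apex`,
#'   `septal_axis` (unit vector).
#' @export
anatomical_frame <- function(heart, base_node_ids, apex_node_id) {
  if (!length(base_node_ids)) stop("base node set is empty")
  if (min(base_node_ids) < 1 || max(base_node_ids) > nrow(heart$nodes) ||
      apex_node_id < 1 || apex_node_id > nrow(heart$nodes))
    stop("frame node indices out of range")
  anchor <- colMeans(heart$nodes[base_node_ids, , drop = FALSE])
  apex <- heart$nodes[apex_node_id, ]
  d <- apex - anchor
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("apex coincides with the anchor point")
  structure(list(anchor = anchor, apex = apex, septal_axis = d / len,
                 base_node_ids = as.integer(base_node_ids),
                 apex_node_id = as.integer(apex_node_id)),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical frame: anchor (%.2f, %.2f, %.2f) mm, septal axis (%.3f, %.3f, %.3f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$septal_axis[1], x$septal_axis[2], x$septal_axis[3]))
  invisible(x)
}

# Rodrigues rotation matrix about unit axis
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal (geodesic) rotation taking unit vector a onto unit vector b;
# antiparallel case: half-turn about an axis perpendicular to a, chosen as
# the projection of +X onto that plane (+Y fallback when a is along X).
rotation_between <- function(a, b) {
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(cr^2))
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    ref <- c(1, 0, 0)
    if (abs(sum(a * ref)) > 0.9) ref <- c(0, 1, 0)
    perp <- ref - sum(ref * a) * a
    return(rotation_about(perp, pi))
  }
  rotation_about(cr / s, atan2(s, d))
}

spherical_angles <- function(u) {
  c(theta = acos(max(-1, min(1, u[3]))), phi = atan2(u[2], u[1]))
}

spherical_to_vec <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Rigid transform realizing a pose
#'
#' Composition convention: (1) roll by `rho` about the nominal septal axis
#' through the anchor, (2) reorient the nominal septal axis onto the
#' direction with spherical angles `(theta0 + theta, phi0 + phi)` — where
#' `(theta0, phi0)` are the nominal axis' own inclination/azimuth — via the
#' minimal rotation about the anchor, (3) translate by `(tx, ty, tz)`. The
#' rotation part is orthonormal with determinant +1 and the anchor maps to
#' `anchor + t`.
#'
#' @param p a [pose_params] (or length-6 numeric).
#' @param frame an [anatomical_frame].
#' @return list with `R` (3 x 3 rotation), `t` (length-3 translation of the
#'   anchor) and `anchor`; the map is `x -> R (x - anchor) + anchor + t`.
#' @export
pose_to_transform <- function(p, frame) {
  p <- as_pose(p)
  u <- frame$septal_axis
  sa <- spherical_angles(u)
  v <- spherical_to_vec(sa[1] + p[["theta"]], sa[2] + p[["phi"]])
  R <- rotation_between(u, v) %*% rotation_about(u, p[["rho"]])
  list(R = R, t = c(p[["tx"]], p[["ty"]], p[["tz"]]), anchor = frame$anchor)
}

#' Apply a pose to the heart mesh
#'
#' Maps every node through the rigid transform of [pose_to_transform()];
#' faces are unchanged, so all edge lengths and the enclosed volume are
#' preserved (up to floating point).
#'
#' @inheritParams pose_to_transform
#' @param heart heart [trimesh].
#' @return the transformed [trimesh].
#' @export
apply_pose <- function(heart, frame, p) {
  p <- as_pose(p)
  if (all(p == 0)) return(heart)  # identity pose: bit-identical geometry
  tr <- pose_to_transform(p, frame)
  centered <- sweep(heart$nodes, 2, tr$anchor)
  heart$nodes <- sweep(centered %*% t(tr$R), 2, tr$anchor + tr$t, "+")
  heart
}

# transform a frame along with the mesh (used to check axis angles)
apply_pose_frame <- function(frame, p) {
  tr <- pose_to_transform(p, frame)
  mapp <- function(x) as.numeric(tr$R %*% (x - tr$anchor) + tr$anchor + tr$t)
  anchor <- mapp(frame$anchor)
  apex <- mapp(frame$apex)
  d <- apex - anchor
  structure(list(anchor = anchor, apex = apex,
                 septal_axis = d / sqrt(sum(d^2)),
                 base_node_ids = frame$base_node_ids,
                 apex_node_id = frame$apex_node_id),
            class = "anatomical_frame")
}

#' Pose bounds (the feasible hyper-rectangle)
#'
#' Per-dimension box constraints on the six pose parameters, certified so
#' that no pose inside the box drives the heart into the torso surface. The
#' box is found by shrinking a user-supplied candidate box: each dimension is
#' first limited on its own by bisection against the intersection test, then
#' the whole box is scaled down until all corner poses and an axis grid of
#' `grid_density` poses per dimension are intersection-free; finally a safety
#' margin is removed from the translation extents. The identity pose is
#' always inside the returned bounds.
#'
#' @param heart,torso closed [trimesh] objects; the nominal heart must be
#'   strictly inside the torso.
#' @param frame an [anatomical_frame].
#' @param candidate_lower,candidate_upper length-6 candidate box (defaults:
#'   +/- 30 mm translations, +/- 0.35 rad angles — a generous prior for
#'   respiratory heart motion; widen it for grossly misregistered geometry).
#' @param grid_density certification grid points per dimension (default 5).
#' @param margin_mm safety clearance subtracted from translation extents (mm).
#' @return object of class `pose_bounds` with `lower` and `upper` poses.
#' @export
compute_bounds <- function(heart, torso, frame,
                           candidate_lower = c(-30, -30, -30,
                                               -0.35, -0.35, -0.35),
                           candidate_upper = c(30, 30, 30, 0.35, 0.35, 0.35),
                           grid_density = 5, margin_mm = 2) {
  if (surfaces_intersect(heart, torso))
    stop("nominal heart already intersects the torso surface")
  lo <- as.numeric(candidate_lower)
  hi <- as.numeric(candidate_upper)
  if (any(lo > 0) || any(hi < 0))
    stop("candidate box must contain the identity pose")
  feasible <- function(p6) {
    !surfaces_intersect(apply_pose(heart, frame, as_pose(p6)), torso)
  }
  # per-dimension bisection, other parameters at zero
  for (d in 1:6) {
    for (side in c("lo", "hi")) {
      ext <- if (side == "lo") lo[d] else hi[d]
      if (ext == 0) next
      probe <- function(s) {
        p <- numeric(6)
        p[d] <- s * ext
        feasible(p)
      }
      if (!probe(1)) {
        a <- 0; b <- 1
        for (k in 1:12) {
          m <- (a + b) / 2
          if (probe(m)) a <- m else b <- m
        }
        if (side == "lo") lo[d] <- a * ext else hi[d] <- a * ext
      }
    }
  }
  # joint certification: shrink extents until corner poses and per-dimension
  # grids are all intersection-free; translations are shrunk first, rotations
  # only if translations alone cannot certify the box
  corner_ok <- function(st, sr) {
    s <- c(rep(st, 3), rep(sr, 3))
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
    for (i in seq_len(nrow(corners))) {
      p <- ifelse(corners[i, ] == 1, hi, lo) * s
      if (!feasible(p)) return(FALSE)
    }
    for (d in 1:6) {
      for (g in seq(lo[d], hi[d], length.out = grid_density) * s[d]) {
        p <- numeric(6)
        p[d] <- g
        if (!feasible(p)) return(FALSE)
      }
    }
    TRUE
  }
  st <- sr <- 1
  while (!corner_ok(st, sr) && st > 0.05) st <- st * 0.85
  if (st <= 0.05) {
    st <- 1
    while (!corner_ok(st, sr) && sr > 0.05) {
      sr <- sr * 0.85
      st <- st * 0.85
    }
  }
  lo <- lo * c(rep(st, 3), rep(sr, 3))
  hi <- hi * c(rep(st, 3), rep(sr, 3))
  lo[1:3] <- pmin(lo[1:3] + margin_mm, 0)
  hi[1:3] <- pmax(hi[1:3] - margin_mm, 0)
  nm <- c("tx", "ty", "tz", "theta", "phi", "rho")
  # bounds are plain (unwrapped) limits: lower angles may legitimately be -pi
  structure(list(lower = stats::setNames(lo, nm),
                 upper = stats::setNames(hi, nm)),
            class = "pose_bounds")
}

#' @export
print.pose_bounds <- function(x, ...) {
  cat("pose bounds (hyper-rectangle):\n")
  m <- rbind(lower = unclass(x$lower), upper = unclass(x$upper))
  print(round(m, 4))
  invisible(x)
}

#' Is a pose inside the bounds?
#'
#' @param p a [pose_params].
#' @param bounds a `pose_bounds` object.
#' @param tol slack for floating-point boundary poses.
#' @return logical scalar.
#' @export
in_bounds <- function(p, bounds, tol = 1e-9) {
  p <- as_pose(p)
  all(p >= unclass(bounds$lower) - tol & p <= unclass(bounds$upper) + tol)
}
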