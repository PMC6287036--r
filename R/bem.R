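#' Epicardial-to-torso transfer matrix (boundary element method)
#'
#' Assembles the linear map `A` from heart-surface node potentials to
#' torso-surface node potentials for a homogeneous volume conductor bounded
#' by the torso surface (zero normal current — the body is insulated) and
#' containing the closed epicardial surface. Discretization is vertex
#' collocation with piecewise-linear potentials on triangles; the
#' double-layer (solid-angle) integrals are analytic and the diagonal terms
#' are fixed by the row-sum identity, so a constant epicardial potential maps
#' exactly to the same constant on the torso (every row of `A` sums to 1).
#' The transfer matrix is independent of the (single, homogeneous)
#' conductivity value.
#'
#' Internally the Green's-identity block system couples the unknown torso
#' potentials and the unknown normal gradient on the heart surface; the
#' gradient is eliminated through the heart single-layer block and the
#' resulting square torso system is solved directly. If that system is
#' numerically rank deficient (degenerate geometry), the additive-constant
#' direction is removed by deflation before solving.
#'
#' @param heart,torso closed [trimesh] objects; the heart must lie strictly
#'   inside the torso with no intersection.
#' @param torso_blocks optional precomputed torso self-interaction blocks from
#'   [torso_self_blocks()]; pass when assembling many matrices for the same
#'   torso (the blocks do not depend on the heart pose).
#' @param heart_blocks optional precomputed heart self-interaction blocks from
#'   [heart_self_blocks()]. These are invariant under rigid motion of the
#'   heart, so the blocks of the nominal heart serve every pose.
#' @param check if `TRUE` (default) verify the containment precondition.
#' @return object of class `transfer_model`: `matrix` (torso nodes x heart
#'   nodes), `heart_id`, `torso_id`, `pose`, `conductivity`.
#' @export
assemble_transfer_matrix <- function(heart, torso, torso_blocks = NULL,
                                     heart_blocks = NULL, check = TRUE) {
  if (check) {
    inside <- .pts_in_mesh(heart$nodes, torso$nodes, torso$faces, 1e-9)
    if (any(inside != 1L)) stop("heart is not strictly inside the torso")
    if (surfaces_intersect(heart, torso))
      stop("heart and torso surfaces intersect")
  }
  if (is.null(torso_blocks)) torso_blocks <- torso_self_blocks(torso)
  if (is.null(heart_blocks)) heart_blocks <- heart_self_blocks(heart)

  D_BH <- .bem_dl_matrix(torso$nodes, heart$nodes, heart$faces)
  D_HB <- .bem_dl_matrix(heart$nodes, torso$nodes, torso$faces)
  S_BH <- .bem_sl_matrix(torso$nodes, heart$nodes, heart$faces)

  # torso collocation: (cI + D_BB) phi_B - D_BH phi_H + S_BH q_H = 0
  # diagonal from the constant-solution identity: rowsum(M_BB) = rowsum(D_BH)
  M_BB <- torso_blocks$D_BB
  diag(M_BB) <- rowSums(D_BH) - torso_blocks$offdiag_rowsum
  # heart collocation: (cI - D_HH) phi_H + D_HB phi_B + S_HH q_H = 0
  T_HH <- -heart_blocks$D_HH
  diag(T_HH) <- -rowSums(D_HB) - heart_blocks$offdiag_rowsum_neg

  G <- S_BH %*% heart_blocks$S_HH_inv
  K <- M_BB - G %*% D_HB
  L <- D_BH + G %*% T_HH
  rc <- rcond(K)
  if (rc < 1e-12) {
    if (rc == 0) stop("singular BEM system: degenerate geometry")
    # deflate the additive-constant direction
    n <- nrow(K)
    K <- K + tcrossprod(rep(1 / n, n), rep(1, n))
  }
  A <- solve(K, L)
  structure(list(matrix = A, heart_id = heart$name, torso_id = torso$name,
                 pose = pose_zero(), conductivity = 1),
            class = "transfer_model")
}

#' @rdname assemble_transfer_matrix
#' @export
torso_self_blocks <- function(torso) {
  D_BB <- .bem_dl_matrix(torso$nodes, torso$nodes, torso$faces)
  diag(D_BB) <- 0
  list(D_BB = D_BB, offdiag_rowsum = rowSums(D_BB))
}

#' @rdname assemble_transfer_matrix
#' @export
heart_self_blocks <- function(heart) {
  D_HH <- .bem_dl_matrix(heart$nodes, heart$nodes, heart$faces)
  diag(D_HH) <- 0
  S_HH <- .bem_sl_matrix(heart$nodes, heart$nodes, heart$faces)
  list(D_HH = D_HH, offdiag_rowsum_neg = rowSums(-D_HH),
       S_HH_inv = solve(S_HH))
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("transfer model: %d torso nodes x %d heart nodes (heart '%s', torso '%s')\n",
              nrow(x$matrix), ncol(x$matrix), x$heart_id, x$torso_id))
  rs <- rowSums(x$matrix)
  cat(sprintf("  row-sum deviation from 1 in [%.2e, %.2e]; pose t = (%.2f, %.2f, %.2f) mm\n",
              min(rs) - 1, max(rs) - 1, x$pose[1], x$pose[2], x$pose[3]))
  invisible(x)
}

#' Apply a forward model to heart potentials
#'
#' Computes torso potentials `y = A x`, column by column over time.
#'
#' @param model a `transfer_model`.
#' @param x heart potentials, nodes x time.
#' @return torso potentials, electrodes x time.
#' @export
forward_map <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(model$matrix))
    stop("x has ", nrow(x), " rows but the model expects ",
         ncol(model$matrix), " heart nodes")
  model$matrix %*% x
}

#' Forward model cache
#'
#' Holds the pose-independent torso self-interaction blocks plus a pose-keyed
#' store of assembled transfer matrices, so repeated evaluations at the same
#' pose (as the optimizer performs) reuse the assembly. Poses are keyed after
#' rounding to 1e-9.
#'
#' @param torso torso [trimesh].
#' @param heart optional nominal heart [trimesh]; when given, the heart
#'   self-interaction blocks (rigid-motion invariant) are precomputed too.
#' @param max_entries maximum cached matrices before the store is cleared.
#' @return an environment used by [transfer_at_pose()] and the optimizer.
#' @export
forward_cache <- function(torso, heart = NULL, max_entries = 500) {
  env <- new.env(parent = emptyenv())
  env$torso_blocks <- torso_self_blocks(torso)
  env$heart_blocks <- if (!is.null(heart)) heart_self_blocks(heart)
  env$heart_id <- if (!is.null(heart)) heart$name
  env$store <- new.env(parent = emptyenv())
  env$n <- 0L
  env$max_entries <- max_entries
  env$hits <- 0L
  env
}

reset_pose_cache <- function(cache) {
  cache$store <- new.env(parent = emptyenv())
  cache$n <- 0L
  invisible(cache)
}

pose_key <- function(p) paste(sprintf("%.9f", as.numeric(p)), collapse = "|")

#' Transfer matrix at a pose
#'
#' Moves the heart to pose `p` and assembles the transfer matrix for the
#' displaced geometry — the map `p -> A(p)` whose smoothness the pose
#' optimizer exploits. Results are cached by pose key when a cache is given.
#'
#' @param heart,torso closed [trimesh] objects (nominal geometry).
#' @param frame an [anatomical_frame].
#' @param p a [pose_params].
#' @param bounds optional `pose_bounds`; a pose outside them is an error.
#' @param cache optional [forward_cache()] environment.
#' @param check verify heart-torso containment before assembly.
#' @return a `transfer_model` whose `pose` field records `p`.
#' @export
transfer_at_pose <- function(heart, torso, frame, p, bounds = NULL,
                             cache = NULL, check = FALSE) {
  p <- as_pose(p)
  if (!is.null(bounds) && !in_bounds(p, bounds))
    stop("pose outside the feasible bounds")
  key <- NULL
  if (!is.null(cache)) {
    key <- pose_key(p)
    got <- cache$store[[key]]
    if (!is.null(got)) {
      cache$hits <- cache$hits + 1L
      return(got)
    }
  }
  moved <- apply_pose(heart, frame, p)
  tb <- hb <- NULL
  if (!is.null(cache)) {
    tb <- cache$torso_blocks
    if (is.null(cache$heart_blocks) || !identical(cache$heart_id, heart$name)) {
      cache$heart_blocks <- heart_self_blocks(heart)
      cache$heart_id <- heart$name
    }
    hb <- cache$heart_blocks
  }
  model <- assemble_transfer_matrix(moved, torso, torso_blocks = tb,
                                    heart_blocks = hb, check = check)
  model$pose <- p
  if (!is.null(cache)) {
    if (cache$n >= cache$max_entries) reset_pose_cache(cache)
    cache$store[[key]] <- model
    cache$n <- cache$n + 1L
  }
  model
}

#' Zero-mean potential referencing
#'
#' Subtracts the spatial mean across channels at each time instant. The
#' volume-conductor potential is defined only up to an additive constant and
#' no reference electrode is singled out, so measured and synthesized
#' potentials are referenced to their spatial mean before any comparison
#' (objective, relative errors).
#'
#' @param y channels x time matrix.
#' @return matrix of the same shape with zero column means.
#' @export
zero_reference <- function(y) {
  y <- as.matrix(y)
  sweep(y, 2, colMeans(y))
}
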