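#' Logarithmic regularization-parameter grid
#'
#' Default grid for the L-curve: 100 values equally spaced on a log scale
#' between 1e-6 and 1.
#'
#' @param n number of grid points.
#' @param range length-2 positive range (smallest, largest).
#' @return strictly increasing numeric vector.
#' @export
lambda_grid <- function(n = 100, range = c(1e-6, 1)) {
  if (any(range <= 0)) stop("lambda range must be positive")
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Zero-order Tikhonov inverse solution
#'
#' Reconstructs heart-surface potentials from torso potentials as the
#' column-wise minimizer of `||Y - A X||^2 + lambda^2 ||X||^2`, i.e. the
#' solution of the normal equations `(A'A + lambda^2 I) X = A'Y`. The solve
#' goes through one SVD of `A`, which can be precomputed and reused across a
#' whole lambda grid.
#'
#' @param A forward matrix (electrodes x heart nodes).
#' @param Y torso potentials (electrodes x time).
#' @param lambda positive regularization parameter.
#' @param dec optional precomputed `svd(A)`.
#' @return heart potentials, nodes x time.
#' @export
tikhonov_solve <- function(A, Y, lambda, dec = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a positive scalar")
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(A)) stop("Y has ", nrow(Y), " rows, A has ", nrow(A))
  if (is.null(dec)) dec <- svd(A)
  f <- dec$d / (dec$d^2 + lambda^2)
  dec$v %*% (f * crossprod(dec$u, Y))
}

#' L-curve selection of the regularization parameter
#'
#' Computes, for each lambda on the grid, the residual norm
#' `||Y - A X(lambda)||_F` and solution norm `||X(lambda)||_F` over the whole
#' beat (all electrodes and time instances jointly, so one lambda serves the
#' whole beat), and picks the grid point of maximum discrete curvature of the
#' log-log curve (the L-curve corner). If the curve is degenerate (all norms
#' essentially equal) the smallest lambda is returned with a warning.
#'
#' @param A forward matrix.
#' @param Y torso potentials (electrodes x time).
#' @param grid increasing positive lambda grid (default [lambda_grid()]).
#' @return list with `lambda` (selected value, an element of the grid),
#'   `index`, and `table` — a data.frame of `lambda`, `residual_norm`,
#'   `solution_norm`, `curvature`.
#' @export
lcurve_select <- function(A, Y, grid = lambda_grid()) {
  if (!length(grid)) stop("empty lambda grid")
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0))
    stop("grid must be strictly increasing and positive")
  Y <- as.matrix(Y)
  dec <- svd(A)
  UtY <- crossprod(dec$u, Y)          # r x T
  uty2 <- rowSums(UtY^2)              # per singular direction
  out2 <- sum((Y - dec$u %*% UtY)^2)  # component outside range(A)
  d2 <- dec$d^2
  res <- sol <- numeric(length(grid))
  for (i in seq_along(grid)) {
    l2 <- grid[i]^2
    fr <- l2 / (d2 + l2)              # residual filter factors
    fs <- dec$d / (d2 + l2)           # solution filter factors
    res[i] <- sqrt(sum(fr^2 * uty2) + out2)
    sol[i] <- sqrt(sum(fs^2 * uty2))
  }
  lr <- log10(res)
  ls <- log10(sol)
  curv <- rep(NA_real_, length(grid))
  if (diff(range(lr)) < 1e-12 || diff(range(ls)) < 1e-12 ||
      !all(is.finite(c(lr, ls)))) {
    warning("degenerate L-curve: returning the smallest lambda")
    idx <- 1L
  } else {
    t <- log10(grid)
    n <- length(grid)
    # parametric curvature via central differences on the log-log curve
    d1x <- d1y <- d2x <- d2y <- rep(NA_real_, n)
    for (i in 2:(n - 1)) {
      h1 <- t[i] - t[i - 1]
      h2 <- t[i + 1] - t[i]
      d1x[i] <- (lr[i + 1] - lr[i - 1]) / (h1 + h2)
      d1y[i] <- (ls[i + 1] - ls[i - 1]) / (h1 + h2)
      d2x[i] <- 2 * (h1 * lr[i + 1] - (h1 + h2) * lr[i] + h2 * lr[i - 1]) /
        (h1 * h2 * (h1 + h2))
      d2y[i] <- 2 * (h1 * ls[i + 1] - (h1 + h2) * ls[i] + h2 * ls[i - 1]) /
        (h1 * h2 * (h1 + h2))
    }
    curv <- (d1x * d2y - d1y * d2x) / (d1x^2 + d1y^2)^1.5
    idx <- which.max(curv)
    if (!length(idx) || !is.finite(curv[idx])) {
      warning("degenerate L-curve: returning the smallest lambda")
      idx <- 1L
    }
  }
  list(lambda = grid[idx], index = idx,
       table = data.frame(lambda = grid, residual_norm = res,
                          solution_norm = sol, curvature = curv))
}

#' Inverse reconstruction with per-beat L-curve regularization
#'
#' Convenience wrapper: selects lambda by the L-curve over the whole beat and
#' returns the Tikhonov solution at that lambda.
#'
#' @inheritParams lcurve_select
#' @return list with `X` (nodes x time), `lambda`, `lcurve` (selection table).
#' @export
tikhonov_inverse <- function(A, Y, grid = lambda_grid()) {
  sel <- lcurve_select(A, Y, grid)
  X <- tikhonov_solve(A, Y, sel$lambda)
  list(X = X, lambda = sel$lambda, lcurve = sel$table)
}
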