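# Rewrapping schemes. Each unwrapping scheme has exactly one consistent
# inverse: lattice wrapping inverts LAT, displacement backtracing inverts
# TOR. Cross-pairing the two silently corrupts the trajectory, which is why
# both are exposed explicitly.

#' Lattice wrap: map coordinates back into the central cell
#'
#' \deqn{w_i = u_i - L_i\,\lfloor u_i/L_i + \alpha/2 \rfloor.}
#' With `alpha = 1` the central cell is `[-L/2, L/2)` (LAMMPS/NAMD), with
#' `alpha = 0` it is `[0, L)` (GROMACS). This is the consistent inverse of
#' [lat_unwrap()]: it assumes wrapped and unwrapped coordinates differ by an
#' integer number of box lengths at every frame. Applied to a TOR-unwrapped
#' trajectory it does \emph{not} recover the original wrapped trajectory
#' once a boundary crossing has occurred under box fluctuations.
#'
#' @param u numeric vector of coordinates (any real values).
#' @param L box edge length per frame (vector or scalar).
#' @param alpha cell convention, 0 or 1.
#' @return Numeric vector of wrapped coordinates inside the alpha-cell.
#' @examples
#' lattice_wrap(2.2, 1, alpha = 1)  # -> 0.2
#' @export
lattice_wrap <- function(u, L, alpha = 1) {
  alpha <- check_alpha(alpha)
  if (any(!is.finite(u))) stop("coordinates must be finite")
  if (any(L <= 0)) stop("box lengths must be strictly positive")
  u - L * floor(u / L + alpha / 2)
}

#' TOR-consistent rewrap: backtrace displacements into the cell
#'
#' Inverse of [tor_unwrap()]: reconstructs the wrapped trajectory
#' iteratively from the displacements of the unwrapped input,
#' \deqn{w_{i+1} = w_i + (u_{i+1}-u_i)
#'   - L_{i+1}\,\lfloor (w_i + u_{i+1}-u_i)/L_{i+1} + \alpha/2 \rfloor,}
#' with \eqn{w_0 = u_0}. Only the displacements of the unwrapped input are
#' consumed; image numbers are never inspected.
#'
#' @param u numeric vector of unwrapped coordinates; `u[1]` must lie inside
#'   the alpha-cell of `L[1]` (otherwise the data were probably produced by
#'   a different scheme, and the pairing is wrong).
#' @inheritParams lattice_wrap
#' @return Numeric vector of wrapped coordinates inside the alpha-cell.
#' @export
tor_rewrap <- function(u, L, alpha = 1) {
  alpha <- check_alpha(alpha)
  L <- check_series(u, L)
  n <- length(u)
  b <- cell_bounds(L[1L], alpha)
  if (u[1L] < b$lower || u[1L] >= b$upper)
    stop("first frame lies outside the central cell; ",
         "input does not look like a TOR-unwrapped trajectory ",
         "starting from a wrapped frame")
  w <- numeric(n)
  w[1L] <- u[1L]
  if (n > 1L) for (i in seq_len(n - 1L)) {
    x <- w[i] + (u[i + 1L] - u[i])
    w[i + 1L] <- x - L[i + 1L] * floor(x / L[i + 1L] + alpha / 2)
  }
  w
}

tor_rewrap_core <- function(U, L, alpha) {
  b <- cell_bounds(L[1L], alpha)
  if (any(U[1L, ] < b$lower | U[1L, ] >= b$upper))
    stop("first frame lies outside the central cell; ",
         "input does not look like a TOR-unwrapped trajectory ",
         "starting from a wrapped frame")
  W <- U
  n <- nrow(U)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    x <- W[i, ] + (U[i + 1L, ] - U[i, ])
    W[i + 1L, ] <- x - L[i + 1L] * floor(x / L[i + 1L] + alpha / 2)
  }
  W
}

#' Rewrap an unwrapped trajectory with the scheme-consistent wrap
#'
#' Dispatches [lattice_wrap()] (`scheme = "lat"`) or [tor_rewrap()]
#' (`scheme = "tor"`) over every particle and axis.
#'
#' @param traj an [unwrapped_trajectory()].
#' @param scheme `"tor"` or `"lat"`; defaults to the trajectory's own scheme
#'   tag when that tag is `"tor"` or `"lat"`/`"kv"`.
#' @param alpha cell convention, 0 or 1.
#' @return A [wrapped_trajectory()].
#' @export
rewrap <- function(traj, scheme = NULL, alpha = 1) {
  stopifnot(inherits(traj, "unwrapped_trajectory"))
  alpha <- check_alpha(alpha)
  if (is.null(scheme)) {
    scheme <- switch(traj$scheme, tor = "tor", lat = , kv = "lat",
                     stop("cannot infer rewrap scheme from tag '",
                          traj$scheme, "'; pass scheme explicitly"))
  }
  scheme <- match.arg(scheme, c("tor", "lat"))
  n <- traj$n_frames
  pos <- array(NA_real_, dim = dim(traj$positions))
  for (a in seq_len(traj$n_axes)) {
    U <- matrix(traj$positions[, , a], nrow = n)
    L <- traj$box$lengths[, a]
    pos[, , a] <- if (scheme == "lat") {
      matrix(lattice_wrap(as.vector(U), rep(L, ncol(U)), alpha), nrow = n)
    } else {
      tor_rewrap_core(U, L, alpha)
    }
  }
  wrapped_trajectory(pos, traj$box, alpha = alpha)
}
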