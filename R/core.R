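#' Per-frame orthorhombic box series
#'
#' Container for the edge lengths \eqn{L_i} of an orthorhombic simulation box
#' at every saved frame, together with the sampling interval \eqn{\Delta t}.
#' Under a barostat the box fluctuates frame to frame; all unwrapping schemes
#' in this package consume the box series alongside the particle coordinates.
#'
#' @param lengths numeric vector (one axis) or matrix with one row per frame
#'   and one column per axis; all entries must be strictly positive.
#' @param dt sampling interval between consecutive frames (time units,
#'   conventionally ps).
#' @return An object of class `"box_series"`: a list with elements
#'   `lengths` (frames x axes matrix), `dt`, `n_frames`, `n_axes`.
#' @examples
#' box_series(rep(2.5, 10), dt = 1)
#' @export
box_series <- function(lengths, dt = 1) {
  if (is.vector(lengths)) lengths <- matrix(as.numeric(lengths), ncol = 1L)
  lengths <- as.matrix(lengths)
  storage.mode(lengths) <- "double"
  if (nrow(lengths) < 1L) stop("box series needs at least one frame")
  if (!ncol(lengths) %in% 1:3) stop("n_axes must be 1, 2 or 3")
  if (anyNA(lengths) || any(!is.finite(lengths)))
    stop("box lengths must be finite")
  if (any(lengths <= 0)) {
    bad <- which(lengths <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive box length at frame %d, axis %d",
                 bad[1L], bad[2L]))
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  structure(list(lengths = unname(lengths), dt = as.numeric(dt),
                 n_frames = nrow(lengths), n_axes = ncol(lengths)),
            class = "box_series")
}

#' @export
print.box_series <- function(x, ...) {
  cat(sprintf("box_series: %d frames, %d axis(es), dt = %g\n",
              x$n_frames, x$n_axes, x$dt))
  cat(sprintf("  mean edge length(s): %s\n",
              paste(signif(colMeans(x$lengths), 6), collapse = ", ")))
  invisible(x)
}

# --- internal helpers ---------------------------------------------------

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !alpha %in% c(0, 1))
    stop("alpha must be 0 (cell [0, L)) or 1 (cell [-L/2, L/2))")
  as.numeric(alpha)
}

# Coerce positions into a frames x particles x axes double array.
as_positions <- function(positions, n_axes = NULL) {
  if (is.vector(positions) && is.numeric(positions))
    positions <- array(positions, dim = c(length(positions), 1L, 1L))
  if (is.matrix(positions))  # frames x axes, single particle
    positions <- array(positions, dim = c(nrow(positions), 1L, ncol(positions)))
  if (!is.array(positions) || length(dim(positions)) != 3L)
    stop("positions must be a vector, matrix or frames x particles x axes array")
  storage.mode(positions) <- "double"
  if (!is.null(n_axes) && dim(positions)[3L] != n_axes)
    stop(sprintf("positions have %d axes but box has %d",
                 dim(positions)[3L], n_axes))
  positions
}

check_box_match <- function(positions, box) {
  if (!inherits(box, "box_series")) stop("box must be a box_series")
  if (dim(positions)[1L] != box$n_frames)
    stop(sprintf("positions have %d frames but box has %d",
                 dim(positions)[1L], box$n_frames))
}

# Half-open central cell bounds for a given alpha.
cell_bounds <- function(L, alpha) {
  if (alpha == 1) list(lower = -L / 2, upper = L / 2)
  else list(lower = 0 * L, upper = L)
}

#' Wrapped trajectory under periodic boundary conditions
#'
#' Particle coordinates mapped into the central simulation cell at every
#' frame. The cell convention is set by `alpha`: `alpha = 1` for cells
#' fluctuating symmetrically around the origin, `[-L/2, L/2)` (LAMMPS/NAMD
#' convention), `alpha = 0` for corner-anchored cells `[0, L)` (GROMACS
#' convention). Intervals are half-open so that wrapping is idempotent and
#' boundary ownership is unambiguous.
#'
#' @param positions numeric vector (frames), matrix (frames x axes, one
#'   particle) or array (frames x particles x axes).
#' @param box a [box_series()] with matching frame count and axes.
#' @param alpha cell convention, 0 or 1.
#' @return Object of class `"wrapped_trajectory"` with elements `positions`
#'   (frames x particles x axes array), `box`, `alpha`, `n_frames`,
#'   `n_particles`, `n_axes`.
#' @seealso [validate_wrapped()], [unwrap()], [lattice_wrap()]
#' @export
wrapped_trajectory <- function(positions, box, alpha = 1) {
  alpha <- check_alpha(alpha)
  if (!inherits(box, "box_series")) stop("box must be a box_series")
  positions <- as_positions(positions, box$n_axes)
  check_box_match(positions, box)
  structure(list(positions = positions, box = box, alpha = alpha,
                 n_frames = dim(positions)[1L],
                 n_particles = dim(positions)[2L],
                 n_axes = dim(positions)[3L]),
            class = "wrapped_trajectory")
}

#' Unwrapped trajectory
#'
#' Particle coordinates allowed to traverse all of space, as produced by one
#' of the unwrapping schemes (or natively by a simulator). Lattice-view
#' trajectories may carry the integer image numbers \eqn{n_i} with
#' \eqn{u_i = w_i + n_i L_i}.
#'
#' @inheritParams wrapped_trajectory
#' @param scheme provenance tag: `"tor"`, `"lat"`, `"hlat"`, `"kv"` or
#'   `"native"` (generated unwrapped).
#' @param images optional integer array (frames x particles x axes) of image
#'   numbers (lattice-view trajectories only).
#' @return Object of class `"unwrapped_trajectory"`.
#' @export
unwrapped_trajectory <- function(positions, box, scheme = "native",
                                 images = NULL) {
  scheme <- match.arg(scheme, c("native", "tor", "lat", "hlat", "kv"))
  if (!inherits(box, "box_series")) stop("box must be a box_series")
  positions <- as_positions(positions, box$n_axes)
  check_box_match(positions, box)
  if (!is.null(images)) {
    images <- as_positions(images, box$n_axes)
    if (!identical(dim(images), dim(positions)))
      stop("images must have the same dimensions as positions")
    if (max(abs(images - round(images))) > 0)
      stop("image numbers must be integers")
  }
  structure(list(positions = positions, box = box, scheme = scheme,
                 images = images,
                 n_frames = dim(positions)[1L],
                 n_particles = dim(positions)[2L],
                 n_axes = dim(positions)[3L]),
            class = "unwrapped_trajectory")
}

#' @export
print.wrapped_trajectory <- function(x, ...) {
  cat(sprintf(
    "wrapped_trajectory: %d frames, %d particle(s), %d axis(es), alpha = %d\n",
    x$n_frames, x$n_particles, x$n_axes, x$alpha))
  invisible(x)
}

#' @export
print.unwrapped_trajectory <- function(x, ...) {
  cat(sprintf(
    "unwrapped_trajectory (%s): %d frames, %d particle(s), %d axis(es)%s\n",
    x$scheme, x$n_frames, x$n_particles, x$n_axes,
    if (!is.null(x$images)) ", with image numbers" else ""))
  invisible(x)
}

#' Validate that a wrapped trajectory lies inside its central cell
#'
#' Checks every coordinate against the half-open central cell of its frame's
#' box: `[-L/2, L/2)` for `alpha = 1`, `[0, L)` for `alpha = 0`. Diagnostic:
#' never throws, returns the violations found.
#'
#' @param traj a [wrapped_trajectory()].
#' @return A data frame with columns `frame`, `particle`, `axis`, `value`,
#'   `lower`, `upper`; zero rows when the trajectory is valid.
#' @examples
#' b <- box_series(rep(1, 2))
#' validate_wrapped(wrapped_trajectory(c(0.2, 0.7), b))  # 0.7 is outside
#' @export
validate_wrapped <- function(traj) {
  stopifnot(inherits(traj, "wrapped_trajectory"))
  out <- list()
  for (a in seq_len(traj$n_axes)) {
    L <- traj$box$lengths[, a]
    bounds <- cell_bounds(L, traj$alpha)
    w <- traj$positions[, , a, drop = FALSE]
    bad <- which(w < bounds$lower | w >= bounds$upper, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        frame = bad[, 1L], particle = bad[, 2L], axis = a,
        value = w[bad], lower = bounds$lower[bad[, 1L]],
        upper = bounds$upper[bad[, 1L]])
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), particle = integer(),
                      axis = integer(), value = numeric(),
                      lower = numeric(), upper = numeric()))
  res <- do.call(rbind, out)
  res[order(res$frame, res$particle, res$axis), , drop = FALSE]
}

#' Decompose a trajectory into independent 1D axis series
#'
#' All unwrapping formulas are one-dimensional and are applied to each
#' Cartesian component independently (orthorhombic boxes make the axes
#' decouple). This view yields one `(w, L)` series per particle per axis;
#' reassembling the series reproduces the original arrays exactly.
#'
#' @param traj a wrapped or unwrapped trajectory.
#' @return A list with one element per particle/axis pair, each a list with
#'   `w` (coordinate series), `L` (box-length series), `particle`, `axis`.
#' @export
per_axis_view <- function(traj) {
  stopifnot(inherits(traj, c("wrapped_trajectory", "unwrapped_trajectory")))
  out <- vector("list", traj$n_particles * traj$n_axes)
  k <- 0L
  for (p in seq_len(traj$n_particles)) {
    for (a in seq_len(traj$n_axes)) {
      k <- k + 1L
      out[[k]] <- list(w = traj$positions[, p, a],
                       L = traj$box$lengths[, a],
                       particle = p, axis = a)
    }
  }
  out
}

# Inverse of per_axis_view: rebuild a frames x particles x axes array.
assemble_axes <- function(view, n_frames, n_particles, n_axes) {
  pos <- array(NA_real_, dim = c(n_frames, n_particles, n_axes))
  for (s in view) pos[, s$particle, s$axis] <- s$w
  pos
}
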