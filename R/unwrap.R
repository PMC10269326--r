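# The three unwrapping schemes plus the Kulke-Vermaas recursion. All
# formulas are 1D and use the mathematical floor (toward -infinity); the
# current-frame box length L_{i+1} enters each recursion, never an average
# of consecutive lengths.

check_series <- function(w, L) {
  if (length(w) < 1L) stop("empty coordinate series")
  if (length(L) == 1L) L <- rep(L, length(w))
  if (length(L) != length(w))
    stop("box length series must match coordinate series length")
  if (any(!is.finite(w)) || any(!is.finite(L))) stop("series must be finite")
  if (any(L <= 0)) stop("box lengths must be strictly positive")
  L
}

#' Heuristic lattice-view (HLAT) unwrapping of a 1D series
#'
#' Classic scheme used by several trajectory tools: places the unwrapped
#' position at the lattice image of the wrapped coordinate that minimizes
#' the displacement from the previous unwrapped position,
#' \deqn{u_{i+1} = w_{i+1} - L_{i+1}\,\lfloor (w_{i+1}-u_i)/L_{i+1} + 1/2 \rfloor.}
#' Under a fluctuating box this heuristic occasionally assigns the wrong
#' image and artificially speeds particles up, which is why the TOR and LAT
#' schemes are preferred.
#'
#' @param w numeric vector, wrapped coordinate per frame.
#' @param L numeric vector of box edge lengths per frame (or a scalar).
#' @return Numeric vector of unwrapped coordinates, `u[1] == w[1]`.
#' @seealso [tor_unwrap()], [lat_unwrap()], [kv_unwrap()]
#' @export
hlat_unwrap <- function(w, L) {
  L <- check_series(w, L)
  n <- length(w)
  u <- numeric(n)
  u[1L] <- w[1L]
  if (n > 1L) for (i in seq_len(n - 1L)) {
    u[i + 1L] <- w[i + 1L] -
      L[i + 1L] * floor((w[i + 1L] - u[i]) / L[i + 1L] + 0.5)
  }
  u
}

#' Toroidal-view (TOR) unwrapping of a 1D series
#'
#' Adds up minimal in-box displacement vectors,
#' \deqn{u_{i+1} = u_i + (w_{i+1}-w_i) - L_{i+1}\,\lfloor (w_{i+1}-w_i)/L_{i+1} + 1/2 \rfloor,}
#' treating the periodic cell as a torus. The result preserves the
#' statistical properties of the wrapped trajectory (the increments are
#' bounded by the box), which makes it the scheme of choice for diffusion
#' estimation from constant-pressure runs. It does not preserve
#' interparticle distances; molecules must be made whole first (see
#' [unwrap_molecule()]).
#'
#' @inheritParams hlat_unwrap
#' @return Numeric vector of unwrapped coordinates, `u[1] == w[1]`.
#' @export
tor_unwrap <- function(w, L) {
  L <- check_series(w, L)
  n <- length(w)
  if (n == 1L) return(w)
  d <- diff(w)
  Ln <- L[-1L]
  d <- d - Ln * floor(d / Ln + 0.5)
  cumsum(c(w[1L], d))
}

#' Lattice-view (LAT) unwrapping of a 1D series
#'
#' Tracks integer image numbers \eqn{n_i} so that
#' \eqn{u_i = w_i + n_i L_i} exactly at every frame. Image changes are
#' detected from large jumps in the wrapped coordinate,
#' \eqn{n_{i+1} = n_i - \lfloor (w_{i+1}-w_i)/L_{i+1} + 1/2 \rfloor};
#' alternatively, bookkept image numbers can be supplied via `images`.
#' LAT preserves interparticle distances but, under a barostat, the box
#' rescaling injects multiplicative noise proportional to the unwrapped
#' coordinate, which grows without bound away from the origin and corrupts
#' diffusion estimates.
#'
#' @inheritParams hlat_unwrap
#' @param images optional integer vector of externally bookkept image
#'   numbers per frame (overrides jump detection).
#' @return A list with `u` (unwrapped coordinates) and `images` (integer
#'   image numbers, `images[1] == 0` in jump-detection mode).
#' @export
lat_unwrap <- function(w, L, images = NULL) {
  L <- check_series(w, L)
  n <- length(w)
  if (is.null(images)) {
    if (n == 1L) {
      images <- 0
    } else {
      d <- diff(w)
      Ln <- L[-1L]
      images <- cumsum(c(0, -floor(d / Ln + 0.5)))
    }
  } else {
    if (length(images) != n) stop("images must match series length")
    if (max(abs(images - round(images))) > 0)
      stop("image numbers must be integers")
  }
  list(u = w + images * L, images = images)
}

#' Kulke-Vermaas corrected recursion (equivalent to LAT)
#'
#' A correction to the TOR recursion that restores the lattice structure by
#' adding a rescaling term acting on the accumulated image offset:
#' \deqn{u_{i+1} = u_i + (w_{i+1}-w_i)
#'   - L_{i+1}\,\lfloor (w_{i+1}-w_i)/L_{i+1} + 1/2 \rfloor
#'   + (L_{i+1}/L_i - 1)(u_i - w_i).}
#' This recursion is algebraically equivalent to [lat_unwrap()]; the package
#' test suite enforces the equivalence numerically, which pins down the
#' transcription.
#'
#' @inheritParams hlat_unwrap
#' @return Numeric vector of unwrapped coordinates, `u[1] == w[1]`.
#' @export
kv_unwrap <- function(w, L) {
  L <- check_series(w, L)
  n <- length(w)
  u <- numeric(n)
  u[1L] <- w[1L]
  if (n > 1L) for (i in seq_len(n - 1L)) {
    dw <- w[i + 1L] - w[i]
    u[i + 1L] <- u[i] + dw - L[i + 1L] * floor(dw / L[i + 1L] + 0.5) +
      (L[i + 1L] / L[i] - 1) * (u[i] - w[i])
  }
  u
}

# Matrix cores: recursion applied column-wise (frames x series), shared L.
hlat_core <- function(W, L) {
  U <- W
  n <- nrow(W)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    U[i + 1L, ] <- W[i + 1L, ] -
      L[i + 1L] * floor((W[i + 1L, ] - U[i, ]) / L[i + 1L] + 0.5)
  }
  U
}

col_cumsum <- function(X) matrix(apply(X, 2L, cumsum), nrow = nrow(X))

tor_core <- function(W, L) {
  n <- nrow(W)
  if (n == 1L) return(W)
  D <- W[-1L, , drop = FALSE] - W[-n, , drop = FALSE]
  D <- D - L[-1L] * floor(D / L[-1L] + 0.5)
  rbind(W[1L, ],
        col_cumsum(D) + rep(W[1L, ], each = n - 1L))
}

lat_core <- function(W, L) {
  n <- nrow(W)
  if (n == 1L) return(list(U = W, N = 0 * W))
  D <- W[-1L, , drop = FALSE] - W[-n, , drop = FALSE]
  J <- -floor(D / L[-1L] + 0.5)
  N <- rbind(rep(0, ncol(W)), col_cumsum(J))
  list(U = W + N * L, N = N)
}

kv_core <- function(W, L) {
  U <- W
  n <- nrow(W)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    dw <- W[i + 1L, ] - W[i, ]
    U[i + 1L, ] <- U[i, ] + dw - L[i + 1L] * floor(dw / L[i + 1L] + 0.5) +
      (L[i + 1L] / L[i] - 1) * (U[i, ] - W[i, ])
  }
  U
}

#' Unwrap a wrapped trajectory with a chosen scheme
#'
#' Applies the selected 1D unwrapping scheme to every particle and Cartesian
#' axis independently. The LAT scheme additionally records the integer image
#' numbers.
#'
#' @param traj a [wrapped_trajectory()].
#' @param scheme one of `"tor"`, `"lat"`, `"hlat"`, `"kv"`.
#' @return An [unwrapped_trajectory()] tagged with the scheme; for
#'   `scheme = "lat"` the `images` array is populated.
#' @examples
#' b <- box_series(c(1, 1, 1))
#' w <- wrapped_trajectory(c(0.4, 0.45, -0.45), b)
#' unwrap(w, "tor")$positions[, 1, 1]  # 0.40 0.45 0.55
#' @export
unwrap <- function(traj, scheme = c("tor", "lat", "hlat", "kv")) {
  stopifnot(inherits(traj, "wrapped_trajectory"))
  scheme <- match.arg(scheme)
  n <- traj$n_frames
  pos <- array(NA_real_, dim = dim(traj$positions))
  img <- if (scheme == "lat") array(NA_real_, dim = dim(traj$positions))
  for (a in seq_len(traj$n_axes)) {
    W <- matrix(traj$positions[, , a], nrow = n)
    L <- traj$box$lengths[, a]
    res <- tryCatch(switch(scheme,
                           tor  = tor_core(W, L),
                           hlat = hlat_core(W, L),
                           kv   = kv_core(W, L),
                           lat  = lat_core(W, L)),
                    error = function(e)
                      stop(sprintf("axis %d: %s", a, conditionMessage(e))))
    if (scheme == "lat") {
      pos[, , a] <- res$U
      img[, , a] <- res$N
    } else {
      pos[, , a] <- res
    }
  }
  unwrapped_trajectory(pos, traj$box, scheme = scheme, images = img)
}
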