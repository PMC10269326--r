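# Minimal stochastic model of a diffusing particle in a fluctuating
# periodic box. It jointly emits three trajectories driven by the same
# noise: the wrapped process w, its true off-lattice unwrapped partner u,
# and the lattice-view partner u*. Because all three share one noise
# realization, they provide exact (seed-matched) oracles for the TOR and
# LAT unwrapping schemes: TOR(w) == u and LAT(w) == u*, frame by frame,
# whenever no single-step displacement exceeds half a box length.
#
# Per step (box lengths L_i = L + sigma_L R'_i, white noise):
#   w_{i+1}  = wrap_{alpha=1, L_{i+1}}( (L_{i+1}/L_i) w_i + sigma_w R_{i+1} )
#   u_{i+1}  = u_i  + (L_{i+1}/L_i - 1) w_i  + sigma_w R_{i+1}
#   u*_{i+1} = (L_{i+1}/L_i) u*_i           + sigma_w R_{i+1}
# The u recursion carries multiplicative noise proportional to the bounded
# wrapped coordinate, so it stays diffusive; the u* recursion rescales the
# unbounded coordinate itself, so its fluctuations grow with |u*|.

#' Parameters of the Gaussian fluctuating-box model
#'
#' @param L mean box edge length (length units).
#' @param sigma_L amplitude of the white box-length noise (same units);
#'   must satisfy `sigma_L < L/2` so boxes stay positive with overwhelming
#'   probability (a sampled nonpositive length is rejected at run time).
#' @param sigma_w diffusive step amplitude per frame (same units). The
#'   per-axis diffusion coefficient implied for a constant box is
#'   `sigma_w^2 / (2 * dt)`.
#' @param n_steps number of time steps (the realization has
#'   `n_steps + 1` frames).
#' @param n_dims number of Cartesian axes (1-3), each with an independent
#'   box-length series shared by all particles.
#' @param n_particles number of independent particles in the same box.
#' @param dt sampling interval.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return Object of class `"gaussian_model_params"`.
#' @export
gaussian_model_params <- function(L = 1, sigma_L = 0.1, sigma_w = 0.05,
                                  n_steps = 1000L, n_dims = 1L,
                                  n_particles = 1L, dt = 1, seed = NULL) {
  stopifnot(L > 0, sigma_L >= 0, sigma_w >= 0, n_steps >= 1,
            n_dims %in% 1:3, n_particles >= 1, dt > 0)
  if (sigma_L >= L / 2)
    stop("sigma_L must be below L/2 to keep sampled boxes positive")
  structure(list(L = L, sigma_L = sigma_L, sigma_w = sigma_w,
                 n_steps = as.integer(n_steps), n_dims = as.integer(n_dims),
                 n_particles = as.integer(n_particles), dt = dt,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "gaussian_model_params")
}

# Shared recursion core operating on stacked columns. Lm: frames x k box
# lengths; S: frames x k diffusive steps (sigma_w * R, row 1 unused);
# w0: length-k initial positions (inside the alpha = 1 cell of Lm[1, ]).
gm_core <- function(w0, Lm, S) {
  n <- nrow(Lm)
  W <- U <- Us <- matrix(NA_real_, n, length(w0))
  W[1L, ] <- U[1L, ] <- Us[1L, ] <- w0
  for (i in seq_len(n - 1L)) {
    ratio <- Lm[i + 1L, ] / Lm[i, ]
    x <- ratio * W[i, ] + S[i + 1L, ]
    W[i + 1L, ] <- x - Lm[i + 1L, ] * floor(x / Lm[i + 1L, ] + 0.5)
    U[i + 1L, ] <- U[i, ] + (ratio - 1) * W[i, ] + S[i + 1L, ]
    Us[i + 1L, ] <- ratio * Us[i, ] + S[i + 1L, ]
  }
  list(W = W, U = U, Us = Us)
}

# Deterministic draw order given the seed: box noise R' (frames x dims),
# initial uniforms (particles x dims), then step noise R (frames x
# particles x dims). Keeping the order fixed makes ensemble replicates
# bit-identical to standalone runs with the derived seed.
gm_draws <- function(params) {
  n <- params$n_steps + 1L
  if (!is.null(params$seed)) set.seed(params$seed)
  Rb <- matrix(stats::rnorm(n * params$n_dims), n, params$n_dims)
  U0 <- matrix(stats::runif(params$n_particles * params$n_dims),
               params$n_particles, params$n_dims)
  R <- array(stats::rnorm(n * params$n_particles * params$n_dims),
             dim = c(n, params$n_particles, params$n_dims))
  list(Rb = Rb, U0 = U0, R = R)
}

#' Simulate one realization of the Gaussian fluctuating-box model
#'
#' Generates the wrapped trajectory together with its two unwrapped partner
#' processes from a single shared noise realization (see the package
#' vignette for the recursions). Initial positions are drawn uniformly in
#' the centered cell of the first-frame box, `w0 = L_0 (R' - 1/2)`.
#'
#' @param params a [gaussian_model_params()].
#' @return Object of class `"model_realization"`: a list with `w`
#'   ([wrapped_trajectory()], alpha = 1), `u_true` and `u_star`
#'   ([unwrapped_trajectory()]s sharing the same box; `u_star` carries its
#'   exact image numbers), `box`, `noises` (the standard-normal draws) and
#'   `params`.
#' @examples
#' r <- simulate_gaussian_model(gaussian_model_params(n_steps = 100, seed = 1))
#' max(abs(unwrap(r$w, "tor")$positions - r$u_true$positions))  # ~1e-16
#' @export
simulate_gaussian_model <- function(params) {
  stopifnot(inherits(params, "gaussian_model_params"))
  n <- params$n_steps + 1L
  dr <- gm_draws(params)
  Lmat <- params$L + params$sigma_L * dr$Rb
  if (any(Lmat <= 0)) {
    bad <- which(Lmat <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "sampled nonpositive box length at frame %d, axis %d; reseed or lower sigma_L",
      bad[1L], bad[2L]))
  }
  k <- params$n_particles * params$n_dims
  # columns ordered particle-major within axis: (p1a1, p2a1, ..., p1a2, ...)
  Lcols <- Lmat[, rep(seq_len(params$n_dims), each = params$n_particles),
                drop = FALSE]
  w0 <- as.vector(Lcols[1L, ] * (as.vector(dr$U0) - 0.5))
  S <- params$sigma_w * matrix(dr$R, n, k)
  res <- gm_core(w0, Lcols, S)
  shape <- c(n, params$n_particles, params$n_dims)
  box <- box_series(Lmat, dt = params$dt)
  w <- wrapped_trajectory(array(res$W, shape), box, alpha = 1)
  u_true <- unwrapped_trajectory(array(res$U, shape), box, scheme = "native")
  img <- round((res$Us - res$W) / Lcols)
  u_star <- unwrapped_trajectory(array(res$Us, shape), box,
                                 scheme = "native",
                                 images = array(img, shape))
  structure(list(w = w, u_true = u_true, u_star = u_star, box = box,
                 noises = list(R = dr$R, R_box = dr$Rb), params = params),
            class = "model_realization")
}

#' @export
print.model_realization <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "model_realization: %d steps, %d particle(s), %d axis(es), L = %g, sigma_L = %g, sigma_w = %g\n",
    p$n_steps, p$n_particles, p$n_dims, p$L, p$sigma_L, p$sigma_w))
  invisible(x)
}

#' Ensemble of independent model realizations
#'
#' Per-replicate seeds are derived deterministically from the master seed,
#' so the whole ensemble is reproducible and each replicate equals a
#' standalone [simulate_gaussian_model()] run with its derived seed.
#'
#' @param params a [gaussian_model_params()]; its `seed` is the master seed
#'   (required).
#' @param n_replicates number of independent realizations.
#' @return List of `"model_realization"` objects. The derived seeds are
#'   attached as attribute `"seeds"`.
#' @export
gaussian_model_ensemble <- function(params, n_replicates) {
  stopifnot(inherits(params, "gaussian_model_params"), n_replicates >= 1)
  if (is.null(params$seed))
    stop("ensemble generation requires a master seed in params")
  set.seed(params$seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  out <- lapply(seeds, function(s) {
    p <- params
    p$seed <- s
    simulate_gaussian_model(p)
  })
  attr(out, "seeds") <- seeds
  out
}
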