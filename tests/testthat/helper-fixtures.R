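# Shared fixtures, built in code. The large seeded ensembles used by the
# acceptance tests are memoized here so several tests can reuse them.

.fixture_env <- new.env(parent = emptyenv())

# 100 realizations of the fluctuating-box model at the standard oracle
# conditions (L = 1, sigma_L = 0.1 L, sigma_w = 0.05 L, 1e4 steps).
oracle_ensemble <- function() {
  if (is.null(.fixture_env$oracle)) {
    params <- gaussian_model_params(L = 1, sigma_L = 0.1, sigma_w = 0.05,
                                    n_steps = 1e4, seed = 20260930)
    .fixture_env$oracle <- gaussian_model_ensemble(params, 100)
  }
  .fixture_env$oracle
}

# 200-realization ensemble for the block-wise scheme-discrimination tests.
blockdiag_ensemble <- function() {
  if (is.null(.fixture_env$blockdiag)) {
    params <- gaussian_model_params(L = 1, sigma_L = 0.1, sigma_w = 0.05,
                                    n_steps = 1e4, seed = 424242)
    .fixture_env$blockdiag <- gaussian_model_ensemble(params, 200)
  }
  .fixture_env$blockdiag
}

# Did any single true step exceed half the (new) box length? When it did,
# the wrapped displacement no longer identifies the image change, every
# unwrapping scheme mis-assigns the image, and the seed-matched scheme
# identities are not expected to hold. (The condition concerns the true
# pre-wrap displacement; the lattice-view partner's own exaggerated steps
# are irrelevant because jump detection reads the wrapped coordinates.)
crossing_resolvable <- function(r) {
  ok <- TRUE
  for (a in seq_len(r$u_true$n_axes)) {
    for (p in seq_len(r$u_true$n_particles)) {
      du <- diff(r$u_true$positions[, p, a])
      if (any(abs(du) >= r$box$lengths[-1L, a] / 2)) ok <- FALSE
    }
  }
  ok
}

# Plain Gaussian random walk in a constant box, optionally with static
# localization noise added on top of the true positions.
constant_box_walk <- function(n_frames, D = 1, dt = 1, L = 1e6,
                              noise_sd = 0, n_particles = 1, n_dims = 1,
                              seed = 1) {
  set.seed(seed)
  steps <- array(stats::rnorm((n_frames - 1) * n_particles * n_dims,
                              sd = sqrt(2 * D * dt)),
                 dim = c(n_frames - 1, n_particles, n_dims))
  pos <- array(0, dim = c(n_frames, n_particles, n_dims))
  for (a in seq_len(n_dims))
    pos[, , a] <- rbind(rep(0, n_particles),
                        matrix(apply(matrix(steps[, , a],
                                            nrow = n_frames - 1),
                                     2, cumsum), nrow = n_frames - 1))
  if (noise_sd > 0)
    pos <- pos + array(stats::rnorm(length(pos), sd = noise_sd),
                       dim = dim(pos))
  unwrapped_trajectory(pos,
                       box_series(matrix(L, n_frames, n_dims), dt = dt),
                       scheme = "native")
}
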