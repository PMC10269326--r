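test_that("msd matches a brute-force double loop exactly", {
  u <- constant_box_walk(200, D = 0.5, n_particles = 2, n_dims = 2,
                         seed = 21)
  curve <- msd(u, max_lag = 30)
  # naive O(N m) oracle
  for (m in c(1, 7, 30)) {
    acc <- 0
    for (p in 1:2) for (i in 1:(200 - m)) {
      acc <- acc + sum((u$positions[i + m, p, ] - u$positions[i, p, ])^2)
    }
    expect_equal(curve$msd[curve$m == m], acc / (2 * (200 - m)))
  }
  expect_equal(curve$n_pairs, 200 - curve$m)
})

test_that("msd of deterministic motions", {
  b <- box_series(matrix(1e6, 50, 1))
  lin <- unwrapped_trajectory(0.3 * (0:49), b)
  curve <- msd(lin, max_lag = 10)
  expect_equal(curve$msd, (0.3 * curve$m)^2)
  const <- unwrapped_trajectory(rep(1.5, 50), b)
  expect_equal(msd(const, max_lag = 10)$msd, rep(0, 11))
})

test_that("msd refuses wrapped input", {
  w <- wrapped_trajectory(c(0.1, 0.2), box_series(c(1, 1)))
  expect_error(msd(w, 1), "unwrap")
})

test_that("ols_fit recovers a noiseless line exactly", {
  b <- box_series(matrix(1e6, 100, 3), dt = 2)
  # construct a curve object directly from the exact line 2 d D tau + a2
  u <- constant_box_walk(100, n_dims = 3, seed = 1)
  curve <- msd(u, max_lag = 20)
  curve$msd <- 2 * 3 * 1 * curve$tau + 0.5
  fit <- suppressWarnings(ols_fit(curve, 1, 20))  # perfect fit warns in lm
  expect_equal(fit$D, 1, tolerance = 1e-12)
  expect_equal(fit$a2, 0.5, tolerance = 1e-12)
  expect_equal(fit$B, 0)
  # negative intercepts are reported as-is
  curve$msd <- 2 * 3 * 1 * curve$tau - 0.2
  expect_equal(suppressWarnings(ols_fit(curve, 1, 20))$a2, -0.2,
               tolerance = 1e-12)
  expect_error(ols_fit(curve, 5, 5), "two lags")
  expect_error(ols_fit(curve, 1, 50), "lag range")
})

test_that("OLS recovers the injected diffusion coefficient", {
  # constant-box Gaussian-model runs: per-axis D = sigma_w^2 / (2 dt)
  ens <- gaussian_model_ensemble(
    gaussian_model_params(sigma_L = 0, sigma_w = 0.05, n_steps = 4000,
                          seed = 31), 40)
  D_true <- 0.05^2 / 2
  Ds <- vapply(ens, function(r)
    ols_fit(msd(r$u_true, max_lag = 20), 1, 20)$D, numeric(1))
  se <- stats::sd(Ds) / sqrt(length(Ds))
  expect_lt(abs(mean(Ds) - D_true), 3 * se)
})

test_that("CVE recovers D for a pure walk and D plus a2 under noise", {
  D_true <- 0.7
  noise_var <- 0.09
  Ds <- a2s <- Dn <- a2n <- numeric(40)
  for (k in 1:40) {
    clean <- constant_box_walk(2000, D = D_true, seed = 1000 + k)
    noisy <- constant_box_walk(2000, D = D_true, noise_sd = sqrt(noise_var),
                               seed = 5000 + k)
    fc <- cve_fit(clean)
    fn <- cve_fit(noisy)
    Ds[k] <- fc$D; a2s[k] <- fc$a2; Dn[k] <- fn$D; a2n[k] <- fn$a2
  }
  expect_lt(abs(mean(Ds) - D_true), 3 * stats::sd(Ds) / sqrt(40))
  expect_lt(abs(mean(a2s) - 0), 3 * stats::sd(a2s) / sqrt(40))
  expect_lt(abs(mean(Dn) - D_true), 3 * stats::sd(Dn) / sqrt(40))
  expect_lt(abs(mean(a2n) - noise_var), 3 * stats::sd(a2n) / sqrt(40))
})

test_that("CVE of a constant series is exactly zero", {
  b <- box_series(matrix(1e6, 100, 1))
  fit <- cve_fit(unwrapped_trajectory(rep(2, 100), b))
  expect_equal(fit$D, 0)
  expect_equal(fit$a2, 0)
})

test_that("identical blocks give identical block estimates", {
  u1 <- constant_box_walk(500, D = 1, seed = 3)
  two <- c(u1$positions[, 1, 1], u1$positions[, 1, 1] + 5)
  u <- unwrapped_trajectory(array(two, dim = c(1000, 1, 1)),
                            box_series(matrix(1e6, 1000, 1)))
  bs <- block_analysis(u, 500, "cve", n_perm = 100)
  expect_equal(bs$blocks$D[1], bs$blocks$D[2])
})

test_that("block trend diagnostics separate stationary from drifting data", {
  r <- simulate_gaussian_model(
    gaussian_model_params(n_steps = 10000, seed = 321))
  bt <- suppressMessages(
    block_analysis(r$u_true, 500, "ols0", perm_seed = 7))
  bl <- suppressMessages(
    block_analysis(r$u_star, 500, "ols0", perm_seed = 7))
  expect_gt(bt$p_value, 0.01)
  expect_lt(bl$p_value, 0.01)
  expect_gt(bl$trend, 0)
})

test_that("block analysis validates input and drops partial blocks noisily", {
  u <- constant_box_walk(1001, D = 1, seed = 6)
  expect_message(block_analysis(u, 500, "cve", n_perm = 10), "partial block")
  expect_error(block_analysis(u, 1001, "cve"), "2 whole blocks")
})

test_that("pair diffusion is additive for independent walks", {
  gaps <- ses <- numeric(20)
  for (k in 1:20) {
    uX <- constant_box_walk(3000, D = 0.4, n_dims = 2, seed = 100 + k)
    uY <- constant_box_walk(3000, D = 0.9, n_dims = 2, seed = 900 + k)
    pr <- pair_diffusion(uX, uY)
    gaps[k] <- pr$gap
  }
  expect_lt(abs(mean(gaps)), 3 * stats::sd(gaps) / sqrt(20))
  # identical processes: the distance vector does not move
  uX <- constant_box_walk(500, D = 1, seed = 77)
  pr <- pair_diffusion(uX, uX)
  expect_equal(pr$D_pair, 0)
  expect_error(pair_diffusion(uX, constant_box_walk(400, seed = 1)),
               "frame count")
})

test_that("compressibility follows the fluctuation relation", {
  expect_equal(as.numeric(compressibility(rep(15.6, 10), 300)), 0)
  # plug-in oracle on synthetic Gaussian volumes
  set.seed(9)
  chis <- numeric(30)
  for (k in 1:30) {
    V <- stats::rnorm(20000, mean = 15.625, sd = 0.05)
    chis[k] <- compressibility(V, 300)
  }
  expected <- 0.05^2 / (0.1380649 * 300 * 15.625)
  expect_lt(abs(mean(chis) - expected), 3 * stats::sd(chis) / sqrt(30))
  # unbiased two-point variance: (V1 - V2)^2 / 2
  V2 <- c(15, 16)
  expect_equal(as.numeric(compressibility(V2, 300)),
               0.5 / (0.1380649 * 300 * 15.5))
  expect_error(compressibility(c(1, -1), 300), "positive")
  expect_error(compressibility(3, 300), "2 volume")
})

test_that("volume series multiplies the per-axis edges", {
  b <- box_series(matrix(c(2, 2, 3, 3, 4, 4), 2, 3))
  expect_equal(volume_series(b), c(24, 24))
})
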