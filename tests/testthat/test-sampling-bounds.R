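spec_diffusive <- function(L = 2.5, epsilon = 0.01, t_total = 1e6,
                           density = 33.3, D = 6) {
  bound_spec("diffusive", epsilon = epsilon, L = L, t_total = t_total,
             temperature = 300, density = density, diffusion = D)
}

spec_ballistic <- function(L = 2.5, epsilon = 0.01, t_total = 1e6,
                           density = 33.3, m = 18) {
  bound_spec("ballistic", epsilon = epsilon, L = L, t_total = t_total,
             temperature = 300, density = density, mass = m)
}

test_that("lambert_w_lower satisfies its defining identity", {
  expect_equal(lambert_w_lower(-exp(-1)), -1)
  for (z in c(-0.1, -0.3, -1e-3, -1e-8, -1e-15)) {
    w <- lambert_w_lower(z)
    expect_lte(w, -1)
    expect_lt(abs(w * exp(w) - z), 1e-12 * abs(z))
  }
  expect_error(lambert_w_lower(0.1), "z must lie")
  expect_error(lambert_w_lower(-1), "z must lie")
})

test_that("lambert_w_lower matches an independent implementation", {
  skip_if_not_installed("pracma")
  for (z in c(-0.05, -0.2, -1e-4)) {
    expect_equal(lambert_w_lower(z), pracma::lambertWn(z),
                 tolerance = 1e-10)
  }
})

test_that("three-term expansion approximates the branch for small z", {
  z <- -1e-4
  expect_lt(abs(lambert_w_lower(z, expansion = TRUE) / lambert_w_lower(z) - 1),
            0.05)
})

test_that("single-crossing probability equals the Gaussian tail mass", {
  # independent oracle: numerical quadrature of the displacement density
  set.seed(1)
  for (i in 1:10) {
    L <- runif(1, 1, 6)
    dt <- runif(1, 0.1, 5)
    spec <- spec_diffusive(L = L)
    res <- crossing_probability(spec, dt)
    sigma <- res$sigma
    tail <- stats::integrate(function(x) stats::dnorm(x, 0, sigma),
                             L / 2, Inf, rel.tol = 1e-12)$value
    expect_equal(res$p_single, 2 * tail, tolerance = 1e-6)
  }
})

test_that("crossing probability limits behave", {
  spec <- spec_diffusive()
  expect_lt(crossing_probability(spec_diffusive(L = 500), 1)$p_single,
            1e-100)
  # enormous displacement scale: erfc(0+) -> 1
  big <- spec_diffusive(L = 1e-3, D = 1e3)
  expect_gt(crossing_probability(big, 100)$p_single, 0.99)
  expect_error(crossing_probability(spec, -1), "dt")
})

test_that("root solve and Lambert-W closed form agree", {
  for (spec in list(spec_diffusive(2.5), spec_diffusive(7.5),
                    spec_ballistic(2.5), spec_ballistic(7.5))) {
    b <- max_sampling_interval(spec)
    expect_lt(abs(b$dt_closed_form / b$dt_max - 1), 0.10)
  }
})

test_that("the solved interval hits epsilon exactly (self-consistency)", {
  for (spec in list(spec_diffusive(), spec_ballistic(5))) {
    b <- max_sampling_interval(spec)
    expect_lt(abs(crossing_probability(spec, b$dt_max)$p_total /
                    spec$epsilon - 1), 1e-10)
  }
})

test_that("safe interval is monotone in box size, epsilon, N and t_total", {
  for (make in list(spec_ballistic, spec_diffusive)) {
    dts <- vapply(c(2.5, 5, 7.5),
                  function(L) max_sampling_interval(make(L))$dt_max,
                  numeric(1))
    expect_true(all(diff(dts) > 0))
  }
  base <- max_sampling_interval(spec_diffusive())$dt_max
  expect_lt(max_sampling_interval(spec_diffusive(epsilon = 1e-3))$dt_max,
            base)
  expect_lt(max_sampling_interval(spec_diffusive(density = 333))$dt_max,
            base)
  expect_lt(max_sampling_interval(spec_diffusive(t_total = 1e7))$dt_max,
            base)
})

test_that("degenerate regimes are signalled", {
  # every probed interval is unsafe: huge diffusivity, tiny box, very
  # long run (so that even the smallest probe interval crosses freely)
  hopeless <- bound_spec("diffusive", epsilon = 1e-6, L = 0.1,
                         t_total = 1e12, temperature = 300,
                         n_particles = 10, diffusion = 1e9)
  expect_error(max_sampling_interval(hopeless), "no safe interval")
  # never unsafe: cap at t_total
  relaxed <- bound_spec("diffusive", epsilon = 0.9, L = 500, t_total = 10,
                        temperature = 300, n_particles = 1, diffusion = 1e-3)
  b <- max_sampling_interval(relaxed)
  expect_true(b$capped)
  expect_equal(b$dt_max, 10)
})

test_that("bound_spec validates mode-specific inputs", {
  expect_error(bound_spec("ballistic", 0.01, 2.5, 1e6, 300,
                          density = 33.3), "mass")
  expect_error(bound_spec("diffusive", 0.01, 2.5, 1e6, 300,
                          density = 33.3), "diffusion")
  expect_error(bound_spec("diffusive", 0.01, 2.5, 1e6, 300,
                          diffusion = 6), "n_particles or density")
})
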