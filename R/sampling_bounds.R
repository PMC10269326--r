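# Safe trajectory-output intervals. If a particle moves more than L/2
# along any axis between saved frames, every unwrapping scheme assigns the
# wrong periodic image. These routines quantify the probability of such an
# event over a whole run and solve for the largest output interval dt that
# keeps it below a tolerance epsilon.
#
# Internal unit registry: nm, ps, K, g/mol. Boltzmann constant in
# kJ/(mol K); conveniently (kJ/mol) / (g/mol) = nm^2/ps^2, so the thermal
# velocity scale kB*T/m is in nm^2/ps^2 without further conversion.

KB_KJ_MOL_K <- 0.008314462618  # kJ/(mol K)
KB_NM3_BAR_K <- 0.1380649      # nm^3 bar / K (for compressibility)

#' Specification for a sampling-interval bound calculation
#'
#' @param mode `"ballistic"` (inertia-dominated displacements between
#'   frames, scale set by the thermal velocity) or `"diffusive"`
#'   (displacement variance `2 D dt`).
#' @param epsilon tolerated total probability of one or more
#'   mis-unwrapping events over the whole run (dimensionless, < 1).
#' @param L cubic box edge length (nm).
#' @param t_total total simulation time (ps).
#' @param temperature absolute temperature (K).
#' @param n_particles number of particles N in the box; alternatively give
#'   `density` (nm^-3) and N = density * L^3 is used.
#' @param density number density (nm^-3), used when `n_particles` is NULL.
#' @param mass particle mass (g/mol); required in ballistic mode.
#' @param diffusion diffusion coefficient in nm^2/ns (as conventionally
#'   quoted); converted internally to nm^2/ps. Required in diffusive mode.
#' @return Object of class `"bound_spec"`.
#' @examples
#' bound_spec("diffusive", epsilon = 0.01, L = 2.5, t_total = 1e6,
#'            temperature = 300, density = 33.3, diffusion = 6)
#' @export
bound_spec <- function(mode = c("ballistic", "diffusive"), epsilon, L,
                       t_total, temperature, n_particles = NULL,
                       density = NULL, mass = NULL, diffusion = NULL) {
  mode <- match.arg(mode)
  stopifnot(epsilon > 0, epsilon < 1, L > 0, t_total > 0, temperature > 0)
  if (is.null(n_particles)) {
    if (is.null(density)) stop("give either n_particles or density")
    n_particles <- density * L^3
  }
  stopifnot(n_particles > 0)
  if (mode == "ballistic") {
    if (is.null(mass) || mass <= 0)
      stop("ballistic mode requires a positive mass (g/mol)")
    if (!is.null(diffusion))
      stop("give mass (ballistic) or diffusion (diffusive), not both modes' inputs")
  } else {
    if (is.null(diffusion) || diffusion <= 0)
      stop("diffusive mode requires a positive diffusion coefficient (nm^2/ns)")
    if (!is.null(mass))
      stop("give mass (ballistic) or diffusion (diffusive), not both modes' inputs")
  }
  structure(list(mode = mode, epsilon = epsilon, L = L, t_total = t_total,
                 temperature = temperature, n_particles = n_particles,
                 mass = mass,
                 diffusion_ps = if (!is.null(diffusion)) diffusion / 1000),
            class = "bound_spec")
}

# Displacement scale sigma for a given interval dt.
bound_sigma <- function(spec, dt) {
  if (spec$mode == "ballistic") {
    dt * sqrt(KB_KJ_MOL_K * spec$temperature / spec$mass)
  } else {
    sqrt(2 * spec$diffusion_ps * dt)
  }
}

# log Pr(X > L/2) = log erfc(x), x = L / (2 sqrt(2) sigma), computed
# stably far into the tail via the asymptotic series when erfc underflows.
log_erfc_tail <- function(x) {
  log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}

#' Probability of an unresolvable boundary crossing
#'
#' Computes the probability that a single particle moves more than `L/2` in
#' one direction within one output interval,
#' `p_single = erfc(L / (2 sqrt(2) sigma))`, and the probability that this
#' happens for at least one of N particles along any of the 3 Cartesian
#' axes in any of the `t_total/dt` saved frames,
#' `p_total = 1 - (1 - p_single)^(3 N t_total/dt)`. When the expected event
#' count `3 N (t_total/dt) p_single` is below `1e-3` the linearized form
#' `p_total = 3 N p_single t_total/dt` is used (relative error below
#' `5e-4`, well under any tolerance of interest).
#'
#' @param spec a [bound_spec()].
#' @param dt candidate output interval (ps), > 0.
#' @return Object of class `"crossing_result"`: list with `p_single`,
#'   `p_total`, `sigma`, plus the stable logs `log_p_single`,
#'   `log_p_total`.
#' @export
crossing_probability <- function(spec, dt) {
  stopifnot(inherits(spec, "bound_spec"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  sigma <- bound_sigma(spec, dt)
  x <- spec$L / (2 * sqrt(2) * sigma)
  log_p1 <- log_erfc_tail(x)
  n_checks <- 3 * spec$n_particles * spec$t_total / dt
  log_expected <- log(n_checks) + log_p1
  if (log_expected < log(1e-3)) {
    log_pt <- log_expected
    p_total <- exp(log_pt)
  } else {
    p1 <- exp(log_p1)
    p_total <- -expm1(n_checks * log1p(-p1))
    log_pt <- log(p_total)
  }
  structure(list(p_single = exp(log_p1), p_total = p_total, sigma = sigma,
                 log_p_single = log_p1, log_p_total = log_pt,
                 n_checks = n_checks, dt = dt),
            class = "crossing_result")
}

#' @export
print.crossing_result <- function(x, ...) {
  cat(sprintf(
    "crossing_result: dt = %g ps, sigma = %g nm, p_single = %.3g, p_total = %.3g\n",
    x$dt, x$sigma, x$p_single, x$p_total))
  invisible(x)
}

#' Lower branch of the Lambert W function
#'
#' Solves `W exp(W) = z` on the branch `W <= -1`, defined for
#' `-1/e <= z < 0`. Used in the closed-form diffusive-regime sampling
#' bound. `expansion = TRUE` instead returns the three-term small-argument
#' asymptotic series
#' `W_-1(z) ~ -ln(-1/z) - ln(ln(-1/z)) - ln(ln(-1/z))/ln(-1/z)`,
#' exposed for cross-checking.
#'
#' @param z numeric vector in `[-1/e, 0)`.
#' @param expansion logical; return the series approximation instead of the
#'   exact branch value.
#' @return Numeric vector of branch values (<= -1).
#' @examples
#' w <- lambert_w_lower(-0.1)
#' w * exp(w)  # -0.1
#' @export
lambert_w_lower <- function(z, expansion = FALSE) {
  if (any(!is.finite(z)) || any(z >= 0) || any(z < -exp(-1) * (1 + 1e-12)))
    stop("z must lie in [-1/e, 0)")
  if (expansion) {
    l1 <- log(-1 / z)   # = -log(-z), positive and large for small |z|
    return(-l1 - log(l1) - log(l1) / l1)
  }
  vapply(z, function(zi) {
    if (zi <= -exp(-1)) return(-1)
    # start from the series; Halley iteration on f(W) = W e^W - z
    l1 <- log(-1 / zi)
    w <- -l1 - log(l1)
    if (w > -1) w <- -1 - sqrt(2 * (1 + exp(1) * zi))  # near branch point
    for (iter in 1:50) {
      ew <- exp(w)
      f <- w * ew - zi
      if (f == 0) break
      wn <- w - f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
      if (!is.finite(wn)) break
      if (abs(wn - w) < 1e-15 * abs(w)) { w <- wn; break }
      w <- wn
    }
    w
  }, numeric(1))
}

# Closed-form asymptotic solutions of the crossing relation (erfc replaced
# by its large-argument expansion, p_total linearized). Ballistic: dt
# cancels from the prefactor and the solve is a plain logarithm,
#   dt = L / (2 sqrt(2) c) / sqrt(log(A/eps)),  c = sqrt(kT/m),
#   A = 3 N t_total 2 sqrt(2) c / (L sqrt(pi)).
# Diffusive: sigma^2 = 2 D dt leaves dt^(-1/2) exp(-b/dt) = eps/C with
# b = L^2/(16 D), solved by the Lambert W lower branch,
#   dt = -2 b / W_-1(-2 b (eps/C)^2),
#   C = 3 N t_total 2 sqrt(2) sqrt(2 D) / (L sqrt(pi)).
closed_form_interval <- function(spec) {
  with(spec, {
    if (mode == "ballistic") {
      cth <- sqrt(KB_KJ_MOL_K * temperature / mass)
      A <- 3 * n_particles * t_total * 2 * sqrt(2) * cth / (L * sqrt(pi))
      L / (2 * sqrt(2) * cth) / sqrt(log(A / epsilon))
    } else {
      D <- diffusion_ps
      b <- L^2 / (16 * D)
      C <- 3 * n_particles * t_total * 2 * sqrt(2) * sqrt(2 * D) /
        (L * sqrt(pi))
      z <- -2 * b * (epsilon / C)^2
      # outside the branch domain the asymptotic expansion has no
      # solution (the small-probability regime never applies)
      if (z < -exp(-1)) NA_real_ else -2 * b / lambert_w_lower(z)
    }
  })
}

#' Maximum safe trajectory-output interval
#'
#' Finds the largest output interval `dt` for which the total probability
#' of an unresolvable boundary crossing over the whole run equals
#' `epsilon`, i.e. solves `p_total(dt) = epsilon` (see
#' [crossing_probability()]). The authoritative answer is a numeric root
#' solve of the full relation; the asymptotic closed form (logarithmic in
#' the ballistic regime, Lambert-W lower branch in the diffusive regime) is
#' evaluated as an independent cross-check and both are returned.
#'
#' @param spec a [bound_spec()].
#' @return Object of class `"sampling_bound"`: list with `dt_max` (ps, the
#'   numeric root), `dt_closed_form` (asymptotic solution), `p_achieved`
#'   (total probability at `dt_max`), `capped` (TRUE when even
#'   `dt = t_total` stays below epsilon and `dt_max` is capped there), and
#'   the input `spec`.
#' @examples
#' s <- bound_spec("diffusive", epsilon = 0.01, L = 2.5, t_total = 1e6,
#'                 temperature = 300, density = 33.3, diffusion = 6)
#' max_sampling_interval(s)$dt_max  # about 2.9 ps
#' @export
max_sampling_interval <- function(spec) {
  stopifnot(inherits(spec, "bound_spec"))
  log_eps <- log(spec$epsilon)
  f <- function(dt) crossing_probability(spec, dt)$log_p_total - log_eps
  lo <- spec$t_total * 1e-12
  hi <- spec$t_total
  flo <- f(lo)
  if (!is.finite(flo)) {          # p underflowed even in logs: push lo up
    while (!is.finite(flo) && lo < hi) { lo <- lo * 10; flo <- f(lo) }
  }
  if (is.finite(flo) && flo >= 0)
    stop(structure(class = c("unwrapnpt_no_safe_interval", "error",
                             "condition"),
                   list(message = paste0(
                     "no safe interval: even the smallest interval ",
                     "exceeds the tolerated crossing probability"),
                     call = sys.call(-1))))
  fhi <- f(hi)
  if (fhi < 0) {
    return(structure(list(dt_max = hi,
                          dt_closed_form = closed_form_interval(spec),
                          p_achieved = crossing_probability(spec, hi)$p_total,
                          capped = TRUE, spec = spec),
                     class = "sampling_bound"))
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-13,
                         maxiter = 5000L)$root
  structure(list(dt_max = root,
                 dt_closed_form = closed_form_interval(spec),
                 p_achieved = crossing_probability(spec, root)$p_total,
                 capped = FALSE, spec = spec),
            class = "sampling_bound")
}

#' @export
print.sampling_bound <- function(x, ...) {
  cat(sprintf(
    "sampling_bound (%s): dt_max = %.3g ps (closed form %.3g ps), P = %.3g%s\n",
    x$spec$mode, x$dt_max, x$dt_closed_form, x$p_achieved,
    if (x$capped) ", capped at t_total" else ""))
  invisible(x)
}
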