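# Diffusion-coefficient estimation from unwrapped trajectories: MSD with
# OLS window fits, the covariance-based estimator (CVE), block-wise drift
# diagnostics (the practical detector of lattice-view unwrapping
# artifacts), pair-diffusion additivity, and the volume-fluctuation
# compressibility relation.

#' Mean squared displacement of an unwrapped trajectory
#'
#' Single-trajectory time-averaged estimator at lag index m:
#' \deqn{MSD_m = \frac{1}{N-m} \sum_{i=0}^{N-m-1} |u_{i+m} - u_i|^2,}
#' summed over the d Cartesian components and averaged over particles.
#' For a diffusive process with static noise the expectation is
#' `2 d D tau + a^2` with `tau = m dt`.
#'
#' @param u an [unwrapped_trajectory()] (wrapped input is rejected: the MSD
#'   of a wrapped trajectory saturates at the box scale and does not
#'   measure diffusion).
#' @param max_lag largest lag index m (must be below the frame count).
#' @return Object of class `"msd_curve"`: a data frame with columns `m`
#'   (lag index, starting at 0), `tau` (lag time), `msd` and `n_pairs`
#'   (averaging count N - m), with attributes `d` (dimension) and `dt`.
#' @export
msd <- function(u, max_lag = NULL) {
  if (inherits(u, "wrapped_trajectory"))
    stop("msd requires an unwrapped trajectory; unwrap() it first")
  stopifnot(inherits(u, "unwrapped_trajectory"))
  n <- u$n_frames
  if (is.null(max_lag)) max_lag <- min(n - 1L, max(1L, n %/% 4L))
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n)
    stop("max_lag must be in [1, n_frames - 1]")
  vals <- numeric(max_lag)
  X <- u$positions
  for (m in seq_len(max_lag)) {
    D2 <- (X[(m + 1L):n, , , drop = FALSE] -
             X[1L:(n - m), , , drop = FALSE])^2
    # sum over axes, mean over time origins and particles
    vals[m] <- mean(rowSums(D2, dims = 2L))
  }
  out <- data.frame(m = 0L:max_lag, tau = (0L:max_lag) * u$box$dt,
                    msd = c(0, vals), n_pairs = n - (0L:max_lag))
  structure(out, d = u$n_axes, dt = u$box$dt,
            class = c("msd_curve", "data.frame"))
}

new_diffusion_fit <- function(D, a2, D_se, window, d, estimator, dt) {
  structure(list(D = D, a2 = a2, D_se = D_se, B = 0, window = window,
                 d = d, estimator = estimator, dt = dt),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit (%s, d = %d): D = %g +/- %s, a2 = %g\n",
              x$estimator, x$d, x$D,
              if (is.na(x$D_se)) "NA" else sprintf("%g", x$D_se), x$a2))
  invisible(x)
}

#' Ordinary least-squares fit of a straight line to the MSD
#'
#' Fits `MSD = 2 d D tau + a^2` over the lag-index window
#' `[m_init, m_end]`. The intercept is reported as-is (negative values are
#' legitimate and are not clipped). This is the classic "fit a line by eye
#' to the linear regime" estimator, which is comparatively robust to
#' lattice-view artifacts at long lags.
#'
#' @param curve an [msd()] result.
#' @param m_init,m_end first and last lag index of the fit window
#'   (`m_end > m_init`; a single point leaves the slope undefined).
#' @param intercept logical; `TRUE` (default) fits a free intercept `a^2`,
#'   `FALSE` anchors the line at the origin (`a^2` fixed to 0), the common
#'   naive straight-line-through-zero practice. The anchored fit inherits
#'   any short-lag MSD inflation as an apparent increase of D, which makes
#'   it the sensitive choice for the block-wise lattice-artifact
#'   diagnostic; the free-intercept fit absorbs such inflation into `a^2`.
#' @return A `"diffusion_fit"` with `D` (slope / 2d), `a2` (intercept) and
#'   the OLS standard error on `D`.
#' @export
ols_fit <- function(curve, m_init, m_end, intercept = TRUE) {
  stopifnot(inherits(curve, "msd_curve"))
  if (m_end <= m_init) stop("fit window must contain at least two lags")
  sel <- curve$m >= m_init & curve$m <= m_end
  if (sum(sel) != m_end - m_init + 1L)
    stop("fit window exceeds the computed lag range")
  d <- attr(curve, "d")
  dat <- curve[sel, , drop = FALSE]
  fit <- if (intercept) stats::lm(msd ~ tau, data = dat)
         else stats::lm(msd ~ tau - 1, data = dat)
  co <- summary(fit)$coefficients
  new_diffusion_fit(D = co["tau", "Estimate"] / (2 * d),
                    a2 = if (intercept) co["(Intercept)", "Estimate"] else 0,
                    D_se = co["tau", "Std. Error"] / (2 * d),
                    window = c(m_init, m_end), d = d,
                    estimator = if (intercept) "ols" else "ols0",
                    dt = attr(curve, "dt"))
}

# Per-series CVE moments: returns c(D, a2) for one 1D coordinate series.
cve_series <- function(x, dt) {
  dx <- diff(x)
  v <- mean(dx^2)
  cv <- if (length(dx) >= 2L) mean(dx[-length(dx)] * dx[-1L]) else 0
  c(D = v / (2 * dt) + cv / dt, a2 = -cv)
}

#' Covariance-based diffusion estimator (CVE)
#'
#' Closed-form, regression-free estimator built from the increment
#' variance and the lag-1 increment covariance of each 1D component:
#' \deqn{\hat D = \frac{\langle \Delta x^2 \rangle}{2\Delta t}
#'   + \frac{\langle \Delta x_i \Delta x_{i+1} \rangle}{\Delta t}, \qquad
#'   \hat a^2 = -\langle \Delta x_i \Delta x_{i+1} \rangle.}
#' For a diffusive walk observed with independent static (localization)
#' noise this is unbiased for both the diffusion coefficient and the
#' per-axis noise variance `a^2`. Estimates are averaged over axes and
#' particles; the standard error on D is computed across the independent
#' particle/axis series (NA for a single 1D series).
#'
#' @param u an [unwrapped_trajectory()] with at least 3 frames.
#' @return A `"diffusion_fit"` with estimator `"cve"`; `a2` is the
#'   per-axis static-noise variance (the MSD intercept of [ols_fit()]
#'   corresponds to `2 d a^2` in this convention).
#' @export
cve_fit <- function(u) {
  if (inherits(u, "wrapped_trajectory"))
    stop("cve_fit requires an unwrapped trajectory; unwrap() it first")
  stopifnot(inherits(u, "unwrapped_trajectory"))
  if (u$n_frames < 3L) stop("cve_fit needs at least 3 frames")
  dt <- u$box$dt
  est <- vapply(per_axis_view(u), function(s) cve_series(s$w, dt),
                numeric(2))
  Ds <- est["D", ]
  D_se <- if (length(Ds) > 1L) stats::sd(Ds) / sqrt(length(Ds)) else NA_real_
  new_diffusion_fit(D = mean(Ds), a2 = mean(est["a2", ]), D_se = D_se,
                    window = NULL, d = u$n_axes, estimator = "cve", dt = dt)
}

#' Block-wise diffusion estimates with a drift diagnostic
#'
#' Splits the trajectory into consecutive non-overlapping blocks of equal
#' duration, estimates D (and a2) independently in each block, and tests
#' for a monotone trend of D with block index using a Spearman rank
#' correlation with a permutation p-value. A stationary diffusive process
#' (e.g. a TOR-unwrapped trajectory) gives statistically flat block
#' estimates; lattice-view unwrapped data drift towards larger D in later
#' blocks as the particles leave the central box.
#'
#' @param u an [unwrapped_trajectory()].
#' @param block_duration block length in time units (a multiple of `dt`
#'   times the frames per block actually used; a trailing partial block is
#'   dropped with a message).
#' @param estimator `"cve"` (default), `"ols"` (free intercept) or
#'   `"ols0"` (origin-anchored OLS; the sensitive artifact detector, see
#'   [ols_fit()]).
#' @param m_init,m_end OLS window (only used for the OLS estimators).
#' @param n_perm number of permutations for the trend p-value.
#' @param perm_seed seed for the permutation draw (kept local; does not
#'   disturb the global RNG state).
#' @return Object of class `"block_series"`: list with `blocks` (data
#'   frame: `block`, `t_start`, `D`, `a2`, `D_se`), `trend` (Spearman rho
#'   of D vs block index), `p_value` (two-sided permutation p),
#'   `frames_per_block`, `estimator`.
#' @export
block_analysis <- function(u, block_duration,
                           estimator = c("cve", "ols", "ols0"),
                           m_init = 1L, m_end = 10L, n_perm = 10000L,
                           perm_seed = 1L) {
  stopifnot(inherits(u, "unwrapped_trajectory"))
  estimator <- match.arg(estimator)
  dt <- u$box$dt
  fpb <- floor(block_duration / dt)
  if (fpb < 3L) stop("block_duration must cover at least 3 frames")
  n_blocks <- u$n_frames %/% fpb
  if (n_blocks < 2L) stop("need at least 2 whole blocks")
  dropped <- u$n_frames - n_blocks * fpb
  if (dropped > 0L)
    message(sprintf("dropping trailing partial block of %d frame(s)",
                    dropped))
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * fpb + 1L):(b * fpb)
    sub <- unwrapped_trajectory(
      u$positions[idx, , , drop = FALSE],
      box_series(u$box$lengths[idx, , drop = FALSE], dt = dt),
      scheme = u$scheme)
    fit <- if (estimator == "cve") cve_fit(sub)
           else ols_fit(msd(sub, max_lag = min(m_end, fpb - 1L)),
                        m_init, min(m_end, fpb - 1L),
                        intercept = estimator == "ols")
    rows[[b]] <- data.frame(block = b, t_start = (idx[1L] - 1L) * dt,
                            D = fit$D, a2 = fit$a2, D_se = fit$D_se)
  }
  blocks <- do.call(rbind, rows)
  tr <- trend_test(blocks$D, n_perm = n_perm, seed = perm_seed)
  structure(list(blocks = blocks, trend = tr$rho, p_value = tr$p,
                 frames_per_block = fpb, estimator = estimator),
            class = "block_series")
}

# Spearman rank correlation of x against its index, two-sided permutation
# p-value. RNG use is isolated so analysis pipelines stay reproducible.
trend_test <- function(x, n_perm = 10000L, seed = 1L) {
  idx <- seq_along(x)
  # zero-variance input has no trend by definition; cor() warns and
  # returns NA there, which we propagate quietly
  rho <- suppressWarnings(stats::cor(idx, x, method = "spearman"))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x)
  ri <- rank(idx)
  null_rho <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    replicate(n_perm, stats::cor(ri, sample(rx)))
  })
  p <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (1 + n_perm)
  list(rho = rho, p = p)
}

#' @export
print.block_series <- function(x, ...) {
  cat(sprintf(
    "block_series (%s): %d blocks of %d frames; mean D = %g; trend rho = %.3f (p = %.3g)\n",
    x$estimator, nrow(x$blocks), x$frames_per_block, mean(x$blocks$D),
    x$trend, x$p_value))
  invisible(x)
}

#' Pair diffusion and the additivity check
#'
#' The distance vector between two independent diffusing particles is
#' itself diffusive with `D_pair = D_X + D_Y`. This estimates D on the two
#' input trajectories and on their difference and reports the additivity
#' gap `D_pair - (D_X + D_Y)`, which should be statistically zero for
#' independent particles when the unwrapping scheme preserves the
#' diffusive character.
#'
#' @param uX,uY [unwrapped_trajectory()]s with identical frame count,
#'   axes and sampling interval.
#' @param estimator `"cve"` (default) or `"ols"`.
#' @param m_init,m_end OLS window when `estimator = "ols"`.
#' @return List with `D_x`, `D_y`, `D_pair`, `gap`, `gap_se` (propagated
#'   from the individual standard errors, NA when unavailable) and the
#'   three fits.
#' @export
pair_diffusion <- function(uX, uY, estimator = c("cve", "ols"),
                           m_init = 1L, m_end = 10L) {
  stopifnot(inherits(uX, "unwrapped_trajectory"),
            inherits(uY, "unwrapped_trajectory"))
  estimator <- match.arg(estimator)
  if (uX$n_frames != uY$n_frames || uX$n_axes != uY$n_axes ||
      uX$box$dt != uY$box$dt)
    stop("trajectories must share frame count, axes and dt")
  diffpos <- uX$positions - uY$positions
  uD <- unwrapped_trajectory(diffpos, uX$box, scheme = "native")
  fit1 <- function(u) {
    if (estimator == "cve") cve_fit(u)
    else ols_fit(msd(u, max_lag = m_end), m_init, m_end)
  }
  fx <- fit1(uX); fy <- fit1(uY); fp <- fit1(uD)
  gap <- fp$D - (fx$D + fy$D)
  gap_se <- sqrt(sum(c(fx$D_se, fy$D_se, fp$D_se)^2))
  list(D_x = fx$D, D_y = fy$D, D_pair = fp$D, gap = gap, gap_se = gap_se,
       fits = list(x = fx, y = fy, pair = fp))
}

#' Isothermal compressibility from volume fluctuations
#'
#' Equilibrium relation `chi_T = Var(V) / (kB T <V>)`, with the unbiased
#' (n - 1) variance estimator. With V in nm^3 and T in K the result is in
#' 1/bar.
#'
#' @param V numeric vector of instantaneous box volumes (nm^3), length
#'   >= 2, all positive.
#' @param temperature absolute temperature (K).
#' @return Compressibility in bar^-1 (attribute `units`).
#' @export
compressibility <- function(V, temperature) {
  if (length(V) < 2L) stop("need at least 2 volume frames")
  if (any(V <= 0)) stop("volumes must be positive")
  stopifnot(temperature > 0)
  chi <- stats::var(V) / (KB_NM3_BAR_K * temperature * mean(V))
  structure(chi, units = "1/bar")
}

#' Per-frame box volume series
#'
#' @param box a [box_series()].
#' @return Numeric vector of per-frame volumes (product of the per-axis
#'   edge lengths).
#' @export
volume_series <- function(box) {
  stopifnot(inherits(box, "box_series"))
  apply(box$lengths, 1L, prod)
}
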