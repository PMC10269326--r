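---
title: "Unwrapping NPT trajectories and estimating diffusion coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unwrapping NPT trajectories and estimating diffusion coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwrapnpt)
```

## The two views of a periodic box, and why they disagree under a barostat

A particle trajectory from a simulation under periodic boundary conditions
is stored *wrapped*: at frame $i$ the coordinate $w_i$ lies inside the
central cell of edge length $L_i$. For diffusion analysis one needs the
*unwrapped* trajectory $u_i$, which records the particle's net
displacement through space. At constant volume the reconstruction is
unambiguous. Under a barostat, where $L_i$ fluctuates, two inequivalent
constructions exist, per Cartesian axis:

**Toroidal view (TOR).** Treat the cell as a torus and accumulate minimal
in-box displacements:
$$u_{i+1} = u_i + (w_{i+1} - w_i) - L_{i+1}
  \left\lfloor \frac{w_{i+1}-w_i}{L_{i+1}} + \tfrac12 \right\rfloor .$$

**Lattice view (LAT).** Treat the system as an infinite lattice of images
and track the integer image number $n_i$, either by bookkeeping or by
detecting jumps larger than half a box in the wrapped coordinates:
$$n_{i+1} = n_i - \left\lfloor \frac{w_{i+1}-w_i}{L_{i+1}} +
  \tfrac12\right\rfloor, \qquad u_i = w_i + n_i L_i .$$

The correction to TOR proposed by Kulke and Vermaas, implemented here as
`kv_unwrap()`, adds the rescaling term
$(L_{i+1}/L_i - 1)(u_i - w_i)$ to the TOR recursion; substituting the
lattice identity $u_i - w_i = n_i L_i$ shows it is algebraically the LAT
scheme, and the package enforces this equivalence numerically rather than
trusting any single transcription. The older heuristic `hlat_unwrap()`
(the image minimizing the apparent step) is provided for comparison; it
is known to pick wrong images under box fluctuations.

The two views genuinely differ: LAT multiplies the *unwrapped* coordinate
by $L_{i+1}/L_i$ each step, so a particle $k$ boxes from the origin picks
up position noise $\propto k\,\sigma_L$, unbounded as it diffuses away.
TOR's increments are bounded by the box, so the statistical character of
the wrapped dynamics is preserved — at the price of not preserving
distances between separately unwrapped particles.

Each view has exactly one consistent inverse. `lattice_wrap()`
($w_i = u_i - L_i\lfloor u_i/L_i + \alpha/2\rfloor$) inverts LAT;
`tor_rewrap()` backtraces displacements and inverts TOR. Cross-pairing
fails as soon as one crossing has occurred: TOR output is generally *not*
on the lattice of its own wrapped trajectory. The cell convention
$\alpha$ is 1 for origin-centered cells $[-L/2, L/2)$ (LAMMPS, NAMD) and
0 for corner-anchored cells $[0, L)$ (GROMACS); we default to $\alpha=1$
and never guess the convention from data. Cell intervals are half-open —
the lower edge owns a boundary point — which makes wrapping idempotent;
the choice of edge ownership is ours, as the conventions in circulation
do not fix it.

## The fluctuating-box model as an exact oracle

`simulate_gaussian_model()` generates the minimal stochastic model of a
diffusing particle in a white-noise box: with $L_i = L + \sigma_L R'_i$
and shared standard-normal draws $R_i$,
$$
\begin{aligned}
w_{i+1} &= \mathrm{wrap}_{\alpha=1,\,L_{i+1}}\!\left(
  \tfrac{L_{i+1}}{L_i} w_i + \sigma_w R_{i+1}\right),\\
u_{i+1} &= u_i + \left(\tfrac{L_{i+1}}{L_i} - 1\right) w_i
  + \sigma_w R_{i+1},\\
u^*_{i+1} &= \tfrac{L_{i+1}}{L_i}\, u^*_i + \sigma_w R_{i+1},
\end{aligned}
$$
with $w_0 = u_0 = u^*_0$ drawn uniformly in the centered cell of the
first-frame box. Because all three recursions consume the same noise,
they pin the schemes down exactly: TOR applied to $w$ must reproduce $u$,
and LAT applied to $w$ must reproduce $u^*$, frame by frame to round-off.
The test suite asserts these identities on ensembles of realizations;
any mis-transcription of either the model or a scheme breaks them.

The identities hold *conditionally*: if a single true step exceeds
$L_{i+1}/2$, the wrapped displacement no longer identifies the image
change and every scheme mis-assigns it. At the study conditions used
throughout ($L = 1$, $\sigma_L = 0.1L$, $\sigma_w = 0.05L$, $10^4$
steps) this is a $\sim 3\times10^{-6}$-per-step event, so a few
realizations per hundred contain one; the tests detect those
realizations explicitly (the condition, not the seed, decides) and
require the identities on all others. This rare failure mode is exactly
the event the sampling-interval bound quantifies.

Default parameters are the model's standard study conditions
($\sigma_L = 0.1L$, $\sigma_w = 0.05L$); box noise is white by
construction, all particles of a realization share one box series, and
each axis carries an independent box series. Ensembles derive
per-replicate seeds deterministically from a master seed, so every
replicate is bit-reproducible standalone.

What the model does *not* emulate: temporally correlated barostat noise
(real barostats have relaxation times of order 0.1–5 ps), interactions,
inertia, and realistic fluctuation amplitudes (for ambient water
$\sigma_L/L < 1\%$, not 10%). Passing tests therefore demonstrate the
algebra and statistics of the schemes, not quantitative agreement with
any particular force field. One consequence of the white-noise
idealization matters for interpreting the diagnostics and is discussed
below.

## Safe trajectory-output intervals

A saved trajectory can only be unwrapped correctly if no particle moves
more than $L/2$ along any axis between saved frames. For $N$ particles,
total time $t_\mathrm{total}$ and interval $\Delta t$, the probability
that this fails at least once is
$$P = 1 - \left(1 - \mathrm{erfc}\!\frac{L}{2\sqrt2\,\sigma}\right)^{3N
  t_\mathrm{total}/\Delta t},\qquad
\sigma^2 = \begin{cases}\Delta t^2/(\beta m) & \text{ballistic}\\
2D\,\Delta t & \text{diffusive,}\end{cases}$$
and `max_sampling_interval()` solves $P(\Delta t) = \varepsilon$ for the
largest safe $\Delta t$. The numeric root of this full relation is the
authoritative answer; the asymptotic closed form (replace erfc by its
large-argument expansion and linearize $P$) is evaluated as a
cross-check. In the ballistic regime $\Delta t$ cancels from the
prefactor and the closed form is a plain logarithm; in the diffusive
regime it requires the lower Lambert-W branch,
$\Delta t = -2b / W_{-1}(-2b(\varepsilon/C)^2)$ with $b = L^2/(16D)$,
implemented in `lambert_w_lower()` (Halley iteration from the series
guess, validated against its defining identity and an independent
implementation). When the expansion's argument leaves the branch domain
the asymptotics have no solution and the closed form reports `NA`; the
root solve still answers.

Numerical choices: probabilities are handled in log space (the erfc tail
underflows around $x \approx 27$, far inside the regime of interest);
the linearized form $P \approx 3 N \,\mathrm{Pr}\, t_\mathrm{total}/\Delta t$
is used when the expected event count is below $10^{-3}$, where its
relative error is below $5\times10^{-4}$; the root is polished to
$10^{-13}$ so that $P(\Delta t_{\max})$ matches $\varepsilon$ to
$10^{-10}$ relative. Units are fixed internally to nm, ps, K and g/mol
(the constructor accepts $D$ in the conventionally quoted nm²/ns);
$k_B T/m$ is then directly in nm²/ps². If even the largest interval
stays below $\varepsilon$ the result is capped at $t_\mathrm{total}$; if
the smallest probed interval is already unsafe, a "no safe interval"
condition is raised.

The total time of the worked water example (0.48/0.94/1.4 ps ballistic,
2.9/11/25 ps diffusive for $L$ = 2.5/5/7.5 nm) is taken as 1 μs, the
production length of the simulations it describes; the dependence is
logarithmic, so the choice is mild.

## Diffusion estimation and the block diagnostic

`msd()` implements the time-averaged single-trajectory estimator
$\mathrm{MSD}_m = \frac{1}{N-m}\sum_i |u_{i+m}-u_i|^2$ (validated
against a brute-force double loop), and the model for a diffusive
process with static noise is $\mathrm{MSD}(\tau) = 2dD\tau + a^2$ — the
motion-blur term that arises for time-averaged detection is identically
zero for simulation data and is fixed to zero here. Three fits are
provided:

- `ols_fit(..., intercept = TRUE)`: straight line with free intercept
  over a lag window, $D$ from the slope, $a^2$ the intercept (reported
  as-is, even when negative);
- `ols_fit(..., intercept = FALSE)` (`"ols0"`): the classic naive line
  through the origin;
- `cve_fit()`: the covariance-based estimator
  $\hat D = \langle\Delta x^2\rangle/2\Delta t +
  \langle\Delta x_i \Delta x_{i+1}\rangle/\Delta t$,
  $\hat a^2 = -\langle\Delta x_i \Delta x_{i+1}\rangle$ per axis. In this
  convention $\hat a^2$ estimates the per-axis static-noise *variance*
  (the MSD intercept equals $2d\,a^2$); the recovery tests inject known
  localization noise and recover it. The more elaborate
  maximum-likelihood and generalized-least-squares estimators from the
  single-particle-tracking literature are deliberately not reimplemented;
  the drift diagnostic below is estimator-agnostic.

Per-axis estimates are averaged; the standard error on $D$ assumes
independent particle/axis series.

`block_analysis()` splits a trajectory into equal non-overlapping blocks,
fits each independently, and tests for a monotone trend of $D_i$ against
block index with a Spearman rank correlation and a seeded permutation
p-value (rank-based because the drift, when present, is strongly
nonlinear). A stationary process gives flat blocks; lattice-view
unwrapped data drift.

**Which estimator sees the drift?** In the white-noise model the
lattice-view increments satisfy, to first order,
$\mathrm{Var}(\Delta u^*) = \sigma_w^2 + 2\,\mathrm{Var}(L)\,E[u^{*2}]/L^2$
with lag-1 covariance $-\mathrm{Var}(L)\,E[u^{*2}]/L^2$ and nothing
beyond — exactly the signature of diffusion plus a static-noise floor
that grows with the particle's squared distance from the origin.
Estimators that model that floor (CVE, free-intercept OLS) therefore
cancel the artifact out of $\hat D$ and report it as a growing
$\hat a^2$, leaving $\hat D$ flat; we verified this both analytically
and numerically. In real barostat data the box noise is temporally
correlated, the single-lag cancellation fails, and $\hat D$ itself
drifts. For a white-noise validation ensemble the sensitive $D$-side
diagnostic is the origin-anchored fit, which inherits the floor as
apparent speed-up — so the package's discrimination test asserts (i) a
positive `ols0` block-$D$ trend and inflated late blocks for LAT with
flat TOR blocks, and (ii) the companion CVE $\hat a^2$ trend. On 200
realizations of $10^4$ steps both discriminate at permutation
$p < 10^{-3}$. Correspondingly, the ensemble-mean MSD of LAT data is
inflated at short lags while its long-lag *slope* converges to the TOR
slope — which is why published diffusion coefficients from long-lag
straight-line fits are much less affected by the wrong unwrapping choice
than short-lag or likelihood-based estimates.

`pair_diffusion()` checks the additivity
$D^{X-Y} = D^X + D^Y$ for independent particles — preserved by TOR
block-by-block — and `compressibility()` implements
$\chi_T = \mathrm{Var}(V) / (k_B T \langle V\rangle)$ (unbiased
variance; nm³ and K in, bar⁻¹ out), the relation that quantifies why
relative box fluctuations, and with them all of the above artifacts,
shrink with system size.

## Molecules

TOR unwrapping must never be applied atom-by-atom to a bonded molecule:
when a bond straddles the boundary while the box rescales, the atoms are
displaced inconsistently and the bond stretches unphysically.
`unwrap_molecule()` applies the safe order of operations — (1) make the
molecule whole in every frame by placing each atom at the minimal image
relative to its already-placed bonded neighbor (deterministic
breadth-first traversal from the reference atom, ascending atom index,
so outputs are bit-reproducible), (2) wrap the center of mass (or a
chosen reference atom, avoiding the mass weighting), (3) TOR-unwrap that
single-particle trajectory, (4) reconstruct atoms around it using their
whole-frame offsets. Reconstruction preserves every intramolecular
distance of the whole frames exactly, and the reconstructed center of
mass equals the unwrapped one. A minimal-image bond component of exactly
$L/2$ is ambiguous and rejected; the procedure assumes true bond lengths
below half the box. End-to-end analyses of polymers need only step (1)
per frame. The test suite drives a rigid dimer through hundreds of
boundary crossings and verifies the bond is preserved to $10^{-12}$
while naive per-atom unwrapping stretches it beyond 1.5 bond lengths.

## Problem sizes and limitations

The validation ensembles used by the tests and described above are
100–200 realizations of $10^4$ steps (single particle, one to three
axes), block lengths of 500–2000 frames, and estimator-recovery runs of
a few thousand frames times tens of replicates — sizes chosen so the
statistical assertions (3-standard-error bands, permutation p-values at
$10^4$ permutations) are well resolved while the whole suite runs in
about a minute.

Known limitations: orthorhombic (per-axis independent) boxes only —
triclinic cells, velocities and per-frame topology changes are out of
scope; the box-noise model is white, so temporally correlated barostat
effects are only represented qualitatively; no finite-size corrections
are applied to diffusion coefficients; and the package deliberately does
not attempt to "sanitize" the bounded multiplicative noise that barostat
rescaling leaves even in correctly (TOR-)unwrapped data — at constant
pressure that noise is part of the ensemble's dynamics, and users who
cannot tolerate it should run at constant volume, where the two views
coincide and unwrapping is unambiguous.
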