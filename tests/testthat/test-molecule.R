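dimer_topology <- function() {
  molecule_topology(masses = c(16, 1), bonds = rbind(c(1L, 2L)),
                    reference = 1L)
}

test_that("topology construction validates the bond graph", {
  expect_error(molecule_topology(c(1, 1), matrix(integer(), ncol = 2)),
               "disconnected")
  expect_error(molecule_topology(c(1, -1), rbind(c(1, 2))), "positive")
  expect_error(molecule_topology(c(1, 1), rbind(c(1, 3))), "out of range")
  topo <- molecule_topology(c(12, 1, 1), rbind(c(1, 2), c(1, 3)))
  expect_equal(topo$adjacency[[1]], c(2L, 3L))
})

test_that("make_whole reconnects a split diatomic by minimal image", {
  topo <- dimer_topology()
  intact <- rbind(0.1, 0.2)
  expect_equal(make_whole(intact, 1, topo), intact)
  split <- rbind(0.45, -0.45)
  expect_equal(make_whole(split, 1, topo), rbind(0.45, 0.55))
})

test_that("make_whole is idempotent on randomized broken molecules", {
  set.seed(14)
  topo <- molecule_topology(c(12, 1, 1, 1),
                            rbind(c(1, 2), c(2, 3), c(3, 4)))
  for (rep in 1:20) {
    L <- c(2, 2.5)
    base <- matrix(runif(8, -0.2, 0.2), 4, 2)          # compact chain
    base <- apply(base, 2, cumsum)
    broken <- base + matrix(sample(-2:2, 8, TRUE), 4, 2) * rep(L, each = 4)
    whole <- make_whole(broken, L, topo)
    expect_equal(make_whole(whole, L, topo), whole)
    # all bond vectors are minimal-image after the pass
    for (b in 1:3) {
      d <- whole[b + 1, ] - whole[b, ]
      expect_true(all(abs(d) < L / 2))
    }
  }
})

test_that("bonds at or beyond half the box are rejected as ambiguous", {
  topo <- dimer_topology()
  expect_error(make_whole(rbind(0, 0.5), 1, topo), "ambiguous")
})

test_that("center of mass series wraps correctly", {
  topo <- molecule_topology(c(1, 1), rbind(c(1, 2)))
  b <- box_series(1)
  frames <- array(c(-0.1, 0.1), dim = c(1, 2, 1))
  com <- com_series(frames, topo, b, alpha = 1)
  expect_equal(com$positions[1, 1, 1], 0)
  # COM at 0.6 L wraps to -0.4 L in the centered cell
  frames2 <- array(c(0.55, 0.65), dim = c(1, 2, 1))
  com2 <- com_series(frames2, topo, b, alpha = 1)
  expect_equal(com2$positions[1, 1, 1], -0.4)
  # single-atom molecule: COM equals the atom
  topo1 <- molecule_topology(5, NULL)
  frames3 <- array(0.3, dim = c(1, 1, 1))
  expect_equal(com_series(frames3, topo1, b)$positions[1, 1, 1], 0.3)
})

# A rigid dimer translating through a fluctuating box; atoms stored
# wrapped, so bonds straddle the boundary in many frames.
rigid_dimer_frames <- function(n = 400, bond = 0.2, seed = 42) {
  set.seed(seed)
  L <- 1 + 0.1 * rnorm(n)
  com_true <- cumsum(c(0, rnorm(n - 1, sd = 0.15)))
  atoms <- array(NA_real_, dim = c(n, 2, 1))
  atoms[, 1, 1] <- lattice_wrap(com_true - bond / 2, L, alpha = 1)
  atoms[, 2, 1] <- lattice_wrap(com_true + bond / 2, L, alpha = 1)
  list(frames = atoms, box = box_series(L), bond = bond)
}

test_that("whole-then-unwrap preserves the bond; naive per-atom TOR breaks it", {
  fx <- rigid_dimer_frames()
  topo <- molecule_topology(c(1, 1), rbind(c(1, 2)))
  res <- unwrap_molecule(fx$frames, topo, fx$box, alpha = 1)
  bonds <- abs(res$atoms[, 2, 1] - res$atoms[, 1, 1])
  expect_lt(max(abs(bonds - fx$bond)), 1e-12)
  # naive per-atom unwrapping stretches the bond when it straddles the
  # boundary while the box changes
  naive <- unwrap(wrapped_trajectory(fx$frames, fx$box, alpha = 1), "tor")
  naive_bonds <- abs(naive$positions[, 2, 1] - naive$positions[, 1, 1])
  expect_gt(max(naive_bonds), 1.5 * fx$bond)
})

test_that("reconstructed center of mass equals the unwrapped one", {
  fx <- rigid_dimer_frames(n = 200, seed = 77)
  topo <- molecule_topology(c(16, 1), rbind(c(1, 2)))
  res <- unwrap_molecule(fx$frames, topo, fx$box, alpha = 1)
  m <- topo$masses
  com_rec <- (res$atoms[, 1, 1] * m[1] + res$atoms[, 2, 1] * m[2]) / sum(m)
  expect_equal(com_rec, res$com$positions[, 1, 1], tolerance = 1e-12)
})

test_that("single-atom molecules reduce to plain TOR unwrapping", {
  set.seed(5)
  L <- 1 + 0.1 * rnorm(100)
  w <- lattice_wrap(cumsum(c(0.2, rnorm(99, sd = 0.2))), L, alpha = 1)
  topo <- molecule_topology(18, NULL)
  res <- unwrap_molecule(array(w, dim = c(100, 1, 1)), topo,
                         box_series(L), alpha = 1)
  expect_equal(res$com$positions[, 1, 1], tor_unwrap(w, L))
})

test_that("reference-atom tracking agrees with center-of-mass tracking", {
  Dc <- Dr <- numeric(15)
  topo <- molecule_topology(c(16, 1), rbind(c(1, 2)))
  for (k in 1:15) {
    fx <- rigid_dimer_frames(n = 1500, seed = 500 + k)
    rc <- unwrap_molecule(fx$frames, topo, fx$box, mode = "com",
                          reconstruct = FALSE)
    rr <- unwrap_molecule(fx$frames, topo, fx$box, mode = "reference",
                          reconstruct = FALSE)
    Dc[k] <- cve_fit(rc$com)$D
    Dr[k] <- cve_fit(rr$com)$D
  }
  gap <- Dc - Dr
  expect_lt(abs(mean(gap)), 3 * stats::sd(gap) / sqrt(15) + 1e-12)
})
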