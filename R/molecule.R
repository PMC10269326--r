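# Handling bonded molecules. TOR unwrapping does not preserve distances
# between separately unwrapped particles, so applying it atom-by-atom
# stretches bonds that straddle a periodic boundary while the box changes.
# The remedy is an order of operations: (1) make the molecule whole in
# every frame using minimal-image bond vectors, (2) wrap its center of
# mass, (3) TOR-unwrap the center-of-mass trajectory, (4) reconstruct the
# atoms around the unwrapped center of mass.

#' Molecular topology for make-whole and center-of-mass operations
#'
#' @param masses positive atomic masses (amu), one per atom.
#' @param bonds two-column integer matrix of bonded atom index pairs
#'   (1-based); the bond graph must be connected.
#' @param reference index of the reference atom from which the make-whole
#'   traversal starts.
#' @return Object of class `"molecule_topology"` with a precomputed
#'   adjacency list.
#' @export
molecule_topology <- function(masses, bonds, reference = 1L) {
  masses <- as.numeric(masses)
  n <- length(masses)
  if (n < 1L || any(masses <= 0)) stop("masses must be positive")
  if (n == 1L) {
    bonds <- matrix(integer(), ncol = 2L)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) != 2L) stop("bonds must be a two-column matrix")
    if (any(bonds < 1L | bonds > n)) stop("bond index out of range")
  }
  reference <- as.integer(reference)
  if (reference < 1L || reference > n) stop("reference atom index invalid")
  adj <- lapply(seq_len(n), function(i)
    sort(unique(c(bonds[bonds[, 1L] == i, 2L], bonds[bonds[, 2L] == i, 1L]))))
  # connectivity check by BFS
  seen <- logical(n)
  queue <- reference
  seen[reference] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) stop("bond graph is disconnected")
  structure(list(masses = masses, bonds = bonds, reference = reference,
                 adjacency = adj, n_atoms = n),
            class = "molecule_topology")
}

#' Make a molecule whole across periodic boundaries
#'
#' Deterministic breadth-first traversal from the reference atom (neighbors
#' visited in ascending index order); each atom is placed at the minimal
#' periodic image relative to its already-placed bonded parent. Afterwards
#' every bond vector is a minimal-image vector. Idempotent: a whole
#' molecule is left untouched.
#'
#' @param positions atoms x axes numeric matrix for one frame.
#' @param L per-axis box edge lengths for that frame (vector, recycled if
#'   scalar).
#' @param topology a [molecule_topology()].
#' @return Positions matrix with all atoms placed contiguously. Errors if
#'   any minimal-image bond component ties at exactly L/2 (ambiguous
#'   image); physical bonds must be shorter than half the box.
#' @export
make_whole <- function(positions, L, topology) {
  stopifnot(inherits(topology, "molecule_topology"))
  positions <- as.matrix(positions)
  if (nrow(positions) != topology$n_atoms)
    stop("positions row count must match atom count")
  n_axes <- ncol(positions)
  L <- rep_len(as.numeric(L), n_axes)
  if (any(L <= 0)) stop("box lengths must be positive")
  out <- positions
  seen <- logical(topology$n_atoms)
  queue <- topology$reference
  seen[topology$reference] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (nb in topology$adjacency[[v]]) {
      if (seen[nb]) next
      d <- out[nb, ] - out[v, ]
      dmin <- d - L * floor(d / L + 0.5)
      if (any(abs(dmin) >= L / 2))
        stop(sprintf(
          "ambiguous image for bond %d-%d: minimal-image component >= L/2",
          v, nb))
      out[nb, ] <- out[v, ] + dmin
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  out
}

#' Wrapped center-of-mass trajectory of a whole molecule
#'
#' Mass-weighted mean position per frame, lattice-wrapped into the central
#' cell whenever it falls outside.
#'
#' @param frames frames x atoms x axes array of already-whole positions.
#' @param topology a [molecule_topology()] (supplies the masses).
#' @param box a [box_series()].
#' @param alpha cell convention, 0 or 1.
#' @return A [wrapped_trajectory()] with a single particle.
#' @export
com_series <- function(frames, topology, box, alpha = 1) {
  stopifnot(inherits(topology, "molecule_topology"),
            inherits(box, "box_series"))
  frames <- as_positions(frames, box$n_axes)
  if (dim(frames)[2L] != topology$n_atoms)
    stop("frame atom count must match topology")
  m <- topology$masses
  mtot <- sum(m)
  if (mtot <= 0) stop("total mass must be positive")
  n <- dim(frames)[1L]
  com <- array(NA_real_, dim = c(n, 1L, box$n_axes))
  for (a in seq_len(box$n_axes)) {
    raw <- matrix(frames[, , a], nrow = n) %*% m / mtot
    com[, 1L, a] <- lattice_wrap(as.vector(raw), box$lengths[, a], alpha)
  }
  wrapped_trajectory(com, box, alpha = alpha)
}

#' Unwrap a molecular trajectory via its center of mass
#'
#' Runs the recommended order of operations for bonded molecules under a
#' fluctuating box: make whole per frame, wrap the center of mass (or a
#' chosen reference atom), TOR-unwrap that single-particle trajectory, and
#' optionally reconstruct all atoms by translating each whole frame so its
#' center of mass coincides with the unwrapped one. Reconstruction
#' preserves every intramolecular distance of the whole frames exactly.
#'
#' @param frames frames x atoms x axes array of (possibly broken) atomic
#'   positions.
#' @param topology a [molecule_topology()].
#' @param box a [box_series()].
#' @param alpha cell convention used for the center-of-mass wrap.
#' @param mode `"com"` (mass-weighted center) or `"reference"` (track the
#'   reference atom instead; avoids the mass weighting).
#' @param reconstruct logical; also return the reconstructed atom array.
#' @return List with `com` (single-particle [unwrapped_trajectory()],
#'   scheme `"tor"`), `atoms` (frames x atoms x axes array or NULL) and
#'   `whole` (the made-whole frames).
#' @export
unwrap_molecule <- function(frames, topology, box, alpha = 1,
                            mode = c("com", "reference"),
                            reconstruct = TRUE) {
  stopifnot(inherits(topology, "molecule_topology"),
            inherits(box, "box_series"))
  mode <- match.arg(mode)
  frames <- as_positions(frames, box$n_axes)
  n <- dim(frames)[1L]
  whole <- frames
  for (i in seq_len(n))
    whole[i, , ] <- make_whole(matrix(frames[i, , ], ncol = box$n_axes),
                               box$lengths[i, ], topology)
  m <- topology$masses
  track <- array(NA_real_, dim = c(n, 1L, box$n_axes))
  raw <- matrix(NA_real_, n, box$n_axes)  # unwrapped-frame tracking point
  for (a in seq_len(box$n_axes)) {
    raw[, a] <- if (mode == "com")
      as.vector(matrix(whole[, , a], nrow = n) %*% m / sum(m))
    else whole[, topology$reference, a]
    track[, 1L, a] <- lattice_wrap(raw[, a], box$lengths[, a], alpha)
  }
  wtrack <- wrapped_trajectory(track, box, alpha = alpha)
  ucom <- unwrap(wtrack, "tor")
  atoms <- NULL
  if (reconstruct) {
    atoms <- whole
    for (a in seq_len(box$n_axes)) {
      shift <- ucom$positions[, 1L, a] - raw[, a]
      atoms[, , a] <- whole[, , a] + shift
    }
  }
  list(com = ucom, atoms = atoms, whole = whole)
}
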