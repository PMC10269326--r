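# Plain-text trajectory format. One row per (frame, particle), columns:
#   frame  time  particle  x [y z]  Lx [Ly Lz]  [nx ny nz]
# Floats are written with 17 significant digits so that write -> read
# round-trips bit-exactly; far-from-origin unwrapped coordinates make
# faithful storage a correctness issue, not cosmetics.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trajectory to the native TSV format
#'
#' @param traj a [wrapped_trajectory()] or [unwrapped_trajectory()];
#'   image numbers, when present, are written as `nx`/`ny`/`nz` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, c("wrapped_trajectory", "unwrapped_trajectory")))
  ax <- c("x", "y", "z")[seq_len(traj$n_axes)]
  Lx <- c("Lx", "Ly", "Lz")[seq_len(traj$n_axes)]
  nx <- c("nx", "ny", "nz")[seq_len(traj$n_axes)]
  has_img <- inherits(traj, "unwrapped_trajectory") && !is.null(traj$images)
  n <- traj$n_frames
  p <- traj$n_particles
  frame <- rep(seq_len(n), each = p)
  particle <- rep(seq_len(p), times = n)
  cols <- list(frame = frame - 1L,
               time = fmt_num((frame - 1L) * traj$box$dt),
               particle = particle)
  for (a in seq_len(traj$n_axes))
    cols[[ax[a]]] <- fmt_num(as.vector(t(traj$positions[, , a])))
  for (a in seq_len(traj$n_axes))
    cols[[Lx[a]]] <- fmt_num(traj$box$lengths[frame, a])
  if (has_img)
    for (a in seq_len(traj$n_axes))
      cols[[nx[a]]] <- format(as.vector(t(traj$images[, , a])),
                              scientific = FALSE, trim = TRUE)
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory from the native TSV format
#'
#' @param path input file path.
#' @param alpha cell convention to attach when the file is read as a
#'   wrapped trajectory (never guessed from the data).
#' @param as `"auto"` (unwrapped when image-number columns are present,
#'   wrapped otherwise), `"wrapped"` or `"unwrapped"`.
#' @param scheme provenance tag attached when reading an unwrapped
#'   trajectory.
#' @return A [wrapped_trajectory()] or [unwrapped_trajectory()].
#' @export
read_trajectory <- function(path, alpha = 1, as = c("auto", "wrapped",
                                                    "unwrapped"),
                            scheme = "native") {
  as <- match.arg(as)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("malformed trajectory file '", path, "': ",
                             conditionMessage(e)))
  cn <- colnames(df)
  for (col in c("frame", "time", "particle"))
    if (!col %in% cn) stop("missing required column '", col, "'")
  ax <- intersect(c("x", "y", "z"), cn)
  if (length(ax) == 0L) stop("missing coordinate column 'x'")
  Lx <- paste0("L", ax)
  for (col in Lx)
    if (!col %in% cn) stop("missing box column '", col, "'")
  nx <- paste0("n", ax)
  has_img <- all(nx %in% cn)
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1L]
    stop(sprintf("ragged or non-numeric data at data line %d", bad))
  }
  frames <- sort(unique(df$frame))
  particles <- sort(unique(df$particle))
  n <- length(frames)
  p <- length(particles)
  if (nrow(df) != n * p)
    stop("file does not contain one row per frame/particle pair")
  df <- df[order(df$frame, df$particle), , drop = FALSE]
  dt <- if (n > 1L) (df$time[p + 1L] - df$time[1L]) else 1
  if (dt <= 0) stop("non-increasing time column")
  k <- length(ax)
  pos <- array(NA_real_, dim = c(n, p, k))
  img <- if (has_img) array(NA_real_, dim = c(n, p, k))
  Lmat <- matrix(NA_real_, n, k)
  first_of_frame <- seq(1L, nrow(df), by = p)
  for (a in seq_len(k)) {
    pos[, , a] <- t(matrix(df[[ax[a]]], nrow = p))
    Lmat[, a] <- df[[Lx[a]]][first_of_frame]
    if (has_img) img[, , a] <- t(matrix(df[[nx[a]]], nrow = p))
  }
  if (any(Lmat <= 0)) {
    bad <- which(Lmat <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive box length at frame %d (data line %d)",
                 frames[bad[1L]], (bad[1L] - 1L) * p + 1L))
  }
  box <- box_series(Lmat, dt = dt)
  type <- if (as == "auto") { if (has_img) "unwrapped" else "wrapped" } else as
  if (type == "wrapped")
    wrapped_trajectory(pos, box, alpha = alpha)
  else
    unwrapped_trajectory(pos, box, scheme = scheme, images = img)
}

#' Read a molecular topology from a JSON sidecar
#'
#' Expected fields: `masses` (array), `bonds` (array of `[i, j]` pairs,
#' 1-based), optional `reference` (default 1).
#'
#' @param path JSON file path.
#' @return A [molecule_topology()].
#' @export
read_topology <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$masses)) stop("topology file must contain 'masses'")
  bonds <- if (is.null(obj$bonds)) matrix(integer(), ncol = 2L)
           else matrix(as.integer(unlist(obj$bonds)), ncol = 2L,
                       byrow = !is.matrix(obj$bonds))
  if (is.matrix(obj$bonds)) bonds <- obj$bonds
  molecule_topology(obj$masses, bonds,
                    reference = if (is.null(obj$reference)) 1L
                                else obj$reference)
}
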