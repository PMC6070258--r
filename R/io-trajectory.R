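# AKMA time unit used by CHARMM-style DCD headers, in ps
.akma_ps <- 0.04888821

#' Trajectory container
#'
#' An `md_trajectory` stores coordinates as a frames x 3N matrix in Angstrom
#' (row layout x1 y1 z1 x2 y2 z2 ...), the frame spacing in ps, and the atom
#' table of the topology it belongs to. All frames share one atom ordering.
#'
#' @param xyz frames x 3N numeric matrix (Angstrom).
#' @param dt_ps frame spacing in picoseconds (> 0).
#' @param atoms atom table (as in [md_structure()]); optional.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(xyz, dt_ps, atoms = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stopf("trajectory must contain at least one frame")
  if (ncol(xyz) %% 3L != 0L) stopf("coordinate row length must be a multiple of 3")
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || dt_ps <= 0) {
    stopf("dt_ps must be a single positive number")
  }
  if (!is.null(atoms) && nrow(atoms) != ncol(xyz) / 3L) {
    stopf("atom table has %d atoms but coordinates have %d",
          nrow(atoms), ncol(xyz) / 3L)
  }
  structure(list(xyz = unname(xyz), dt_ps = dt_ps, atoms = atoms),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, dt = %g ps (%.4g ns total)\n",
              n_frames(x), n_atoms(x), x$dt_ps,
              n_frames(x) * x$dt_ps / 1000))
  invisible(x)
}

#' @rdname md_trajectory
#' @param x an `md_trajectory`.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' @rdname md_trajectory
#' @export
n_atoms <- function(x) ncol(x$xyz) / 3L

#' Frame times in ns
#' @param x an `md_trajectory`.
#' @return numeric vector, one value per frame (first frame at 0).
#' @export
frame_times_ns <- function(x) (seq_len(n_frames(x)) - 1) * x$dt_ps / 1000

#' Build a trajectory from structures
#'
#' Stacks an `md_ensemble` (multi-model PDB) or a list of conformers of one
#' topology into an `md_trajectory` so ensemble analyses (e.g. cross
#' correlation over crystal structures) reuse the trajectory operations.
#'
#' @param x an `md_ensemble` or list of `md_structure` objects.
#' @param dt_ps nominal frame spacing (default 1 ps; ensembles have no time axis).
#' @return an `md_trajectory`.
#' @export
as_trajectory <- function(x, dt_ps = 1) {
  if (inherits(x, "md_structure")) x <- list(x)
  n <- vapply(x, function(s) nrow(s$xyz), integer(1))
  if (length(unique(n)) != 1L) stopf("structures differ in atom count")
  xyz <- do.call(rbind, lapply(x, function(s) coords_row(s$xyz)))
  md_trajectory(xyz, dt_ps = dt_ps, atoms = x[[1]]$atoms)
}

#' Extract one frame as a structure
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @return an `md_structure` (requires the trajectory to carry an atom table).
#' @export
frame_structure <- function(traj, frame) {
  if (is.null(traj$atoms)) stopf("trajectory carries no atom table")
  md_structure(traj$atoms, frame_coords(traj$xyz, frame))
}

#' Read a trajectory file
#'
#' Reads DCD coordinate trajectories (CHARMM/NAMD flavour). Coordinates are
#' returned in Angstrom. The frame spacing is taken from the DCD header when
#' present, otherwise from `dt_ps`.
#'
#' @param path path to a `.dcd` file.
#' @param topology `md_structure` whose atom count must match the file.
#' @param dt_ps frame spacing override in ps.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(path, topology, dt_ps = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc") {
    stopf("XTC trajectories are not supported; convert to DCD")
  }
  if (ext != "dcd") stopf("unknown trajectory extension '.%s' (expected .dcd)", ext)
  hdr <- read_dcd_header(path)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) == 0L) stopf("trajectory %s contains no frames", path)
  n_at <- ncol(xyz) / 3L
  if (!missing(topology) && !is.null(topology)) {
    if (nrow(topology$atoms) != n_at) {
      stopf("atom count mismatch: trajectory has %d atoms, topology has %d",
            n_at, nrow(topology$atoms))
    }
  }
  dt <- dt_ps %||% hdr$dt_ps
  if (is.null(dt) || !is.finite(dt) || dt <= 0) dt <- 1
  md_trajectory(xyz, dt_ps = dt,
                atoms = if (!missing(topology) && !is.null(topology)) topology$atoms else NULL)
}

# minimal DCD header peek: frame count and time step
read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  end <- "little"
  m <- readBin(con, "integer", 1, size = 4, endian = end)
  if (m != 84) {
    end <- "big"
    seek(con, 0)
    m <- readBin(con, "integer", 1, size = 4, endian = end)
    if (m != 84) stopf("%s is not a DCD file", path)
  }
  tag <- rawToChar(readBin(con, "raw", 4))
  if (tag != "CORD") stopf("%s is not a coordinate DCD file", path)
  icntrl_raw <- readBin(con, "raw", 80)
  ints <- readBin(icntrl_raw, "integer", 20, size = 4, endian = end)
  delta <- readBin(icntrl_raw[37:40], "numeric", 1, size = 4, endian = end)
  nsavc <- ints[3]
  dt_ps <- if (is.finite(delta) && delta > 0) delta * .akma_ps * max(1, nsavc) else NULL
  list(n_frames = ints[1], dt_ps = dt_ps, endian = end)
}

#' Write a trajectory to a DCD file
#'
#' Writes a CHARMM-format binary DCD (no unit cell). The frame spacing is
#' stored in the header so it round-trips through [read_trajectory()].
#'
#' @param traj an `md_trajectory`.
#' @param path output path (`.dcd`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4)
  # header record (84 bytes): CORD + 20 control ints, slot 10 is a float
  wint(84)
  writeBin(charToRaw("CORD"), con)
  wint(c(nf, 0L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(traj$dt_ps / .akma_ps, con, size = 4)  # delta, AKMA units
  wint(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84)
  title <- formatC("written by mdscope", width = -80)
  wint(4 + 80)
  wint(1)
  writeBin(charToRaw(title), con)
  wint(4 + 80)
  wint(4)
  wint(na)
  wint(4)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj$xyz, f)
    for (ax in 1:3) {
      wint(4 * na)
      writeBin(as.numeric(m[, ax]), con, size = 4)
      wint(4 * na)
    }
  }
  invisible(path)
}
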