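#' Free-energy landscape over two principal components
#'
#' Estimates the joint density of two projection coordinates with a 2-D
#' Gaussian kernel (Scott's rule bandwidth per axis unless overridden) on a
#' regular grid, and converts it to a free energy
#' G = -kB * T * ln(P / P_max) in J/mol, so the most populated cell sits at
#' G = 0 (kB*T is about 2519 J/mol at 303 K). Every frame is assigned to its
#' containing cell.
#'
#' @param proj a `projection_series` (or frames x modes matrix).
#' @param pc_pair the two mode indices to use (default c(1, 2)).
#' @param grid cells per axis (default 100).
#' @param temperature Kelvin (default 303).
#' @param bandwidth optional length-2 kernel standard deviations (data units).
#' @param pad grid margin in bandwidths beyond the data range (default 3).
#' @return a `fel_grid`: grid centre vectors `x`, `y`, `energy` matrix
#'   (J/mol; +Inf where the density underflows), `frame_cell` (frames x 2
#'   cell indices), the projected coordinates, and metadata.
#' @export
fel_from_projections <- function(proj, pc_pair = c(1, 2), grid = 100L,
                                 temperature = 303, bandwidth = NULL, pad = 3) {
  proj <- as.matrix(proj)
  if (nrow(proj) < 100L) stopf("need at least 100 frames for a landscape")
  if (max(pc_pair) > ncol(proj)) stopf("pc_pair exceeds available modes")
  x <- proj[, pc_pair[1]]
  y <- proj[, pc_pair[2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("degenerate (zero-variance) reaction coordinate")
  }
  n <- length(x)
  bw <- bandwidth %||% (c(stats::sd(x), stats::sd(y)) * n^(-1 / 6))  # Scott
  lims <- c(range(x) + c(-pad, pad) * bw[1], range(y) + c(-pad, pad) * bw[2])
  # MASS::kde2d uses h/4 as the kernel standard deviation
  kd <- MASS::kde2d(x, y, h = 4 * bw, n = grid, lims = lims)
  p <- kd$z
  pmax_ <- max(p)
  energy <- ifelse(p > 0, -.kB * temperature * log(p / pmax_), Inf)
  energy[energy < 0] <- 0
  cell_x <- findInterval(x, midpoints(kd$x), all.inside = TRUE) + 1L
  cell_y <- findInterval(y, midpoints(kd$y), all.inside = TRUE) + 1L
  cell_x <- pmin(pmax(cell_x, 1L), grid)
  cell_y <- pmin(pmax(cell_y, 1L), grid)
  structure(list(x = kd$x, y = kd$y, energy = energy, density = p,
                 frame_cell = cbind(cell_x, cell_y),
                 coords = cbind(x, y), pc_pair = pc_pair,
                 temperature = temperature, bandwidth = bw),
            class = "fel_grid")
}

midpoints <- function(v) (v[-1] + v[-length(v)]) / 2

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("fel_grid over PC%d/PC%d: %d x %d cells, kT = %.1f J/mol\n",
              x$pc_pair[1], x$pc_pair[2], length(x$x), length(x$y),
              .kB * x$temperature))
  invisible(x)
}

#' Extract low-energy basins from a landscape
#'
#' Connected components (4-neighbour) of grid cells with G below `threshold`.
#' Each basin reports its member frames (frames assigned to member cells),
#' its occupancy-weighted centroid in PC space, and its minimum-energy cell;
#' basins are ordered by increasing minimum energy (ties broken by occupancy).
#'
#' @param fel a `fel_grid`.
#' @param threshold free-energy cutoff in J/mol (default 100).
#' @return list of basins (possibly empty), each a list with `frames`,
#'   `centroid`, `min_cell`, `min_energy`, `n_cells`, `occupancy`.
#' @export
extract_basins <- function(fel, threshold = 100) {
  if (threshold <= 0) stopf("threshold must be > 0")
  low <- is.finite(fel$energy) & fel$energy < threshold
  if (!any(low)) {
    message("no cells below the free-energy threshold")
    return(list())
  }
  nx <- nrow(fel$energy)
  ny <- ncol(fel$energy)
  comp <- matrix(0L, nx, ny)
  cur <- 0L
  for (s in which(low & comp == 0L)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      i <- (v - 1L) %% nx + 1L
      j <- (v - 1L) %/% nx + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1L || ii > nx || jj < 1L || jj > ny) next
        w <- (jj - 1L) * nx + ii
        if (low[w] && comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  frame_comp <- comp[cbind(fel$frame_cell[, 1], fel$frame_cell[, 2])]
  basins <- lapply(seq_len(cur), function(b) {
    cells <- which(comp == b)
    frames <- which(frame_comp == b)
    centroid <- if (length(frames)) {
      colMeans(fel$coords[frames, , drop = FALSE])
    } else {
      ci <- (cells - 1L) %% nx + 1L
      cj <- (cells - 1L) %/% nx + 1L
      c(mean(fel$x[ci]), mean(fel$y[cj]))
    }
    mc <- cells[which.min(fel$energy[cells])]
    list(frames = frames,
         centroid = as.numeric(centroid),
         min_cell = c((mc - 1L) %% nx + 1L, (mc - 1L) %/% nx + 1L),
         min_energy = min(fel$energy[cells]),
         n_cells = length(cells),
         occupancy = length(frames))
  })
  ord <- order(vapply(basins, `[[`, numeric(1), "min_energy"),
               -vapply(basins, `[[`, numeric(1), "occupancy"))
  basins[ord]
}

#' Displacement of the deepest basin between two landscapes
#'
#' Vector difference (b minus a) of the deepest-basin centroids of two
#' landscapes built over the same PC pair in a comparable coordinate frame
#' (common eigenbasis recommended). A population shift between wells under a
#' perturbation (e.g. ligand binding) shows up as this displacement.
#'
#' @param fel_a,fel_b `fel_grid` objects.
#' @param threshold basin cutoff passed to [extract_basins()].
#' @return length-2 numeric vector (PC units).
#' @export
basin_shift <- function(fel_a, fel_b, threshold = 100) {
  if (!identical(fel_a$pc_pair, fel_b$pc_pair)) {
    warning("landscapes were built over different PC pairs")
  }
  ba <- extract_basins(fel_a, threshold)
  bb <- extract_basins(fel_b, threshold)
  if (!length(ba) || !length(bb)) stopf("a landscape has no basin below threshold")
  bb[[1]]$centroid - ba[[1]]$centroid
}

#' Inter-domain bending angle series
#'
#' Vertex angle (degrees) formed by the C-alpha atoms of three residues,
#' evaluated per frame — an empirical one-dimensional monitor of a bending
#' mode (e.g. a peripheral domain closing over the catalytic core). Angles
#' are invariant to global rotation/translation, so no alignment is needed.
#'
#' @param traj an `md_trajectory` with an atom table.
#' @param triple length-3 vector of residue ids (apex second).
#' @return numeric vector of angles in \[0, 180\] (NA for frames with
#'   coincident points), frame times (ns) as names.
#' @export
bend_angle_series <- function(traj, triple) {
  if (length(triple) != 3L || length(unique(triple)) != 3L) {
    stopf("triple must give three distinct residue ids")
  }
  idx <- vapply(triple, function(r) {
    k <- which(traj$atoms$resid == r & traj$atoms$name == "CA")
    if (!length(k)) stopf("residue %s has no CA atom", r)
    k[1]
  }, integer(1))
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj$xyz, f)
    vertex_angle(m[idx[1], ], m[idx[2], ], m[idx[3], ])
  }, numeric(1))
  names(out) <- sprintf("%.6g", frame_times_ns(traj))
  out
}
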