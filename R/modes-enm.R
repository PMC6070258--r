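#' Elastic-network (anisotropic network model) normal modes
#'
#' Builds the Hessian of a pairwise harmonic potential with uniform spring
#' constant `gamma` between selected atoms closer than `cutoff`, removes the
#' six near-zero rigid-body modes (global translation and rotation), and
#' returns the lowest `n_modes` internal modes in ascending eigenvalue order.
#' Thermal mode amplitudes scale as kB*T / eigenvalue, so low modes dominate
#' the collective motion.
#'
#' @param x an `md_structure`.
#' @param selection network nodes (default `"name CA"`).
#' @param cutoff contact distance in Angstrom (default 12).
#' @param gamma spring constant (default 1; arbitrary units — correlation
#'   maps and relative fluctuations do not depend on it).
#' @param n_modes internal modes to retain (default 26).
#' @return a `mode_set` with `source = "ENM"` and `removed_rigid_modes = 6`.
#' @export
enm_modes <- function(x, selection = "name CA", cutoff = 12, gamma = 1,
                      n_modes = 26L) {
  stopifnot(inherits(x, "md_structure"))
  sel <- resolve_selection(x, selection)
  coords <- x$xyz[sel$indices, , drop = FALSE]
  n <- nrow(coords)
  if (n < 3L) stopf("need at least 3 network nodes")
  d2 <- as.matrix(stats::dist(coords))^2
  contact <- d2 <= cutoff^2 & d2 > 0
  comp <- connected_components(contact)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stopf("contact network is disconnected at cutoff %g A (%d components of sizes %s)",
          cutoff, max(comp), paste(sizes, collapse = ", "))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1L)) {
    js <- which(contact[i, ] & seq_len(n) > i)
    for (j in js) {
      d <- coords[j, ] - coords[i, ]
      blk <- -gamma * tcrossprod(d) / d2[i, j]
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  rigid <- vals < 1e-8 * max(vals)
  if (sum(rigid) != 6L) {
    stopf("expected 6 rigid-body modes, found %d: degenerate geometry", sum(rigid))
  }
  keep <- which(!rigid)
  k <- min(n_modes, length(keep))
  keep <- keep[seq_len(k)]
  mode_set(vecs[, keep, drop = FALSE], vals[keep],
           mean_coords = coords_row(coords), source = "ENM",
           atoms = x$atoms[sel$indices, ], removed_rigid_modes = 6L)
}

# label connected components of an adjacency matrix (BFS)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
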