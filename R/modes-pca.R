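#' Mode set container
#'
#' Holds an ordered set of collective-motion modes: orthonormal eigenvectors
#' over the 3N coordinates of a selection, their eigenvalues (variance in
#' Angstrom^2 for PCA; spring-constant units for elastic-network modes), the
#' mean/reference coordinates, and provenance. Eigenvector signs follow the
#' convention that each vector's largest-magnitude component is positive.
#'
#' @param vectors 3N x M matrix, columns orthonormal.
#' @param values length-M eigenvalues (PCA: descending; ENM: ascending).
#' @param mean_coords length-3N reference coordinates (Angstrom).
#' @param source `"PCA"` or `"ENM"`.
#' @param atoms atom table of the selection the modes live on.
#' @param removed_rigid_modes count of discarded rigid-body modes (ENM: 6).
#' @param fractions normalised eigenvalue fractions (PCA).
#' @return an object of class `mode_set`.
#' @export
mode_set <- function(vectors, values, mean_coords, source,
                     atoms = NULL, removed_rigid_modes = 0L, fractions = NULL) {
  vectors <- as.matrix(vectors)
  for (m in seq_len(ncol(vectors))) {
    j <- which.max(abs(vectors[, m]))
    if (vectors[j, m] < 0) vectors[, m] <- -vectors[, m]
  }
  structure(list(vectors = vectors, values = as.numeric(values),
                 mean_coords = as.numeric(mean_coords), source = source,
                 atoms = atoms, removed_rigid_modes = as.integer(removed_rigid_modes),
                 fractions = fractions),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes over %d coordinates", x$source,
              ncol(x$vectors), nrow(x$vectors)))
  if (x$removed_rigid_modes > 0)
    cat(sprintf(" (%d rigid-body modes removed)", x$removed_rigid_modes))
  cat("\n")
  if (!is.null(x$fractions)) {
    k <- min(3L, length(x$fractions))
    cat(sprintf("  top-%d eigenvalue fraction: %.1f%%\n", k,
                100 * sum(x$fractions[seq_len(k)])))
  }
  invisible(x)
}

#' Coordinate covariance matrix of a trajectory
#'
#' c_ij = <r_i r_j> - <r_i><r_j> over frames sampled every `offset` frames,
#' on the 3N coordinates of the selection. The trajectory must already be
#' aligned so that global rotation/translation does not enter the covariance.
#'
#' @param traj an aligned `md_trajectory`.
#' @param selection atoms to include (default `"heavy"`).
#' @param offset frame stride (default 10).
#' @return symmetric 3N x 3N covariance matrix (Angstrom^2) with the atom
#'   indices used stored in attribute `indices`.
#' @export
covariance_matrix <- function(traj, selection = "heavy", offset = 10L) {
  if (offset < 1L) stopf("offset must be >= 1")
  sel <- resolve_selection(traj, selection)
  rows <- seq(1L, n_frames(traj), by = offset)
  if (length(rows) < 2L) stopf("fewer than 2 frames sampled at offset %d", offset)
  sub <- traj$xyz[rows, xyz_index(sel$indices), drop = FALSE]
  centered <- sweep(sub, 2, colMeans(sub))
  cv <- crossprod(centered) / nrow(centered)
  cv <- (cv + t(cv)) / 2
  attr(cv, "indices") <- sel$indices
  cv
}

#' Eigendecompose a covariance matrix into PCA modes
#'
#' Returns the leading eigenpairs in descending eigenvalue order, together
#' with normalised eigenvalue fractions (eigenvalue_i / sum of all
#' eigenvalues) and their cumulative sums, so statements like "the first 3
#' components account for X% of the total motion" can be read off directly.
#'
#' @param cov symmetric covariance matrix (e.g. from [covariance_matrix()]).
#' @param n_modes number of modes to keep (default all).
#' @param mean_coords reference coordinates to attach (length 3N).
#' @param atoms atom table of the selection.
#' @return a `mode_set` with `source = "PCA"`; `fractions` covers all modes.
#' @export
eigendecompose <- function(cov, n_modes = NULL, mean_coords = NULL, atoms = NULL) {
  cov <- as.matrix(cov)
  if (max(abs(cov - t(cov))) > 1e-8) stopf("covariance matrix is not symmetric")
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  fr <- if (total > 0) vals / total else rep(0, length(vals))
  k <- n_modes %||% length(vals)
  k <- min(k, length(vals))
  mode_set(e$vectors[, seq_len(k), drop = FALSE], vals[seq_len(k)],
           mean_coords %||% rep(0, nrow(cov)), "PCA",
           atoms = atoms, fractions = fr)
}

#' Essential dynamics (PCA) of a trajectory
#'
#' Convenience wrapper: covariance of the selection at the given frame
#' offset, eigendecomposed, with the selection's mean coordinates attached.
#'
#' @inheritParams covariance_matrix
#' @param n_modes number of modes to keep (default 20).
#' @return a `mode_set` with `source = "PCA"`.
#' @export
pca_modes <- function(traj, selection = "heavy", offset = 10L, n_modes = 20L) {
  sel <- resolve_selection(traj, selection)
  cv <- covariance_matrix(traj, sel, offset)
  sub <- traj$xyz[, xyz_index(sel$indices), drop = FALSE]
  eigendecompose(cv, n_modes, mean_coords = colMeans(sub),
                 atoms = if (!is.null(traj$atoms)) traj$atoms[sel$indices, ] else NULL)
}

#' Project a trajectory onto modes
#'
#' value_m(t) = (x(t) - mean_coords) . v_m for the first `k` modes. The
#' trajectory must be in the same frame of reference as the modes' mean
#' coordinates (i.e. aligned the same way).
#'
#' @param traj an `md_trajectory` restricted or restrictable to the mode
#'   atoms (its selection must match the eigenvector length).
#' @param modes a `mode_set`.
#' @param k number of modes to project onto (default all).
#' @param selection selection mapping trajectory atoms onto the mode
#'   coordinates; default `"all"`.
#' @return a `projection_series`: frames x k matrix (Angstrom) with frame
#'   times (ns) in attribute `times_ns`.
#' @export
project_trajectory <- function(traj, modes, k = NULL, selection = "all") {
  sel <- resolve_selection(traj, selection)
  sub <- traj$xyz[, xyz_index(sel$indices), drop = FALSE]
  if (ncol(sub) != nrow(modes$vectors)) {
    stopf("selection has %d coordinates but eigenvectors have %d",
          ncol(sub), nrow(modes$vectors))
  }
  k <- min(k %||% ncol(modes$vectors), ncol(modes$vectors))
  centered <- sweep(sub, 2, modes$mean_coords)
  proj <- centered %*% modes$vectors[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("pc", seq_len(k))
  structure(proj, times_ns = frame_times_ns(traj), source = modes$source,
            class = c("projection_series", "matrix"))
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("projection_series: %d frames x %d modes (%s)\n",
              nrow(x), ncol(x), attr(x, "source") %||% "?"))
  invisible(x)
}

#' Kullback-Leibler divergence between two sample sets
#'
#' Histograms both samples on the shared support (union of ranges) with
#' `n_bins` bins and a pseudo-count of `pseudocount` per bin, then computes
#' KLD(p || q) = sum p ln(p/q) in nats. With `symmetric = TRUE` the
#' symmetrised (KLD(p||q) + KLD(q||p)) / 2 is returned.
#'
#' @param a,b numeric sample vectors (p is estimated from `a`).
#' @param n_bins number of histogram bins (default 100).
#' @param pseudocount smoothing count added to every bin (default 0.5).
#' @param symmetric return the symmetrised divergence.
#' @return non-negative divergence (nats).
#' @export
kld_divergence <- function(a, b, n_bins = 100L, pseudocount = 0.5,
                           symmetric = FALSE) {
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  if (!length(a) || !length(b)) stopf("empty sample")
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  count <- function(x) {
    h <- graphics::hist(x, breaks = edges, plot = FALSE, include.lowest = TRUE)$counts
    (h + pseudocount) / (length(x) + pseudocount * n_bins)
  }
  p <- count(a)
  q <- count(b)
  kl <- sum(p * log(p / q))
  if (symmetric) kl <- (kl + sum(q * log(q / p))) / 2
  kl
}

#' PCA-histogram convergence diagnostic (KLD of the two trajectory halves)
#'
#' For each mode, splits the projection series into its first and second
#' halves and returns the Kullback-Leibler divergence between the two
#' histograms (first half playing the role of p). Values near zero indicate
#' that both halves explore the same region of the essential subspace.
#'
#' @param proj a `projection_series`, or a numeric matrix (frames x modes).
#' @param proj_b optional second series; when given, the divergence is
#'   computed between `proj` and `proj_b` per mode instead of between halves.
#' @param n_bins,pseudocount,symmetric passed to [kld_divergence()].
#' @return numeric vector, one KLD (nats) per mode.
#' @export
kld_convergence <- function(proj, proj_b = NULL, n_bins = 100L,
                            pseudocount = 0.5, symmetric = FALSE) {
  proj <- as.matrix(proj)
  if (is.null(proj_b)) {
    half <- nrow(proj) %/% 2L
    a <- proj[seq_len(half), , drop = FALSE]
    b <- proj[(half + 1L):nrow(proj), , drop = FALSE]
  } else {
    a <- proj
    b <- as.matrix(proj_b)
    if (ncol(a) != ncol(b)) stopf("mode counts differ (%d vs %d)", ncol(a), ncol(b))
  }
  vapply(seq_len(ncol(a)), function(m) {
    kld_divergence(a[, m], b[, m], n_bins, pseudocount, symmetric)
  }, numeric(1))
}

#' KLD-vs-time convergence profile
#'
#' Evaluates the half-vs-half KLD on growing prefixes of the series (the
#' first `f` fraction of frames, for `n_points` fractions up to 1), giving a
#' convergence curve that should decay towards its plateau as sampling
#' accumulates.
#'
#' @inheritParams kld_convergence
#' @param n_points number of prefix lengths (default 10).
#' @return matrix n_points x modes with prefix end-times (ns, if available)
#'   as rownames.
#' @export
kld_profile <- function(proj, n_points = 10L, n_bins = 100L, pseudocount = 0.5) {
  proj_m <- as.matrix(proj)
  fr <- seq(1 / n_points, 1, length.out = n_points)
  out <- t(vapply(fr, function(f) {
    n <- max(4L, floor(nrow(proj_m) * f))
    kld_convergence(proj_m[seq_len(n), , drop = FALSE],
                    n_bins = n_bins, pseudocount = pseudocount)
  }, numeric(ncol(proj_m))))
  tns <- attr(proj, "times_ns")
  rownames(out) <- if (!is.null(tns)) {
    sprintf("%.6g", tns[pmax(1L, floor(length(tns) * fr))])
  } else {
    sprintf("%.2f", fr)
  }
  out
}

# squared thermal amplitude per mode: PCA modes carry their variance, ENM
# modes fluctuate as kB*T / eigenvalue
mode_amplitudes2 <- function(modes, k, temperature = 303) {
  idx <- seq_len(k)
  if (modes$source == "PCA") {
    modes$values[idx]
  } else {
    .kB * temperature / modes$values[idx]
  }
}

#' Per-atom fluctuations implied by a mode set
#'
#' Mean-square fluctuation of atom i from the first `first_k` modes:
#' sum_m amp_m^2 |v_m,i|^2, with amp_m^2 the mode variance for PCA and
#' kB*T/eigenvalue for elastic-network modes; converted to B-factors with
#' [bfactor_from_rmsf()]. Collapsed per residue when the mode set carries an
#' atom table.
#'
#' @param modes a `mode_set`.
#' @param first_k number of modes to sum (default 3).
#' @param temperature Kelvin (default 303), used for ENM amplitudes.
#' @return a `fluct_profile` data.frame (`resid` is the atom index when no
#'   atom table is attached).
#' @export
mode_fluctuations <- function(modes, first_k = 3L, temperature = 303) {
  first_k <- min(first_k, ncol(modes$vectors))
  amp2 <- mode_amplitudes2(modes, first_k, temperature)
  v2 <- modes$vectors[, seq_len(first_k), drop = FALSE]^2
  msf_coord <- as.numeric(v2 %*% amp2)
  n <- length(msf_coord) / 3L
  msf_atom <- msf_coord[seq(1, by = 3, length.out = n)] +
    msf_coord[seq(2, by = 3, length.out = n)] +
    msf_coord[seq(3, by = 3, length.out = n)]
  resid <- if (!is.null(modes$atoms)) modes$atoms$resid else seq_len(n)
  resids <- unique(resid)
  msf <- vapply(resids, function(r) mean(msf_atom[resid == r]), numeric(1))
  profile <- data.frame(resid = resids, rmsf = sqrt(msf))
  profile$bfactor <- bfactor_from_rmsf(profile$rmsf)
  class(profile) <- c("fluct_profile", "data.frame")
  profile
}

#' Generate conformers along one mode
#'
#' Frames x_t = mean + amplitude * sin(2 pi t / n_frames) * v_mode for
#' t = 0 .. n_frames - 1, e.g. to animate a mode or to feed backbone-dihedral
#' hinge detection.
#'
#' @param modes a `mode_set`.
#' @param mode_index which mode to animate.
#' @param amplitude displacement amplitude (Angstrom) along the unit mode.
#' @param n_frames frames per cycle (default 20).
#' @param dt_ps nominal frame spacing for the output trajectory.
#' @return an `md_trajectory` over the mode atoms.
#' @export
mode_conformers <- function(modes, mode_index, amplitude, n_frames = 20L,
                            dt_ps = 1) {
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (mode_index > ncol(modes$vectors)) stopf("mode %d not available", mode_index)
  phase <- sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
  xyz <- outer(phase * amplitude, modes$vectors[, mode_index]) +
    matrix(modes$mean_coords, n_frames, length(modes$mean_coords), byrow = TRUE)
  md_trajectory(xyz, dt_ps = dt_ps, atoms = modes$atoms)
}
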