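#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) squared deviation of `mobile` onto `reference`. The transform
#' maps a coordinate row `x` to `R x + t`.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix, same atom order.
#' @param weights optional per-atom non-negative weights (default uniform).
#' @return a `kabsch_fit`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom, computed post-transform).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stopf("coordinate sets differ in atom count")
  if (n < 3L) stopf("need at least 3 atoms to define a rigid fit")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0) stopf("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  s <- svd(H)
  # degenerate (collinear/coincident) configurations make the rotation
  # ill-defined: the cross-covariance then has rank < 2
  if (s$d[2] <= 1e-10 * max(s$d[1], 1e-300)) {
    stopf("degenerate (collinear) coordinates: rigid fit is ill-defined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cr - as.numeric(R %*% cm)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("kabsch_fit: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param fit a `kabsch_fit`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_fit <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

# coordinates of a reference argument (md_structure or n x 3 matrix)
ref_coords <- function(reference) {
  if (inherits(reference, "md_structure")) reference$xyz else as.matrix(reference)
}

#' Remove global rotation and translation from a trajectory
#'
#' Fits every frame, on the atoms of `fit_selection`, either onto a fixed
#' reference structure or onto the iteratively refined average structure
#' (fit to the running mean, recompute the mean, until the mean moves less
#' than `tol` or `max_iter` passes). The per-frame transform is applied to
#' all atoms.
#'
#' @param traj an `md_trajectory`.
#' @param reference an `md_structure`, an n x 3 matrix, or `"average"`.
#' @param fit_selection selection used for the fit (default `"all"`).
#' @param weights optional per-atom fitting weights over the selection.
#' @param tol convergence threshold on the mean-structure displacement
#'   (Angstrom) for `reference = "average"`.
#' @param max_iter iteration cap for the average-structure fit.
#' @return the aligned `md_trajectory`.
#' @export
align_trajectory <- function(traj, reference = "average", fit_selection = "all",
                             weights = NULL, tol = 1e-6, max_iter = 10L) {
  sel <- resolve_selection(traj, fit_selection)
  xi <- xyz_index(sel$indices)
  align_once <- function(xyz, ref_sel) {
    out <- xyz
    for (f in seq_len(nrow(xyz))) {
      mob <- matrix(xyz[f, xi], ncol = 3, byrow = TRUE)
      fit <- kabsch_fit(mob, ref_sel, weights)
      out[f, ] <- coords_row(apply_fit(fit, frame_coords(xyz, f)))
    }
    out
  }
  xyz <- traj$xyz
  if (identical(reference, "average")) {
    ref_sel <- matrix(xyz[1, xi], ncol = 3, byrow = TRUE)
    for (it in seq_len(max_iter)) {
      xyz <- align_once(xyz, ref_sel)
      new_ref <- matrix(colMeans(xyz[, xi, drop = FALSE]), ncol = 3, byrow = TRUE)
      shift <- sqrt(max(rowSums((new_ref - ref_sel)^2)))
      ref_sel <- new_ref
      if (shift < tol) break
    }
  } else {
    full <- ref_coords(reference)
    ref_sel <- full[sel$indices, , drop = FALSE]
    xyz <- align_once(xyz, ref_sel)
  }
  md_trajectory(xyz, dt_ps = traj$dt_ps, atoms = traj$atoms)
}

#' RMSD time series against a reference structure
#'
#' @param traj an `md_trajectory`.
#' @param reference an `md_structure` or n x 3 matrix.
#' @param selection atoms entering the RMSD (and the fit, when `fit = TRUE`);
#'   exclusion clauses such as `"heavy and not resid 1832-2000"` let the
#'   series be recomputed without a mobile domain.
#' @param fit refit each frame onto the reference on `selection` before
#'   measuring (default TRUE).
#' @return numeric vector, one RMSD (Angstrom) per frame, with frame times
#'   (ns) as names.
#' @export
rmsd_series <- function(traj, reference, selection = "all", fit = TRUE) {
  sel <- resolve_selection(traj, selection)
  xi <- xyz_index(sel$indices)
  ref <- ref_coords(reference)
  if (nrow(ref) == n_atoms(traj)) ref <- ref[sel$indices, , drop = FALSE]
  if (nrow(ref) != length(sel$indices)) {
    stopf("reference does not match selection (%d vs %d atoms)",
          nrow(ref), length(sel$indices))
  }
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    mob <- matrix(traj$xyz[f, xi], ncol = 3, byrow = TRUE)
    if (fit) {
      kabsch_fit(mob, ref)$rmsd
    } else {
      sqrt(mean(rowSums((mob - ref)^2)))
    }
  }, numeric(1))
  names(out) <- sprintf("%.6g", frame_times_ns(traj))
  out
}

#' Per-residue RMSD map through time
#'
#' Tracks, for every residue, the deviation of its selected atoms from a
#' reference position, averaged over non-overlapping windows of `window`
#' frames. The default reference is each atom's time-average position; an
#' explicit structure (e.g. the crystallographic model) may be given instead.
#'
#' @param traj an aligned `md_trajectory` (align first with
#'   [align_trajectory()]; set `aligned = FALSE` to auto-align here).
#' @param selection atoms to track (default `"name CA"`).
#' @param window frames per averaging window (default 1 = no smoothing).
#' @param reference `"average"` or an `md_structure`.
#' @param aligned set FALSE to have the trajectory aligned internally.
#' @return residues x windows matrix (Angstrom); rownames are residue ids,
#'   colnames window mid-times in ns. Attribute `bin_edges` carries the
#'   default 2/4/6 Angstrom display bins.
#' @export
residual_rmsd_map <- function(traj, selection = "name CA", window = 1L,
                              reference = "average", aligned = TRUE) {
  if (window > n_frames(traj)) stopf("window (%d) exceeds frame count (%d)",
                                     window, n_frames(traj))
  if (!aligned) {
    traj <- align_trajectory(traj, if (identical(reference, "average"))
      "average" else reference, fit_selection = selection)
  }
  sel <- resolve_selection(traj, selection)
  xi <- xyz_index(sel$indices)
  sub <- traj$xyz[, xi, drop = FALSE]
  if (identical(reference, "average")) {
    refv <- colMeans(sub)
  } else {
    refv <- coords_row(ref_coords(reference)[sel$indices, , drop = FALSE])
  }
  dev2 <- sweep(sub, 2, refv)^2
  resid_of <- traj$atoms$resid[sel$indices]
  resids <- unique(resid_of)
  nf <- n_frames(traj)
  nw <- nf %/% window
  wid <- rep(seq_len(nw), each = window, length.out = nf)
  out <- matrix(NA_real_, length(resids), nw,
                dimnames = list(resids, NULL))
  # mean squared deviation per residue per frame, then window-average
  for (k in seq_along(resids)) {
    cols <- xyz_index(which(resid_of == resids[k]))
    msd_t <- rowSums(dev2[, cols, drop = FALSE]) / (length(cols) / 3)
    out[k, ] <- sqrt(tapply(msd_t, wid, mean)[seq_len(nw)])
  }
  tms <- frame_times_ns(traj)
  colnames(out) <- sprintf("%.6g", tapply(tms, wid, mean)[seq_len(nw)])
  attr(out, "bin_edges") <- c(2, 4, 6)
  out
}
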