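# Backbone phi/psi handling and dihedral-based hinge detection.

# per-residue backbone atom row indices (N, CA, C); NA when missing
backbone_index <- function(atoms) {
  resids <- unique(atoms$resid)
  idx <- function(nm) {
    vapply(resids, function(r) {
      k <- which(atoms$resid == r & atoms$name == nm)
      if (length(k)) k[1] else NA_integer_
    }, integer(1))
  }
  list(resids = resids, N = idx("N"), CA = idx("CA"), C = idx("C"))
}

# phi/psi angles (degrees) for one coordinate frame; chain breaks (peptide
# C-N distance beyond `break_cut`) and missing atoms yield NA
backbone_phi_psi <- function(coords, bb, break_cut = 2.5) {
  nres <- length(bb$resids)
  phi <- rep(NA_real_, nres)
  psi <- rep(NA_real_, nres)
  bonded <- function(i, j) {
    if (is.na(bb$C[i]) || is.na(bb$N[j])) return(FALSE)
    sqrt(sum((coords[bb$C[i], ] - coords[bb$N[j], ])^2)) <= break_cut
  }
  for (i in seq_len(nres)) {
    ok_self <- !is.na(bb$N[i]) && !is.na(bb$CA[i]) && !is.na(bb$C[i])
    if (!ok_self) next
    if (i > 1L && bonded(i - 1L, i)) {
      phi[i] <- dihedral_angle(coords[c(bb$C[i - 1L], bb$N[i], bb$CA[i], bb$C[i]), ])
    }
    if (i < nres && bonded(i, i + 1L)) {
      psi[i] <- dihedral_angle(coords[c(bb$N[i], bb$CA[i], bb$C[i], bb$N[i + 1L]), ])
    }
  }
  list(phi = phi, psi = psi)
}

#' Average unsigned dihedral deviation (hinge detection)
#'
#' For every residue, the mean over conformers of the absolute deviation of
#' its backbone phi and psi angles from those of a reference (average)
#' structure, with differences wrapped into (-180, 180] degrees. Rigid-body
#' motion leaves dihedrals untouched, so peaks in this profile mark residues
#' about which quasi-rigid blocks articulate. Conformers from several modes
#' may be pooled by passing a list of trajectories.
#'
#' @param conformers an `md_trajectory` (e.g. from [mode_conformers()]) or a
#'   list of them sharing one topology (pooled).
#' @param average reference `md_structure` with N/CA/C backbone atoms.
#' @param hinge_percentile quantile of the combined AUD profile above which
#'   local maxima are reported as hinge candidates (default 0.9).
#' @return data.frame with `resid`, `aud_phi`, `aud_psi` (degrees; NA where a
#'   backbone atom is missing or the chain is broken) and logical `hinge`.
#'   Attribute `hinges` lists the candidate residue ids.
#' @export
dihedral_aud <- function(conformers, average, hinge_percentile = 0.9) {
  if (inherits(conformers, "md_trajectory")) conformers <- list(conformers)
  stopifnot(inherits(average, "md_structure"))
  bb <- backbone_index(average$atoms)
  if (all(is.na(bb$N)) || all(is.na(bb$CA)) || all(is.na(bb$C))) {
    stopf("reference structure lacks N/CA/C backbone atoms")
  }
  ref <- backbone_phi_psi(average$xyz, bb)
  nres <- length(bb$resids)
  sum_phi <- rep(0, nres); n_phi <- rep(0L, nres)
  sum_psi <- rep(0, nres); n_psi <- rep(0L, nres)
  for (traj in conformers) {
    if (n_atoms(traj) != nrow(average$atoms)) {
      stopf("conformer atom count does not match the reference")
    }
    for (f in seq_len(n_frames(traj))) {
      ang <- backbone_phi_psi(frame_coords(traj$xyz, f), bb)
      dphi <- abs(wrap_angle(ang$phi - ref$phi))
      dpsi <- abs(wrap_angle(ang$psi - ref$psi))
      ok <- !is.na(dphi)
      sum_phi[ok] <- sum_phi[ok] + dphi[ok]; n_phi[ok] <- n_phi[ok] + 1L
      ok <- !is.na(dpsi)
      sum_psi[ok] <- sum_psi[ok] + dpsi[ok]; n_psi[ok] <- n_psi[ok] + 1L
    }
  }
  aud_phi <- ifelse(n_phi > 0, sum_phi / pmax(n_phi, 1L), NA_real_)
  aud_psi <- ifelse(n_psi > 0, sum_psi / pmax(n_psi, 1L), NA_real_)
  combined <- pmax(aud_phi, aud_psi, na.rm = TRUE)
  combined[is.na(aud_phi) & is.na(aud_psi)] <- NA
  thr <- stats::quantile(combined, hinge_percentile, na.rm = TRUE)
  hinge <- rep(FALSE, nres)
  for (i in seq_len(nres)) {
    if (is.na(combined[i]) || combined[i] < thr) next
    left <- if (i > 1) combined[i - 1] else -Inf
    right <- if (i < nres) combined[i + 1] else -Inf
    if (combined[i] >= max(left, right, na.rm = TRUE)) hinge[i] <- TRUE
  }
  out <- data.frame(resid = bb$resids, aud_phi = aud_phi, aud_psi = aud_psi,
                    hinge = hinge)
  attr(out, "hinges") <- bb$resids[hinge]
  out
}
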