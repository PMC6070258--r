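#' Per-residue RMSF and B-factor profile
#'
#' Root-mean-square fluctuation of each selected atom about its time-average
#' position, RMSF_i = sqrt( (1/nsteps) * sum_t ||r_i(t) - <r_i>||^2 ),
#' collapsed to one value per residue and converted to a B-factor via
#' B = RMSF^2 * (8/3) * pi^2. For a C-alpha selection the residue value is
#' the C-alpha value; for multi-atom selections atoms are averaged within
#' each residue, mass-weighted when `mass_weighted = TRUE`.
#'
#' @param traj an aligned `md_trajectory` (global rotation/translation must
#'   already be removed; see [align_trajectory()]).
#' @param selection atoms to analyse (default `"name CA"`).
#' @param mass_weighted use atomic masses when averaging several atoms of a
#'   residue into one value (no-op for single-atom selections).
#' @param aligned assertion flag: set FALSE only to acknowledge an unaligned
#'   trajectory, which is an error.
#' @return a `fluct_profile` data.frame with columns `resid`, `rmsf`
#'   (Angstrom) and `bfactor` (Angstrom^2).
#' @export
rmsf_profile <- function(traj, selection = "name CA", mass_weighted = FALSE,
                         aligned = TRUE) {
  if (!aligned) stopf("trajectory must be aligned before computing RMSF")
  if (n_frames(traj) < 2L) stopf("RMSF is undefined for a single frame")
  sel <- resolve_selection(traj, selection)
  xi <- xyz_index(sel$indices)
  sub <- traj$xyz[, xi, drop = FALSE]
  dev2 <- sweep(sub, 2, colMeans(sub))^2
  msf_atom <- colMeans(dev2)
  msf_atom <- msf_atom[seq(1, length(msf_atom), by = 3)] +
    msf_atom[seq(2, length(msf_atom), by = 3)] +
    msf_atom[seq(3, length(msf_atom), by = 3)]
  resid_of <- traj$atoms$resid[sel$indices]
  w <- if (mass_weighted) {
    atom_mass(traj$atoms$element[sel$indices])
  } else {
    rep(1, length(sel$indices))
  }
  resids <- unique(resid_of)
  msf <- vapply(resids, function(r) {
    k <- resid_of == r
    sum(w[k] * msf_atom[k]) / sum(w[k])
  }, numeric(1))
  profile <- data.frame(resid = resids, rmsf = sqrt(msf))
  profile$bfactor <- bfactor_from_rmsf(profile$rmsf)
  class(profile) <- c("fluct_profile", "data.frame")
  profile
}

atom_mass <- function(element) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, CA = 40.078, NA2 = 22.99)
  m <- tbl[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Convert RMSF to crystallographic B-factor
#'
#' B = RMSF^2 * (8/3) * pi^2, in Angstrom^2 for RMSF in Angstrom
#' (RMSF of 1 A gives B of about 26.3189 A^2).
#'
#' @param rmsf numeric vector of RMSF values (Angstrom), or a `fluct_profile`.
#' @return numeric vector of B-factors, or the profile with `bfactor` refilled.
#' @export
bfactor_from_rmsf <- function(rmsf) {
  if (inherits(rmsf, "fluct_profile")) {
    rmsf$bfactor <- rmsf$rmsf^2 * (8 / 3) * pi^2
    return(rmsf)
  }
  rmsf^2 * (8 / 3) * pi^2
}

#' Correlate computed and experimental B-factors
#'
#' Pearson correlation between a computed per-residue B-factor profile and
#' the experimental B-factor column of a structure (per-residue C-alpha
#' values), over the intersection of residue ids.
#'
#' @param calculated a `fluct_profile` (or data.frame with `resid`, `bfactor`).
#' @param experimental an `md_structure` with B-factors, or a data.frame with
#'   `resid`, `bfactor`.
#' @return list with `r` (Pearson), `n` (residues used) and `dropped`
#'   (residue ids present on one side only).
#' @export
bfactor_correlation <- function(calculated, experimental) {
  if (inherits(experimental, "md_structure")) {
    a <- experimental$atoms
    ca <- a$name == "CA"
    if (!any(ca)) ca <- !duplicated(a$resid)
    if (all(is.na(a$b[ca]))) stopf("experimental structure has no B-factors")
    experimental <- data.frame(resid = a$resid[ca], bfactor = a$b[ca])
  }
  shared <- intersect(calculated$resid, experimental$resid)
  if (length(shared) < 3L) stopf("fewer than 3 shared residues (%d)", length(shared))
  x <- calculated$bfactor[match(shared, calculated$resid)]
  y <- experimental$bfactor[match(shared, experimental$resid)]
  list(
    r = stats::cor(x, y, method = "pearson"),
    n = length(shared),
    dropped = sort(c(setdiff(calculated$resid, shared),
                     setdiff(experimental$resid, shared)))
  )
}
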