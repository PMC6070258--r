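#' Hydrogen-bond occurrence map between ligand and protein
#'
#' Counts, over the frames of a trajectory (typically the members of a
#' free-energy basin cluster), how often each candidate donor-acceptor pair
#' is hydrogen-bonded. Candidate heavy atoms are N and O on either side. A
#' pair is bonded in a frame when the donor-acceptor distance is at most
#' `d_cut`; when the topology contains hydrogens, the donor additionally
#' needs an attached H with a donor-H...acceptor angle of at least
#' `angle_cut` (hydrogen-free topologies use the distance criterion alone).
#'
#' @param traj an `md_trajectory` with an atom table.
#' @param ligand_sel,protein_sel selections for the two sides.
#' @param d_cut heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param angle_cut donor-H-acceptor angle cutoff in degrees (default 135).
#' @return an `hbond_map` data.frame: `ligand_atom`, `residue`,
#'   `residue_atom`, `role` (`donor` = ligand donates), `occurrence_pct`
#'   in \[0, 100\]; one row per candidate pair with non-zero occurrence, plus
#'   zero rows retained for pairs within `d_cut` + 1.5 A in any frame.
#' @export
hbond_occurrence <- function(traj, ligand_sel, protein_sel, d_cut = 3.5,
                             angle_cut = 135) {
  lig <- resolve_selection(traj, ligand_sel)
  pro <- resolve_selection(traj, protein_sel)
  if (!length(lig$indices) || !length(pro$indices)) stopf("empty selection")
  atoms <- traj$atoms
  polar <- function(idx) idx[toupper(atoms$element[idx]) %in% c("N", "O")]
  ligp <- polar(lig$indices)
  prop <- polar(pro$indices)
  if (!length(ligp) || !length(prop)) stopf("no N/O atoms in a selection")
  hyd <- which(toupper(atoms$element) == "H")
  # hydrogens attached to a heavy atom: within 1.25 A in the first frame
  first <- frame_coords(traj$xyz, 1)
  attached <- function(i) {
    if (!length(hyd)) return(integer())
    d <- sqrt(rowSums(sweep(first[hyd, , drop = FALSE], 2, first[i, ])^2))
    hyd[d <= 1.25]
  }
  h_of <- lapply(seq_len(nrow(atoms)), function(i) integer())
  for (i in unique(c(ligp, prop))) h_of[[i]] <- attached(i)
  nf <- n_frames(traj)
  pairs <- expand.grid(li = ligp, pi_ = prop)
  count <- matrix(0L, nrow(pairs), 2)  # ligand-donor, ligand-acceptor
  near <- rep(FALSE, nrow(pairs))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj$xyz, f)
    d <- sqrt(rowSums((m[pairs$li, , drop = FALSE] - m[pairs$pi_, , drop = FALSE])^2))
    near <- near | d <= d_cut + 1.5
    ok_d <- d <= d_cut
    for (k in which(ok_d)) {
      li <- pairs$li[k]
      pi_ <- pairs$pi_[k]
      # ligand as donor
      if (h_geom_ok(m, li, pi_, h_of[[li]], angle_cut)) {
        count[k, 1] <- count[k, 1] + 1L
      }
      if (h_geom_ok(m, pi_, li, h_of[[pi_]], angle_cut)) {
        count[k, 2] <- count[k, 2] + 1L
      }
    }
  }
  keep <- which(near | count[, 1] + count[, 2] > 0)
  out <- do.call(rbind, lapply(keep, function(k) {
    li <- pairs$li[k]
    pi_ <- pairs$pi_[k]
    roles <- c("donor", "acceptor")
    best <- which.max(count[k, ])
    data.frame(
      ligand_atom = atoms$name[li],
      residue = sprintf("%s%d", atoms$resname[pi_], atoms$resid[pi_]),
      residue_atom = atoms$name[pi_],
      role = roles[best],
      occurrence_pct = 100 * max(count[k, ]) / nf,
      stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(ligand_atom = character(), residue = character(),
                      residue_atom = character(), role = character(),
                      occurrence_pct = numeric())
  }
  class(out) <- c("hbond_map", "data.frame")
  out
}

# donor-H...acceptor geometry; hydrogen-free donors pass on distance alone
h_geom_ok <- function(m, donor, acceptor, hs, angle_cut) {
  if (!length(hs)) return(TRUE)
  for (h in hs) {
    ang <- vertex_angle(m[donor, ], m[h, ], m[acceptor, ])
    if (!is.na(ang) && ang >= angle_cut) return(TRUE)
  }
  FALSE
}

#' @export
print.hbond_map <- function(x, ...) {
  cat(sprintf("hbond_map: %d candidate pair(s), %d with occurrence > 0\n",
              nrow(x), sum(x$occurrence_pct > 0)))
  if (nrow(x)) print.data.frame(x[order(-x$occurrence_pct), ], row.names = FALSE)
  invisible(x)
}

#' Minimum-distance contact occurrence (stacking/hydrophobic)
#'
#' Non-polar contact listing complementary to [hbond_occurrence()]: a
#' (ligand atom, protein residue) pair is in contact in a frame when any
#' heavy-atom distance is at most `d_cut` (default 4.5 Angstrom). Labelled
#' `contact`, never `hbond`.
#'
#' @inheritParams hbond_occurrence
#' @param d_cut contact distance cutoff (default 4.5).
#' @return data.frame `ligand_atom`, `residue`, `kind`, `occurrence_pct`.
#' @export
contact_occurrence <- function(traj, ligand_sel, protein_sel, d_cut = 4.5) {
  lig <- resolve_selection(traj, ligand_sel)
  pro <- resolve_selection(traj, protein_sel)
  atoms <- traj$atoms
  heavy <- function(idx) idx[toupper(atoms$element[idx]) != "H"]
  ligh <- heavy(lig$indices)
  proh <- heavy(pro$indices)
  res_of <- sprintf("%s%d", atoms$resname[proh], atoms$resid[proh])
  combos <- expand.grid(li = ligh, res = unique(res_of),
                        stringsAsFactors = FALSE)
  hits <- matrix(0L, nrow(combos), 1)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj$xyz, f)
    for (k in seq_len(nrow(combos))) {
      pa <- proh[res_of == combos$res[k]]
      dmin <- min(sqrt(rowSums(sweep(m[pa, , drop = FALSE], 2,
                                     m[combos$li[k], ])^2)))
      if (dmin <= d_cut) hits[k] <- hits[k] + 1L
    }
  }
  out <- data.frame(ligand_atom = atoms$name[combos$li],
                    residue = combos$res, kind = "contact",
                    occurrence_pct = 100 * as.numeric(hits) / nf)
  out[out$occurrence_pct > 0, , drop = FALSE]
}
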