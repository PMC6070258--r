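# Synthetic-trajectory generators with planted, recoverable structure.
# Every generator is a pure function of its arguments (seed included) and
# returns ground-truth metadata sufficient to predict the downstream
# analysis results, so the whole pipeline is testable without external data.

#' Synthetic C-alpha chain topology
#'
#' A single-chain C-alpha trace laid out on an ideal alpha-helical curve
#' (rise 1.5 A, 100 degrees per residue, radius 2.3 A), giving a compact,
#' connected contact network for elastic-network models.
#'
#' @param n_res number of residues (default 200).
#' @param first_resid author numbering of the first residue (default 1).
#' @return an `md_structure` with one CA atom per residue.
#' @export
synthetic_ca_chain <- function(n_res = 200L, first_resid = 1L) {
  i <- seq_len(n_res) - 1L
  ang <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  atoms <- data.frame(
    serial = seq_len(n_res),
    name = "CA",
    resname = "ALA",
    resid = first_resid + i,
    chain = "A",
    element = "C",
    b = NA_real_,
    stringsAsFactors = FALSE
  )
  md_structure(atoms, xyz)
}

# N/CA/C backbone chain along +x with small out-of-plane offsets so all
# dihedrals are well defined; CA atoms lie in the z = 0 plane
synthetic_backbone_chain <- function(n_res = 60L, first_resid = 1L) {
  rows <- NULL
  xyz <- NULL
  serial <- 0L
  for (i in seq_len(n_res)) {
    x0 <- 3.8 * (i - 1L)
    zz <- 0.3 * (-1)^i
    # CA atoms zig-zag in the z = 0 plane so any sub-chain is non-collinear
    pos <- rbind(c(x0, 0.0, zz),
                 c(x0 + 1.2, 0.8 * (-1)^i, 0.0),
                 c(x0 + 2.5, 0.0, -zz))
    for (k in 1:3) {
      serial <- serial + 1L
      rows <- rbind(rows, data.frame(
        serial = serial, name = c("N", "CA", "C")[k], resname = "ALA",
        resid = first_resid + i - 1L, chain = "A",
        element = c("N", "C", "C")[k], b = NA_real_,
        stringsAsFactors = FALSE))
    }
    xyz <- rbind(xyz, pos)
  }
  md_structure(rows, xyz)
}

# random orthonormal 3N x k matrix
random_orthonormal <- function(n3, k) {
  qr.Q(qr(matrix(stats::rnorm(n3 * k), n3, k)))
}

# orthonormal basis of the 6 rigid-body directions (translations and
# infinitesimal rotations about the centroid) of a coordinate set
rigid_basis <- function(coords) {
  n <- nrow(coords)
  c0 <- sweep(coords, 2, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  for (ax in 1:3) B[seq(ax, by = 3, length.out = n), ax] <- 1
  for (ax in 1:3) {
    e <- diag(3)[ax, ]
    rot <- t(apply(c0, 1, function(r) c(e[2] * r[3] - e[3] * r[2],
                                        e[3] * r[1] - e[1] * r[3],
                                        e[1] * r[2] - e[2] * r[1])))
    B[, 3 + ax] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))
}

# random orthonormal internal (rigid-motion-free) mode directions, so that
# least-squares fitting leaves planted motions intact
random_internal_modes <- function(coords, k) {
  n3 <- 3 * nrow(coords)
  R <- rigid_basis(coords)
  M <- matrix(stats::rnorm(n3 * k), n3, k)
  M <- M - R %*% (t(R) %*% M)
  qr.Q(qr(M))
}

#' Gaussian trajectory with planted covariance or mode structure
#'
#' Frames x(t) = mean + sum_m amp_m z_m(t) v_m + noise, with independent
#' standard-normal z and isotropic noise floor, or draws from an explicit
#' covariance matrix. The planted modes (including the noise contribution to
#' their variance) are returned as the ground-truth mode set.
#'
#' @param n_res residues (one CA atom each; default 200).
#' @param n_frames frames (default 5000).
#' @param dt_ps frame spacing (default 10 ps).
#' @param seed RNG seed.
#' @param amplitudes planted per-mode displacement amplitudes in Angstrom
#'   (default c(3, 2, 1.4)).
#' @param mode_vectors optional 3N x k orthonormal matrix of planted
#'   directions (default random orthonormal).
#' @param covariance optional 3N x 3N covariance to sample from instead
#'   (must be positive semidefinite; noise is not added).
#' @param noise isotropic per-coordinate noise floor, Angstrom (default 0.2).
#' @return list with `trajectory`, `structure`, ground-truth `modes`
#'   (a `mode_set`) and `covariance`.
#' @export
gen_gaussian_traj <- function(n_res = 200L, n_frames = 5000L, dt_ps = 10,
                              seed = 1L, amplitudes = c(3, 2, 1.4),
                              mode_vectors = NULL, covariance = NULL,
                              noise = 0.2) {
  base <- synthetic_ca_chain(n_res)
  n3 <- 3L * n_res
  mean_row <- coords_row(base$xyz)
  with_seed(seed, {
    if (!is.null(covariance)) {
      e <- eigen(as.matrix(covariance), symmetric = TRUE)
      if (min(e$values) < -1e-8 * max(abs(e$values))) {
        stopf("planted covariance is not positive semidefinite")
      }
      vals <- pmax(e$values, 0)
      L <- e$vectors %*% diag(sqrt(vals))
      Z <- matrix(stats::rnorm(n_frames * n3), n_frames, n3)
      xyz <- Z %*% t(L)
      truth <- mode_set(e$vectors, vals, mean_row, "PCA", atoms = base$atoms)
      cov_true <- as.matrix(covariance)
    } else {
      k <- length(amplitudes)
      V <- mode_vectors %||% random_internal_modes(base$xyz, k)
      Z <- matrix(stats::rnorm(n_frames * k), n_frames, k)
      xyz <- (Z %*% diag(amplitudes, k)) %*% t(V)
      if (noise > 0) {
        xyz <- xyz + matrix(stats::rnorm(n_frames * n3, sd = noise),
                            n_frames, n3)
      }
      truth <- mode_set(V, amplitudes^2 + noise^2, mean_row, "PCA",
                        atoms = base$atoms)
      cov_true <- V %*% diag(amplitudes^2, k) %*% t(V) + diag(noise^2, n3)
    }
    xyz <- sweep(xyz, 2, mean_row, `+`)
    list(trajectory = md_trajectory(xyz, dt_ps, base$atoms),
         structure = base, modes = truth, covariance = cov_true)
  })
}

#' Two-domain hinge trajectory
#'
#' A backbone (N/CA/C) chain with a static 45-degree kink at the pivot
#' residue; all atoms after the pivot's CA rotate rigidly about the vertical
#' axis through that CA by theta(t) = theta0 * sin(2 pi t / period), plus a
#' small isotropic noise floor. After least-squares fitting, the two blocks
#' move in anti-correlated directions; backbone dihedrals deviate only at
#' the pivot; the CA bending angle (block1 tip, pivot, block2 tip)
#' oscillates with amplitude theta0.
#'
#' @param n_res residues (default 60).
#' @param n_frames frames (default 2000).
#' @param dt_ps frame spacing (default 10 ps).
#' @param seed RNG seed.
#' @param theta0 hinge half-amplitude in degrees (default 20).
#' @param period_ns oscillation period (default 4 ns).
#' @param noise isotropic noise floor in Angstrom (default 0.02 — small
#'   relative to bond lengths so dihedral deviations stay localised).
#' @return list with `structure` (average geometry), `trajectory`, and
#'   `truth` (pivot residue, theta0, block residue ranges, bend triple).
#' @export
gen_two_domain_hinge <- function(n_res = 60L, n_frames = 2000L, dt_ps = 10,
                                 seed = 1L, theta0 = 20, period_ns = 4,
                                 noise = 0.02) {
  pivot <- n_res %/% 2L
  base <- synthetic_backbone_chain(n_res)
  atoms <- base$atoms
  ca_pivot_row <- which(atoms$resid == pivot & atoms$name == "CA")
  center <- base$xyz[ca_pivot_row, ]
  moving <- which(atoms$resid > pivot |
                    (atoms$resid == pivot & atoms$name == "C"))
  if (!length(moving) || length(moving) == nrow(atoms)) {
    stopf("blocks must be non-empty and non-overlapping")
  }
  # static kink so the bend angle stays well inside (0, 180)
  xyz0 <- base$xyz
  Rk <- rotation_about_axis(c(0, 0, 1), -45)
  xyz0[moving, ] <- sweep(sweep(xyz0[moving, , drop = FALSE], 2, center) %*%
                            t(Rk), 2, center, `+`)
  avg <- md_structure(atoms, xyz0)
  period_frames <- period_ns * 1000 / dt_ps
  with_seed(seed, {
    xyz <- matrix(0, n_frames, 3L * nrow(atoms))
    for (f in seq_len(n_frames)) {
      th <- theta0 * sin(2 * pi * (f - 1) / period_frames)
      m <- xyz0
      if (th != 0) {
        R <- rotation_about_axis(c(0, 0, 1), th)
        m[moving, ] <- sweep(sweep(m[moving, , drop = FALSE], 2, center) %*%
                               t(R), 2, center, `+`)
      }
      xyz[f, ] <- coords_row(m)
    }
    if (noise > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise), nrow(xyz))
    }
    truth <- list(pivot = pivot, theta0 = theta0, period_ns = period_ns,
                  block1 = c(1L, pivot), block2 = c(pivot + 1L, n_res),
                  bend_triple = c(2L, pivot, n_res - 1L))
    list(structure = avg, trajectory = md_trajectory(xyz, dt_ps, atoms),
         truth = truth)
  })
}

#' Trajectory with planted periodic oscillations per residue group
#'
#' Each group's atoms oscillate along fixed random unit directions at the
#' group's period; all atoms additionally carry a white-noise floor. A group
#' may be time-localised (`burst = c(from, to)` frame window) to emulate a
#' transient event.
#'
#' @param n_res residues (default 30; CA chain).
#' @param groups list of lists with fields `resids` (residue ids), `period_ns`,
#'   optional `amplitude` (Angstrom, default 1) and optional `burst`
#'   (length-2 frame window).
#' @param n_frames frames (default 10000).
#' @param dt_ps frame spacing (default 10).
#' @param seed RNG seed.
#' @param noise white-noise floor per coordinate (default 0.2 Angstrom).
#' @return list with `structure`, `trajectory`, `truth` (the group list).
#' @export
gen_oscillatory <- function(n_res = 30L, groups = list(), n_frames = 10000L,
                            dt_ps = 10, seed = 1L, noise = 0.2) {
  base <- synthetic_ca_chain(n_res)
  t_ns <- (seq_len(n_frames) - 1) * dt_ps / 1000
  total_ns <- n_frames * dt_ps / 1000
  for (g in groups) {
    if (g$period_ns < 2 * dt_ps / 1000 || g$period_ns > total_ns / 2) {
      stopf("period %g ns outside the resolvable range [%g, %g] ns",
            g$period_ns, 2 * dt_ps / 1000, total_ns / 2)
    }
  }
  with_seed(seed, {
    xyz <- matrix(stats::rnorm(n_frames * 3L * n_res, sd = noise),
                  n_frames, 3L * n_res)
    for (g in groups) {
      amp <- g$amplitude %||% 1
      phase <- sin(2 * pi * t_ns / g$period_ns)
      if (!is.null(g$burst)) {
        w <- rep(0, n_frames)
        w[g$burst[1]:g$burst[2]] <- 1
        phase <- phase * w
      }
      for (r in g$resids) {
        ai <- which(base$atoms$resid == r)
        for (a in ai) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cols <- (3 * a - 2):(3 * a)
          xyz[, cols] <- xyz[, cols] + outer(phase * amp, u)
        }
      }
    }
    xyz <- sweep(xyz, 2, coords_row(base$xyz), `+`)
    list(structure = base, trajectory = md_trajectory(xyz, dt_ps, base$atoms),
         truth = groups)
  })
}

#' Two-basin (double-well) trajectory
#'
#' Frames are drawn from a two-component Gaussian mixture along two planted
#' orthonormal mode directions: component A at (-d/2, 0) with probability
#' `p`, component B at (+d/2, 0) with probability 1 - p, each with isotropic
#' in-plane spread `well_sigma`, plus a noise floor on all coordinates.
#'
#' @param n_res residues (default 50; CA chain).
#' @param n_frames frames (default 5000).
#' @param dt_ps frame spacing (default 10).
#' @param seed RNG seed.
#' @param p occupancy of well A, in (0, 1) (default 0.5).
#' @param separation inter-centre distance in units of `well_sigma`
#'   (default 6).
#' @param well_sigma in-well spread, Angstrom (default 0.5).
#' @param noise noise floor per coordinate (default 0.2 Angstrom).
#' @return list with `structure`, `trajectory`, `truth` (planted mode
#'   vectors, centres in mode coordinates, `p`, per-frame `state`).
#' @export
gen_double_well <- function(n_res = 50L, n_frames = 5000L, dt_ps = 10,
                            seed = 1L, p = 0.5, separation = 6,
                            well_sigma = 0.5, noise = 0.2) {
  if (p <= 0 || p >= 1) stopf("p must lie strictly inside (0, 1)")
  base <- synthetic_ca_chain(n_res)
  n3 <- 3L * n_res
  d <- separation * well_sigma
  with_seed(seed, {
    V <- random_internal_modes(base$xyz, 2L)
    state <- stats::rbinom(n_frames, 1, 1 - p)  # 0 = A, 1 = B
    c1 <- ifelse(state == 0, -d / 2, d / 2) + stats::rnorm(n_frames, sd = well_sigma)
    c2 <- stats::rnorm(n_frames, sd = well_sigma)
    xyz <- cbind(c1, c2) %*% t(V) +
      matrix(stats::rnorm(n_frames * n3, sd = noise), n_frames, n3)
    xyz <- sweep(xyz, 2, coords_row(base$xyz), `+`)
    truth <- list(modes = V, centers = rbind(A = c(-d / 2, 0), B = c(d / 2, 0)),
                  p = p, state = state, well_sigma = well_sigma)
    list(structure = base, trajectory = md_trajectory(xyz, dt_ps, base$atoms),
         truth = truth)
  })
}

#' Protein-ligand hydrogen-bond fixture
#'
#' A rigid 10-residue binding pocket plus a 23-atom disaccharide-like ligand
#' with three planted donor-acceptor pairs following a deterministic
#' per-frame schedule: pair 1 bonded in every frame, pair 2 in every second
#' frame, pair 3 never (held at 6 Angstrom). No hydrogens are present, so
#' the distance criterion applies.
#'
#' @param seed RNG seed (fixes the pocket geometry jitter).
#' @param n_frames frames (default 20, even).
#' @return list with `structure`, `trajectory`, `truth` (planted pairs and
#'   presence fractions).
#' @export
gen_hbond_fixture <- function(seed = 1L, n_frames = 20L) {
  # pocket: 10 residues, backbone N/CA/C/O, spread on an arc of radius 14 A
  rows <- NULL
  xyz <- NULL
  serial <- 0L
  for (i in 1:10) {
    ang <- (i - 1) * 2 * pi / 10
    c0 <- c(14 * cos(ang), 14 * sin(ang), 0)
    # backbone N sits well behind the carbonyl O so only O is reachable
    # from the pocket centre
    u <- c(cos(ang), sin(ang), 0)
    offs <- rbind(N = 4.5 * u + c(0, 0, 1.2), CA = 3.5 * u + c(0, 0, -0.8),
                  C = 1.5 * u + c(0, 0, 0.8), O = c(0, 0, 0))
    for (k in seq_len(nrow(offs))) {
      serial <- serial + 1L
      rows <- rbind(rows, data.frame(
        serial = serial, name = rownames(offs)[k], resname = "SER",
        resid = i, chain = "A",
        element = substr(rownames(offs)[k], 1, 1), b = NA_real_,
        stringsAsFactors = FALSE))
      xyz <- rbind(xyz, c0 + offs[k, ])
    }
  }
  # ligand: 23 atoms (12 C, 11 O) near the pocket centre, residue 900
  with_seed(seed, {
    lig_base <- matrix(stats::rnorm(23 * 3, sd = 1.2), 23, 3)
  })
  lig_base <- sweep(lig_base, 2, colMeans(lig_base))
  lig_names <- c(paste0("C", 1:12), paste0("O", 1:11))
  for (k in 1:23) {
    serial <- serial + 1L
    rows <- rbind(rows, data.frame(
      serial = serial, name = lig_names[k], resname = "SUC", resid = 900L,
      chain = "B", element = substr(lig_names[k], 1, 1), b = NA_real_,
      stringsAsFactors = FALSE))
  }
  xyz <- rbind(xyz, lig_base)
  # planted pairs: ligand O1/O2/O3 against the backbone O of residues 1-3
  o_rows <- function(r) which(rows$resid == r & rows$name == "O")
  lig_row <- function(nm) which(rows$resid == 900L & rows$name == nm)
  plant <- function(m, lig_nm, res, dist) {
    target <- m[o_rows(res), ]
    dir <- target - c(0, 0, 0)
    dir <- dir / sqrt(sum(dir^2))
    m[lig_row(lig_nm), ] <- target - dir * dist
    m
  }
  xyz <- plant(xyz, "O1", 1L, 2.9)
  xyz <- plant(xyz, "O2", 2L, 2.9)
  xyz <- plant(xyz, "O3", 3L, 4.6)  # listed as a near pair, never bonded
  # keep the remaining ligand atoms well away from every pocket N/O
  lig_all <- which(rows$resid == 900L & !(rows$name %in% c("O1", "O2", "O3")))
  xyz[lig_all, 3] <- xyz[lig_all, 3] + 8
  structure0 <- md_structure(rows, xyz)
  frames <- matrix(0, n_frames, 3L * nrow(rows))
  for (f in seq_len(n_frames)) {
    m <- xyz
    if (f %% 2L == 0L) m <- plant(m, "O2", 2L, 5.0)  # pair 2 off on even frames
    frames[f, ] <- coords_row(m)
  }
  truth <- list(pairs = data.frame(
    ligand_atom = c("O1", "O2", "O3"),
    residue = c("SER1", "SER2", "SER3"),
    fraction = c(1.0, 0.5, 0.0)))
  list(structure = structure0,
       trajectory = md_trajectory(frames, dt_ps = 10, atoms = rows),
       truth = truth)
}
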