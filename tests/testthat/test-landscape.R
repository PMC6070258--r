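kT303 <- 8.314462618 * 303

test_that("free energy follows G = -kT ln(P/Pmax) with the minimum at zero", {
  set.seed(41)
  proj <- matrix(rnorm(4000), 2000, 2)
  fel <- fel_from_projections(proj, c(1, 2), grid = 60, temperature = 303)
  fin <- is.finite(fel$energy)
  expect_equal(min(fel$energy[fin]), 0)
  expected <- -kT303 * log(fel$density[fin] / max(fel$density))
  expect_equal(fel$energy[fin], expected, tolerance = 1e-10)
  # a density ratio of 1/e costs exactly one kT (about 2519 J/mol at 303 K)
  g_at_ratio <- -kT303 * log(exp(-1))
  expect_equal(g_at_ratio, 2519.282, tolerance = 1e-6 * 2519.282)
  cell <- which.min(abs(fel$density / max(fel$density) - exp(-1)))
  expect_equal(fel$energy[cell], kT303, tolerance = 0.05 * kT303)
})

test_that("a symmetric Gaussian cloud yields a radially increasing landscape", {
  set.seed(42)
  proj <- matrix(rnorm(60000), 30000, 2)
  fel <- fel_from_projections(proj, c(1, 2), grid = 40)
  mid_x <- which.min(abs(fel$x))
  mid_y <- which.min(abs(fel$y))
  ray <- fel$energy[mid_x:length(fel$x), mid_y]
  # within the well-sampled region (up to ~7 kT, density ratio 1e-3) the
  # profile climbs monotonically apart from small KDE noise
  ray <- ray[is.finite(ray) & ray < 7 * kT303]
  expect_true(all(diff(ray) > -kT303 * 0.1))
  expect_gt(ray[length(ray)], ray[1] + 3 * kT303)
  b <- extract_basins(fel, 100)
  expect_length(b, 1L)
  # the basin contains the maximum-density cell
  expect_equal(b[[1]]$min_energy, 0)
})

test_that("landscape construction validates its inputs", {
  expect_error(fel_from_projections(matrix(rnorm(40), 20, 2)), "100 frames")
  degen <- cbind(rnorm(200), rep(1, 200))
  expect_error(fel_from_projections(degen), "degenerate")
  set.seed(43)
  fel <- fel_from_projections(matrix(rnorm(400), 200, 2))
  expect_error(extract_basins(fel, -5), "threshold")
  # a vanishing threshold keeps only the global-minimum cell
  b <- extract_basins(fel, 1e-9)
  expect_length(b, 1L)
  expect_equal(b[[1]]$n_cells, 1L)
})

test_that("a balanced double well shows two near-degenerate basins", {
  dw <- gen_double_well(n_res = 30, n_frames = 12000, seed = 44, p = 0.5)
  al <- align_trajectory(dw$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 4)
  fel <- fel_from_projections(project_trajectory(al, p), c(1, 2))
  b <- extract_basins(fel, 2 * kT303)
  expect_length(b, 2L)
  expect_lt(abs(b[[1]]$min_energy - b[[2]]$min_energy), 0.2 * kT303)
  occ <- vapply(b, `[[`, numeric(1), "occupancy")
  expect_equal(occ[1] / occ[2], 1, tolerance = 0.1)
  # basins are disjoint and cover at most all frames
  expect_lte(sum(occ), n_frames(al))
  expect_length(intersect(b[[1]]$frames, b[[2]]$frames), 0L)
})

test_that("a 60/40 double well reproduces the planted Boltzmann ratio", {
  dw <- gen_double_well(n_res = 30, n_frames = 20000, seed = 45, p = 0.6,
                        separation = 8)
  al <- align_trajectory(dw$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 4)
  fel <- fel_from_projections(project_trajectory(al, p), c(1, 2))
  b <- extract_basins(fel, 3 * kT303)
  expect_length(b, 2L)
  occ <- vapply(b, `[[`, numeric(1), "occupancy")
  expect_equal(max(occ) / min(occ), 0.6 / 0.4, tolerance = 0.1)
})

test_that("basin shifts track planted population moves and translations", {
  # translation: same landscape shifted in PC space
  set.seed(46)
  proj <- matrix(rnorm(6000, sd = 1.5), 3000, 2)
  f1 <- fel_from_projections(proj)
  f2 <- fel_from_projections(sweep(proj, 2, c(-2, 0), `+`))
  cell <- diff(f1$x[1:2])
  sh <- basin_shift(f1, f2)
  expect_equal(sh, c(-2, 0), tolerance = 2 * cell)
  expect_equal(basin_shift(f1, f1), c(0, 0), tolerance = 1e-12)
})

test_that("population reversal moves the deepest basin across the well gap", {
  dwA <- gen_double_well(n_res = 30, n_frames = 15000, seed = 47, p = 0.8)
  dwB <- gen_double_well(n_res = 30, n_frames = 15000, seed = 47, p = 0.2)
  alA <- align_trajectory(dwA$trajectory, "average", "all")
  alB <- align_trajectory(dwB$trajectory, "average", "all")
  pA <- pca_modes(alA, "all", offset = 1, n_modes = 4)
  # common eigenbasis: project both runs onto run A's modes
  fA <- fel_from_projections(project_trajectory(alA, pA), c(1, 2))
  fB <- fel_from_projections(project_trajectory(alB, pA), c(1, 2))
  sh <- basin_shift(fA, fB)
  # expected: inter-centre vector expressed in the PC basis
  d3n <- dwA$truth$modes %*% (dwA$truth$centers["B", ] - dwA$truth$centers["A", ])
  expected <- as.numeric(t(pA$vectors[, 1:2]) %*% d3n)
  cell <- max(diff(fA$x[1:2]), diff(fA$y[1:2]))
  expect_equal(sh, expected, tolerance = 2 * cell)
})

test_that("bending angles hit exact values on constructed geometries", {
  coords <- rbind(c(-3, 0, 0), c(0, 0, 0), c(5, 0, 0))
  tr <- traj_from_frames(list(coords), atoms = tiny_atoms(3))
  expect_equal(unname(bend_angle_series(tr, c(1, 2, 3))), 180)
  right <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  tr2 <- traj_from_frames(list(right), atoms = tiny_atoms(3))
  expect_equal(unname(bend_angle_series(tr2, c(1, 2, 3))), 90)
  expect_error(bend_angle_series(tr2, c(1, 1, 3)), "distinct")
})

test_that("a hinge closing by 15 degrees shows in the angle series mean", {
  open <- gen_two_domain_hinge(n_res = 30, n_frames = 200, seed = 48,
                               theta0 = 0, noise = 0.01)
  # closed: same geometry with a -15 degree static rotation of block 2
  closed <- gen_two_domain_hinge(n_res = 30, n_frames = 200, seed = 49,
                                 theta0 = 0, noise = 0.01)
  atoms <- closed$trajectory$atoms
  pivot <- closed$truth$pivot
  ca_row <- which(atoms$resid == pivot & atoms$name == "CA")
  moving <- which(atoms$resid > pivot |
                    (atoms$resid == pivot & atoms$name == "C"))
  R <- rot_z(-15)
  center <- closed$structure$xyz[ca_row, ]
  xyz <- closed$trajectory$xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m[moving, ] <- sweep(sweep(m[moving, , drop = FALSE], 2, center) %*% t(R),
                         2, center, `+`)
    xyz[f, ] <- as.numeric(t(m))
  }
  closed_tr <- md_trajectory(xyz, 10, atoms)
  triple <- closed$truth$bend_triple
  a_open <- bend_angle_series(open$trajectory, triple)
  a_closed <- bend_angle_series(closed_tr, triple)
  expect_equal(abs(mean(a_open) - mean(a_closed)), 15, tolerance = 0.5)
})
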