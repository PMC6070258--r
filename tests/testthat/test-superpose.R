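test_that("fitting identical coordinate sets gives the identity transform", {
  set.seed(1)
  A <- matrix(rnorm(24), 8, 3)
  f <- kabsch_fit(A, A)
  expect_equal(f$rotation, diag(3), tolerance = 1e-12)
  expect_equal(f$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
})

test_that("a known rotation + translation is recovered to 1e-8", {
  set.seed(2)
  A <- matrix(rnorm(30), 10, 3)
  R <- rot_xyz(30 * pi / 180, 0.3, -1.1)
  B <- A %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  f <- kabsch_fit(A, B)
  expect_lt(max(abs(f$rotation - R)), 1e-8)
  expect_lt(f$rmsd, 1e-8)
  expect_lt(max(abs(apply_fit(f, A) - B)), 1e-8)
  # proper rotation
  expect_equal(det(f$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(f$rotation), diag(3), tolerance = 1e-10)
})

test_that("fitted RMSD matches a rotation-grid-search oracle to 1e-3", {
  set.seed(3)
  for (case in 1:2) {
    A <- matrix(rnorm(12), 4, 3)
    B <- matrix(rnorm(12), 4, 3)
    expect_equal(kabsch_fit(A, B)$rmsd, oracle_min_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("the Kabsch RMSD lower-bounds any other rigid transform", {
  set.seed(4)
  A <- matrix(rnorm(21), 7, 3)
  B <- matrix(rnorm(21), 7, 3)
  best <- kabsch_fit(A, B)$rmsd
  for (i in 1:25) {
    R <- rot_xyz(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    moved <- sweep(sweep(A, 2, colMeans(A)) %*% t(R), 2, colMeans(B), `+`)
    expect_gte(sqrt(mean(rowSums((moved - B)^2))) + 1e-12, best)
  }
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "degenerate")
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("RMSD agrees with bio3d on a random pair", {
  set.seed(5)
  A <- matrix(rnorm(36), 12, 3)
  B <- matrix(rnorm(36), 12, 3)
  ours <- kabsch_fit(A, B)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("rmsd series has closed form for a single displaced atom", {
  base <- matrix(rnorm(15), 5, 3)
  moved <- base
  d <- 2.4
  moved[3, 1] <- moved[3, 1] + d
  tr <- traj_from_frames(list(base, moved))
  ref <- tiny_structure(base)
  series <- rmsd_series(tr, ref, "all", fit = FALSE)
  expect_equal(unname(series), c(0, d / sqrt(5)), tolerance = 1e-12)
})

test_that("excluding the only mobile block yields a near-zero rmsd series", {
  h <- gen_two_domain_hinge(n_res = 40, n_frames = 100, seed = 6, noise = 0.001)
  ref <- h$structure
  p <- h$truth$pivot
  with_v <- rmsd_series(h$trajectory, ref, "name CA")
  without_v <- rmsd_series(h$trajectory, ref,
                           sprintf("name CA and not resid %d-%d", p + 1L, 40L))
  expect_gt(max(with_v), 1)
  expect_lt(max(without_v), 0.05)
})

test_that("aligning rigid-body copies collapses them onto one structure", {
  set.seed(7)
  base <- matrix(rnorm(30), 10, 3)
  frames <- lapply(1:6, function(i) {
    R <- rot_xyz(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    base %*% t(R) + matrix(runif(3, -5, 5), 10, 3, byrow = TRUE)
  })
  al <- align_trajectory(traj_from_frames(frames), "average", "all")
  spread <- apply(al$xyz, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
})

test_that("per-frame rmsd after alignment is invariant to input global rotations", {
  g <- gen_gaussian_traj(n_res = 10, n_frames = 40, seed = 8)
  tr <- g$trajectory
  # rotate every input frame by its own random rigid transform
  set.seed(9)
  xyz2 <- tr$xyz
  for (f in seq_len(n_frames(tr))) {
    R <- rot_xyz(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    m <- matrix(tr$xyz[f, ], ncol = 3, byrow = TRUE) %*% t(R)
    xyz2[f, ] <- as.numeric(t(m + matrix(runif(3, -9, 9), nrow(m), 3, byrow = TRUE)))
  }
  tr2 <- md_trajectory(xyz2, tr$dt_ps, tr$atoms)
  a1 <- align_trajectory(tr, "average", "all")
  a2 <- align_trajectory(tr2, "average", "all")
  ref <- tiny_structure(matrix(colMeans(a1$xyz), ncol = 3, byrow = TRUE),
                        resid = tr$atoms$resid)
  s1 <- rmsd_series(a1, ref, "all", fit = TRUE)
  s2 <- rmsd_series(a2, ref, "all", fit = TRUE)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-6)
})

test_that("residual rmsd map is zero for a static trajectory", {
  base <- matrix(rnorm(24), 8, 3)
  tr <- traj_from_frames(rep(list(base), 5))
  m <- residual_rmsd_map(tr, "all")
  expect_equal(max(abs(m)), 0, tolerance = 1e-12)
  expect_error(residual_rmsd_map(tr, "all", window = 10), "window")
})

test_that("an oscillating residue shows its closed-form residual deviation", {
  # one atom moving +/- a along x; over a full cycle the rms deviation from
  # the mean position is a / sqrt(2)
  a <- 3
  n <- 64
  base <- matrix(seq_len(30), 10, 3)
  frames <- lapply(seq_len(n), function(t) {
    m <- base
    m[4, 1] <- m[4, 1] + a * sin(2 * pi * (t - 1) / n)
    m
  })
  tr <- traj_from_frames(frames)
  m <- residual_rmsd_map(tr, "all", window = n)
  expect_equal(m[4, 1], a / sqrt(2), tolerance = 1e-2)
  expect_lt(max(m[-4, 1]), 1e-10)
})

test_that("a planted high-mobility block alone exceeds the 6 A display bin", {
  g <- gen_oscillatory(n_res = 12,
                       groups = list(list(resids = 5:6, period_ns = 2,
                                          amplitude = 12)),
                       n_frames = 400, dt_ps = 10, seed = 10, noise = 0.05)
  # generated in a fixed laboratory frame: no global motion to remove
  m <- residual_rmsd_map(g$trajectory, "all")
  peak <- apply(m, 1, max)
  expect_true(all(peak[5:6] > 6))
  expect_true(all(peak[-(5:6)] < 6))
})
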