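test_that("covariance matches a brute-force double loop on a tiny trajectory", {
  frames <- list(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                 matrix(c(0.5, 0.2, 0, 1.1, -0.3, 0.4), 2, 3, byrow = TRUE),
                 matrix(c(-0.5, 0.1, 0.2, 0.9, 0.3, -0.4), 2, 3, byrow = TRUE),
                 matrix(c(0.2, -0.3, -0.2, 1.0, 0.0, 0.0), 2, 3, byrow = TRUE))
  tr <- traj_from_frames(frames)
  cv <- covariance_matrix(tr, "all", offset = 1)
  X <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    brute[i, j] <- mean(X[, i] * X[, j]) - mean(X[, i]) * mean(X[, j])
  }
  expect_equal(unname(cv[1:6, 1:6]), brute, tolerance = 1e-12)
})

test_that("covariance handles static input, strides and degenerate frame counts", {
  base <- matrix(rnorm(12), 4, 3)
  tr <- traj_from_frames(rep(list(base), 30))
  expect_equal(max(abs(covariance_matrix(tr, "all", offset = 1))), 0)
  expect_error(covariance_matrix(tr, "all", offset = 40), "fewer than 2")
  expect_error(covariance_matrix(tr, "all", offset = 0), "offset")
})

test_that("sampled covariance converges to the planted covariance", {
  g <- gen_gaussian_traj(n_res = 15, n_frames = 30000, seed = 15)
  al <- align_trajectory(g$trajectory, "average", "all")
  cv <- covariance_matrix(al, "all", offset = 1)
  rel <- norm(unname(cv) - g$covariance, "F") / norm(g$covariance, "F")
  expect_lt(rel, 0.05)
})

test_that("eigendecomposition orders modes and normalises fractions", {
  cv <- diag(c(4, 1, 0, 0, 0, 0))
  ms <- eigendecompose(cv)
  expect_equal(ms$values[1:3], c(4, 1, 0))
  expect_equal(abs(ms$vectors[1, 1]), 1, tolerance = 1e-12)
  expect_equal(ms$fractions[1:2], c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(sum(ms$fractions), 1, tolerance = 1e-12)
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2, 2)), "not symmetric")
  # orthonormality of returned modes
  g <- crossprod(ms$vectors)
  expect_equal(g, diag(ncol(ms$vectors)), tolerance = 1e-8)
})

test_that("PCA recovers planted directions and amplitudes", {
  g <- gen_gaussian_traj(n_res = 40, n_frames = 20000, seed = 16)
  al <- align_trajectory(g$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 6)
  dots <- abs(colSums(p$vectors[, 1:3] * g$modes$vectors[, 1:3]))
  expect_true(all(dots > 0.99))
  expect_equal(p$values[1:3], g$modes$values[1:3], tolerance = 0.05)
  # planted-mode variance dominates the top of the spectrum
  expect_gt(sum(p$fractions[1:3]), 0.9 * sum(g$modes$values[1:3]) /
              sum(diag(g$covariance)))
})

test_that("PCA agrees with bio3d's implementation on the same frames", {
  g <- gen_gaussian_traj(n_res = 10, n_frames = 400, seed = 17)
  al <- align_trajectory(g$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 5)
  theirs <- bio3d::pca.xyz(al$xyz)
  # bio3d normalises the covariance by n - 1, this package by n
  nf <- n_frames(al)
  expect_equal(p$values[1:5], theirs$L[1:5] * (nf - 1) / nf, tolerance = 1e-6)
  for (m in 1:3) {
    expect_equal(abs(sum(p$vectors[, m] * theirs$U[, m])), 1, tolerance = 1e-6)
  }
})

test_that("projections obey the orthonormal-mode identities", {
  g <- gen_gaussian_traj(n_res = 12, n_frames = 2000, seed = 18)
  al <- align_trajectory(g$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 5)
  # frame equal to the mean projects to zero
  tr0 <- md_trajectory(rbind(p$mean_coords, p$mean_coords), 10, al$atoms)
  expect_equal(max(abs(project_trajectory(tr0, p))), 0, tolerance = 1e-10)
  # mean + a v1 projects to (a, 0, 0, ...)
  a <- 2.7
  tr1 <- md_trajectory(rbind(p$mean_coords + a * p$vectors[, 1],
                             p$mean_coords), 10, al$atoms)
  pr <- project_trajectory(tr1, p)
  expect_equal(unname(pr[1, 1]), a, tolerance = 1e-10)
  expect_equal(max(abs(pr[1, -1])), 0, tolerance = 1e-10)
  # variance of each projection equals its eigenvalue
  pr_all <- project_trajectory(al, p)
  v <- apply(pr_all, 2, function(x) mean(x^2) - mean(x)^2)
  expect_equal(unname(v), p$values[1:5], tolerance = 0.02 * max(p$values))
  expect_error(project_trajectory(gen_gaussian_traj(n_res = 5, n_frames = 3,
                                                    seed = 1)$trajectory, p),
               "coordinates")
})

test_that("mode conformers project back onto the generating sine", {
  g <- gen_gaussian_traj(n_res = 10, n_frames = 500, seed = 19)
  al <- align_trajectory(g$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 4)
  nc <- 24
  amp <- 1.8
  conf <- mode_conformers(p, 2, amp, nc)
  pr <- project_trajectory(conf, p)
  expected <- amp * sin(2 * pi * (seq_len(nc) - 1) / nc)
  expect_equal(unname(pr[, 2]), expected, tolerance = 1e-10)
  expect_lt(max(abs(pr[, -2])), 1e-10)
  conf0 <- mode_conformers(p, 1, 0, 6)
  expect_equal(max(abs(sweep(conf0$xyz, 2, p$mean_coords))), 0, tolerance = 1e-12)
})

test_that("mode fluctuations reproduce trajectory RMSF when all modes are kept", {
  g <- gen_gaussian_traj(n_res = 10, n_frames = 800, seed = 20)
  al <- align_trajectory(g$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 30)
  fl <- mode_fluctuations(p, 30)
  prof <- rmsf_profile(al, "all")
  expect_equal(fl$rmsf^2, prof$rmsf^2, tolerance = 1e-6)
  # a single mode concentrated on one atom moves only that atom
  v <- rep(0, 9); v[1] <- 1
  ms <- mode_set(matrix(v), 2.5, rep(0, 9), "PCA", atoms = tiny_atoms(3))
  f1 <- mode_fluctuations(ms, 1)
  expect_equal(f1$rmsf, c(sqrt(2.5), 0, 0), tolerance = 1e-12)
})
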