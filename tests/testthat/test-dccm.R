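test_that("uniform common displacement gives all-ones correlation", {
  base <- matrix(rnorm(15), 5, 3)
  set.seed(27)
  frames <- lapply(1:6, function(i) base + matrix(rnorm(3), 5, 3, byrow = TRUE))
  m <- dccm_map(traj_from_frames(frames), "all", fit = FALSE)
  expect_equal(max(abs(unclass(m)[1:5, 1:5] - 1)), 0, tolerance = 1e-10)
})

test_that("exactly opposite motion gives correlation -1", {
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, 3, byrow = TRUE)
  set.seed(28)
  frames <- lapply(1:8, function(i) {
    d <- rnorm(3)
    m <- base
    m[1, ] <- m[1, ] + d
    m[2, ] <- m[2, ] - d
    m
  })
  m <- dccm_map(traj_from_frames(frames), "all", fit = FALSE)
  expect_equal(m[1, 2], -1, tolerance = 1e-10)
  expect_true(is.na(m[3, 1]))  # static atom flagged undefined
  expect_true(attr(m, "undefined")[3])
})

test_that("the map matches a brute-force double-loop oracle to 1e-12", {
  set.seed(29)
  frames <- lapply(1:5, function(i) matrix(rnorm(9), 3, 3))
  m <- dccm_map(traj_from_frames(frames), "all", fit = FALSE)
  expect_equal(unname(unclass(m)[1:3, 1:3]), oracle_dccm(frames),
               tolerance = 1e-12)
})

test_that("the map agrees with bio3d's dccm on the same frames", {
  g <- gen_gaussian_traj(n_res = 8, n_frames = 300, seed = 30)
  al <- align_trajectory(g$trajectory, "average", "all")
  ours <- dccm_map(al, "all", fit = FALSE)
  theirs <- suppressMessages(bio3d::dccm.xyz(al$xyz))
  expect_equal(unname(unclass(ours)[1:8, 1:8]), unname(theirs[1:8, 1:8]),
               tolerance = 1e-8)
})

test_that("time order does not matter and bounds always hold", {
  g <- gen_gaussian_traj(n_res = 6, n_frames = 50, seed = 31)
  tr <- g$trajectory
  perm <- sample(n_frames(tr))
  tr2 <- md_trajectory(tr$xyz[perm, ], tr$dt_ps, tr$atoms)
  m1 <- dccm_map(tr, "all", fit = FALSE)
  m2 <- dccm_map(tr2, "all", fit = FALSE)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(m1[!is.na(m1)]) <= 1 + 1e-9))
  expect_equal(unname(diag(unclass(m1))), rep(1, 6))
})

test_that("a single mode gives the rank-1 direction-cosine map", {
  # under the scalar-product convention <dr_i . dr_j>, one mode yields
  # C_ij = cos(angle between the atomic direction vectors)
  set.seed(32)
  v <- rnorm(12)
  v <- v / sqrt(sum(v^2))
  ms <- mode_set(matrix(v), 2, rep(0, 12), "PCA", atoms = tiny_atoms(4))
  m <- dccm_from_modes(ms, 1)
  V <- matrix(ms$vectors[, 1], ncol = 3, byrow = TRUE)
  lens <- sqrt(rowSums(V^2))
  expected <- tcrossprod(V) / outer(lens, lens)
  expect_equal(unname(unclass(m)[1:4, 1:4]), expected, tolerance = 1e-10)
  # perfectly parallel / anti-parallel directions do reach +1 / -1
  v2 <- as.numeric(t(rbind(c(1, 0, 0), c(-2, 0, 0))))
  ms2 <- mode_set(matrix(v2 / sqrt(5)), 1, rep(0, 6), "PCA",
                  atoms = tiny_atoms(2))
  m2 <- dccm_from_modes(ms2, 1)
  expect_equal(m2[1, 2], -1, tolerance = 1e-12)
})

test_that("all PCA modes reproduce the trajectory map exactly", {
  g <- gen_gaussian_traj(n_res = 10, n_frames = 600, seed = 33)
  al <- align_trajectory(g$trajectory, "average", "all")
  p <- pca_modes(al, "all", offset = 1, n_modes = 30)
  m_modes <- dccm_from_modes(p, 30)
  m_traj <- dccm_map(al, "all", fit = FALSE)
  expect_equal(unclass(m_modes), unclass(m_traj), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(compare_dccm(m_modes, m_traj)$r, 0.99)
})

test_that("map comparison matches a first-principles Pearson evaluation", {
  set.seed(34)
  mk <- function() {
    x <- matrix(rnorm(16), 4)
    x <- (x + t(x)) / 2
    diag(x) <- 1
    x <- pmin(pmax(x, -1), 1)
    mdscope:::new_dccm(x, 1:4, "atom", "trajectory")
  }
  a <- mk()
  b <- mk()
  r <- compare_dccm(a, b)
  expect_equal(r$n, 6L)
  expect_equal(r$r, oracle_pearson(a[upper.tri(a)], b[upper.tri(b)]),
               tolerance = 1e-12)
  expect_equal(compare_dccm(a, a)$r, 1, tolerance = 1e-12)
  neg <- mdscope:::new_dccm(-unclass(a), 1:4, "atom", "trajectory")
  expect_equal(compare_dccm(a, neg)$r, -1, tolerance = 1e-12)
})

test_that("block statistics summarise named residue partitions", {
  u <- matrix(0.4, 6, 6)
  diag(u) <- 1
  m <- mdscope:::new_dccm(u, 101:106, "atom", "trajectory")
  bs <- block_statistics(m, list(a = 101:103, b = 104:106))
  expect_equal(bs$mean, rep(0.4, 3), tolerance = 1e-12)
  # planted two-block anti-correlation
  x <- rbind(cbind(matrix(0.8, 3, 3), matrix(-0.6, 3, 3)),
             cbind(matrix(-0.6, 3, 3), matrix(0.7, 3, 3)))
  diag(x) <- 1
  m2 <- mdscope:::new_dccm(x, 1:6, "atom", "trajectory")
  bs2 <- block_statistics(m2, list(b1 = 1:3, b2 = 4:6))
  expect_lt(bs2$mean[bs2$block_i == "b2" & bs2$block_j == "b1"], 0)
  expect_gt(min(bs2$mean[bs2$block_i == bs2$block_j]), 0)
  # single-residue blocks recover the entry exactly
  bs3 <- block_statistics(m2, list(i = 2, j = 5))
  cross <- bs3$block_i == "j" & bs3$block_j == "i"
  expect_equal(bs3$mean[cross], x[2, 5])
  expect_error(block_statistics(m2, list(z = 999)), "empty block")
})

test_that("residue granularity averages atom-level correlations", {
  g <- gen_gaussian_traj(n_res = 4, n_frames = 200, seed = 35)
  tr <- g$trajectory
  tr$atoms$resid <- c(1, 1, 2, 2)
  m_at <- dccm_map(tr, "all", granularity = "atom", fit = FALSE)
  m_res <- dccm_map(tr, "all", granularity = "residue", fit = FALSE)
  expect_equal(dim(m_res), c(2L, 2L))
  expect_equal(m_res[1, 2], mean(unclass(m_at)[1:2, 3:4]), tolerance = 1e-12)
})
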