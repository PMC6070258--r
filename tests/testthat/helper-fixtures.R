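# Shared fixtures and independent oracles, built in code at test time.

# minimal atom table for n CA pseudo-atoms
tiny_atoms <- function(n, resid = seq_len(n), name = "CA", element = "C") {
  data.frame(serial = seq_len(n), name = name, resname = "ALA",
             resid = resid, chain = "A", element = element, b = NA_real_,
             stringsAsFactors = FALSE)
}

tiny_structure <- function(coords, ...) {
  md_structure(tiny_atoms(nrow(coords), ...), coords)
}

# trajectory from a list of n x 3 coordinate frames
traj_from_frames <- function(frames, dt_ps = 10, atoms = NULL) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  md_trajectory(xyz, dt_ps = dt_ps,
                atoms = atoms %||% tiny_atoms(nrow(frames[[1]])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

rot_xyz <- function(a, b, g) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# independent oracle: minimum RMSD over rigid transforms by nested grid
# search over Euler angles (translations handled by centering)
oracle_min_rmsd <- function(mobile, reference, levels = 3, steps = 16) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rmsd_at <- function(a, b, g) {
    sqrt(mean(rowSums((P %*% t(rot_xyz(a, b, g)) - Q)^2)))
  }
  ctr <- c(0, 0, 0)
  span <- pi
  best <- Inf
  for (lv in seq_len(levels)) {
    grid <- seq(-span, span, length.out = steps)
    for (a in ctr[1] + grid) for (b in ctr[2] + grid / 2) for (g in ctr[3] + grid) {
      r <- rmsd_at(a, b, g)
      if (r < best) {
        best <- r
        ctr <- c(a, b, g)
      }
    }
    span <- span / (steps / 3)
  }
  best
}

# brute-force scalar-displacement covariance and DCCM (double loop)
oracle_dccm <- function(frames) {
  n <- nrow(frames[[1]])
  nf <- length(frames)
  arr <- simplify2array(frames)          # n x 3 x nf
  mu <- apply(arr, c(1, 2), mean)
  cij <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (f in seq_len(nf)) {
      s <- s + sum((arr[i, , f] - mu[i, ]) * (arr[j, , f] - mu[j, ]))
    }
    cij[i, j] <- s / nf
  }
  cij / sqrt(outer(diag(cij), diag(cij)))
}

# textbook Pearson correlation evaluated from first principles
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
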