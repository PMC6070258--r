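# Internal helpers shared across modules.

# Gas constant in J/(mol K); energies are reported per mole so that the
# free-energy landscape comes out in J/mol.
.kB <- 8.314462618

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state on
#' exit, so generators are pure functions of their seed and never clobber the
#' session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)  # force RNG initialisation so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# frames x 3N matrix -> n x 3 coordinate matrix for one frame
frame_coords <- function(xyz, frame) {
  matrix(xyz[frame, ], ncol = 3, byrow = TRUE)
}

# n x 3 coordinate matrix -> length-3N row vector (x1 y1 z1 x2 ...)
coords_row <- function(m) {
  as.numeric(t(m))
}

# indices into a 3N vector for atom indices `idx`
xyz_index <- function(idx) {
  as.integer(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
}

# signed dihedral angle (degrees) for four points (rows of a 4x3 matrix)
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  -atan2(y, x) * 180 / pi
}

# wrap angle differences into (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# vertex angle (degrees, [0, 180]) at point b for points a, b, c
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  ct <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, ct))) * 180 / pi
}

# rotation matrix about a unit axis by angle (degrees), Rodrigues form
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
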