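#' Geometric scale grid for the continuous wavelet transform
#'
#' s_k = scale_min * factor^k, truncated at `scale_max`. Defaults follow the
#' usual protein-trajectory setup: 0.2 to 25 ns with a multiplicative step
#' of 1.01.
#'
#' @param scale_min,scale_max scale range in ns (0 < min < max).
#' @param factor multiplicative step (> 1).
#' @return increasing numeric vector of scales (ns).
#' @export
build_scale_grid <- function(scale_min = 0.2, scale_max = 25, factor = 1.01) {
  if (!(scale_min > 0 && scale_min < scale_max)) {
    stopf("require 0 < scale_min < scale_max")
  }
  if (factor <= 1) stopf("factor must be > 1")
  n <- floor(log(scale_max / scale_min) / log(factor))
  scale_min * factor^(0:n)
}

# Morlet scale -> Fourier period conversion factor
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# CWT power (scales x frames) of one centred series via FFT convolution,
# Torrence-Compo normalisation: white noise of variance s2 has expected
# power s2 at every scale.
morlet_power <- function(series, scales, dt, omega0 = 6) {
  n <- length(series)
  np <- stats::nextn(2L * n, 2)
  x <- c(series - mean(series), rep(0, np - n))
  fx <- stats::fft(x) / np
  k <- 0:(np - 1)
  omega <- 2 * pi * ifelse(k <= np / 2, k, k - np) / (np * dt)
  pos <- omega > 0
  pw <- matrix(0, length(scales), n)
  norm0 <- pi^(-1 / 4)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psihat <- numeric(np)
    psihat[pos] <- norm0 * sqrt(2 * pi * s / dt) * exp(-(s * omega[pos] - omega0)^2 / 2)
    W <- stats::fft(fx * psihat, inverse = TRUE)
    pw[si, ] <- Mod(W[seq_len(n)])^2
  }
  pw
}

#' Morlet wavelet map of a trajectory
#'
#' For each selected atom the scalar displacement series ||r_i(t) - <r_i>||
#' is transformed with the Morlet continuous wavelet (omega0 = 6) over the
#' scale grid; power is averaged over each residue's atoms, and at every
#' (residue, frame) cell the scale of maximum power defines the dominant
#' period.
#'
#' The default transforms the x, y, z displacement components separately and
#' sums their power, which preserves the period of a planted oscillation.
#' `component = "magnitude"` instead transforms the scalar displacement
#' magnitude ||r_i(t) - <r_i>||; note that the magnitude of a centred
#' oscillation is rectified, so periodic signals then show up at half their
#' true period.
#'
#' @param traj an aligned `md_trajectory`.
#' @param selection atoms to analyse (default `"heavy"`).
#' @param scales scale grid in ns (default [build_scale_grid()]).
#' @param omega0 Morlet carrier frequency (default 6).
#' @param component `"per_axis"` (default) or `"magnitude"`.
#' @return a `wavelet_map`: list with `power` and `dominant_period`
#'   (residue x frame, power at / period of the dominant scale), `edge`
#'   (cone-of-influence flags), per-residue noise statistics used by
#'   [significance_mask()], the scale and period grids (ns) and frame times.
#' @export
morlet_map <- function(traj, selection = "heavy", scales = build_scale_grid(),
                       omega0 = 6, component = c("per_axis", "magnitude")) {
  component <- match.arg(component)
  sel <- resolve_selection(traj, selection)
  dt <- traj$dt_ps / 1000  # ns
  nf <- n_frames(traj)
  if (nf * dt < 2 * max(scales)) {
    stopf("trajectory (%.3g ns) is shorter than twice the largest scale (%.3g ns)",
          nf * dt, max(scales))
  }
  resid_of <- if (!is.null(traj$atoms)) traj$atoms$resid[sel$indices] else sel$indices
  resids <- unique(resid_of)
  nr <- length(resids)
  ns <- length(scales)
  power <- matrix(0, nr, nf)
  dom <- matrix(1L, nr, nf)
  sigma2 <- numeric(nr)
  lag1 <- numeric(nr)
  for (ri in seq_len(nr)) {
    atoms_r <- sel$indices[resid_of == resids[ri]]
    acc <- matrix(0, ns, nf)
    s2 <- 0
    a1 <- 0
    for (ai in atoms_r) {
      cols <- (3 * ai - 2):(3 * ai)
      d <- sweep(traj$xyz[, cols, drop = FALSE], 2,
                 colMeans(traj$xyz[, cols, drop = FALSE]))
      if (component == "per_axis") {
        for (ax in 1:3) {
          serie <- d[, ax]
          acc <- acc + morlet_power(serie, scales, dt, omega0)
          s2 <- s2 + stats::var(serie)
          a1 <- a1 + lag1_autocor(serie) / 3
        }
      } else {
        serie <- sqrt(rowSums(d^2))
        acc <- acc + morlet_power(serie, scales, dt, omega0)
        s2 <- s2 + stats::var(serie)
        a1 <- a1 + lag1_autocor(serie)
      }
    }
    acc <- acc / length(atoms_r)
    sigma2[ri] <- s2 / length(atoms_r)
    lag1[ri] <- a1 / length(atoms_r)
    dom[ri, ] <- max.col(t(acc), ties.method = "first")
    power[ri, ] <- acc[cbind(dom[ri, ], seq_len(nf))]
  }
  times <- frame_times_ns(traj)
  # cone of influence: e-folding time sqrt(2)*scale from either edge,
  # evaluated at each cell's dominant scale
  sdom <- matrix(scales[dom], nr, nf)
  tmat <- matrix(times, nr, nf, byrow = TRUE)
  edge <- tmat < sqrt(2) * sdom | (max(times) - tmat) < sqrt(2) * sdom
  structure(list(power = power, dominant_scale = dom,
                 dominant_period = sdom * morlet_fourier_factor(omega0),
                 edge = edge, scales = scales,
                 periods = scales * morlet_fourier_factor(omega0),
                 times_ns = times, resid = resids, sigma2 = sigma2,
                 lag1 = lag1, omega0 = omega0, dt_ns = dt),
            class = "wavelet_map")
}

lag1_autocor <- function(x) {
  if (stats::var(x) == 0) return(0)
  n <- length(x)
  xc <- x - mean(x)
  max(0, sum(xc[-1] * xc[-n]) / sum(xc^2))
}

#' @export
print.wavelet_map <- function(x, ...) {
  cat(sprintf("wavelet_map: %d residues x %d frames, %d scales (%.3g-%.3g ns period)\n",
              nrow(x$power), ncol(x$power), length(x$scales),
              min(x$periods), max(x$periods)))
  invisible(x)
}

# normalised red-noise (lag-1 AR) background spectrum at a Fourier period,
# Torrence-Compo form; alpha = 0 gives the flat white-noise background
red_noise_spectrum <- function(period, dt, alpha) {
  freq <- dt / period  # cycles per sample
  (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * freq))
}

#' Significance mask for a wavelet map
#'
#' A (residue, frame) cell is significant when its power at the dominant
#' scale exceeds the background spectrum (white or lag-1 autoregressive red
#' noise, estimated per residue from the input series) times the
#' `chi2_critical` threshold constant times the `confidence` quantile of the
#' chi-squared law with the wavelet's 2 degrees of freedom (scaled by 1/2).
#'
#' @param map a `wavelet_map`.
#' @param chi2_critical threshold constant (default 1.6094).
#' @param confidence confidence level in (0, 1) (default 0.99).
#' @param background `"red"` (default) or `"white"`.
#' @param exclude_edge force cone-of-influence cells to FALSE (default TRUE).
#' @return logical residue x frame matrix.
#' @export
significance_mask <- function(map, chi2_critical = 1.6094, confidence = 0.99,
                              background = c("red", "white"),
                              exclude_edge = TRUE) {
  background <- match.arg(background)
  if (!(confidence > 0 && confidence < 1)) stopf("confidence must be in (0,1)")
  nr <- nrow(map$power)
  nf <- ncol(map$power)
  qfac <- stats::qchisq(confidence, df = 2) / 2
  alpha <- if (background == "red") map$lag1 else rep(0, nr)
  thr <- matrix(0, nr, nf)
  for (ri in seq_len(nr)) {
    pk <- red_noise_spectrum(map$periods[map$dominant_scale[ri, ]],
                             map$dt_ns, alpha[ri])
    thr[ri, ] <- map$sigma2[ri] * pk * chi2_critical * qfac
  }
  sig <- map$power > thr
  if (exclude_edge) sig <- sig & !map$edge
  sig
}

#' Tabulate a wavelet map
#'
#' Long-format summary: one row per (residue, frame) with dominant period and
#' significance flag, the layout used for period-map rendering (period bins
#' 0-5, 5-10, 10-15, 15-20, 20-25 ns).
#'
#' @param map a `wavelet_map`.
#' @param significant optional mask from [significance_mask()].
#' @return data.frame with `resid`, `time_ns`, `dominant_period_ns`,
#'   `power`, `edge`, `significant`.
#' @export
wavelet_table <- function(map, significant = NULL) {
  significant <- significant %||% significance_mask(map)
  data.frame(
    resid = rep(map$resid, times = ncol(map$power)),
    time_ns = rep(map$times_ns, each = nrow(map$power)),
    dominant_period_ns = as.numeric(map$dominant_period),
    power = as.numeric(map$power),
    edge = as.logical(map$edge),
    significant = as.logical(significant)
  )
}
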