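#' Dynamical cross-correlation map
#'
#' Normalised covariance of atomic displacement vectors,
#' C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>), over the frames of a
#' trajectory or the members of a structure ensemble. +1 marks fully
#' correlated, -1 fully anti-correlated motion. Frames are least-squares
#' fitted on `fit_selection` first (disable with `fit = FALSE` if already
#' aligned).
#'
#' @param frames an `md_trajectory` or `md_ensemble`.
#' @param selection atoms entering the map (default `"name CA"`).
#' @param granularity `"atom"` (one row per selected atom, the usual choice
#'   with a C-alpha selection) or `"residue"` (atom-level correlations
#'   averaged over residue pairs).
#' @param fit least-squares fit every frame before analysing (default TRUE).
#' @param fit_selection atoms used for the fit (default `"heavy"`, i.e.
#'   backbone and side chains).
#' @return a `dccm_map`: N x N matrix in \[-1, 1\] with residue-id labels.
#'   Atoms with zero variance give NA rows/columns, flagged in attribute
#'   `undefined`.
#' @export
dccm_map <- function(frames, selection = "name CA",
                     granularity = c("atom", "residue"), fit = TRUE,
                     fit_selection = "heavy") {
  granularity <- match.arg(granularity)
  if (inherits(frames, "md_ensemble")) frames <- as_trajectory(frames)
  if (n_frames(frames) < 2L) stopf("need at least 2 frames/structures")
  if (fit) frames <- align_trajectory(frames, "average", fit_selection)
  sel <- resolve_selection(frames, selection)
  sub <- frames$xyz[, xyz_index(sel$indices), drop = FALSE]
  centered <- sweep(sub, 2, colMeans(sub))
  n <- length(sel$indices)
  cij <- matrix(0, n, n)
  for (ax in 1:3) {
    Xax <- centered[, seq(ax, by = 3, length.out = n), drop = FALSE]
    cij <- cij + crossprod(Xax) / nrow(Xax)
  }
  v <- diag(cij)
  undef <- v <= 0
  denom <- sqrt(outer(v, v))
  C <- cij / denom
  C[undef, ] <- NA
  C[, undef] <- NA
  diag(C)[!undef] <- 1
  stopifnot(all(abs(C[!is.na(C)]) <= 1 + 1e-9))
  C <- pmin(pmax(C, -1), 1)
  labels <- frames$atoms$resid[sel$indices] %||% sel$indices
  if (granularity == "residue") {
    resids <- unique(labels)
    M <- matrix(NA_real_, length(resids), length(resids))
    for (a in seq_along(resids)) {
      for (b in seq_len(a)) {
        blk <- C[labels == resids[a], labels == resids[b], drop = FALSE]
        M[a, b] <- M[b, a] <- mean(blk, na.rm = TRUE)
      }
    }
    C <- M
    labels <- resids
    undef <- apply(C, 1, function(r) all(is.na(r)))
  }
  new_dccm(C, labels, granularity, source = "trajectory", undefined = undef)
}

new_dccm <- function(C, labels, granularity, source, undefined = NULL) {
  dimnames(C) <- list(labels, labels)
  structure(C, labels = labels, granularity = granularity, source = source,
            undefined = undefined %||% rep(FALSE, nrow(C)),
            class = c("dccm_map", "matrix"))
}

#' @export
print.dccm_map <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("dccm_map (%s, %s): %d x %d; off-diagonal mean %.3f, range [%.2f, %.2f]\n",
              attr(x, "source"), attr(x, "granularity"), nrow(x), ncol(x),
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Cross-correlation map implied by a mode set
#'
#' c_ij = sum_m amp_m^2 (v_m,i . v_m,j) over the first `first_k` modes, with
#' amp_m^2 the mode variance (PCA) or kB*T/eigenvalue (elastic network),
#' normalised to correlations. With all PCA modes this reproduces the
#' trajectory covariance by construction.
#'
#' @param modes a `mode_set`.
#' @param first_k number of modes (default 3).
#' @param temperature Kelvin, for elastic-network amplitudes.
#' @return a `dccm_map`.
#' @export
dccm_from_modes <- function(modes, first_k = 3L, temperature = 303) {
  first_k <- min(first_k, ncol(modes$vectors))
  amp2 <- mode_amplitudes2(modes, first_k, temperature)
  n <- nrow(modes$vectors) / 3L
  cij <- matrix(0, n, n)
  for (m in seq_len(first_k)) {
    V <- matrix(modes$vectors[, m], ncol = 3, byrow = TRUE)
    cij <- cij + amp2[m] * tcrossprod(V)
  }
  v <- diag(cij)
  undef <- v <= .Machine$double.eps * max(v)
  C <- cij / sqrt(outer(v, v))
  C[undef, ] <- NA
  C[, undef] <- NA
  diag(C)[!undef] <- 1
  C <- pmin(pmax(C, -1), 1)
  labels <- if (!is.null(modes$atoms)) modes$atoms$resid else seq_len(n)
  new_dccm(C, labels, "atom", source = "modes", undefined = undef)
}

#' Pearson correlation between two cross-correlation maps
#'
#' Computed over the unique off-diagonal (i < j) pairs shared by both maps,
#' excluding undefined entries. Maps with differing label sets are compared
#' on the intersection, with a warning.
#'
#' @param a,b `dccm_map` objects.
#' @return list with `r` (Pearson) and `n` (pairs used).
#' @export
compare_dccm <- function(a, b) {
  la <- attr(a, "labels")
  lb <- attr(b, "labels")
  shared <- intersect(la, lb)
  if (length(shared) < length(la) || length(shared) < length(lb)) {
    warning("label sets differ; comparing on the intersection")
  }
  A <- a[match(shared, la), match(shared, la)]
  B <- b[match(shared, lb), match(shared, lb)]
  ut <- upper.tri(A)
  ok <- ut & !is.na(A) & !is.na(B)
  if (sum(ok) < 3L) stopf("fewer than 3 usable pairs")
  list(r = stats::cor(A[ok], B[ok], method = "pearson"), n = sum(ok))
}

#' Mean correlation within and between named residue blocks
#'
#' Summarises a cross-correlation map over a named partition of residues
#' (e.g. structural domains; blocks may be discontiguous).
#'
#' @param map a `dccm_map` labelled by residue id.
#' @param blocks named list of residue-id vectors.
#' @return data.frame with `block_i`, `block_j`, `mean`, `min`, `max`, `n`
#'   for every unordered block pair (diagonal pairs exclude self-correlations).
#' @export
block_statistics <- function(map, blocks) {
  labels <- attr(map, "labels")
  nm <- names(blocks)
  if (is.null(nm) || any(nm == "")) stopf("blocks must be named")
  idx <- lapply(blocks, function(r) which(labels %in% r))
  empty <- vapply(idx, length, integer(1)) == 0L
  if (any(empty)) stopf("empty block(s): %s", paste(nm[empty], collapse = ", "))
  out <- NULL
  for (a in seq_along(idx)) {
    for (b in seq_len(a)) {
      sub <- map[idx[[a]], idx[[b]], drop = FALSE]
      if (a == b) {
        vals <- sub[upper.tri(sub)]
        if (!length(vals)) vals <- diag(sub)
      } else {
        vals <- as.numeric(sub)
      }
      vals <- vals[!is.na(vals)]
      out <- rbind(out, data.frame(
        block_i = nm[a], block_j = nm[b],
        mean = if (length(vals)) mean(vals) else NA_real_,
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_,
        n = length(vals)))
    }
  }
  out
}

#' Write a cross-correlation map as labelled TSV
#' @param map a `dccm_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dccm <- function(map, path) {
  df <- as.data.frame(unclass(map)[seq_len(nrow(map)), , drop = FALSE])
  names(df) <- attr(map, "labels")
  utils::write.table(cbind(resid = attr(map, "labels"), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
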