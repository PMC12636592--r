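#' Zero-normalized cross-correlation of two rasters at a fixed offset
#'
#' Places raster `b` at offset `(dx, dy)` relative to raster `a` (both
#' anchored at their top-left corner; x indexes columns, y indexes rows,
#' 0-based) and computes the dot product of the mean-centred, unit-norm
#' overlap intensities. 1 means a perfect affine-intensity match.
#'
#' @param a,b numeric matrices.
#' @param dx,dy integer offset of `b` relative to `a` in pixels.
#' @return scalar in `[-1, 1]`; `NA` if the overlap has fewer than 2 pixels;
#'   0 (flagged with attribute `degenerate = TRUE`) if either overlap vector
#'   has zero variance.
#' @export
zncc <- function(a, b, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  ha <- nrow(a); wa <- ncol(a); hb <- nrow(b); wb <- ncol(b)
  x0 <- max(0L, dx); x1 <- min(wa, dx + wb)
  y0 <- max(0L, dy); y1 <- min(ha, dy + hb)
  if ((x1 - x0) * (y1 - y0) < 2L) return(NA_real_)
  va <- as.vector(a[(y0 + 1L):y1, (x0 + 1L):x1])
  vb <- as.vector(b[(y0 - dy + 1L):(y1 - dy), (x0 - dx + 1L):(x1 - dx)])
  va <- va - mean(va); vb <- vb - mean(vb)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    return(structure(0, degenerate = TRUE))
  }
  sum(va * vb) / (na * nb)
}

# Circular cross-correlation surface of two equally sized rasters via FFT.
# Rasters are mean-subtracted upstream, so the surface is the plain
# (DC-free) circular cross-correlation; with normalize = TRUE the
# cross-power spectrum is whitened instead (classic phase correlation,
# sharper peaks but fragile on band-limited textures). The 0-based index
# (row, col) of a peak corresponds to candidate offsets
# (dy, dx) in {row, row - h} x {col, col - w} of b relative to a.
cross_correlation_surface <- function(fa, fb, normalize = FALSE) {
  p <- fa * Conj(fb)
  if (normalize) {
    m <- Mod(p)
    m[m < 1e-12] <- 1e-12
    p <- p / m
  }
  Re(stats::fft(p, inverse = TRUE)) / length(p)
}

# Top n distinct peak positions (0-based row/col) of a correlation surface.
top_peaks <- function(surface, n = 2L) {
  o <- order(surface, decreasing = TRUE)[seq_len(min(n, length(surface)))]
  h <- nrow(surface)
  cbind(row = (o - 1L) %% h, col = (o - 1L) %/% h)
}

#' Refine a pairwise offset by phase cross-correlation
#'
#' Computes the circular cross-correlation of the two rasters in the
#' frequency domain, expands the top two correlation maxima into the four
#' circular-ambiguity offsets each, scores all eight candidates by [zncc()]
#' on the implied overlap, and returns the best.
#'
#' @param a,b numeric matrices (the fiducial rasters of the two tiles).
#' @param fa,fb optional precomputed FFTs of the mean-subtracted rasters
#'   (padded to common size); passed by the batch refiner to avoid repeated
#'   FFTs.
#' @param normalize whiten the cross-power spectrum (classic phase
#'   correlation) instead of plain mean-free cross-correlation. Off by
#'   default: whitening amplifies featureless high frequencies and can bury
#'   the true peak on smooth textures.
#' @param n_peaks number of correlation maxima to expand (default 2).
#' @param min_overlap smallest overlap area (px) a candidate may imply;
#'   smaller overlaps produce chance-level ZNCC scores and are excluded.
#' @return list with `dx`, `dy` (integer offset of `b` relative to `a`),
#'   `score` (ZNCC of the winning candidate; -1 if every candidate implied a
#'   degenerate overlap) and `ok` (logical).
#' @export
phase_align <- function(a, b, fa = NULL, fb = NULL, normalize = FALSE,
                        n_peaks = 2L, min_overlap = 32L) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("phase_align requires non-constant rasters")
  h <- max(nrow(a), nrow(b)); w <- max(ncol(a), ncol(b))
  pad <- function(m) {
    if (nrow(m) == h && ncol(m) == w) return(m)
    out <- matrix(0, h, w)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  if (is.null(fa)) fa <- stats::fft(pad(a - mean(a)))
  if (is.null(fb)) fb <- stats::fft(pad(b - mean(b)))
  surf <- cross_correlation_surface(fa, fb, normalize = normalize)
  pk <- top_peaks(surf, n_peaks)
  best <- list(dx = 0L, dy = 0L, score = -1, ok = FALSE)
  for (p in seq_len(nrow(pk))) {
    for (dy in c(pk[p, "row"], pk[p, "row"] - h)) {
      for (dx in c(pk[p, "col"], pk[p, "col"] - w)) {
        ow <- min(ncol(a), dx + ncol(b)) - max(0, dx)
        oh <- min(nrow(a), dy + nrow(b)) - max(0, dy)
        if (ow * oh < min_overlap) next
        s <- zncc(a, b, dx, dy)
        if (is.na(s) || isTRUE(attr(s, "degenerate"))) next
        if (s > best$score || !best$ok) {
          best <- list(dx = as.integer(dx), dy = as.integer(dy),
                       score = as.numeric(s), ok = TRUE)
        }
      }
    }
  }
  if (!best$ok) best$score <- -1
  best
}

# Single-peak phase-correlation offset with each coordinate unwrapped to the
# centred range (-n/2, n/2]. Used for block-wise alignment evaluation where
# the expected offset is near zero.
phase_offset_centered <- function(a, b, normalize = FALSE) {
  fa <- stats::fft(a - mean(a)); fb <- stats::fft(b - mean(b))
  surf <- cross_correlation_surface(fa, fb, normalize = normalize)
  pk <- top_peaks(surf, 1L)
  h <- nrow(a); w <- ncol(a)
  dy <- pk[1, "row"]; dx <- pk[1, "col"]
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dx = as.numeric(dx), dy = as.numeric(dy))
}
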