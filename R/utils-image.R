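#' Discrete 1-D Gaussian kernel
#'
#' Normalized Gaussian sampled on integers, truncated at `radius`
#' (default 4 sigma, matching common scale-space practice).
#'
#' @param sigma standard deviation in pixels.
#' @param radius half-width of the kernel support in pixels.
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @export
gaussian_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# Convolve down the columns of a matrix with replicate (nearest) boundary.
# Processes in column strips so peak memory stays bounded on large mosaics;
# strips are exact (pad >= kernel radius), so chunking never changes output.
conv_cols <- function(m, k, chunk = 2048L) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  nc <- ncol(m)
  out <- matrix(0, n, nc)
  for (c0 in seq(1L, nc, by = chunk)) {
    c1 <- min(nc, c0 + chunk - 1L)
    mp <- m[idx, c0:c1, drop = FALSE]
    acc <- matrix(0, n, c1 - c0 + 1L)
    for (s in seq_along(k)) {
      acc <- acc + k[s] * mp[s:(s + n - 1L), , drop = FALSE]
    }
    out[, c0:c1] <- acc
  }
  out
}

#' Gaussian blur of a matrix
#'
#' Separable convolution with a truncated discrete Gaussian; boundaries are
#' handled by edge replication, so a constant image is reproduced exactly.
#'
#' @param m numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @param radius kernel half-width; defaults to `ceiling(4 * sigma)`.
#' @return blurred matrix, same dimensions as `m`.
#' @export
gaussian_blur <- function(m, sigma, radius = ceiling(4 * sigma)) {
  k <- gaussian_kernel1d(sigma, radius)
  t(conv_cols(t(conv_cols(m, k)), k))
}

# 4-neighbour discrete Laplacian with replicate boundary.
laplacian <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up    <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(n)[-1L], n), , drop = FALSE]
  left  <- m[, c(1L, seq_len(p - 1L)), drop = FALSE]
  right <- m[, c(seq_len(p)[-1L], p), drop = FALSE]
  up + down + left + right - 4 * m
}

# Local maxima of a 3-D array (row, col, scale) over the 26-neighbourhood.
# Out-of-bounds neighbours count as -Inf. Returns integer index matrix.
local_maxima_3d <- function(a, threshold = -Inf) {
  d <- dim(a)
  best <- array(-Inf, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    si <- seq_len(d[1]) + di; sj <- seq_len(d[2]) + dj; sk <- seq_len(d[3]) + dk
    oi <- si >= 1 & si <= d[1]; oj <- sj >= 1 & sj <= d[2]; ok <- sk >= 1 & sk <= d[3]
    if (!any(oi) || !any(oj) || !any(ok)) next
    sub <- array(-Inf, d)
    sub[oi, oj, ok] <- a[si[oi], sj[oj], sk[ok], drop = FALSE]
    best <- pmax(best, sub)
  }
  which(a > best & a > threshold, arr.ind = TRUE)
}
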