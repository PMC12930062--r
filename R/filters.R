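#' Percentile intensity normalization
#'
#' Rescales a grid so that the \code{p_low}-th percentile of its intensities
#' maps to 0 and the \code{p_high}-th to 1, clipping outside \code{[0, 1]}.
#' This removes sample-to-sample variation in staining and detector gain
#' before any filtering. If the two percentiles coincide (a constant grid)
#' the output is identically 0.
#'
#' @param grid a [VoxelGrid-class].
#' @param p_low,p_high percentiles in percent, \code{0 <= p_low < p_high <=
#'   100}.
#' @return A [VoxelGrid-class] with values in \code{[0, 1]}.
#' @examples
#' g <- VoxelGrid(array(runif(512), dim = c(16, 16, 2)))
#' range(intensities(normalizeIntensity(g, 1, 99)))
#' @export
normalizeIntensity <- function(grid, p_low = 0.1, p_high = 99.9) {
  stopifnot(is(grid, "VoxelGrid"),
            p_low >= 0, p_low < p_high, p_high <= 100)
  v <- grid@values
  q <- stats::quantile(v, probs = c(p_low, p_high) / 100,
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    v[] <- 0
  } else {
    v <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  initialize(grid, values = v)
}

#' Per-slice white top-hat background removal
#'
#' Subtracts the morphological opening with a disc structuring element from
#' each z-slice, removing background structures larger than the disc while
#' preserving small bright puncta. Output is non-negative and bounded above
#' by the input everywhere.
#'
#' @param grid a [VoxelGrid-class] (normally a normalized grid).
#' @param radius disc radius in pixels, \code{>= 1}.
#' @return A [VoxelGrid-class] of the same geometry.
#' @export
topHatFilter <- function(grid, radius = 8) {
  stopifnot(is(grid, "VoxelGrid"), radius >= 1)
  d <- dim(grid@values)
  if (2 * radius + 1 > min(d[1], d[2]))
    stop("tophat radius larger than the slice extent")
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  out <- EBImage::whiteTopHat(grid@values, kern)
  # float morphology can leave tiny negative residues
  out <- array(pmax(out, 0), dim = d)
  initialize(grid, values = out)
}

# Per-slice box mean over a w x w window, replicate boundary, via running
# sums (separable, O(n) per slice). Returns a list of matrices, one per z.
.boxMean <- function(x, w) {
  r <- (w - 1L) %/% 2L
  run1 <- function(m, n) {
    # window mean along rows with replicate padding
    mp <- m[c(rep(1L, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
    cs <- apply(mp, 2L, cumsum)
    top <- cs[(2L * n + 1L):nrow(mp), , drop = FALSE]
    bot <- rbind(0, cs[seq_len(nrow(mp) - 2L * n - 1L), , drop = FALSE])
    (top - bot) / (2L * n + 1L)
  }
  lapply(seq_len(dim(x)[3]), function(k) {
    t(run1(t(run1(x[, , k], r)), r))
  })
}

#' Per-slice adaptive Wiener denoising
#'
#' Local-adaptive (pixel-wise) Wiener filter applied to every z-slice:
#' \deqn{y = m + \frac{\max(s^2 - \nu, 0)}{s^2}\,(x - m)}
#' with \eqn{m} and \eqn{s^2} the local mean and variance over a square
#' window and \eqn{\nu} the noise variance. Where the local variance does
#' not exceed the noise estimate the output collapses to the local mean, so
#' a noiseless constant region is preserved exactly.
#'
#' @param grid a [VoxelGrid-class].
#' @param window odd window edge in pixels, \code{>= 3}.
#' @param noise noise variance, or \code{"auto"} (default) to estimate it
#'   per slice as the mean of the local variances.
#' @return A [VoxelGrid-class] of the same geometry.
#' @export
wienerFilter <- function(grid, window = 3L, noise = "auto") {
  stopifnot(is(grid, "VoxelGrid"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("wiener window must be odd and >= 3")
  if (identical(noise, "auto")) noise <- NA_real_
  noise <- as.numeric(noise)
  if (!is.na(noise) && noise < 0) stop("noise variance must be >= 0")
  v <- grid@values
  m <- .boxMean(v, window)
  m2 <- .boxMean(v * v, window)
  out <- v
  for (k in seq_len(dim(v)[3])) {
    lv <- pmax(m2[[k]] - m[[k]]^2, 0)
    nu <- if (is.na(noise)) mean(lv) else noise
    gain <- ifelse(lv > 0, pmax(lv - nu, 0) / lv, 0)
    out[, , k] <- m[[k]] + gain * (v[, , k] - m[[k]])
  }
  initialize(grid, values = array(pmax(out, 0), dim = dim(v)))
}

# Discrete negated scale-normalized LoG kernel (-sigma^2 * Laplacian of a
# unit-mass Gaussian), zero-sum so a flat input responds exactly 0.
.logKernel <- function(sigma) {
  r <- max(2L, as.integer(ceiling(4 * sigma)))
  ix <- seq(-r, r)
  rr2 <- outer(ix^2, ix^2, "+")
  g <- exp(-rr2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- -(rr2 - 2 * sigma^2) / sigma^2 * g
  k - mean(k)
}

#' Per-slice scale-normalized LoG blob response
#'
#' Convolves each z-slice with a negated, scale-normalized
#' Laplacian-of-Gaussian kernel (\eqn{-\sigma^2 \nabla^2 G_\sigma}), so
#' bright Gaussian-like blobs of scale about \eqn{\sigma} pixels produce
#' positive local maxima. A flat input yields an identically zero response.
#'
#' @param grid a [VoxelGrid-class].
#' @param sigma Gaussian scale in pixels, \code{> 0}.
#' @return A numeric array \code{(ny, nx, nz)} of signed responses (not a
#'   \code{VoxelGrid}: responses can be negative).
#' @export
logResponse <- function(grid, sigma) {
  stopifnot(is(grid, "VoxelGrid"), sigma > 0)
  k <- .logKernel(sigma)
  array(EBImage::filter2(grid@values, k, boundary = "replicate"),
        dim = dim(grid@values))
}
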