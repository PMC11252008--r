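## Intensity normalisation and smoothing primitives. Percentiles use linear
## interpolation between order statistics (stats::quantile type 7, the common
## default of array libraries).

#' Percentile-based contrast stretching
#'
#' Linearly maps the intensity window [P(pLow), P(pHigh)] to [0, 1] and clips.
#' The structural channel is stretched with the 1st/99th percentiles before
#' thresholding; a degenerate window (equal percentiles) yields an all-zero
#' volume with a warning.
#'
#' @param volume A [Volume-class].
#' @param pLow,pHigh Percentiles in [0, 100], pLow < pHigh.
#' @return A rescaled [Volume-class] with values in [0, 1].
#' @export
#' @examples
#' v <- Volume(array(seq(0, 999), c(10, 10, 10)))
#' r <- contrastStretch(v, 1, 99)
#' range(voxelData(r))
contrastStretch <- function(volume, pLow = 1, pHigh = 99) {
  stopifnot(is(volume, "Volume"))
  if (!(pLow >= 0 && pLow < pHigh && pHigh <= 100))
    stop("need 0 <= pLow < pHigh <= 100")
  x <- volume@data
  lim <- stats::quantile(x, c(pLow, pHigh) / 100, names = FALSE, type = 7)
  if (lim[2] <= lim[1]) {
    warning("degenerate intensity window; returning all-zero volume")
    volume@data <- array(0, dim(x))
    return(volume)
  }
  y <- (x - lim[1]) / (lim[2] - lim[1])
  volume@data <- array(pmin(1, pmax(0, y)), dim(x))
  volume
}

#' Difference-of-Gaussians background subtraction
#'
#' Smooths the volume with a narrow "signal" Gaussian and a wide "background"
#' Gaussian, subtracts background from signal and clips negatives to zero.
#' The marker channels use sigmas (15, 1) voxels; the refined local cleft
#' pipeline uses (7, 0.3).
#'
#' @param volume A [Volume-class].
#' @param sigmaBg Background sigma in voxels (isotropic), > sigmaSig.
#' @param sigmaSig Signal sigma in voxels, >= 0 (0 = identity).
#' @return A [Volume-class] of clipped differences.
#' @export
dogSubtract <- function(volume, sigmaBg = 15, sigmaSig = 1) {
  stopifnot(is(volume, "Volume"))
  if (!(sigmaBg > sigmaSig && sigmaSig >= 0))
    stop("need sigmaBg > sigmaSig >= 0")
  x <- volume@data
  sig <- if (sigmaSig > 0) .gaussian_blur(x, rep(sigmaSig, 3)) else x
  bg <- .gaussian_blur(x, rep(sigmaBg, 3))
  volume@data <- array(pmax(0, sig - bg), dim(x))
  volume
}

#' Grayscale erosion with a Euclidean ball
#'
#' Replaces every voxel by the minimum over the digital ball of the given
#' radius; the refined local pipeline uses radius 1 to counteract the
#' blurring of denoising and background subtraction.
#'
#' @param volume A [Volume-class].
#' @param radiusVoxels Ball radius in voxels, >= 1.
#' @return The eroded [Volume-class].
#' @export
grayscaleErode <- function(volume, radiusVoxels = 1) {
  stopifnot(is(volume, "Volume"), radiusVoxels >= 1)
  volume@data <- .ball_filter(volume@data, radiusVoxels, 0L)
  volume
}

#' Contrast-limited adaptive histogram equalisation (3D)
#'
#' Tile-based CLAHE: the volume is divided into a grid of tiles of size
#' \code{kernelFrac} of each dimension, a clipped 256-bin histogram is
#' equalised per tile, and per-voxel mappings are blended by trilinear
#' interpolation between tile centres. Used to flatten slow intensity
#' gradients with depth before manual dense segmentation.
#'
#' @param volume A [Volume-class] normalised to [0, 1].
#' @param clipLimit Histogram clip limit as a fraction of tile voxel count.
#' @param kernelFrac Tile size as a fraction of each dimension.
#' @return The equalised [Volume-class] in [0, 1].
#' @export
equalizeAdaptive <- function(volume, clipLimit = 0.02, kernelFrac = 1 / 5) {
  stopifnot(is(volume, "Volume"))
  x <- volume@data
  if (min(x) < 0 || max(x) > 1)
    stop("volume must be normalised to [0, 1]")
  d <- dim(x)
  nbins <- 256L
  if (max(x) == min(x)) return(volume)  # constant in, constant out
  ntile <- pmax(1L, as.integer(round(1 / kernelFrac)))
  ntile <- rep(ntile, length.out = 3)
  tsz <- d / ntile
  bin <- pmin(nbins, pmax(1L, as.integer(floor(x * nbins)) + 1L))
  ## tile index per axis and tile-centre coordinate
  tix <- lapply(1:3, function(ax)
    pmin(ntile[ax], pmax(1L, ceiling(seq_len(d[ax]) / tsz[ax]))))
  centers <- lapply(1:3, function(ax) (seq_len(ntile[ax]) - 0.5) * tsz[ax])
  ## per-tile clipped CDF mapping: M[tile, bin]
  ntiles <- prod(ntile)
  M <- matrix(0, ntiles, nbins)
  tid_of <- function(iz, iy, ix) (ix - 1L) * ntile[1] * ntile[2] +
    (iy - 1L) * ntile[1] + iz
  tid_arr <- array(0L, d)
  tid_arr[] <- tid_of(tix[[1]][slice.index(x, 1)],
                      tix[[2]][slice.index(x, 2)],
                      tix[[3]][slice.index(x, 3)])
  for (t in seq_len(ntiles)) {
    sel <- tid_arr == t
    nvox <- sum(sel)
    h <- tabulate(bin[sel], nbins)
    clip <- max(1, clipLimit * nvox)
    excess <- sum(pmax(0, h - clip))
    h <- pmin(h, clip) + excess / nbins
    cdf <- cumsum(h) / sum(h)
    M[t, ] <- cdf
  }
  ## trilinear interpolation between the 8 surrounding tile mappings
  wts <- lapply(1:3, function(ax) {
    pos <- seq_len(d[ax])
    ct <- centers[[ax]]
    lo <- findInterval(pos, ct)                    # 0..ntile
    lo <- pmin(pmax(lo, 1L), max(1L, ntile[ax] - 1L))
    hi <- pmin(lo + 1L, ntile[ax])
    w <- if (ntile[ax] == 1L) rep(0, d[ax]) else
      pmin(1, pmax(0, (pos - ct[lo]) / (ct[hi] - ct[lo])))
    list(lo = lo, hi = hi, w = w)
  })
  out <- array(0, d)
  iz <- slice.index(x, 1); iy <- slice.index(x, 2); ix <- slice.index(x, 3)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    tz <- if (cz == 0) wts[[1]]$lo else wts[[1]]$hi
    ty <- if (cy == 0) wts[[2]]$lo else wts[[2]]$hi
    tx <- if (cx == 0) wts[[3]]$lo else wts[[3]]$hi
    wz <- if (cz == 0) 1 - wts[[1]]$w else wts[[1]]$w
    wy <- if (cy == 0) 1 - wts[[2]]$w else wts[[2]]$w
    wx <- if (cx == 0) 1 - wts[[3]]$w else wts[[3]]$w
    w <- wz[iz] * wy[iy] * wx[ix]
    if (all(w == 0)) next
    tid <- tid_of(tz[iz], ty[iy], tx[ix])
    out <- out + w * array(M[cbind(as.vector(tid), as.vector(bin))], d)
  }
  volume@data <- out
  volume
}

#' Percentile-formula global threshold
#'
#' Computes \code{thr = P(pBase) + s * (max - P(pBase))}, the global
#' threshold placed between a base percentile of voxel brightness and the
#' maximum. The cleft pipelines use (p95, s = 0.65) / (p95, s = 0.6) /
#' (p93, s = 0.4) / (p96, s = 0.65) depending on dataset and variant.
#'
#' @param volume A [Volume-class], or a numeric vector of the intensity
#'   domain over which percentiles are taken.
#' @param pBase Base percentile in [0, 100).
#' @param s Fraction in [0, 1] of the distance from P(pBase) to the maximum.
#' @return The scalar threshold.
#' @export
percentileThreshold <- function(volume, pBase = 95, s = 0.65) {
  if (!(pBase >= 0 && pBase < 100 && s >= 0 && s <= 1))
    stop("need 0 <= pBase < 100 and 0 <= s <= 1")
  x <- if (is(volume, "Volume")) as.vector(volume@data) else as.numeric(volume)
  if (!length(x)) stop("empty percentile domain")
  pb <- stats::quantile(x, pBase / 100, names = FALSE, type = 7)
  pb + s * (max(x) - pb)
}
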