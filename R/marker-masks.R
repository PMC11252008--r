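## Marker channels (immunostained or network-predicted) are turned into
## binary guide masks by Otsu-style histogram thresholding on 256 bins over
## [min, max]; ties in between-class variance break toward the lower
## threshold so results are deterministic.

.otsu_hist <- function(x, nbins = 256L) {
  rng <- range(x)
  bin <- pmin(nbins, pmax(1L, as.integer(floor(
    (x - rng[1]) / (rng[2] - rng[1]) * nbins)) + 1L))
  h <- as.numeric(tabulate(bin, nbins))  # numeric: counts overflow int32 in products
  mids <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  list(h = h, mids = mids, rng = rng, nbins = nbins)
}

## scalar Otsu threshold (bin-edge value maximising between-class variance)
.otsu_threshold <- function(x, nbins = 256L) {
  H <- .otsu_hist(x, nbins)
  h <- H$h; m <- H$mids
  n <- sum(h)
  w0 <- cumsum(h)[-H$nbins]
  s0 <- cumsum(h * m)[-H$nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) stop("degenerate input: fewer than 2 occupied bins")
  mu0 <- s0 / w0
  mu1 <- (sum(h * m) - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  t <- which.max(bcv)  # first maximum = lower threshold on ties
  H$rng[1] + t * (H$rng[2] - H$rng[1]) / H$nbins
}

#' Global Otsu binarisation of a marker channel
#'
#' Threshold maximises the between-class variance on a 256-bin histogram;
#' foreground is strictly above the threshold.
#'
#' @param volume A [Volume-class] with at least two distinct values.
#' @param provenance Mask provenance tag: "immuno" or "predicted".
#' @return A [BinaryMask-class]; the threshold is attached as attribute
#'   \code{threshold} of the mask array.
#' @export
otsuMask <- function(volume, provenance = "immuno") {
  stopifnot(is(volume, "Volume"))
  x <- volume@data
  if (length(unique(as.vector(x))) < 2L)
    stop("degenerate input: constant volume")
  thr <- .otsu_threshold(as.vector(x))
  m <- BinaryMask(x > thr, voxelNm = volume@voxelNm, provenance = provenance)
  attr(m@data, "threshold") <- thr
  m
}

#' Upper threshold of three-class Otsu
#'
#' Exhaustively maximises the between-class variance over all ordered
#' threshold pairs of a 256-bin histogram and returns the larger threshold
#' (the refined local cleft pipeline binarises the structural channel at
#' this level).
#'
#' @param volume A [Volume-class] (or numeric vector) with >= 3 distinct
#'   values.
#' @param classes Number of classes; only 3 is supported.
#' @return The scalar upper threshold.
#' @export
multiotsuUpperThreshold <- function(volume, classes = 3) {
  stopifnot(classes == 3)
  x <- if (is(volume, "Volume")) as.vector(volume@data) else as.numeric(volume)
  if (length(unique(x)) < 3L)
    stop("degenerate input: need at least 3 distinct values for 3 classes")
  H <- .otsu_hist(x)
  h <- H$h; m <- H$mids; nb <- H$nbins
  cw <- cumsum(h)
  cs <- cumsum(h * m)
  n <- cw[nb]; stot <- cs[nb]
  best <- -Inf; bt <- c(1L, 2L)
  for (t1 in 1:(nb - 2L)) {
    w0 <- cw[t1]
    if (w0 == 0) next
    mu0sq <- (cs[t1] / w0)^2 * w0
    t2 <- (t1 + 1L):(nb - 1L)
    w1 <- cw[t2] - cw[t1]
    w2 <- n - cw[t2]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    mu1 <- (cs[t2] - cs[t1]) / w1
    mu2 <- (stot - cs[t2]) / w2
    crit <- mu0sq + ifelse(ok, w1 * mu1^2 + w2 * mu2^2, -Inf)
    j <- which.max(crit)
    if (crit[j] > best) { best <- crit[j]; bt <- c(t1, t2[j]) }
  }
  if (!is.finite(best)) stop("degenerate input: histogram supports < 3 classes")
  H$rng[1] + bt[2] * (H$rng[2] - H$rng[1]) / nb
}

#' Binary dilation with a Euclidean ball
#'
#' Guide masks are dilated with a 2-voxel ball (marker-guided variant) or a
#' 1-voxel ball (refined local variant) before gating the structural
#' channel; radius 0 is the identity.
#'
#' @param mask A [BinaryMask-class] or [LabelMap-class] (label maps are
#'   dilated as their foreground support).
#' @param radiusVoxels Ball radius >= 0.
#' @return Object of the same class as \code{mask}; for label maps, a
#'   [BinaryMask-class] of the dilated support.
#' @export
dilateMask <- function(mask, radiusVoxels) {
  stopifnot(radiusVoxels >= 0)
  if (is(mask, "BinaryMask")) {
    mask@data <- .binary_dilate(mask@data, radiusVoxels)
    return(mask)
  }
  if (is(mask, "LabelMap")) {
    return(BinaryMask(.binary_dilate(mask@data > 0, radiusVoxels),
                      voxelNm = mask@voxelNm))
  }
  stop("mask must be a BinaryMask or LabelMap")
}

#' Overlap region of pre- and (non-dilated) post-synaptic masks
#'
#' The classification step keeps cleft candidates overlapping the voxel-wise
#' AND of the pre-synaptic mask with the raw, non-dilated post-synaptic
#' mask (even when segmentation used a dilated guide).
#'
#' @param preMask,postMaskUndilated [BinaryMask-class] objects on the same
#'   grid.
#' @return A [BinaryMask-class] of the intersection.
#' @export
markerIntersection <- function(preMask, postMaskUndilated) {
  stopifnot(is(preMask, "BinaryMask"), is(postMaskUndilated, "BinaryMask"))
  if (!identical(dim(preMask@data), dim(postMaskUndilated@data)))
    stop("grid mismatch between marker masks")
  preMask@data <- preMask@data & postMaskUndilated@data
  preMask
}

#' Marker channel to guide mask (smoothing + background subtraction + Otsu)
#'
#' The canonical marker-mask recipe: difference-of-Gaussians smoothing and
#' background subtraction (sigmas 15 and 1 voxels), then global Otsu
#' binarisation. Raw marker channels are noisy; Otsu on the smoothed,
#' background-subtracted channel yields clean punctum masks.
#'
#' @param volume The marker [Volume-class] (immunostained or predicted).
#' @param sigmaBg,sigmaSig Difference-of-Gaussians sigmas in voxels.
#' @param provenance "immuno" or "predicted".
#' @return A [BinaryMask-class].
#' @export
markerMask <- function(volume, sigmaBg = 15, sigmaSig = 1,
                       provenance = "immuno") {
  otsuMask(dogSubtract(volume, sigmaBg, sigmaSig), provenance = provenance)
}
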