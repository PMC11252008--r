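## Low-level 3D morphology shared by several pipeline stages. The structuring
## element is always the digital Euclidean ball: integer offsets d with
## ||d|| <= r (so r = 1 has 7 voxels, r = 2 has 33).

#' Integer offsets of the Euclidean ball of radius r
#'
#' @param radius Non-negative radius in voxels.
#' @return Integer matrix (K x 3) of (dz, dy, dx) offsets with norm <= radius.
#' @export
#' @examples
#' nrow(ballOffsets(1))  # 7
#' nrow(ballOffsets(2))  # 33
ballOffsets <- function(radius) {
  stopifnot(radius >= 0)
  r <- floor(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  keep <- g$dz^2 + g$dy^2 + g$dx^2 <= radius^2 + 1e-9
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

.ball_filter <- function(arr, radius, op) {
  if (radius <= 0) return(arr)
  d <- dim(arr)
  out <- .cpp_ball_filter(as.numeric(arr), as.integer(d),
                          ballOffsets(radius), as.integer(op))
  array(out, d)
}

.binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  array(.cpp_binary_dilate(as.logical(mask), as.integer(d),
                           ballOffsets(radius)), d)
}

.binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  array(.ball_filter(mask * 1, radius, 0L) > 0.5, dim(mask))
}

.binary_open <- function(mask, radius) {
  .binary_dilate(.binary_erode(mask, radius), radius)
}

#' Label connected foreground components
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26 (voxel face / face+edge / full
#'   neighbourhood).
#' @return Integer 3D array of instance labels (background 0), labelled
#'   1..K in scan order, with attribute \code{n} = K.
#' @keywords internal
.label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  lab <- .cpp_label_components(as.logical(mask), as.integer(d),
                               as.integer(connectivity))
  n <- attr(lab, "n")
  out <- array(as.integer(lab), d)
  attr(out, "n") <- n
  out
}

## Separable Gaussian blur, reflect boundary, kernel truncated at 4 sigma.
## sigma is per axis (z, y, x) in voxels; zeros skip the axis.
.gaussian_blur <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    ## reflect indices (scipy-style 'reflect': abcd -> dcba|abcd|dcba)
    refl <- function(i) {
      i <- ifelse(i < 1L, 1L - i, i)
      i <- ifelse(i > n, 2L * n + 1L - i, i)
      ## a second pass covers kernels wider than the axis
      i <- ifelse(i < 1L, 1L - i, i)
      ifelse(i > n, 2L * n + 1L - i, i)
    }
    K <- matrix(0, n, n)
    for (j in seq_len(2 * r + 1)) {
      rows <- refl(seq_len(n) + (j - r - 1L))
      K[cbind(seq_len(n), rows)] <- K[cbind(seq_len(n), rows)] + k[j]
    }
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = da[1])
    a <- array(a, da)
    arr <- aperm(a, order(perm))
  }
  arr
}

## morphological gradient support: voxels whose 6-neighbourhood spans more
## than one value of an integer map (object boundaries, both sides)
.boundary_voxels <- function(lab) {
  d <- dim(lab)
  mx <- array(.cpp_ball_filter(as.numeric(lab), as.integer(d),
                               ballOffsets(1), 1L), d)
  mn <- array(.cpp_ball_filter(as.numeric(lab), as.integer(d),
                               ballOffsets(1), 0L), d)
  mx != mn
}
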