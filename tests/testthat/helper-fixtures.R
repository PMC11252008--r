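## Shared fixtures and independent oracles. Phantoms are memoised per session
## because geometry + rendering is the slow part of the suite.

.fixture_env <- new.env(parent = emptyenv())

## the acceptance-scale phantom: 3 boutons, 4 clefts each, seed 7
std_phantom <- function(noise = FALSE) {
  key <- paste0("std_", noise)
  if (is.null(.fixture_env[[key]])) {
    cfg <- phantomConfig(pscrPerBouton = c(4L, 4L), seed = 7L)
    .fixture_env[[key]] <- generatePhantom(cfg, noise = noise)
  }
  .fixture_env[[key]]
}

## a small fast phantom for unit tests: 1 bouton, 2 spines, 3 clefts
small_phantom <- function(noise = FALSE, seed = 3L) {
  key <- paste0("small_", noise, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- phantomConfig(gridShape = c(64, 64, 96), nBoutons = 1L,
                         nSpines = 2L, pscrPerBouton = c(3L, 3L),
                         nHotspots = 10L, seed = seed)
    .fixture_env[[key]] <- generatePhantom(cfg, noise = noise)
  }
  .fixture_env[[key]]
}

## truth-derived label maps
truth_boutons <- function(truth) truthLabels(truth, "bouton")
truth_interfaces <- function(truth, dilate = 1)
  truthInterfaces(truth, dilate = dilate)
truth_dendrite_mask <- function(truth) {
  inst <- voxelData(labelMap(truth))
  BinaryMask(inst == 1L | SynaptoSeg:::.role_mask(truth, "spine"),
             voxelNm = voxelNm(labelMap(truth)))
}

## percentile by explicit sort + linear interpolation between order
## statistics (independent of stats::quantile)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

## brute-force grayscale erosion with a Euclidean ball
oracle_erode <- function(arr, radius) {
  d <- dim(arr)
  out <- array(Inf, d)
  off <- expand.grid(dz = -radius:radius, dy = -radius:radius,
                     dx = -radius:radius)
  off <- off[off$dz^2 + off$dy^2 + off$dx^2 <= radius^2 + 1e-9, ]
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    zz <- z + off$dz; yy <- y + off$dy; xx <- x + off$dx
    ok <- zz >= 1 & yy >= 1 & xx >= 1 & zz <= d[1] & yy <= d[2] & xx <= d[3]
    out[z, y, x] <- min(arr[cbind(zz[ok], yy[ok], xx[ok])])
  }
  out
}

## exhaustive Otsu: maximise between-class variance over all 255 bin splits
oracle_otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  bin <- pmin(nbins, pmax(1L, as.integer(floor(
    (x - rng[1]) / (rng[2] - rng[1]) * nbins)) + 1L))
  h <- as.numeric(tabulate(bin, nbins))
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  best <- -Inf; bt <- NA
  for (t in 1:(nbins - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):nbins] * mids[(t + 1):nbins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; bt <- t }
  }
  rng[1] + bt * diff(rng) / nbins
}

## exhaustive 3-class Otsu over all ordered threshold pairs
oracle_multiotsu_upper <- function(x, nbins = 256L) {
  rng <- range(x)
  bin <- pmin(nbins, pmax(1L, as.integer(floor(
    (x - rng[1]) / (rng[2] - rng[1]) * nbins)) + 1L))
  h <- as.numeric(tabulate(bin, nbins))
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  best <- -Inf; bp <- c(NA, NA)
  for (t1 in 1:(nbins - 2)) for (t2 in (t1 + 1):(nbins - 1)) {
    w <- c(sum(h[1:t1]), sum(h[(t1 + 1):t2]), sum(h[(t2 + 1):nbins]))
    if (any(w == 0)) next
    mu <- c(sum(h[1:t1] * mids[1:t1]),
            sum(h[(t1 + 1):t2] * mids[(t1 + 1):t2]),
            sum(h[(t2 + 1):nbins] * mids[(t2 + 1):nbins])) / w
    crit <- sum(w * mu^2)
    if (crit > best + 1e-12) { best <- crit; bp <- c(t1, t2) }
  }
  rng[1] + bp[2] * diff(rng) / nbins
}

## independent all-pairs object matcher + P/R/F1 (set arithmetic on voxel
## index vectors; no reuse of the package's tabulation path)
oracle_match_prf <- function(ref, test, thresholds, criterion = "iou") {
  rids <- setdiff(unique(as.vector(ref)), 0L)
  tids <- setdiff(unique(as.vector(test)), 0L)
  pairs <- data.frame()
  for (r in rids) {
    rv <- which(ref == r)
    bestScore <- -1; bestT <- NA; row <- NULL
    for (t in tids) {
      tv <- which(test == t)
      ov <- length(intersect(rv, tv))
      if (ov == 0) next
      iou <- ov / length(union(rv, tv))
      dice <- 2 * ov / (length(rv) + length(tv))
      score <- if (criterion == "iou") iou else dice
      if (score > bestScore + 1e-12 ||
          (abs(score - bestScore) <= 1e-12 && !is.na(bestT) && t < bestT)) {
        bestScore <- score; bestT <- t
        row <- data.frame(ref_id = r, test_id = t, overlap_voxels = ov,
                          iou = iou, dice = dice)
      }
    }
    if (!is.null(row)) pairs <- rbind(pairs, row)
  }
  curve <- do.call(rbind, lapply(thresholds, function(th) {
    sc <- if (nrow(pairs)) pairs[[criterion]] else numeric()
    tp <- sum(sc >= th)
    fp <- length(tids) - tp
    fn <- length(rids) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(threshold = th, n_tp = tp, n_fp = fp, n_fn = fn,
               precision = p, recall = r,
               f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
  }))
  list(pairs = pairs, curve = curve)
}

## random small 3D label map with <= maxSegments blobs
random_label_map <- function(dim3 = c(12, 12, 12), maxSegments = 10) {
  lab <- array(0L, dim3)
  n <- sample.int(maxSegments, 1)
  for (i in seq_len(n)) {
    c0 <- sapply(dim3, function(d) sample.int(d, 1))
    r <- runif(1, 1, 3)
    g <- expand.grid(z = 1:dim3[1], y = 1:dim3[2], x = 1:dim3[3])
    sel <- (g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2 <= r^2
    lab[as.matrix(g[sel, ])] <- i
  }
  lab
}

## digital ball mask
digital_ball <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2, c(n, n, n))
}

## hand-built closed unit cube mesh (12 triangles)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(z = 0:1, y = 0:1, x = 0:1))
  f <- matrix(c(1,3,4, 1,4,2, 5,6,8, 5,8,7, 1,2,6, 1,6,5,
                3,7,8, 3,8,4, 1,5,7, 1,7,3, 2,4,8, 2,8,6),
              ncol = 3, byrow = TRUE)
  TriMesh(v, f)
}


## dilate every label's support by a ball (first label wins on collisions)
dilate_labels <- function(labels, radius) {
  lab <- voxelData(labels)
  out <- array(0L, dim(lab))
  for (id in sort(setdiff(unique(as.vector(lab)), 0L))) {
    m <- SynaptoSeg:::.binary_dilate(lab == id, radius)
    out[m & out == 0L] <- id
  }
  LabelMap(out, voxelNm = voxelNm(labels))
}
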