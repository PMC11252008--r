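## Seeded synthetic phantom: a dendrite with complex spines, large boutons
## engulfing the spine heads across a 2-voxel extracellular gap, disk-like
## high-intensity cleft patches on those gaps, marker puncta flanking each
## patch, anisotropic Gaussian PSF blur and Poisson + Gaussian read noise.
## Every stage of the analysis is testable against the returned ground truth.

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct a phantom configuration
#'
#' Defaults state the emulated world once: 50-nm isotropic voxels, a
#' 0.35-um-radius dendrite carrying 5 complex spines, 3 boutons of
#' 0.6 +/- 0.05 um semi-axes engulfing spine heads across a 2-voxel gap,
#' per-bouton cleft counts drawn from a desk-scaled 3-8 range, marker
#' puncta displaced 100 nm to either side of each cleft, a ~55-nm-sigma
#' PSF, and photon-counting noise at moderate counts. Spine heads grow
#' beyond \code{spineHeadRadiusUm} when the drawn cleft count needs more
#' surface to host separable patches.
#'
#' @param gridShape Integer (z, y, x) voxel counts, each >= 32.
#' @param voxelNm Spacing in nm.
#' @param nBoutons,nSpines Object counts (nBoutons <= nSpines when both
#'   positive; each bouton engulfs one spine head).
#' @param boutonRadiusUm Mean and sd of bouton semi-axes (um).
#' @param dendriteRadiusUm,spineHeadRadiusUm Radii (um).
#' @param pscrPerBouton Integer range (lo, hi) within [1, 50]. The default
#'   3-8 is the observed per-bouton range scaled to the desk-sized default
#'   grid: spine heads grow to host the drawn count at a separation the PSF
#'   can resolve, and the default grid cannot hold heads for more than ~8
#'   patches. Supply a larger \code{gridShape} for the full observed 3-28.
#' @param nHotspots Number of bright extracellular distractor features.
#'   Dense tissue is full of protein-rich spots that are not synapses; they
#'   fill the top intensity percentiles, which is why segmentation needs a
#'   marker guide. Hotspots are placed away from the cleft neighbourhoods.
#' @param hotspotRadiusVoxels,hotspotAmp Ranges (lo, hi) for hotspot radius
#'   (voxels) and amplitude (relative to the membrane base).
#' @param markerOffsetNm Pre/post punctum displacement from the cleft
#'   centroid along the interface normal (nm).
#' @param psfSigmaNm Named list (structural, pre, post) of per-axis PSF
#'   sigmas in nm.
#' @param contrastRatio Cleft amplitude over membrane base amplitude
#'   (>= 2 assumed; no measured value exists).
#' @param photonScale Expected photons at unit intensity (> 0).
#' @param readNoiseSd Additive Gaussian sd in photon units.
#' @param background Baseline intensity fraction added before noise.
#' @param seed RNG seed; fixes geometry and noise.
#' @return A [PhantomConfig-class].
#' @export
phantomConfig <- function(gridShape = c(112, 96, 144),
                          voxelNm = c(50, 50, 50),
                          nBoutons = 3, nSpines = 5,
                          boutonRadiusUm = c(0.60, 0.05),
                          dendriteRadiusUm = 0.35,
                          spineHeadRadiusUm = 0.30,
                          pscrPerBouton = c(3L, 8L),
                          nHotspots = 60L,
                          hotspotRadiusVoxels = c(4, 6),
                          hotspotAmp = c(1.5, 2.5),
                          markerOffsetNm = 100,
                          psfSigmaNm = list(structural = c(55, 55, 55),
                                            pre = c(55, 55, 55),
                                            post = c(55, 55, 55)),
                          contrastRatio = 3,
                          photonScale = 50, readNoiseSd = 1,
                          background = 0.05, seed = 1L) {
  if (length(pscrPerBouton) == 1L) pscrPerBouton <- rep(pscrPerBouton, 2L)
  new("PhantomConfig",
      gridShape = as.integer(gridShape), voxelNm = as.numeric(voxelNm),
      nBoutons = as.integer(nBoutons), nSpines = as.integer(nSpines),
      boutonRadiusUm = as.numeric(boutonRadiusUm),
      dendriteRadiusUm = as.numeric(dendriteRadiusUm),
      spineHeadRadiusUm = as.numeric(spineHeadRadiusUm),
      pscrPerBouton = as.integer(pscrPerBouton),
      nHotspots = as.integer(nHotspots),
      hotspotRadiusVoxels = as.numeric(hotspotRadiusVoxels),
      hotspotAmp = as.numeric(hotspotAmp),
      markerOffsetNm = as.numeric(markerOffsetNm),
      psfSigmaNm = psfSigmaNm, contrastRatio = as.numeric(contrastRatio),
      photonScale = as.numeric(photonScale),
      readNoiseSd = as.numeric(readNoiseSd),
      background = as.numeric(background), seed = as.integer(seed))
}

## coordinate grids (1-based voxel centres) for a bounding box
.box_grid <- function(lo, hi) {
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  list(z = zz, y = yy, x = xx,
       Z = array(rep(zz, times = length(yy) * length(xx)),
                 c(length(zz), length(yy), length(xx))),
       Y = array(rep(rep(yy, each = length(zz)), times = length(xx)),
                 c(length(zz), length(yy), length(xx))),
       X = array(rep(xx, each = length(zz) * length(yy)),
                 c(length(zz), length(yy), length(xx))))
}

.clamp_box <- function(center, r, d) {
  lo <- pmax(1L, floor(center - r)); hi <- pmin(d, ceiling(center + r))
  if (any(lo > hi)) NULL else list(lo = as.integer(lo), hi = as.integer(hi))
}

## stamp TRUE into `target` where the predicate holds inside the box
.stamp <- function(d, center, r, predicate) {
  out <- array(FALSE, d)
  bx <- .clamp_box(center, r, d)
  if (is.null(bx)) return(out)
  g <- .box_grid(bx$lo, bx$hi)
  out[g$z, g$y, g$x] <- predicate(g$Z, g$Y, g$X)
  out
}

.ball_mask <- function(d, center, r) {
  .stamp(d, center, r + 1, function(Z, Y, X)
    (Z - center[1])^2 + (Y - center[2])^2 + (X - center[3])^2 <= r^2)
}

.ellipsoid_mask <- function(d, center, semi) {
  .stamp(d, center, max(semi) + 1, function(Z, Y, X)
    ((Z - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((X - center[3]) / semi[3])^2 <= 1)
}

## finite cylinder: axis point p0, unit direction dir, radius rn, axial range
.cylinder_mask <- function(d, p0, dir, rn, t0, t1) {
  r <- abs(t1) + rn + 2
  .stamp(d, p0 + dir * (t0 + t1) / 2, (t1 - t0) / 2 + rn + 1,
    function(Z, Y, X) {
      dz <- Z - p0[1]; dy <- Y - p0[2]; dx <- X - p0[3]
      t <- dz * dir[1] + dy * dir[2] + dx * dir[3]
      r2 <- (dz - t * dir[1])^2 + (dy - t * dir[2])^2 + (dx - t * dir[3])^2
      t >= t0 & t <= t1 & r2 <= rn^2
    })
}

## smallest head radius (voxels) whose patch-hosting cap can take k patches
## at the required angular separation (area heuristic, packing factor 0.7)
.head_radius_for <- function(k, rhBase, coneDeg = 75, chordMin = 11) {
  cone <- 1 - cos(coneDeg * pi / 180)
  for (rh in seq(from = max(3, rhBase), to = 40)) {
    R <- rh + 1
    amin <- 2 * asin(min(0.95, chordMin / (2 * R)))
    cap <- 1 - cos(amin / 2)
    if (0.7 * cone / cap >= k) return(rh)
  }
  stop("geometry infeasible: cannot host ", k, " cleft patches per bouton")
}

#' Build the phantom geometry and ground truth
#'
#' Places one dendrite cylinder, \code{nSpines} spine heads on necks, and
#' \code{nBoutons} ellipsoidal boutons each engulfing one spine head across
#' a 2-voxel extracellular gap; disk-like cleft interface patches are laid
#' on the gap shell with a minimum separation that keeps them resolvable at
#' the stated PSF. Placement uses rejection sampling capped at 1000
#' attempts per object; infeasible configurations raise an error naming the
#' failing object. Deterministic given \code{config@seed}.
#'
#' @param config A [phantomConfig()].
#' @return A [PhantomTruth-class].
#' @export
buildGeometry <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  if (config@nBoutons > 0 && config@nBoutons > config@nSpines)
    stop("geometry infeasible: need nSpines >= nBoutons (one head per bouton)")
  d <- config@gridShape
  vox <- mean(config@voxelNm)
  um2vox <- 1000 / vox
  rd <- config@dendriteRadiusUm * um2vox
  rhBase <- config@spineHeadRadiusUm * um2vox
  rn <- 2           # neck radius (voxels)
  neckLen <- 6      # neck length (voxels)
  gap <- 1.5        # extracellular gap (voxels; stated range 1-2)
  rpatch <- 3       # cleft patch in-plane radius (voxels)
  .with_seed(config@seed, {
    inst <- array(0L, d)
    ## one-voxel safety rim: objects must not touch the volume border
    outOfBounds <- array(TRUE, d)
    outOfBounds[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
    roles <- character(); vols <- numeric(); ids <- integer()
    ## --- dendrite (label 1) along x ---
    z0 <- round(d[1] * 0.22); y0 <- round(d[2] / 2)
    dend <- .stamp(d, c(z0, y0, (d[3] + 1) / 2), max(d),
      function(Z, Y, X) (Z - z0)^2 + (Y - y0)^2 <= rd^2)
    inst[dend] <- 1L
    ids <- 1L; roles <- "dendrite"
    vols <- pi * config@dendriteRadiusUm^2 * (d[3] * config@voxelNm[3] / 1000)
    ## --- per-bouton cleft counts, then spine head radii ---
    kvals <- config@pscrPerBouton[1]:config@pscrPerBouton[2]
    kdraw <- if (config@nBoutons > 0)
      kvals[sample.int(length(kvals), config@nBoutons, replace = TRUE)]
      else integer()
    rhs <- rep(rhBase, config@nSpines)
    ## boutons sit on spines spread along the dendrite, not adjacent ones
    boutonSpine <- if (config@nBoutons > 0)
      round(seq(1, config@nSpines, length.out = config@nBoutons)) else integer()
    if (config@nBoutons > 0)
      rhs[boutonSpine] <- vapply(kdraw, .head_radius_for, 0, rhBase = rhBase)
    ## --- spines (labels 2 .. 1 + nSpines) ---
    spineDir <- vector("list", config@nSpines)
    headCenter <- vector("list", config@nSpines)
    if (config@nSpines > 0) {
      ## end spines must leave room for an engulfing bouton plus jitter
      margin <- max(rhs) + gap + 9
      if (2 * margin >= d[3])
        stop("placement error: grid too small along x for the spine row")
      xs0 <- seq(margin, d[3] - margin, length.out = config@nSpines)
      phis0 <- rep(c(-25, 10, 25, -10, 0), length.out = config@nSpines)
      for (i in seq_len(config@nSpines)) {
        placed <- FALSE
        ## 2-voxel clearance map from everything but the dendrite
        nearOthers <- .binary_dilate(inst > 1L, 2)
        for (attempt in seq_len(1000)) {
          xi <- xs0[i] + stats::runif(1, -3, 3)
          phi <- (phis0[i] + stats::runif(1, -5, 5)) * pi / 180
          dir <- c(cos(phi), sin(phi), 0)
          p0 <- c(z0, y0, xi)
          h <- p0 + dir * (rd + neckLen + rhs[i] - 1)
          neck <- .cylinder_mask(d, p0, dir, rn, rd - 1, rd + neckLen)
          head <- .ball_mask(d, h, rhs[i])
          cand <- (neck | head) & !dend
          if (any(cand & outOfBounds)) next
          if (any(cand & nearOthers)) next
          inst[cand] <- 1L + i
          spineDir[[i]] <- dir; headCenter[[i]] <- h
          placed <- TRUE
          break
        }
        if (!placed) stop("placement error: spine ", i)
        ids <- c(ids, 1L + i); roles <- c(roles, "spine")
        vols <- c(vols,
          ((4 / 3) * pi * rhs[i]^3 + pi * rn^2 * (neckLen + 1)) *
            prod(config@voxelNm) / 1e9)
      }
    }
    ## --- boutons (labels 2 + nSpines .. ) ---
    boutonLab <- integer(config@nBoutons)
    for (j in seq_len(config@nBoutons)) {
      lab <- 1L + config@nSpines + j
      sj <- boutonSpine[j]
      h <- headCenter[[sj]]; dir <- spineDir[[sj]]
      placed <- FALSE
      gapCarve <- .binary_dilate(inst > 0L, gap)
      for (attempt in seq_len(1000)) {
        semi <- pmax(rhs[sj] + gap + 3,
                     stats::rnorm(3, config@boutonRadiusUm[1] * um2vox,
                                  config@boutonRadiusUm[2] * um2vox))
        b <- h + dir * round(0.35 * max(semi))
        ell <- .ellipsoid_mask(d, b, semi)
        cand <- ell & !gapCarve
        if (!any(cand)) next
        ## keep the largest connected piece (carving can shed slivers)
        cl <- .label_components(cand, 26)
        ncl <- attr(cl, "n")
        if (ncl > 1L) {
          sz <- tabulate(cl[cl > 0], ncl)
          cand <- cl == which.max(sz)
        }
        if (sum(cand) < 500) next
        if (any(cand & outOfBounds)) next
        inst[cand] <- lab
        ## inner lining: the bouton hugs the head at a uniform 2-voxel gap
        ## across the contact cap (real boutons appose the spine tightly at
        ## contact sites; the raw carve leaves a lattice-dependent 2-3 voxel
        ## standoff)
        obst <- .binary_dilate(inst > 0L & inst != lab, gap)
        lining <- .stamp(d, h, rhs[sj] + gap + 2.5, function(Z, Y, X) {
          dz <- Z - h[1]; dy <- Y - h[2]; dx <- X - h[3]
          rr <- sqrt(dz^2 + dy^2 + dx^2)
          ang <- (dz * dir[1] + dy * dir[2] + dx * dir[3]) / pmax(rr, 1e-9)
          rr > rhs[sj] + gap & rr <= rhs[sj] + gap + 1.45 &
            ang >= cos(80 * pi / 180)
        })
        lining <- lining & inst == 0L & !obst & !outOfBounds
        inst[lining] <- lab
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: bouton ", j)
      boutonLab[j] <- lab
      ids <- c(ids, lab); roles <- c(roles, "bouton")
      vols <- c(vols, sum(inst == lab) * prod(config@voxelNm) / 1e9)
    }
    ## --- cleft interface patches on the gap shells ---
    interfaces <- list(); edges <- list()
    pid <- 0L
    for (j in seq_len(config@nBoutons)) {
      sj <- boutonSpine[j]
      lab <- boutonLab[j]; slab <- 1L + sj
      h <- headCenter[[sj]]; dir <- spineDir[[sj]]
      rh <- rhs[sj]; R <- rh + 1
      k <- kdraw[j]
      amin <- 2 * asin(min(0.95, 11 / (2 * R)))
      cone <- 75 * pi / 180
      ## neighbourhood maps for the adjacency test
      nearB <- .binary_dilate(inst == lab, 1.8)   # 26-neighbourhood reach
      nearS <- .binary_dilate(inst == slab, 1.8)
      bg <- inst == 0L
      e1 <- c(-dir[2], dir[1], 0)
      e2 <- c(0, 0, 1)
      ## candidate directions: Fibonacci spiral over the contact cap
      ## (near-optimal spread), jittered; deterministic on the last attempt
      spiral <- function(jit) {
        golden <- pi * (3 - sqrt(5))
        lapply(seq_len(k), function(i) {
          ct <- 1 - (i - 0.5) / k * (1 - cos(cone))
          th <- acos(ct) + jit * stats::runif(1, -1, 1)
          az <- (i - 1) * golden + jit * stats::runif(1, -1, 1)
          cos(th) * dir + sin(th) * (cos(az) * e1 + sin(az) * e2)
        })
      }
      carve <- function(u) {
        patch <- .stamp(d, h + R * u, gap + rpatch + 2,
          function(Z, Y, X) {
            dz <- Z - h[1]; dy <- Y - h[2]; dx <- X - h[3]
            rr <- sqrt(dz^2 + dy^2 + dx^2)
            ang <- (dz * u[1] + dy * u[2] + dx * u[3]) / pmax(rr, 1e-9)
            rr > rh & rr <= rh + gap + 0.5 & ang >= cos(atan(rpatch / R))
          })
        patch & bg & nearB & nearS
      }
      done <- FALSE
      for (attempt in seq_len(100)) {
        us <- spiral(if (attempt < 100) 0.05 else 0)
        sepOk <- TRUE
        if (k > 1) for (a in seq_len(k - 1)) for (b2 in (a + 1):k)
          if (sum(us[[a]] * us[[b2]]) > cos(0.9 * amin)) sepOk <- FALSE
        if (!sepOk) next
        patches <- lapply(us, carve)
        if (any(vapply(patches, sum, 0) < 18)) next
        for (p in seq_len(k)) {
          pid <- pid + 1L
          vxs <- which(patches[[p]], arr.ind = TRUE)
          dimnames(vxs) <- NULL
          interfaces[[pid]] <- list(id = pid, bouton_id = lab,
            spine_id = slab, voxels = vxs, normal = -us[[p]],
            center = h + R * us[[p]])
          edges[[pid]] <- data.frame(bouton_id = lab, spine_id = slab,
                                     pscr_id = pid)
        }
        done <- TRUE
        break
      }
      if (!done) stop("placement error: cleft patches of bouton ", j)
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
      data.frame(bouton_id = integer(), spine_id = integer(),
                 pscr_id = integer())
    ## --- bright extracellular distractor hotspots, away from the cleft
    ## neighbourhoods (so marker guidance, not placement, excludes them) ---
    hotspots <- list()
    if (config@nHotspots > 0L) {
      nearObj <- .binary_dilate(inst > 0L, 3)
      cleftCenters <- do.call(rbind, lapply(interfaces, function(i) i$center))
      for (hId in seq_len(config@nHotspots)) {
        ok <- FALSE
        for (attempt in seq_len(1000)) {
          r <- stats::runif(1, config@hotspotRadiusVoxels[1],
                            config@hotspotRadiusVoxels[2])
          cc <- c(stats::runif(1, r + 2, d[1] - r - 1),
                  stats::runif(1, r + 2, d[2] - r - 1),
                  stats::runif(1, r + 2, d[3] - r - 1))
          if (!is.null(cleftCenters) &&
              any(sqrt(colSums((t(cleftCenters) - cc)^2)) < r + 14)) next
          ip <- round(cc)
          if (nearObj[ip[1], ip[2], ip[3]]) next
          ball <- .ball_mask(d, cc, r)
          if (any(ball & nearObj)) next
          hotspots[[length(hotspots) + 1L]] <- list(center = cc, radius = r,
            amp = stats::runif(1, config@hotspotAmp[1], config@hotspotAmp[2]))
          ok <- TRUE
          break
        }
        if (!ok) stop("placement error: hotspot ", hId)
      }
    }
    objectTable <- data.frame(id = ids, role = roles, volume_um3 = vols)
    new("PhantomTruth",
        instanceMap = LabelMap(inst, voxelNm = config@voxelNm,
          table = data.frame(id = ids, role = roles)),
        interfaces = interfaces, hotspots = hotspots, edges = edges,
        objectTable = objectTable, config = config)
  })
}

#' Render noise-free phantom channels
#'
#' The structural channel carries the base amplitude on all inter-object
#' boundary voxels (morphological gradient of the instance map) and
#' \code{contrastRatio} times that on cleft interface voxels. Marker puncta
#' (Gaussian blobs, sigma 1.5 voxels) are centred \code{markerOffsetNm}
#' inside the bouton (pre) and inside the spine (post) from each interface
#' centroid along the stored normal; offsets that leave the parent object
#' are clamped to its interior with a warning. Each channel is blurred with
#' its PSF. A line profile along any interface normal shows the ordering
#' pre peak, cleft peak, post peak.
#'
#' @param truth A [PhantomTruth-class].
#' @param config The generating [PhantomConfig-class] (defaults to the one
#'   stored in \code{truth}).
#' @return A noise-free [ChannelSet-class].
#' @export
renderChannels <- function(truth, config = truth@config) {
  stopifnot(is(truth, "PhantomTruth"))
  inst <- truth@instanceMap@data
  d <- dim(inst)
  if (!identical(as.integer(d), config@gridShape))
    stop("truth grid does not match the config")
  vox <- mean(config@voxelNm)
  structural <- array(0, d)
  structural[.boundary_voxels(inst)] <- 1
  for (hs in truth@hotspots) {
    ball <- .ball_mask(d, hs$center, hs$radius)
    structural[ball] <- pmax(structural[ball], hs$amp)
  }
  for (itf in truth@interfaces) structural[itf$voxels] <- config@contrastRatio
  pre <- array(0, d); post <- array(0, d)
  sigmaP <- 1.5  # punctum size (voxels)
  offv <- config@markerOffsetNm / vox
  warned <- FALSE
  addPunctum <- function(chan, center) {
    bx <- .clamp_box(center, ceiling(3 * sigmaP), d)
    if (is.null(bx)) return(chan)
    g <- .box_grid(bx$lo, bx$hi)
    blob <- exp(-((g$Z - center[1])^2 + (g$Y - center[2])^2 +
                  (g$X - center[3])^2) / (2 * sigmaP^2))
    chan[g$z, g$y, g$x] <- chan[g$z, g$y, g$x] + blob
    chan
  }
  clampInside <- function(center, away, label) {
    ## pull the punctum back toward the interface until it sits inside its
    ## parent object
    for (f in c(1, 0.75, 0.5, 0.25)) {
      p <- away(f)
      ip <- pmin(pmax(round(p), 1), d)
      if (inst[ip[1], ip[2], ip[3]] == label) {
        if (f < 1 && !warned) {
          warning("marker offset exceeds object thickness; clamped inside")
          warned <<- TRUE
        }
        return(p)
      }
    }
    away(0.25)
  }
  for (itf in truth@interfaces) {
    cen <- colMeans(itf$voxels)
    nrm <- itf$normal  # bouton -> spine
    preC <- clampInside(cen, function(f) cen - f * offv * nrm, itf$bouton_id)
    postC <- clampInside(cen, function(f) cen + f * offv * nrm, itf$spine_id)
    pre <- addPunctum(pre, preC)
    post <- addPunctum(post, postC)
  }
  blur <- function(chan, key) {
    s <- config@psfSigmaNm[[key]] / config@voxelNm
    if (all(s <= 0)) chan else .gaussian_blur(chan, s)
  }
  new("ChannelSet",
    structural = Volume(blur(structural, "structural"),
                        voxelNm = config@voxelNm, name = "structural"),
    preMarker = Volume(blur(pre, "pre"), voxelNm = config@voxelNm,
                       name = "pre_marker"),
    postMarker = Volume(blur(post, "post"), voxelNm = config@voxelNm,
                        name = "post_marker"))
}

#' Add photon-counting noise to rendered channels
#'
#' Each voxel becomes Poisson(photonScale * (intensity + background)) plus
#' Normal(0, readNoiseSd), clipped at zero; deterministic given the config
#' seed.
#'
#' @param channels A noise-free [ChannelSet-class].
#' @param config A [PhantomConfig-class].
#' @return A noisy [ChannelSet-class] in photon units.
#' @export
addNoise <- function(channels, config) {
  stopifnot(is(channels, "ChannelSet"), is(config, "PhantomConfig"))
  .with_seed(config@seed + 77003L, {
    noisify <- function(v) {
      lam <- config@photonScale * (v@data + config@background)
      n <- length(lam)
      x <- stats::rpois(n, lam) + stats::rnorm(n, 0, config@readNoiseSd)
      v@data <- array(pmax(0, x), dim(v@data))
      v
    }
    new("ChannelSet", structural = noisify(channels@structural),
        preMarker = noisify(channels@preMarker),
        postMarker = noisify(channels@postMarker))
  })
}

#' Generate a complete phantom
#'
#' Composition of [buildGeometry()], [renderChannels()] and (optionally)
#' [addNoise()]; optionally writes a fixture bundle to disk (HDF5 channels
#' and instance map plus a JSON ground-truth file).
#'
#' @param config A [phantomConfig()].
#' @param noise Apply photon noise (default TRUE).
#' @param dir Optional output directory for the fixture bundle.
#' @return list(channels = [ChannelSet-class], truth =
#'   [PhantomTruth-class]).
#' @export
generatePhantom <- function(config = phantomConfig(), noise = TRUE,
                            dir = NULL) {
  truth <- buildGeometry(config)
  channels <- renderChannels(truth, config)
  if (noise) channels <- addNoise(channels, config)
  if (!is.null(dir)) writePhantomBundle(channels, truth, dir)
  list(channels = channels, truth = truth)
}

## run-length encode voxel index triples (1-based rows; runs along x)
.rle_voxels <- function(vxs) {
  o <- order(vxs[, 1], vxs[, 2], vxs[, 3])
  v <- vxs[o, , drop = FALSE]
  runs <- list()
  i <- 1L
  while (i <= nrow(v)) {
    j <- i
    while (j < nrow(v) && v[j + 1L, 1] == v[i, 1] && v[j + 1L, 2] == v[i, 2] &&
           v[j + 1L, 3] == v[j, 3] + 1L) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(v[i, 1], v[i, 2], v[i, 3], j - i + 1L)
    i <- j + 1L
  }
  runs
}

.unrle_voxels <- function(runs) {
  if (is.matrix(runs)) runs <- split(runs, seq_len(nrow(runs)))
  do.call(rbind, lapply(runs, function(r) {
    r <- as.integer(unlist(r))
    cbind(r[1], r[2], r[3] + seq_len(r[4]) - 1L)
  }))
}

#' Write a phantom fixture bundle
#'
#' One HDF5 file (datasets /channels/structural, /channels/pre,
#' /channels/post, /labels/instances, each with a voxel_nm attribute) plus
#' truth.json holding the connectivity edges, run-length-encoded interface
#' voxel lists, normals, the object table and a config echo.
#'
#' @param channels A [ChannelSet-class].
#' @param truth A [PhantomTruth-class].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writePhantomBundle <- function(channels, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h5 <- file.path(dir, "phantom.h5")
  if (file.exists(h5)) unlink(h5)
  writeVolume(channels@structural, h5, dataset = "channels/structural")
  writeVolume(channels@preMarker, h5, dataset = "channels/pre")
  writeVolume(channels@postMarker, h5, dataset = "channels/post")
  writeVolume(truth@instanceMap, h5, dataset = "labels/instances")
  cfg <- truth@config
  truthJson <- list(
    edges = truth@edges,
    interfaces = lapply(truth@interfaces, function(itf) list(
      id = itf$id, bouton_id = itf$bouton_id, spine_id = itf$spine_id,
      normal = itf$normal, center = itf$center,
      voxels_rle = .rle_voxels(itf$voxels))),
    object_table = truth@objectTable,
    config = list(grid_shape = cfg@gridShape, voxel_nm = cfg@voxelNm,
      n_boutons = cfg@nBoutons, n_spines = cfg@nSpines,
      bouton_radius_um = cfg@boutonRadiusUm,
      dendrite_radius_um = cfg@dendriteRadiusUm,
      spine_head_radius_um = cfg@spineHeadRadiusUm,
      pscr_per_bouton = cfg@pscrPerBouton,
      marker_offset_nm = cfg@markerOffsetNm,
      psf_sigma_nm = cfg@psfSigmaNm, contrast_ratio = cfg@contrastRatio,
      photon_scale = cfg@photonScale, read_noise_sd = cfg@readNoiseSd,
      background = cfg@background, seed = cfg@seed))
  jsonlite::write_json(truthJson, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}

#' Read back a phantom fixture bundle
#'
#' @param dir Directory written by [writePhantomBundle()].
#' @return list(channels = [ChannelSet-class], instanceMap =
#'   [LabelMap-class], truth = parsed truth list with decoded interface
#'   voxel matrices).
#' @export
readPhantomBundle <- function(dir) {
  h5 <- file.path(dir, "phantom.h5")
  channels <- new("ChannelSet",
    structural = readVolume(h5, dataset = "channels/structural",
                            name = "structural"),
    preMarker = readVolume(h5, dataset = "channels/pre", name = "pre_marker"),
    postMarker = readVolume(h5, dataset = "channels/post",
                            name = "post_marker"))
  inst <- readLabelMap(h5, dataset = "labels/instances")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (length(truth$interfaces))
    truth$interfaces$voxels <- lapply(truth$interfaces$voxels_rle,
                                      .unrle_voxels)
  list(channels = channels, instanceMap = inst, truth = truth)
}

#' Ground-truth label maps by role
#'
#' Extracts the instances of one role (dendrite, spine or bouton) from a
#' phantom's instance map, e.g. the bouton label map that stands in for the
#' study's manual bouton segmentations.
#'
#' @param truth A [PhantomTruth-class].
#' @param role "dendrite", "spine" or "bouton".
#' @return A [LabelMap-class] with only that role's instances.
#' @export
truthLabels <- function(truth, role = c("bouton", "spine", "dendrite")) {
  stopifnot(is(truth, "PhantomTruth"))
  .role_labels(truth, match.arg(role))
}

#' Ground-truth cleft interfaces as a label map
#'
#' One instance per cleft patch, optionally dilated to a target thickness
#' for object-level matching against recovered segments.
#'
#' @param truth A [PhantomTruth-class].
#' @param dilate Ball radius for thickening (0 = the raw interface voxels).
#' @return A [LabelMap-class] whose labels are the truth cleft ids.
#' @export
truthInterfaces <- function(truth, dilate = 0) {
  stopifnot(is(truth, "PhantomTruth"))
  .interface_labels(truth, dilate = dilate)
}
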