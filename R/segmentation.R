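## Instance segmentation of putative synaptic cleft regions (pSCRs) from the
## structural channel, classification against marker masks, and assignment to
## boutons. Two variants mirror the published pipelines: a marker-guided
## global percentile threshold, and a refined local multi-Otsu procedure.

#' Segmentation parameter set
#'
#' Collects every tunable of the cleft segmentation: the contrast-stretch
#' window, the percentile-formula parameters, the minimum object size (strict:
#' objects *smaller* than \code{minSizeVoxels} are discarded, so objects of
#' exactly that size survive), the guide-mask dilation radius and the labeling
#' connectivity.
#'
#' @param stretchLow,stretchHigh Contrast-stretch percentiles.
#' @param pBase,s Percentile-formula threshold parameters (global variant).
#' @param minSizeVoxels Minimum retained component size (default 8 for the
#'   global variant; the local variant uses 6).
#' @param guideDilationVoxels Guide-mask dilation ball radius (default 2;
#'   the local variant uses 1).
#' @param connectivity Component connectivity: 6, 18 or 26.
#' @param thresholdDomain "full" computes the p-base/max percentiles over the
#'   whole stretched volume; "masked" restricts them to nonzero voxels of the
#'   guide-gated product.
#' @return A named list of class \code{ThresholdParams}.
#' @export
thresholdParams <- function(stretchLow = 1, stretchHigh = 99,
                            pBase = 95, s = 0.65, minSizeVoxels = 8L,
                            guideDilationVoxels = 2L, connectivity = 26L,
                            thresholdDomain = c("full", "masked")) {
  stopifnot(minSizeVoxels >= 1, s >= 0, s <= 1,
            connectivity %in% c(6, 18, 26))
  structure(list(stretchLow = stretchLow, stretchHigh = stretchHigh,
    pBase = pBase, s = s, minSizeVoxels = as.integer(minSizeVoxels),
    guideDilationVoxels = as.integer(guideDilationVoxels),
    connectivity = as.integer(connectivity),
    thresholdDomain = match.arg(thresholdDomain)),
    class = "ThresholdParams")
}

#' Label connected components and drop small objects
#'
#' Components are labelled with the stated connectivity; components with
#' fewer than \code{minSize} voxels are removed (strictly smaller) and the
#' survivors renumbered 1..K in scan order.
#'
#' @param mask A [BinaryMask-class] (or logical array).
#' @param connectivity 6, 18 or 26.
#' @param minSize Minimum voxel count.
#' @param voxelNm Spacing for plain-array input.
#' @return A [LabelMap-class].
#' @export
labelFilteredComponents <- function(mask, connectivity = 26, minSize = 1,
                                    voxelNm = c(50, 50, 50)) {
  if (is(mask, "BinaryMask")) {
    voxelNm <- mask@voxelNm
    mask <- mask@data
  }
  lab <- .label_components(mask, connectivity)
  n <- attr(lab, "n")
  if (n > 0 && minSize > 1) {
    sizes <- tabulate(lab[lab > 0], n)
    keep <- which(sizes >= minSize)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    out <- array(0L, dim(lab))
    pos <- lab > 0
    out[pos] <- remap[lab[pos]]
    lab <- out
  }
  attr(lab, "n") <- NULL
  LabelMap(lab, voxelNm = voxelNm)
}

#' Marker-guided global-threshold cleft segmentation
#'
#' The structural channel is contrast stretched, gated by the dilated guide
#' mask (post-synaptic marker or predicted pre-synaptic marker), binarised at
#' the percentile-formula threshold \code{thr = pBase + s (p100 - pBase)} and
#' instance labelled; objects smaller than \code{minSizeVoxels} are
#' discarded.
#'
#' @param structural The structural [Volume-class] (already denoised
#'   upstream).
#' @param guideMask A [BinaryMask-class] on the same grid.
#' @param params A [thresholdParams()] list.
#' @return A [PSCRSet-class] of candidates (unclassified, unassigned). The
#'   threshold actually applied is stored in the set's metadata attribute.
#' @export
segmentPscrGlobal <- function(structural, guideMask,
                              params = thresholdParams()) {
  stopifnot(is(structural, "Volume"), is(guideMask, "BinaryMask"))
  if (!identical(dim(structural@data), dim(guideMask@data)))
    stop("structural volume and guide mask must share the grid")
  if (!any(guideMask@data)) {
    warning("guide mask is empty; returning empty candidate set")
    return(.empty_pscr_set(structural))
  }
  st <- contrastStretch(structural, params$stretchLow, params$stretchHigh)
  guide <- dilateMask(guideMask, params$guideDilationVoxels)
  gated <- st@data * guide@data
  dom <- if (params$thresholdDomain == "full") as.vector(st@data)
         else gated[guide@data]
  thr <- percentileThreshold(dom, params$pBase, params$s)
  lab <- labelFilteredComponents(gated > thr, params$connectivity,
                                 params$minSizeVoxels, structural@voxelNm)
  out <- PSCRSet(lab)
  attr(out@segments, "threshold") <- thr
  out
}

#' Refined local-threshold cleft segmentation
#'
#' Contrast stretch, difference-of-Gaussians background subtraction (sigmas
#' 7 / 0.3 voxels), grayscale erosion with a 1-voxel ball, binarisation at
#' the upper three-class Otsu threshold, gating by the guide mask dilated
#' with a 1-voxel ball, and removal of objects smaller than 6 voxels.
#' The background-subtraction and erosion stages can be toggled off, as one
#' published application omits them.
#'
#' @param structural The structural [Volume-class].
#' @param guideMask A [BinaryMask-class] on the same grid.
#' @param params A [thresholdParams()] list; \code{minSizeVoxels} defaults
#'   here to 6 and \code{guideDilationVoxels} to 1.
#' @param sigmaBg,sigmaSig Difference-of-Gaussians sigmas (voxels).
#' @param backgroundSubtract,grayscaleErosion Stage toggles.
#' @return A [PSCRSet-class] of candidates.
#' @export
segmentPscrLocal <- function(structural, guideMask,
                             params = thresholdParams(minSizeVoxels = 6L,
                                                      guideDilationVoxels = 1L),
                             sigmaBg = 7, sigmaSig = 0.3,
                             backgroundSubtract = TRUE,
                             grayscaleErosion = TRUE) {
  stopifnot(is(structural, "Volume"), is(guideMask, "BinaryMask"))
  if (!identical(dim(structural@data), dim(guideMask@data)))
    stop("structural volume and guide mask must share the grid")
  if (!any(guideMask@data)) {
    warning("guide mask is empty; returning empty candidate set")
    return(.empty_pscr_set(structural))
  }
  v <- contrastStretch(structural, params$stretchLow, params$stretchHigh)
  if (backgroundSubtract) v <- dogSubtract(v, sigmaBg, sigmaSig)
  if (grayscaleErosion) v <- grayscaleErode(v, 1)
  thr <- multiotsuUpperThreshold(v)
  guide <- dilateMask(guideMask, params$guideDilationVoxels)
  fg <- (v@data > thr) & guide@data
  lab <- labelFilteredComponents(fg, params$connectivity,
                                 params$minSizeVoxels, structural@voxelNm)
  out <- PSCRSet(lab)
  attr(out@segments, "threshold") <- thr
  out
}

.empty_pscr_set <- function(volume) {
  PSCRSet(LabelMap(array(0L, dim(volume@data)), voxelNm = volume@voxelNm))
}

#' Classify cleft candidates by marker co-localization
#'
#' A candidate is retained as a putative synaptic cleft region iff it
#' overlaps the intersection of the pre-synaptic mask with the non-dilated
#' post-synaptic mask by at least one voxel; all other candidates are
#' dropped. Overlap uses the raw candidate voxels (no candidate dilation).
#'
#' @param candidates A [PSCRSet-class].
#' @param preMask,postMaskUndilated [BinaryMask-class] objects on the
#'   candidate grid.
#' @return The filtered [PSCRSet-class] with
#'   \code{overlaps_marker_intersection} flags set; labels are renumbered
#'   1..K in scan order.
#' @export
classifyPscr <- function(candidates, preMask, postMaskUndilated) {
  stopifnot(is(candidates, "PSCRSet"))
  inter <- markerIntersection(preMask, postMaskUndilated)
  lab <- candidates@labels@data
  if (!identical(dim(lab), dim(inter@data)))
    stop("grid mismatch between candidates and marker masks")
  ids <- candidates@segments$id
  if (!length(ids)) return(candidates)
  hit <- sort(unique(lab[inter@data & lab > 0L]))
  keep <- ids %in% hit
  remap <- integer(max(ids))
  remap[ids[keep]] <- seq_len(sum(keep))
  out <- array(0L, dim(lab))
  pos <- lab > 0L & array(lab %in% ids[keep], dim(lab))
  out[pos] <- remap[lab[pos]]
  seg <- candidates@segments[keep, , drop = FALSE]
  if (nrow(seg)) {
    seg$id <- remap[seg$id]
    seg$overlaps_marker_intersection <- TRUE
    seg <- seg[order(seg$id), , drop = FALSE]
    rownames(seg) <- NULL
  }
  new("PSCRSet", labels = LabelMap(out, voxelNm = candidates@labels@voxelNm),
      segments = seg)
}

#' Assign classified clefts to boutons
#'
#' Bouton masks are dilated with a ball of the given radius; every cleft
#' overlapping a dilated bouton by at least one voxel is assigned to the
#' bouton with the largest voxel overlap (ties break toward the lowest
#' bouton label). Voxels are never modified, only the per-segment
#' \code{bouton_id} attribute.
#'
#' @param pscrs A [PSCRSet-class].
#' @param boutons A [LabelMap-class] of bouton instances on the same grid.
#' @param dilation Ball radius for the bouton dilation (default 2).
#' @return The [PSCRSet-class] with \code{bouton_id} filled in (NA when
#'   unassigned).
#' @export
assignToBoutons <- function(pscrs, boutons, dilation = 2) {
  stopifnot(is(pscrs, "PSCRSet"), is(boutons, "LabelMap"))
  lab <- pscrs@labels@data
  if (!identical(dim(lab), dim(boutons@data)))
    stop("grid mismatch between clefts and boutons")
  if (!nrow(pscrs@segments)) return(pscrs)
  ids <- sort(unique(as.vector(boutons@data)))
  ids <- ids[ids > 0]
  ## dilate each bouton separately so dilations may overlap without
  ## overwriting each other
  ov <- matrix(0L, nrow(pscrs@segments), length(ids),
               dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    dil <- .binary_dilate(boutons@data == ids[j], dilation)
    tab <- table(lab[dil & lab > 0L])
    if (length(tab))
      ov[match(as.integer(names(tab)), pscrs@segments$id), j] <- as.integer(tab)
  }
  assigned <- apply(ov, 1, function(r) {
    if (all(r == 0L)) NA_integer_ else ids[which.max(r)]  # ties: lowest label
  })
  pscrs@segments$bouton_id <- as.integer(assigned)
  pscrs
}

#' Apply a proofreading edit list
#'
#' Interactive proofreading is represented as a JSON edit file: a list of
#' operations \code{remove} (drop a segment id), \code{merge} (relabel one
#' segment into another) and \code{add} (paint a new segment from explicit
#' voxel coordinates). Edited segments carry \code{proofread_flag = TRUE}.
#'
#' @param pscrs A [PSCRSet-class].
#' @param edits Path to a JSON edit file, or an equivalent list with an
#'   \code{operations} element.
#' @return The edited [PSCRSet-class], labels renumbered 1..K.
#' @export
applyProofreading <- function(pscrs, edits) {
  stopifnot(is(pscrs, "PSCRSet"))
  if (is.character(edits)) edits <- jsonlite::read_json(edits)
  ops <- edits$operations
  lab <- pscrs@labels@data
  flagged <- integer()
  for (op in ops) {
    kind <- op$op
    if (kind == "remove") {
      lab[lab == op$id] <- 0L
    } else if (kind == "merge") {
      lab[lab == op$from] <- as.integer(op$into)
      flagged <- c(flagged, as.integer(op$into))
    } else if (kind == "add") {
      vox <- do.call(rbind, lapply(op$voxels, function(v)
        as.integer(unlist(v))))
      nid <- max(lab) + 1L
      lab[vox] <- nid
      flagged <- c(flagged, nid)
    } else stop("unknown proofreading operation: ", kind)
  }
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  remap <- integer(max(ids, 1L))
  remap[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  lm <- LabelMap(lab, voxelNm = pscrs@labels@voxelNm)
  seg <- .segment_records(lm@data)
  old <- pscrs@segments
  keepers <- intersect(seg$id, remap[old$id[old$id <= length(remap)]])
  seg$proofread_flag <- seg$id %in% remap[flagged[flagged <= length(remap)]]
  ## carry over classification/assignment flags where ids survived unchanged
  surv <- match(seg$id, remap[old$id])
  carried <- !is.na(surv)
  seg$overlaps_marker_intersection[carried] <-
    old$overlaps_marker_intersection[surv[carried]]
  seg$bouton_id[carried] <- old$bouton_id[surv[carried]]
  new("PSCRSet", labels = lm, segments = seg)
}
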