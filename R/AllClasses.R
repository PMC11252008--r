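## Core S4 containers. Axes are always ordered (z, y, x); physical spacing is
## carried per axis in nanometres; all reported geometry is in um / um^2 / um^3.

#' @include AllGenerics.R
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' VoxelGrid: shared scaffold of all gridded types
#'
#' Virtual base for [Volume-class], [LabelMap-class] and [BinaryMask-class]:
#' a 3D array in (z, y, x) order plus a strictly positive physical voxel
#' spacing in nanometres.
#'
#' @slot data 3D array.
#' @slot voxelNm Numeric length-3, nm per axis (z, y, x).
#' @name VoxelGrid-class
#' @aliases VoxelGrid
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation("VIRTUAL",
  data = "array", voxelNm = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (z, y, x)")
  if (length(object@voxelNm) != 3L || any(!is.finite(object@voxelNm)) ||
      any(object@voxelNm <= 0))
    msg <- c(msg, "voxelNm must be 3 strictly positive finite values")
  if (length(msg)) msg else TRUE
})

#' Volume: a scalar 3D intensity grid with physical spacing
#'
#' The canonical imaging grid of the pipeline: z-STED-like volumes at
#' (default) 50 x 50 x 50 nm voxels. Values must be finite.
#'
#' @slot name Channel identifier (e.g. "structural", "pre_marker").
#' @export Volume
#' @exportClass Volume
#' @examples
#' v <- Volume(array(runif(8 * 8 * 8), c(8, 8, 8)))
#' gridDim(v)
#' voxelNm(v)
setClass("Volume", contains = "VoxelGrid",
  representation(name = "character"),
  prototype(name = "volume", voxelNm = c(50, 50, 50)))

setValidity("Volume", function(object) {
  if (any(!is.finite(object@data))) "intensities must be finite" else TRUE
})

#' @rdname Volume-class
#' @param data 3D numeric array (z, y, x).
#' @param voxelNm Numeric length-3 spacing in nm; default 50 nm isotropic.
#' @param name Channel identifier.
#' @return A \code{Volume}.
Volume <- function(data, voxelNm = c(50, 50, 50), name = "volume") {
  new("Volume", data = data, voxelNm = as.numeric(voxelNm), name = name)
}

#' LabelMap: non-negative integer instance map
#'
#' Instance segmentation sharing a Volume's grid; 0 is reserved for
#' background and labels need not be consecutive.
#'
#' @slot table Optional data.frame mapping id to name/role.
#' @export LabelMap
#' @exportClass LabelMap
setClass("LabelMap", contains = "VoxelGrid",
  representation(table = "data.frameOrNULL"),
  prototype(table = NULL, voxelNm = c(50, 50, 50)))

setValidity("LabelMap", function(object) {
  d <- object@data
  if (any(d < 0) || any(d != round(d)))
    return("labels must be non-negative integers")
  TRUE
})

#' @rdname LabelMap-class
#' @param data 3D array of non-negative integers.
#' @param voxelNm Numeric length-3 spacing in nm.
#' @param table Optional id/name/role data.frame.
#' @return A \code{LabelMap}.
LabelMap <- function(data, voxelNm = c(50, 50, 50), table = NULL) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, voxelNm = as.numeric(voxelNm), table = table)
}

#' BinaryMask: boolean guide/selection mask on a Volume grid
#'
#' @slot provenance Either "immuno" (from an immunostained marker channel)
#'   or "predicted" (from a network-predicted marker channel).
#' @export BinaryMask
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "VoxelGrid",
  representation(provenance = "character"),
  prototype(provenance = "immuno", voxelNm = c(50, 50, 50)))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@data)) msg <- c(msg, "mask data must be logical")
  if (!object@provenance %in% c("immuno", "predicted"))
    msg <- c(msg, "provenance must be 'immuno' or 'predicted'")
  if (length(msg)) msg else TRUE
})

#' @rdname BinaryMask-class
#' @param data 3D logical array.
#' @param voxelNm Numeric length-3 spacing in nm.
#' @param provenance "immuno" or "predicted".
#' @return A \code{BinaryMask}.
BinaryMask <- function(data, voxelNm = c(50, 50, 50), provenance = "immuno") {
  storage.mode(data) <- "logical"
  new("BinaryMask", data = data, voxelNm = as.numeric(voxelNm),
      provenance = provenance)
}

#' TriMesh: triangle surface in physical units (micrometres)
#'
#' @slot vertices N x 3 numeric matrix of points in um (z, y, x).
#' @slot faces M x 3 integer matrix of 1-based vertex indices.
#' @export TriMesh
#' @exportClass TriMesh
setClass("TriMesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("TriMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be N x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be M x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' @rdname TriMesh-class
#' @param vertices N x 3 numeric matrix (um).
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @return A \code{TriMesh}.
TriMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (!nrow(faces)) dim(faces) <- c(0L, 3L)
  if (!nrow(vertices)) dim(vertices) <- c(0L, 3L)
  new("TriMesh", vertices = vertices, faces = faces)
}

#' PSCRSet: instance-segmented synaptic cleft candidates
#'
#' Holds the retained candidate label map plus one record per segment:
#' id, voxel count, centroid (voxel coordinates), whether it overlaps the
#' pre/post marker intersection, the assigned bouton (NA when unassigned)
#' and a proofreading flag.
#'
#' @slot labels A [LabelMap-class] of the retained candidates.
#' @slot segments data.frame with columns id, voxel_count, cz, cy, cx,
#'   overlaps_marker_intersection, bouton_id, proofread_flag.
#' @export PSCRSet
#' @exportClass PSCRSet
setClass("PSCRSet", representation(labels = "LabelMap", segments = "data.frame"))

setValidity("PSCRSet", function(object) {
  need <- c("id", "voxel_count", "cz", "cy", "cx",
            "overlaps_marker_intersection", "bouton_id", "proofread_flag")
  if (!all(need %in% names(object@segments)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  ids <- sort(unique(as.vector(object@labels@data)))
  ids <- ids[ids > 0]
  if (!setequal(ids, object@segments$id))
    return("segment table ids must match label map labels")
  TRUE
})

#' @rdname PSCRSet-class
#' @param labels A [LabelMap-class].
#' @param segments Per-segment record data.frame (computed from \code{labels}
#'   when omitted).
#' @return A \code{PSCRSet}.
PSCRSet <- function(labels, segments = NULL) {
  if (is.null(segments)) segments <- .segment_records(labels@data)
  new("PSCRSet", labels = labels, segments = segments)
}

## per-segment bookkeeping (voxel_count, centroid) from a label array
.segment_records <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (!length(ids)) {
    return(data.frame(id = integer(), voxel_count = integer(),
      cz = numeric(), cy = numeric(), cx = numeric(),
      overlaps_marker_intersection = logical(), bouton_id = integer(),
      proofread_flag = logical()))
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  co <- arrayInd(idx, dim(lab))
  n <- as.integer(table(factor(lv, levels = ids)))
  cz <- vapply(split(co[, 1], lv), mean, 0)[as.character(ids)]
  cy <- vapply(split(co[, 2], lv), mean, 0)[as.character(ids)]
  cx <- vapply(split(co[, 3], lv), mean, 0)[as.character(ids)]
  data.frame(id = as.integer(ids), voxel_count = n, cz = unname(cz),
    cy = unname(cy), cx = unname(cx),
    overlaps_marker_intersection = NA, bouton_id = NA_integer_,
    proofread_flag = FALSE)
}

#' PhantomConfig: the stated world of the synthetic generator
#'
#' Defaults emulate the imaging and biology the analysis assumes: 50-nm
#' isotropic voxels, a dendrite with complex spines, large boutons engulfing
#' spine heads across a ~2-voxel extracellular gap, and a per-bouton synaptic
#' cleft count drawn from the observed 3-28 range.
#'
#' @slot gridShape Integer length-3 (z, y, x) voxels.
#' @slot voxelNm Numeric length-3 spacing in nm.
#' @slot nBoutons,nSpines Object counts.
#' @slot boutonRadiusUm Length-2: mean and sd of ellipsoid semi-axes (um).
#' @slot dendriteRadiusUm Cylinder radius (um).
#' @slot spineHeadRadiusUm Spine head radius (um); heads grow beyond this
#'   when needed to host the drawn number of cleft patches.
#' @slot pscrPerBouton Integer range (lo, hi) the per-bouton count is drawn
#'   from; equal values fix the count.
#' @slot nHotspots Count of bright extracellular distractor features
#'   (protein-dense hotspots that are not synaptic clefts); they populate
#'   the top intensity percentiles the way dense tissue does, which is what
#'   makes marker guidance necessary.
#' @slot hotspotRadiusVoxels,hotspotAmp Ranges (lo, hi) for hotspot size and
#'   amplitude (amplitude relative to the membrane base).
#' @slot markerOffsetNm Displacement of pre/post marker puncta from the
#'   interface centroid along the interface normal (nm).
#' @slot psfSigmaNm Per-channel PSF sigma in nm, named list with entries
#'   structural, pre, post (each length 3, z/y/x).
#' @slot contrastRatio Cleft-patch amplitude relative to the membrane base
#'   amplitude (the paper gives no quantitative ratio; >= 2 is assumed).
#' @slot photonScale Expected photons at unit intensity.
#' @slot readNoiseSd Additive Gaussian sd (photon units).
#' @slot background Baseline intensity fraction.
#' @slot seed RNG seed.

#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  gridShape = "integer", voxelNm = "numeric",
  nBoutons = "integer", nSpines = "integer",
  boutonRadiusUm = "numeric", dendriteRadiusUm = "numeric",
  spineHeadRadiusUm = "numeric",
  pscrPerBouton = "integer", nHotspots = "integer",
  hotspotRadiusVoxels = "numeric", hotspotAmp = "numeric",
  markerOffsetNm = "numeric",
  psfSigmaNm = "list", contrastRatio = "numeric",
  photonScale = "numeric", readNoiseSd = "numeric",
  background = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (any(object@gridShape < 32L))
    msg <- c(msg, "gridShape must be at least (32, 32, 32)")
  if (any(object@voxelNm <= 0)) msg <- c(msg, "voxelNm must be positive")
  if (object@nBoutons < 0L || object@nSpines < 0L)
    msg <- c(msg, "object counts must be non-negative")
  if (object@boutonRadiusUm[1] <= 0 || object@dendriteRadiusUm <= 0 ||
      object@spineHeadRadiusUm <= 0)
    msg <- c(msg, "all radii must be positive")
  if (length(object@pscrPerBouton) != 2L ||
      object@pscrPerBouton[1] > object@pscrPerBouton[2] ||
      object@pscrPerBouton[1] < 1L || object@pscrPerBouton[2] > 50L)
    msg <- c(msg, "pscrPerBouton range must lie within [1, 50]")
  if (object@photonScale <= 0) msg <- c(msg, "photonScale must be positive")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: generated geometry and ground truth
#'
#' @slot instanceMap [LabelMap-class] of all objects with a role table
#'   (dendrite / spine / bouton; background 0).
#' @slot interfaces List, one entry per synaptic cleft patch: list(id,
#'   bouton_id, spine_id, voxels = K x 3 voxel-index matrix, normal = unit
#'   vector bouton -> spine, center = length-3 voxel coordinate).
#' @slot hotspots List of bright distractor features: list(center, radius,
#'   amp); extracellular, never synaptic.
#' @slot edges data.frame(bouton_id, spine_id, pscr_id) connectivity truth.
#' @slot objectTable data.frame(id, role, volume_um3) with analytic volumes.
#' @slot config The generating [PhantomConfig-class].

#' @exportClass PhantomTruth
setClass("PhantomTruth", representation(
  instanceMap = "LabelMap", interfaces = "list", hotspots = "list",
  edges = "data.frame", objectTable = "data.frame",
  config = "PhantomConfig"))

#' ChannelSet: the multi-channel phantom rendering
#'
#' @slot structural [Volume-class]; extracellular structural channel, high
#'   intensity where the extracellular label is dense.
#' @slot preMarker,postMarker [Volume-class]; marker puncta flanking each
#'   cleft patch on the bouton / spine side.

#' @exportClass ChannelSet
setClass("ChannelSet", representation(
  structural = "Volume", preMarker = "Volume", postMarker = "Volume"))

setValidity("ChannelSet", function(object) {
  d <- dim(object@structural@data)
  if (!identical(d, dim(object@preMarker@data)) ||
      !identical(d, dim(object@postMarker@data)))
    return("all channels must share the grid shape")
  if (min(object@structural@data) < 0 || min(object@preMarker@data) < 0 ||
      min(object@postMarker@data) < 0)
    return("intensities must be >= 0")
  TRUE
})

#' InteractionGraph: pSCR-mediated bouton-spine connectivity
#'
#' @slot edges data.frame(pscr_id, bouton_id, spine_id); one row per
#'   (cleft, bouton, spine) interaction after the largest-overlap bouton rule.
#' @slot boutonOnly data.frame(pscr_id, bouton_id) for clefts contacting a
#'   bouton but no spine.

#' @exportClass InteractionGraph
setClass("InteractionGraph",
  representation(edges = "data.frame", boutonOnly = "data.frame"))

## ---- accessors & show ----

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelGrid", function(x) x@data)

#' @rdname voxelNm
#' @export
setMethod("voxelNm", "VoxelGrid", function(x) x@voxelNm)

#' @rdname voxelNm-set
#' @export
setReplaceMethod("voxelNm", "VoxelGrid", function(x, value) {
  x@voxelNm <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname gridDim
#' @export
setMethod("gridDim", "VoxelGrid", function(x) dim(x@data))

#' @rdname meshVertices
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)

#' @rdname meshFaces
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

#' @rdname segmentTable
#' @export
setMethod("segmentTable", "PSCRSet", function(x) x@segments)

#' @rdname labelMap
#' @export
setMethod("labelMap", "PSCRSet", function(x) x@labels)

#' @rdname labelMap
#' @export
setMethod("labelMap", "PhantomTruth", function(x) x@instanceMap)

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume '%s': %d x %d x %d voxels (z,y,x), %g x %g x %g nm\n",
    object@name, d[1], d[2], d[3],
    object@voxelNm[1], object@voxelNm[2], object@voxelNm[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
    min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  n <- length(setdiff(unique(as.vector(object@data)), 0L))
  cat(sprintf("LabelMap: %d x %d x %d voxels, %d instance(s)\n",
    d[1], d[2], d[3], n))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask (%s): %d x %d x %d voxels, %d foreground\n",
    object@provenance, d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n",
    nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "PSCRSet", function(object) {
  cat(sprintf("PSCRSet: %d segment(s)\n", nrow(object@segments)))
  if (nrow(object@segments)) {
    cat(sprintf("  assigned to boutons: %d; marker-overlap flags set: %d\n",
      sum(!is.na(object@segments$bouton_id)),
      sum(!is.na(object@segments$overlaps_marker_intersection))))
  }
})

setMethod("show", "PhantomTruth", function(object) {
  tab <- object@objectTable
  cat(sprintf(
    "PhantomTruth: %d object(s) (%d dendrite, %d spines, %d boutons), %d cleft interface(s)\n",
    nrow(tab), sum(tab$role == "dendrite"), sum(tab$role == "spine"),
    sum(tab$role == "bouton"), length(object@interfaces)))
})

setMethod("show", "ChannelSet", function(object) {
  d <- dim(object@structural@data)
  cat(sprintf("ChannelSet: structural + pre/post markers, %d x %d x %d voxels\n",
    d[1], d[2], d[3]))
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph: %d edge(s), %d bouton-only contact(s)\n",
    nrow(object@edges), nrow(object@boutonOnly)))
})
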