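#' Extract the raw voxel array of a grid object
#'
#' @param x A [Volume-class], [LabelMap-class] or [BinaryMask-class].
#' @return The underlying 3D array (z, y, x order).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Physical voxel spacing in nanometres
#'
#' @param x A grid object.
#' @return Numeric length-3 vector, nm per axis in (z, y, x) order.
#' @export
setGeneric("voxelNm", function(x) standardGeneric("voxelNm"))

#' Replace the voxel spacing
#' @param x A grid object.
#' @param value Numeric length-3, nm per axis.
#' @export
setGeneric("voxelNm<-", function(x, value) standardGeneric("voxelNm<-"))

#' Grid dimensions in voxels
#' @param x A grid object.
#' @return Integer length-3 (z, y, x).
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Mesh vertices (micrometres)
#' @param x A [TriMesh-class].
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' Mesh faces (1-based vertex index triples)
#' @param x A [TriMesh-class].
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Per-segment record table of a segmented object set
#' @param x A [PSCRSet-class].
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' Instance label map of a segmented object set
#' @param x A [PSCRSet-class] or [PhantomTruth-class].
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
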