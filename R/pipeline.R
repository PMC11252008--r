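## Config-driven orchestration: phantom (or files) -> preprocess -> segment
## -> classify -> assign -> morphometry -> connectivity -> evaluate, with a
## run manifest for reproducibility. Configs are YAML (or equivalent lists);
## every published constant appears as a named key with its value as default.

.pipeline_defaults <- function() list(
  variant = "global",
  seed = 1L,
  preprocess = list(stretch_low = 1, stretch_high = 99,
                    marker_sigma_bg = 15, marker_sigma_sig = 1),
  segment = list(
    p_base = 95, s = 0.65, min_size_voxels = 8, guide_dilation_voxels = 2,
    connectivity = 26, threshold_domain = "full",
    local = list(sigma_bg = 7, sigma_sig = 0.3, min_size_voxels = 6,
                 guide_dilation_voxels = 1, background_subtract = TRUE,
                 grayscale_erosion = TRUE)),
  assign = list(bouton_dilation_voxels = 2),
  connectivity = list(pscr_dilation_voxels = 1),
  morphometry = list(contact_adjacency = 26, bp_radii_voxels = c(1, 1.5),
                     spine_opening_radius = 3),
  evaluate = list(criterion = "iou", thresholds = seq(0.05, 0.95, by = 0.05),
                  headline_threshold = 0.2))

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML file, or a named list; missing keys fall
#'   back to the published defaults. Inputs come either from a
#'   \code{phantom} block (forwarded to [phantomConfig()]) or from a
#'   \code{paths} block with entries \code{structural}, \code{guide}
#'   (marker channel for guiding, or \code{predicted} for the
#'   prediction-guided variant), \code{pre}, \code{post} and optionally
#'   \code{boutons}, \code{spines}.
#' @return The completed configuration list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.pipeline_defaults(), config)
  if (!cfg$variant %in% c("global", "local", "prediction_guided"))
    stop("variant must be global, local or prediction_guided")
  if (is.null(cfg$phantom)) {
    p <- cfg$paths
    if (is.null(p$structural)) stop("config lacks a structural channel path")
    need <- if (cfg$variant == "prediction_guided") "predicted" else "guide"
    if (is.null(p[[need]]))
      stop("variant '", cfg$variant, "' needs a '", need, "' channel path")
    for (f in unlist(p)) if (!file.exists(f)) stop("missing input: ", f)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on phantom- or file-sourced inputs and
#' writes result tables, meshes, metrics and a run manifest (config echo,
#' package version, seed, and every threshold actually computed) to
#' \code{outDir}. The \code{global} and \code{local} variants gate the
#' structural channel with the binarised post-synaptic marker; the
#' \code{prediction_guided} variant uses the Otsu mask of a predicted
#' pre-synaptic marker channel instead.
#'
#' @param config A [pipelineConfig()] list or YAML path.
#' @param outDir Output directory.
#' @return Invisibly, list(pscrs, summary, graph, metrics, manifest).
#' @export
runPipeline <- function(config, outDir = tempfile("pscr_run_")) {
  cfg <- pipelineConfig(if (is.character(config)) config else config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  truth <- NULL
  if (!is.null(cfg$phantom)) {
    pargs <- cfg$phantom[setdiff(names(cfg$phantom), "noise")]
    if (is.null(pargs$seed)) pargs$seed <- cfg$seed
    pcfg <- do.call(phantomConfig, pargs)
    ph <- generatePhantom(pcfg, noise = !isFALSE(cfg$phantom$noise))
    truth <- ph$truth
    structural <- ph$channels@structural
    preChan <- ph$channels@preMarker
    postChan <- ph$channels@postMarker
    guideChan <- if (cfg$variant == "prediction_guided") preChan else postChan
    boutons <- .role_labels(truth, "bouton")
    spines <- NULL  # derived below via extractSpines
    dendriteMask <- BinaryMask(
      truth@instanceMap@data == 1L |
        .role_mask(truth, "spine"), voxelNm = pcfg@voxelNm)
  } else {
    p <- cfg$paths
    structural <- readVolume(p$structural, name = "structural")
    preChan <- if (!is.null(p$pre)) readVolume(p$pre, name = "pre_marker")
    postChan <- if (!is.null(p$post)) readVolume(p$post, name = "post_marker")
    guideChan <- if (cfg$variant == "prediction_guided")
      readVolume(p$predicted, name = "predicted_marker")
      else readVolume(p$guide, name = "guide_marker")
    boutons <- if (!is.null(p$boutons)) readLabelMap(p$boutons)
    spines <- if (!is.null(p$spines)) readLabelMap(p$spines)
    dendriteMask <- NULL
  }
  ## --- guide mask (DoG smoothing/background subtraction, then Otsu) ---
  mk <- cfg$preprocess
  guideMask <- markerMask(guideChan,
    sigmaBg = if (is.null(mk$marker_sigma_bg)) 15 else mk$marker_sigma_bg,
    sigmaSig = if (is.null(mk$marker_sigma_sig)) 1 else mk$marker_sigma_sig,
    provenance = if (cfg$variant == "prediction_guided") "predicted"
                 else "immuno")
  log$guide_otsu_threshold <- attr(guideMask@data, "threshold")
  ## --- segmentation ---
  sg <- cfg$segment
  params <- thresholdParams(
    stretchLow = cfg$preprocess$stretch_low,
    stretchHigh = cfg$preprocess$stretch_high,
    pBase = sg$p_base, s = sg$s,
    minSizeVoxels = if (cfg$variant == "local") sg$local$min_size_voxels
                    else sg$min_size_voxels,
    guideDilationVoxels = if (cfg$variant == "local")
      sg$local$guide_dilation_voxels else sg$guide_dilation_voxels,
    connectivity = sg$connectivity,
    thresholdDomain = sg$threshold_domain)
  pscrs <- if (cfg$variant == "local")
    segmentPscrLocal(structural, guideMask, params,
      sigmaBg = sg$local$sigma_bg, sigmaSig = sg$local$sigma_sig,
      backgroundSubtract = isTRUE(sg$local$background_subtract),
      grayscaleErosion = isTRUE(sg$local$grayscale_erosion))
  else segmentPscrGlobal(structural, guideMask, params)
  log$structural_threshold <- attr(pscrs@segments, "threshold")
  log$n_candidates <- nrow(pscrs@segments)
  ## --- classification ---
  if (!is.null(preChan) && !is.null(postChan)) {
    preMask <- markerMask(preChan)
    postMask <- markerMask(postChan)
    log$pre_otsu_threshold <- attr(preMask@data, "threshold")
    log$post_otsu_threshold <- attr(postMask@data, "threshold")
    pscrs <- classifyPscr(pscrs, preMask, postMask)
  }
  log$n_classified <- nrow(pscrs@segments)
  ## --- bouton assignment, morphometry, connectivity ---
  summary <- NULL; graph <- NULL
  if (!is.null(boutons)) {
    pscrs <- assignToBoutons(pscrs, boutons,
                             dilation = cfg$assign$bouton_dilation_voxels)
    summary <- boutonSummary(pscrs, boutons,
      contactAdjacency = cfg$morphometry$contact_adjacency,
      bpRadiiVoxels = cfg$morphometry$bp_radii_voxels)
    writeTables(summary$boutons, file.path(outDir, "boutons.csv"))
    for (pt in summary$patches) {
      if (nrow(pt$mesh@faces))
        writeMesh(pt$mesh, file.path(outDir,
          sprintf("contact_b%02d_p%03d.ply", pt$bouton_id, pt$pscr_id)))
    }
    if (is.null(spines) && !is.null(dendriteMask)) {
      sp <- extractSpines(dendriteMask,
                          openingRadius = cfg$morphometry$spine_opening_radius)
      spines <- sp$spines
    }
    if (!is.null(spines)) {
      graph <- interactionEdges(pscrs, boutons, spines,
        pscrDilation = cfg$connectivity$pscr_dilation_voxels)
      writeMetricsJson(list(edges = graph@edges,
        degrees = degreeSummaries(graph)), file.path(outDir, "graph.json"))
    }
  }
  writeTables(pscrs@segments, file.path(outDir, "pscr_segments.csv"))
  writeLabelMap(pscrs@labels, file.path(outDir, "pscr_labels.h5"),
                dataset = "labels")
  ## --- evaluation against phantom truth ---
  metrics <- NULL
  if (!is.null(truth)) {
    ## reference thickness matched to the variant's segment thickness: the
    ## local variant erodes segments to the cleft core, the global variant
    ## keeps a one-voxel halo
    ref <- .interface_labels(truth,
                             dilate = if (cfg$variant == "local") 0 else 1)
    pairs <- matchObjects(ref, pscrs@labels,
                          criterion = cfg$evaluate$criterion)
    metrics <- prfCurve(pairs, nRef = length(truth@interfaces),
      nTest = nrow(pscrs@segments), thresholds = cfg$evaluate$thresholds,
      criterion = cfg$evaluate$criterion)
    writeMetricsJson(list(curve = metrics,
      headline_f1 = metrics$f1[which.min(abs(
        metrics$threshold - cfg$evaluate$headline_threshold))]),
      file.path(outDir, "metrics.json"))
  }
  manifest <- list(config = cfg, thresholds = log,
    package_version = as.character(utils::packageVersion("SynaptoSeg")),
    seed = cfg$seed, timestamp = format(Sys.time(), tz = "UTC"))
  writeMetricsJson(manifest, file.path(outDir, "manifest.json"))
  invisible(list(pscrs = pscrs, summary = summary, graph = graph,
                 metrics = metrics, manifest = manifest, truth = truth,
                 outDir = outDir))
}

## helpers over phantom truth
.role_labels <- function(truth, role) {
  keep <- truth@objectTable$id[truth@objectTable$role == role]
  lab <- truth@instanceMap@data
  out <- array(0L, dim(lab))
  sel <- array(lab %in% keep, dim(lab))
  out[sel] <- lab[sel]
  LabelMap(out, voxelNm = truth@instanceMap@voxelNm)
}

.role_mask <- function(truth, role) {
  keep <- truth@objectTable$id[truth@objectTable$role == role]
  array(truth@instanceMap@data %in% keep, dim(truth@instanceMap@data))
}

## ground-truth interfaces as a label map, optionally thickened to match
## the apparent segment thickness
.interface_labels <- function(truth, dilate = 0) {
  d <- dim(truth@instanceMap@data)
  out <- array(0L, d)
  for (itf in truth@interfaces) {
    if (dilate > 0) {
      m <- array(FALSE, d)
      m[itf$voxels] <- TRUE
      m <- .binary_dilate(m, dilate)
      out[m & out == 0L] <- itf$id
    } else out[itf$voxels] <- itf$id
  }
  LabelMap(out, voxelNm = truth@instanceMap@voxelNm)
}
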