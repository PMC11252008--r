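test_that("component labeling respects connectivity and strict size filter", {
  d <- c(6, 6, 6)
  expect_identical(max(voxelData(labelFilteredComponents(array(FALSE, d)))), 0L)

  ## two diagonally touching voxels: one object at 26, two at 6
  diag2 <- array(FALSE, d)
  diag2[2, 2, 2] <- diag2[3, 3, 3] <- TRUE
  expect_identical(max(voxelData(labelFilteredComponents(diag2, 26))), 1L)
  expect_identical(max(voxelData(labelFilteredComponents(diag2, 6))), 2L)

  ## blobs of 7 and 9 voxels with minSize 8: only the 9-voxel blob survives
  blobs <- array(FALSE, c(10, 10, 10))
  blobs[2, 2, 1:7] <- TRUE
  blobs[8, 8, 1:9] <- TRUE
  lab <- labelFilteredComponents(blobs, 26, minSize = 8)
  expect_identical(max(voxelData(lab)), 1L)
  expect_identical(sum(voxelData(lab) > 0), 9L)
  ## exactly-8-voxel objects survive ("smaller than" is strict)
  eight <- array(FALSE, c(6, 6, 6)); eight[3, 3, 1:4] <- TRUE; eight[4, 3, 1:4] <- TRUE
  expect_identical(max(voxelData(labelFilteredComponents(eight, 26, 8))), 1L)
})

test_that("marker-guided global segmentation recovers phantom clefts", {
  ph <- std_phantom(noise = FALSE)
  guide <- markerMask(ph$channels@postMarker)

  expect_warning(
    empty <- segmentPscrGlobal(ph$channels@structural,
      BinaryMask(array(FALSE, dim(voxelData(ph$channels@structural))))),
    "empty")
  expect_identical(nrow(segmentTable(empty)), 0L)

  ps <- segmentPscrGlobal(ph$channels@structural, guide)
  expect_identical(nrow(segmentTable(ps)), length(ph$truth@interfaces))
  expect_true(all(segmentTable(ps)$voxel_count >= 8))

  ## s = 1: only voxels at the volume maximum can survive
  psMax <- segmentPscrGlobal(ph$channels@structural, guide,
    thresholdParams(s = 1, minSizeVoxels = 1))
  expect_lte(nrow(segmentTable(psMax)), 1L)
})

test_that("refined local segmentation recovers phantom clefts", {
  ph <- std_phantom(noise = FALSE)
  guide <- markerMask(ph$channels@postMarker)

  ## constant input: the degenerate stretch warns, then multi-Otsu errors
  expect_error(suppressWarnings(
    segmentPscrLocal(Volume(array(1, c(33, 33, 33))),
                     BinaryMask(array(TRUE, c(33, 33, 33))))), "degenerate")

  ps <- segmentPscrLocal(ph$channels@structural, guide)
  expect_identical(nrow(segmentTable(ps)), length(ph$truth@interfaces))
  expect_true(all(segmentTable(ps)$voxel_count >= 6))
})

test_that("raising s shrinks the segmented support; size filter is monotone", {
  ph <- small_phantom(noise = FALSE)
  guide <- markerMask(ph$channels@postMarker)
  ## the foreground voxel set shrinks as s rises (segment *counts* need not
  ## fall monotonically: a lower threshold can merge neighbouring clefts
  ## into one component)
  supports <- lapply(c(0.4, 0.65, 0.9), function(s)
    voxelData(labelMap(segmentPscrGlobal(ph$channels@structural, guide,
      thresholdParams(s = s, minSizeVoxels = 1)))) > 0)
  expect_true(all(supports[[1]][supports[[2]]]))
  expect_true(all(supports[[2]][supports[[3]]]))
  ## raising the size filter never adds segments
  counts_m <- vapply(c(4L, 8L, 40L), function(m)
    nrow(segmentTable(segmentPscrGlobal(ph$channels@structural, guide,
      thresholdParams(minSizeVoxels = m)))), 0L)
  expect_true(all(diff(counts_m) <= 0))
})

test_that("classification keeps only candidates on the marker intersection", {
  ## authored 5x5x5 fixture: one candidate overlaps pre only, one overlaps
  ## the pre/post intersection, one overlaps neither
  d <- c(5, 5, 5)
  lab <- array(0L, d)
  lab[1, 1, 1:2] <- 1L   # pre only
  lab[3, 3, 3] <- 2L     # intersection
  lab[5, 5, 5] <- 3L     # neither
  pre <- array(FALSE, d); pre[1, 1, ] <- TRUE; pre[3, 3, ] <- TRUE
  post <- array(FALSE, d); post[3, , 3] <- TRUE
  cand <- PSCRSet(LabelMap(lab))
  kept <- classifyPscr(cand, BinaryMask(pre), BinaryMask(post))
  expect_identical(nrow(segmentTable(kept)), 1L)
  expect_identical(sum(voxelData(labelMap(kept)) > 0), 1L)
  expect_true(all(segmentTable(kept)$overlaps_marker_intersection))
  ## classification never increases the segment count
  expect_lte(nrow(segmentTable(kept)), nrow(segmentTable(cand)))

  ## phantom: all true candidates retained, injected decoy rejected
  ph <- std_phantom(noise = FALSE)
  guide <- markerMask(ph$channels@postMarker)
  ps <- segmentPscrGlobal(ph$channels@structural, guide)
  plab <- voxelData(labelMap(ps))
  decoy_id <- max(plab) + 1L
  stopifnot(all(plab[103:105, 5:7, 5:7] == 0))
  plab[103:105, 5:7, 5:7] <- decoy_id   # far from any marker
  withDecoy <- PSCRSet(LabelMap(plab, voxelNm = voxelNm(labelMap(ps))))
  cls <- classifyPscr(withDecoy, markerMask(ph$channels@preMarker),
                      markerMask(ph$channels@postMarker))
  expect_identical(nrow(segmentTable(cls)), length(ph$truth@interfaces))
})

test_that("bouton assignment picks the largest overlap", {
  d <- c(8, 8, 8)
  plab <- array(0L, d)
  plab[4, 4, 2:6] <- 1L       # candidate spanning two boutons' reach
  plab[1, 1, 1] <- 2L         # far from everything
  blab <- array(0L, d)
  blab[5, 4, 2:4] <- 1L       # bouton 1 will overlap 3 voxels after dilation
  blab[5, 4, 6] <- 2L         # bouton 2 overlaps 1
  ps <- assignToBoutons(PSCRSet(LabelMap(plab)), LabelMap(blab), dilation = 2)
  seg <- segmentTable(ps)
  expect_identical(seg$bouton_id[seg$id == 1L], 1L)
  expect_true(is.na(seg$bouton_id[seg$id == 2L]))
  ## voxels are untouched by assignment
  expect_identical(voxelData(labelMap(ps)), plab)

  ## phantom: assignments equal ground truth edges
  ph <- std_phantom(noise = FALSE)
  guide <- markerMask(ph$channels@postMarker)
  cand <- segmentPscrGlobal(ph$channels@structural, guide)
  asg <- assignToBoutons(cand, truth_boutons(ph$truth))
  pairs <- matchObjects(truth_interfaces(ph$truth), labelMap(asg))
  seg <- segmentTable(asg)
  tr <- ph$truth@edges
  expect_identical(nrow(pairs), length(ph$truth@interfaces))
  got <- seg$bouton_id[match(pairs$test_id, seg$id)]
  want <- tr$bouton_id[match(pairs$ref_id, tr$pscr_id)]
  expect_identical(got, want)
})

test_that("proofreading edits apply and set flags", {
  d <- c(6, 6, 6)
  lab <- array(0L, d)
  lab[1, 1, 1:3] <- 1L; lab[3, 3, 1:3] <- 2L; lab[5, 5, 1:3] <- 3L
  ps <- PSCRSet(LabelMap(lab))
  edits <- list(operations = list(
    list(op = "remove", id = 2),
    list(op = "merge", from = 3, into = 1),
    list(op = "add", voxels = list(c(6, 6, 5), c(6, 6, 6)))))
  out <- applyProofreading(ps, edits)
  seg <- segmentTable(out)
  expect_identical(nrow(seg), 2L)
  expect_identical(sum(voxelData(labelMap(out)) > 0), 8L)  # 3+3 merged + 2 added
  expect_true(any(seg$proofread_flag))

  ## JSON round trip of the edit file
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(edits, p, auto_unbox = TRUE)
  out2 <- applyProofreading(ps, p)
  expect_identical(voxelData(labelMap(out2)), voxelData(labelMap(out)))
})
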