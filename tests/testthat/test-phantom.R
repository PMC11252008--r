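test_that("geometry handles the empty case and is deterministic", {
  bare <- buildGeometry(phantomConfig(nBoutons = 0, nSpines = 0, nHotspots = 0,
                                      gridShape = c(48, 48, 64)))
  expect_identical(nrow(bare@objectTable), 1L)
  expect_identical(bare@objectTable$role, "dendrite")
  expect_identical(nrow(bare@edges), 0L)

  cfg <- phantomConfig(seed = 7L, gridShape = c(64, 64, 96), nBoutons = 1,
                       nSpines = 2, pscrPerBouton = c(3, 3), nHotspots = 10)
  a <- buildGeometry(cfg)
  b <- buildGeometry(cfg)
  expect_identical(voxelData(labelMap(a)), voxelData(labelMap(b)))

  ## distinct seeds give distinct maps
  cfg2 <- phantomConfig(seed = 8L, gridShape = c(64, 64, 96), nBoutons = 1,
                        nSpines = 2, pscrPerBouton = c(3, 3), nHotspots = 10)
  expect_false(identical(voxelData(labelMap(a)),
                         voxelData(labelMap(buildGeometry(cfg2)))))
})

test_that("interfaces are adjacent to their bouton and spine (brute force)", {
  ph <- std_phantom(noise = FALSE)
  truth <- ph$truth
  expect_identical(length(truth@interfaces), 12L)  # 3 boutons x 4 clefts
  inst <- voxelData(labelMap(truth))
  d <- dim(inst)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  for (itf in truth@interfaces) {
    for (k in seq_len(nrow(itf$voxels))) {
      v <- itf$voxels[k, ]
      nb <- sweep(off, 2, v, `+`)
      nb <- nb[nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
               nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3], ]
      labs <- inst[nb]
      expect_identical(inst[v[1], v[2], v[3]], 0L)  # cleft is extracellular
      expect_true(itf$bouton_id %in% labs)
      expect_true(itf$spine_id %in% labs)
    }
  }
  ## every connectivity edge references existing objects; labels unique
  expect_true(all(truth@edges$bouton_id %in% truth@objectTable$id))
  expect_true(all(truth@edges$spine_id %in% truth@objectTable$id))
  expect_identical(anyDuplicated(truth@objectTable$id), 0L)

  ## connectivity edges recoverable from the instance map by brute-force
  ## adjacency scan across the gap (via the interface voxel sets)
  for (itf in truth@interfaces) {
    e <- truth@edges[truth@edges$pscr_id == itf$id, ]
    expect_identical(e$bouton_id, itf$bouton_id)
    expect_identical(e$spine_id, itf$spine_id)
  }
})

test_that("voxel bookkeeping is conserved", {
  ph <- small_phantom(noise = FALSE)
  inst <- voxelData(labelMap(ph$truth))
  counts <- table(factor(inst, levels = c(0, ph$truth@objectTable$id)))
  expect_identical(sum(counts), length(inst))
  expect_true(all(counts[-1] > 0))
})

test_that("rendered channels show the pre/cleft/post sandwich ordering", {
  ph <- std_phantom(noise = FALSE)
  ch <- ph$channels
  st <- voxelData(ch@structural)
  pre <- voxelData(ch@preMarker)
  post <- voxelData(ch@postMarker)
  expect_true(min(st) >= 0 && min(pre) >= 0 && min(post) >= 0)
  d <- dim(st)
  sample_at <- function(arr, p) {
    ip <- pmin(pmax(round(p), 1), d)
    arr[ip[1], ip[2], ip[3]]
  }
  for (itf in ph$truth@interfaces) {
    cen <- colMeans(itf$voxels)
    nrm <- itf$normal  # bouton -> spine
    ts <- seq(-4, 4, by = 0.5)
    stp <- vapply(ts, function(t) sample_at(st, cen + t * nrm), 0)
    prp <- vapply(ts, function(t) sample_at(pre, cen + t * nrm), 0)
    pop <- vapply(ts, function(t) sample_at(post, cen + t * nrm), 0)
    ## peaks ordered along the normal: pre (bouton side, negative t),
    ## cleft (centre), post (spine side, positive t)
    expect_lt(ts[which.max(prp)], ts[which.max(stp)])
    expect_gt(ts[which.max(pop)], ts[which.max(stp)])
    expect_lte(abs(ts[which.max(stp)]), 1.5)
  }
})

test_that("markers vanish when there are no clefts", {
  cfg <- phantomConfig(nBoutons = 0, nSpines = 1, nHotspots = 0,
                       gridShape = c(48, 48, 64))
  truth <- buildGeometry(cfg)
  ch <- renderChannels(truth, cfg)
  expect_identical(max(voxelData(ch@preMarker)), 0)
  expect_identical(max(voxelData(ch@postMarker)), 0)
})

test_that("photon noise has the configured first moments", {
  cfg <- phantomConfig(gridShape = c(48, 48, 64), nBoutons = 0, nSpines = 0,
                       nHotspots = 5, photonScale = 40, readNoiseSd = 1,
                       background = 0.05, seed = 11L)
  truth <- buildGeometry(cfg)
  ch <- renderChannels(truth, cfg)
  ## pick one bright voxel and average over 200 seeded replicates
  idx <- which.max(voxelData(ch@structural))
  mu_true <- 40 * (voxelData(ch@structural)[idx] + 0.05)
  draws <- vapply(1:200, function(s) {
    cfg@seed <- as.integer(s)
    voxelData(addNoise(ch, cfg)@structural)[idx]
  }, 0)
  se <- sqrt((mu_true + 1) / 200)  # Poisson + read-noise variance
  expect_lt(abs(mean(draws) - mu_true), 3 * se)

  ## deterministic given the seed
  n1 <- addNoise(ch, cfg)
  n2 <- addNoise(ch, cfg)
  expect_identical(voxelData(n1@structural), voxelData(n2@structural))

  ## large photon count: relative deviation from the clean channel vanishes
  cfg@photonScale <- 1e6; cfg@readNoiseSd <- 0
  big <- addNoise(ch, cfg)
  rel <- abs(voxelData(big@structural) / 1e6 -
             (voxelData(ch@structural) + 0.05)) /
         (voxelData(ch@structural) + 0.05)
  expect_lt(max(rel), 0.05)
})

test_that("fixture bundles round-trip losslessly", {
  dirp <- file.path(tempdir(), "phantom_bundle_test")
  cfg <- phantomConfig(gridShape = c(64, 64, 96), nBoutons = 1, nSpines = 2,
                       pscrPerBouton = c(3, 3), nHotspots = 10, seed = 1L)
  ph <- generatePhantom(cfg, noise = TRUE, dir = dirp)
  rb <- readPhantomBundle(dirp)
  expect_identical(voxelData(rb$channels@structural),
                   voxelData(ph$channels@structural))
  expect_identical(voxelData(rb$instanceMap), voxelData(labelMap(ph$truth)))
  ## RLE-encoded interface voxels decode to the original sets
  for (i in seq_along(ph$truth@interfaces)) {
    want <- ph$truth@interfaces[[i]]$voxels
    got <- rb$truth$interfaces$voxels[[i]]
    expect_true(setequal(paste(got[, 1], got[, 2], got[, 3]),
                         paste(want[, 1], want[, 2], want[, 3])))
  }
  expect_identical(nrow(as.data.frame(rb$truth$edges)),
                   nrow(ph$truth@edges))
  expect_identical(rb$truth$config$seed, 1L)
})

test_that("infeasible geometry fails with a named placement error", {
  ## boutons need a host spine each
  expect_error(buildGeometry(phantomConfig(nBoutons = 2, nSpines = 1)),
               "nSpines")
  ## a grid too small for the spine row names the failing stage
  expect_error(buildGeometry(phantomConfig(gridShape = c(33, 33, 33))),
               "placement error")
})
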