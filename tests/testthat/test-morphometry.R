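test_that("marching-cubes meshes reproduce analytic volumes and areas", {
  expect_error(meshFromMask(array(FALSE, c(5, 5, 5))), "empty")

  ## 10^3 solid box at 50 nm: volume within 5% of 0.125 um^3
  box <- array(FALSE, c(14, 14, 14)); box[3:12, 3:12, 3:12] <- TRUE
  mb <- meshFromMask(box, voxelNm = c(50, 50, 50))
  expect_lt(abs(meshVolume(mb) - 0.125) / 0.125, 0.05)

  ## digital ball r = 10 at 50 nm: volume and area within 5% of the
  ## analytic sphere (r = 0.5 um)
  ball <- digital_ball(10)
  m <- meshFromMask(ball, voxelNm = c(50, 50, 50))
  tv <- 4 / 3 * pi * 0.5^3
  ta <- 4 * pi * 0.5^2
  expect_lt(abs(meshVolume(m) - tv) / tv, 0.05)
  expect_lt(abs(meshArea(m) - ta) / ta, 0.05)
  ## watertight: closed-mesh check passes silently
  expect_silent(vol <- meshVolume(m))
})

test_that("mesh volume and area are exact on hand-built meshes", {
  cube <- unit_cube_mesh()
  expect_identical(meshVolume(cube), 1)
  expect_identical(meshArea(cube), 6)

  tri <- TriMesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE),
                 matrix(c(1, 2, 3), ncol = 3))
  expect_identical(meshArea(tri), 0.5)

  ## volume invariant under rigid rotation
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- TriMesh(meshVertices(cube) %*% Rz, meshFaces(cube))
  expect_equal(meshVolume(rot), 1, tolerance = 1e-9)
})

test_that("digital-ball mesh volume converges with radius", {
  errs <- vapply(c(8, 12, 16), function(r) {
    m <- meshFromMask(digital_ball(r), voxelNm = c(1000, 1000, 1000))
    abs(meshVolume(m) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, 0)
  expect_true(all(diff(errs) < 0))
  ## voxel-count consistency for solid objects >= 500 voxels
  r <- 8
  m <- meshFromMask(digital_ball(r), voxelNm = c(1000, 1000, 1000))
  vc <- sum(digital_ball(r))
  expect_lt(abs(meshVolume(m) - vc) / vc, 0.05)
})

test_that("contact points are the cleft voxels touching the bouton", {
  d <- c(8, 8, 8)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[2, , ] <- TRUE            # cleft slab
  b[5, , ] <- TRUE            # bouton slab, 2 planes away
  expect_identical(nrow(contactPoints(a, b)), 0L)

  b2 <- array(FALSE, d); b2[3, , ] <- TRUE  # face-adjacent
  pts <- contactPoints(a, b2, voxelNm = c(1000, 1000, 1000))
  expect_identical(nrow(pts), 64L)          # the whole touching layer
  expect_true(all(pts[, "z"] == 1))         # 0-based physical coordinate

  ## 6- vs 26-adjacency on a diagonal contact
  p <- array(FALSE, d); q <- array(FALSE, d)
  p[4, 4, 4] <- TRUE
  q[5, 5, 5] <- TRUE
  expect_identical(nrow(contactPoints(p, q, adjacency = 26)), 1L)
  expect_identical(nrow(contactPoints(p, q, adjacency = 6)), 0L)

  ## translation invariance
  p2 <- array(FALSE, d); q2 <- array(FALSE, d)
  p2[5, 5, 5] <- TRUE; q2[6, 6, 6] <- TRUE
  expect_identical(nrow(contactPoints(p2, q2)), nrow(contactPoints(p, q)))
})

test_that("ball pivoting triangulates point sheets at bounded circumradius", {
  ## fewer than 3 points: empty mesh, zero area
  two <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  expect_identical(nrow(meshFaces(ballPivotSurface(two))), 0L)
  expect_identical(meshArea(ballPivotSurface(two)), 0)

  ## planar 10 x 10 unit grid: area exactly 81 (9 x 9 unit cells)
  grid <- cbind(as.matrix(expand.grid(0:9, 0:9)), 0)
  mesh <- ballPivotSurface(grid, radii = c(1, 1.5))
  expect_identical(meshArea(mesh), 81)

  ## circumradius bound holds for every triangle
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  circum <- vapply(seq_len(nrow(f)), function(i) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    la <- sqrt(sum((b - cc)^2)); lb <- sqrt(sum((a - cc)^2))
    lc <- sqrt(sum((a - b)^2))
    s <- (la + lb + lc) / 2
    area <- sqrt(max(0, s * (s - la) * (s - lb) * (s - lc)))
    la * lb * lc / (4 * area)
  }, 0)
  expect_true(all(circum <= 1.5 + 1e-9))

  ## hemisphere point cloud: area within 10% of 2 pi r^2
  n <- 400
  i <- seq_len(n)
  cz <- 1 - (i - 0.5) / n
  az <- 2 * pi * i / ((1 + sqrt(5)) / 2)
  rxy <- sqrt(pmax(0, 1 - cz^2))
  hemi <- cbind(cz, rxy * sin(az), rxy * cos(az))
  spacing <- sqrt(2 * pi / n)
  hm <- ballPivotSurface(hemi, radii = c(1.5, 2.2) * spacing)
  expect_lt(abs(meshArea(hm) - 2 * pi) / (2 * pi), 0.10)
})

test_that("bouton summary integrates meshes and contact patches", {
  ph <- small_phantom(noise = FALSE)
  truth <- ph$truth
  boutons <- truth_boutons(truth)
  vox <- voxelNm(labelMap(truth))

  ## build the cleft set straight from ground truth so contact areas can be
  ## checked against the analytic patch size
  itfLab <- truth_interfaces(truth, dilate = 0)
  ps <- PSCRSet(itfLab)
  ps <- assignToBoutons(ps, boutons)
  ## face adjacency keeps the contact cloud a single voxel layer here (the
  ## phantom cleft is thin; 26-adjacency would pick up both layers)
  bs <- boutonSummary(ps, boutons, contactAdjacency = 6)
  tab <- bs$boutons
  expect_identical(tab$n_pscr, length(truth@interfaces))
  ## conservation: sum of patch areas equals the bouton total exactly
  patchSum <- sum(vapply(bs$patches, function(p) p$area_um2, 0))
  expect_equal(sum(tab$A_pSCR_MFB_um2), patchSum, tolerance = 1e-12)
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))

  ## every patch area is positive and bounded by the analytic disk size
  ## (voxel-centre sampling clips roughly half a cell at the rim, so small
  ## desk-scale patches sit below pi r^2; the analytic oracle at a radius
  ## where the rim bias is inside 15% is tested below)
  rpatch_um <- 3 * mean(vox) / 1000
  areas <- vapply(bs$patches, function(p) p$area_um2, 0)
  expect_true(all(areas > 0.3 * pi * rpatch_um^2 &
                  areas < 1.3 * pi * rpatch_um^2))

  ## analytically placed disk interface: a flat cleft disk of radius 10
  ## voxels face-adjacent to a bouton slab reconstructs to within 15% of
  ## pi r^2
  dd <- c(8, 28, 28)
  bout <- array(FALSE, dd); bout[1:3, , ] <- TRUE
  g3 <- expand.grid(z = 1:dd[1], y = 1:dd[2], x = 1:dd[3])
  disk <- array(g3$z == 4 & (g3$y - 14)^2 + (g3$x - 14)^2 <= 100, dd)
  pts <- contactPoints(disk, bout, adjacency = 6,
                       voxelNm = c(1000, 1000, 1000))
  dm <- ballPivotSurface(pts, radii = c(1, 1.5))
  expect_lt(abs(meshArea(dm) - pi * 100) / (pi * 100), 0.15)

  ## a bouton with no assigned clefts reports zero contact area
  empty <- PSCRSet(LabelMap(array(0L, dim(voxelData(boutons))),
                            voxelNm = vox))
  bs0 <- boutonSummary(empty, boutons)
  expect_identical(bs0$boutons$A_pSCR_MFB_um2, 0)
  expect_identical(bs0$boutons$fraction, 0)
})

test_that("spine extraction by morphological opening", {
  ## bare thick cylinder: no spines
  d <- c(24, 24, 40)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  cyl <- array((g$z - 12)^2 + (g$y - 12)^2 <= 64, d)
  sp0 <- extractSpines(cyl, voxelNm = c(50, 50, 50))
  expect_identical(max(voxelData(sp0$spines)), 0L)

  ## cylinder + one spherical bump (r = 4) on a thin neck: one spine whose
  ## volume is within 20% of the analytic bump + neck volume
  d2 <- c(48, 32, 48)
  g2 <- expand.grid(z = 1:d2[1], y = 1:d2[2], x = 1:d2[3])
  seg <- array((g2$z - 12)^2 + (g2$y - 16)^2 <= 64, d2)
  neck <- (g2$y - 16)^2 + (g2$x - 24)^2 <= 4 & g2$z >= 12 & g2$z <= 26
  head <- (g2$z - 30)^2 + (g2$y - 16)^2 + (g2$x - 24)^2 <= 16
  seg <- seg | array(neck, d2) | array(head, d2)
  sp1 <- extractSpines(seg, voxelNm = c(50, 50, 50))
  expect_identical(max(voxelData(sp1$spines)), 1L)
  got <- sum(voxelData(sp1$spines) > 0)
  analytic <- sum(array(head, d2) & (g2$z - 12)^2 + (g2$y - 16)^2 > 64) +
    sum(array(neck, d2) & (g2$z - 12)^2 + (g2$y - 16)^2 > 64 &
        !((g2$z - 30)^2 + (g2$y - 16)^2 + (g2$x - 24)^2 <= 16))
  expect_lt(abs(got - analytic) / analytic, 0.20)

  ## phantom dendrite: all spines recovered; decomposition covers the
  ## original segment (Dice >= 0.99)
  ph <- std_phantom(noise = FALSE)
  dm <- truth_dendrite_mask(ph$truth)
  sp <- extractSpines(dm)
  expect_identical(max(voxelData(sp$spines)), 5L)
  unionMask <- voxelData(sp$mainBranch) | voxelData(sp$spines) > 0
  orig <- voxelData(dm)
  dice <- 2 * sum(unionMask & orig) / (sum(unionMask) + sum(orig))
  expect_gte(dice, 0.99)
})
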