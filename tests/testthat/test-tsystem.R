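test_that("distance map matches the brute-force oracle on random volumes", {
  set.seed(30)
  spc <- c(0.2, 0.1, 0.1)
  for (rep in 1:6) {
    d <- c(sample(10:18, 1), sample(10:20, 1), sample(10:20, 1))
    tgt <- array(runif(prod(d)) < 0.03, d)
    if (!any(tgt)) tgt[1, 1, 1] <- TRUE
    cell <- array(TRUE, d)
    seg <- segFromMasks(cell, tgt, spc)
    dmap <- ttDistanceMap(seg)
    idx <- sample(prod(d), 150)
    expect_lt(max(abs(dmap[idx] - bruteForceDistance(tgt, spc, idx))), 1e-6)
  }
})

test_that("distance map semantics: zeros on targets, NA outside, errors", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(8, 12, 12)
  cell <- array(FALSE, d); cell[2:7, 2:11, 2:11] <- TRUE
  tgt <- array(FALSE, d); tgt[4, , ] <- cell[4, , ]
  seg <- segFromMasks(cell, tgt, spc)
  dmap <- ttDistanceMap(seg)
  expect_true(all(dmap[tgt] == 0))
  expect_true(all(is.na(dmap[!cell])))
  # straight-line distance: 7 lateral voxels from a plane at fixed y
  tgt2 <- array(FALSE, d); tgt2[, 2, ] <- cell[, 2, ]
  seg2 <- segFromMasks(cell, tgt2, spc)
  dmap2 <- ttDistanceMap(seg2)
  expect_equal(dmap2[4, 9, 6], 0.7)
  # no reference membrane
  segEmpty <- segFromMasks(cell, array(FALSE, d), spc)
  expect_error(ttDistanceMap(segEmpty), "no reference membrane")
})

test_that("mean TT distance: lattice oracle, deletion monotonicity, edge", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(20, 30, 60)
  cell <- array(FALSE, d); cell[3:18, 3:28, 3:58] <- TRUE
  # regular transverse planes with 2.0 um period along x
  tgt <- array(FALSE, d)
  for (ix in seq(8, 58, by = 20)) tgt[, , ix] <- cell[, , ix]
  seg <- segFromMasks(cell, tgt, spc)
  got <- ttDistanceMean(seg)
  sel <- which(cell & !tgt)
  oracle <- mean(bruteForceDistance(tgt, spc, sel))
  expect_equal(got, oracle, tolerance = 1e-10)

  # deleting every second plane strictly increases the mean
  tgt2 <- array(FALSE, d)
  for (ix in seq(8, 58, by = 40)) tgt2[, , ix] <- cell[, , ix]
  seg2 <- segFromMasks(cell, tgt2, spc)
  expect_gt(ttDistanceMean(seg2), got)

  # degenerate: everything is tubule -> mean 0
  segAll <- segFromMasks(cell, cell, spc)
  expect_equal(ttDistanceMean(segAll), 0)
})

test_that("TT density counts voxels and hits its bounds", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(10, 10, 10)
  cell <- array(TRUE, d)
  expect_equal(ttDensity(segFromMasks(cell, array(FALSE, d), spc)), 0)
  expect_equal(ttDensity(segFromMasks(cell, cell, spc)), 100)
  tgt <- array(FALSE, d); tgt[, , 1:2] <- TRUE
  expect_equal(ttDensity(segFromMasks(cell, tgt, spc)), 20)
})

test_that("skeleton length handles digitized tubes and anisotropy", {
  spc <- c(0.2, 0.1, 0.1)
  # 50-voxel plus-cross tube along x at 0.1 um: physical length 5.0
  m <- array(FALSE, c(9, 9, 54))
  m[5, 4:6, 3:52] <- TRUE; m[4:6, 5, 3:52] <- TRUE
  expect_true(abs(as.numeric(skeletonLength(m, spc)) - 5.0) <= 0.2)
  # 25-voxel tube along z at 0.2 um: same physical length, honored spacing
  m2 <- array(FALSE, c(30, 9, 9))
  m2[3:27, 4:6, 5] <- TRUE; m2[3:27, 5, 4:6] <- TRUE
  expect_true(abs(as.numeric(skeletonLength(m2, spc)) - 5.0) <= 0.25)
  # single voxel blob: zero length, flagged degenerate
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  l <- skeletonLength(sv, spc)
  expect_equal(as.numeric(l), 0)
  expect_equal(attr(l, "n_degenerate"), 1L)
  expect_error(skeletonLength(array(FALSE, c(4, 4, 4)), spc), "empty")
})

test_that("volume-length ratio: cylinder vs sheet reproduces the t-sheet signature", {
  spc <- c(0.2, 0.1, 0.1)
  cyl <- makeCylinderX(0.25)
  segC <- segFromMasks(array(TRUE, dim(cyl)), cyl, spc)
  ratioC <- ttVolumeLengthRatio(segC)
  expect_equal(ratioC, pi * 0.25^2, tolerance = 0.2)

  # slab 0.3 um (y) x 2.0 um (z) cross-section, same length
  slab <- array(FALSE, c(16, 9, 106)); slab[4:13, 4:6, 3:103] <- TRUE
  segS <- segFromMasks(array(TRUE, dim(slab)), slab, spc)
  ratioS <- ttVolumeLengthRatio(segS)
  expect_equal(ratioS, 0.6, tolerance = 0.2)
  expect_gt(ratioS, ratioC)

  # isotropic dilation strictly increases the ratio
  dil <- ttquant:::.edt(cyl, spc) <= 0.1
  segD <- segFromMasks(array(TRUE, dim(cyl)), cyl | dil, spc)
  expect_gt(ttVolumeLengthRatio(segD), ratioC)
})

test_that("cell area and volume follow the analytic geometry", {
  spc <- c(0.2, 0.1, 0.1)
  # cuboid 8 um (z) x 10 um (y) x 20 um (x): largest section 200 um^2
  cub <- array(FALSE, c(50, 110, 210))
  cub[3:42, 3:102, 3:202] <- TRUE   # 40 x 100 x 200 voxels
  segQ <- segFromMasks(cub, array(FALSE, dim(cub)) | (cub & FALSE), spc)
  segQ@tSystem <- binaryVolume(array(FALSE, dim(cub)), spc)
  expect_equal(cellArea(segQ), 200)
  expect_equal(cellVolume(segQ), 8 * 10 * 20, tolerance = 1e-10)

  # digitized sphere radius 5 um: max section ~ pi * 25
  d <- c(60, 110, 110)
  zc <- (seq_len(d[1]) - 1) * spc[1]; yc <- (seq_len(d[2]) - 1) * spc[2]
  xc <- (seq_len(d[3]) - 1) * spc[3]
  sph <- array(FALSE, d)
  for (ix in seq_len(d[3])) {
    r2 <- 25 - (xc[ix] - mean(range(xc)))^2
    if (r2 <= 0) next
    sph[, , ix] <- outer((zc - mean(range(zc)))^2, (yc - mean(range(yc)))^2,
                         `+`) <= r2
  }
  segS <- segFromMasks(sph, array(FALSE, d), spc)
  expect_equal(cellArea(segS), pi * 25, tolerance = 0.02)

  # single voxel
  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  segV <- segFromMasks(sv, array(FALSE, dim(sv)), spc)
  expect_equal(cellArea(segV), 0.01)
})

test_that("scale consistency: doubling the spacing scales metrics correctly", {
  set.seed(31)
  ph <- generateCellPhantom(phantomPreset("control", seed = 32,
                                          lengthUm = 8, semiAxisY = 3,
                                          semiAxisZ = 2.5))
  cell <- maskData(ph$truth$cellMask)
  tub <- maskData(ph$truth$tubules)
  seg1 <- segFromMasks(cell, tub, c(0.2, 0.1, 0.1))
  seg2 <- segFromMasks(cell, tub, c(0.4, 0.2, 0.2))
  expect_equal(ttDistanceMean(seg2), 2 * ttDistanceMean(seg1),
               tolerance = 1e-10)
  expect_equal(ttDensity(seg2), ttDensity(seg1))
  expect_equal(cellArea(seg2), 4 * cellArea(seg1))
  expect_equal(as.numeric(skeletonLength(tub, c(0.4, 0.2, 0.2))),
               2 * as.numeric(skeletonLength(tub, c(0.2, 0.1, 0.1))),
               tolerance = 1e-10)
})

test_that("monotonicity: removing t-system voxels never lowers the mean distance", {
  set.seed(33)
  spc <- c(0.2, 0.1, 0.1)
  d <- c(14, 16, 16)
  cell <- array(TRUE, d)
  tgt <- array(runif(prod(d)) < 0.05, d)
  tgt[1, 1, 1] <- TRUE
  base <- ttDistanceMean(segFromMasks(cell, tgt, spc))
  for (rep in 1:5) {
    tgt2 <- tgt
    on <- which(tgt2)
    tgt2[sample(on, ceiling(length(on) / 3))] <- FALSE
    if (!any(tgt2)) next
    expect_gte(ttDistanceMean(segFromMasks(cell, tgt2, spc)), base)
  }
})
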