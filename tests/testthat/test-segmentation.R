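test_that("histogram thresholds follow their stated rules", {
  # mode 100 (most voxels), SD from the full image; k = 1
  set.seed(5)
  img <- array(100, c(10, 10, 10))
  img[1:2, , ] <- sample(60:140, 200, replace = TRUE)  # spread, mode stays 100
  thr <- histogramThreshold(img, "mode_plus_k_sd", k = 1)
  expect_equal(thr@metadata$threshold, 100 + sd(img), tolerance = 0.5)

  # bimodal image: Otsu misclassifies < 1% of voxels
  set.seed(6)
  d <- c(20, 20, 20)
  truth <- array(runif(prod(d)) < 0.2, d)
  img2 <- array(rnorm(prod(d), 100, 10), d)
  img2[truth] <- rnorm(sum(truth), 200, 10)
  fg <- histogramThreshold(img2, "otsu")
  expect_lt(mean(maskData(fg) != truth), 0.01)

  # all-background image with mode + k SD: only the Gaussian tail passes
  # (P(N > mode + k*SD) ~ 16% at k = 1, < 1% at k = 2.5)
  set.seed(7)
  bg <- array(rnorm(8000, 100, 20), c(20, 20, 20))
  fg1 <- histogramThreshold(bg, "mode_plus_k_sd", k = 1)
  expect_lt(mean(maskData(fg1)), 0.35)
  fg2 <- histogramThreshold(bg, "mode_plus_k_sd", k = 2.5)
  expect_lt(mean(maskData(fg2)), 0.02)

  expect_error(histogramThreshold(array(1, c(4, 4, 4)), "otsu"), "constant")
})

test_that("watershed separates two phantom cells with high Dice", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(30, 60, 110)
  mem <- array(0, d)
  cellA <- array(FALSE, d); cellB <- array(FALSE, d)
  cellA[5:25, 5:28, 5:105] <- TRUE
  cellB[5:25, 33:56, 5:105] <- TRUE
  shell <- function(m) m & (ttquant:::.edt(!m, spc) <= 0.25)
  mem[shell(cellA) | shell(cellB)] <- 100
  labs <- watershedCells(mem, spacing = spc, minCellVolume = 50)
  expect_equal(max(labelData(labs)), 2L)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  l1 <- labelData(labs) == 1L; l2 <- labelData(labs) == 2L
  d1 <- max(dice(l1, cellA), dice(l1, cellB))
  d2 <- max(dice(l2, cellA), dice(l2, cellB))
  expect_gt(d1, 0.95)
  expect_gt(d2, 0.95)

  # single cell: one label
  memA <- array(0, d); memA[shell(cellA)] <- 100
  labsA <- watershedCells(memA, spacing = spc, minCellVolume = 50)
  expect_equal(max(labelData(labsA)), 1L)

  # supplied seeds: label count equals seed count, and the partition is
  # invariant to permuting seed labels
  seeds <- array(0L, d)
  seeds[15, 16, 55] <- 1L; seeds[15, 45, 55] <- 2L
  ws1 <- watershedCells(mem, spacing = spc,
                        seeds = labelVolume(seeds, spc), minCellVolume = 50)
  seedsPerm <- array(0L, d)
  seedsPerm[15, 16, 55] <- 2L; seedsPerm[15, 45, 55] <- 1L
  ws2 <- watershedCells(mem, spacing = spc,
                        seeds = labelVolume(seedsPerm, spc),
                        minCellVolume = 50)
  expect_equal(max(labelData(ws1)), 2L)
  # same partition: label images agree after swapping 1 <-> 2
  expect_true(all((labelData(ws1) == 1) == (labelData(ws2) == 2)))
  expect_error(watershedCells(array(0, d), spacing = spc), "empty")
})

test_that("morphological closing fills slits and fixes convex sets", {
  spc <- c(0.2, 0.1, 0.1)
  solid <- array(FALSE, c(20, 40, 40))
  solid[4:16, 6:34, 6:34] <- TRUE
  # 0.3 um slit (3 lateral voxels) through the middle
  slit <- solid
  slit[, 19:21, ] <- FALSE
  closed <- closeCellMask(binaryVolume(slit, spc), 0.5)
  expect_true(all(maskData(closed)[slit]))           # superset of input
  filled <- sum(maskData(closed)) - sum(slit)
  slitVol <- sum(solid & !slit)
  expect_gt(filled / slitVol, 0.95)                  # slit essentially filled

  cub <- binaryVolume(solid, spc)
  expect_equal(maskData(closeCellMask(cub, 0.4)), maskData(cub))  # convex
  expect_equal(maskData(closeCellMask(cub, 0)), maskData(cub))    # radius 0
})

test_that("membrane classification partitions and is monotone in depth", {
  ph <- generateCellPhantom(phantomPreset("control", seed = 21,
                                          lengthUm = 10, semiAxisY = 3.5,
                                          semiAxisZ = 3))
  truth <- ph$truth
  memFg <- binaryVolume(truth$surface@mask | truth$tubules@mask,
                        spacing(truth$cellMask))
  seg <- classifyMembrane(truth$cellMask, memFg, shellDepth = 0.5)
  # partition property
  inCell <- maskData(memFg) & maskData(truth$cellMask)
  expect_true(all((maskData(surfaceMembrane(seg)) |
                   maskData(tSystem(seg))) == inCell))
  expect_false(any(maskData(surfaceMembrane(seg)) & maskData(tSystem(seg))))
  # >= 98% of interior tubule voxels classified as t-system
  interiorTubule <- maskData(truth$tubules) &
    (ttquant:::.edt(!maskData(truth$cellMask), spacing(seg)) > 0.6)
  expect_gt(mean(maskData(tSystem(seg))[interiorTubule]), 0.98)
  # monotonicity: deeper shell never moves voxels from surface to t-system
  seg2 <- classifyMembrane(truth$cellMask, memFg, shellDepth = 1.0)
  expect_true(all(maskData(tSystem(seg2)) <= maskData(tSystem(seg))))
  # empty membrane foreground: both classes empty
  emptyFg <- binaryVolume(array(FALSE, dim(maskData(memFg))),
                          spacing(truth$cellMask))
  seg3 <- classifyMembrane(truth$cellMask, emptyFg)
  expect_equal(sum(maskData(tSystem(seg3))), 0)
  expect_equal(sum(maskData(surfaceMembrane(seg3))), 0)
})
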