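test_that("identical spec and seed give identical phantom and truth", {
  a <- generateCellPhantom(phantomPreset("myocarditis", seed = 70,
                                         lengthUm = 8, semiAxisY = 3,
                                         semiAxisZ = 2.5))
  b <- generateCellPhantom(phantomPreset("myocarditis", seed = 70,
                                         lengthUm = 8, semiAxisY = 3,
                                         semiAxisZ = 2.5))
  expect_identical(voxelData(a$stack), voxelData(b$stack))
  expect_identical(maskData(a$truth$tubules), maskData(b$truth$tubules))
  expect_identical(a$truth$segments, b$truth$segments)
})

test_that("tubule loss and t-sheet dilation shape the truth as configured", {
  full <- generateCellPhantom(cellPhantomSpec(seed = 71))
  segsFull <- full$truth$segments
  nLattice <- sum(segsFull$type != "x")
  # keep probability 0.5 halves the kept lattice tubules (binomial 99.9% CI)
  half <- generateCellPhantom(cellPhantomSpec(keepProb = 0.5, seed = 72))
  kept <- sum(half$truth$segments$length > 0 &
              half$truth$segments$type != "x")
  expect_gt(kept, qbinom(5e-4, nLattice, 0.5))
  expect_lt(kept, qbinom(1 - 5e-4, nLattice, 0.5))

  # control truth density sits in the configured ~2% range
  expect_gt(full$truth$ttDensity, 1.3)
  expect_lt(full$truth$ttDensity, 3.2)

  # sheet-flagged tubules have at least twice the cross-section volume
  sheets <- generateCellPhantom(cellPhantomSpec(sheetFraction = 0.5,
                                                seed = 73))
  segs <- sheets$truth$segments
  keptSegs <- segs[segs$length > 0 & segs$type != "x", ]
  expect_gt(sum(keptSegs$sheet), 0)
  volPerLen <- sheets$truth$tubuleVolume / sum(keptSegs$length)
  volPerLenPlain <- full$truth$tubuleVolume / sum(segsFull$length)
  expect_gt(volPerLen, 1.5 * volPerLenPlain)

  expect_error(generateCellPhantom(cellPhantomSpec(tubuleRadius = 0.05,
                                                   seed = 74)),
               "resolvable")
})

test_that("junction phantom endpoints: certain and impossible coupling", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(30, 50, 50)
  cell <- array(FALSE, d); cell[3:28, 3:48, 3:48] <- TRUE
  cellBV <- binaryVolume(cell, spc)
  th <- function(st, ch) binaryVolume(getChannel(st, ch) > 50, spc)

  full <- generateJunctionPhantom(junctionPhantomSpec(pTriple = 1,
                                                      pRyROnly = 0,
                                                      pJPH2Only = 0,
                                                      seed = 75), cellBV)
  l <- detectClusters(th(full$stack, "LTCC"), cellBV, "LTCC")
  r <- detectClusters(th(full$stack, "RyR"), cellBV, "RyR")
  j <- detectClusters(th(full$stack, "JPH2"), cellBV, "JPH2")
  expect_gte(intactJunctionFraction(l, r, j), 95)

  none <- generateJunctionPhantom(junctionPhantomSpec(pTriple = 0,
                                                      pRyROnly = 0,
                                                      pJPH2Only = 0,
                                                      seed = 76), cellBV)
  l0 <- detectClusters(th(none$stack, "LTCC"), cellBV, "LTCC")
  r0 <- detectClusters(th(none$stack, "RyR"), cellBV, "RyR")
  j0 <- detectClusters(th(none$stack, "JPH2"), cellBV, "JPH2")
  expect_lte(intactJunctionFraction(l0, r0, j0), 5)
})

test_that("tissue phantom hits its target fraction and is monotone", {
  f20 <- generateTissuePhantom(20, fieldUm = c(2, 19.2, 19.2), seed = 77)
  f35 <- generateTissuePhantom(35, fieldUm = c(2, 19.2, 19.2), seed = 77)
  expect_lt(abs(f20$truth$ecmFraction - 20), 2)
  expect_lt(abs(f35$truth$ecmFraction - 35), 2)
  expect_gt(f35$truth$ecmFraction, f20$truth$ecmFraction)
  expect_error(generateTissuePhantom(0), "must be in")
  expect_error(generateTissuePhantom(100), "must be in")
})

test_that("imaging forward model: identity spec and seed determinism", {
  set.seed(78)
  s <- imageStack(array(runif(10 * 12 * 12, 0, 100), c(10, 12, 12)))
  idm <- applyImaging(s, identityImagingSpec())
  expect_equal(voxelData(idm), voxelData(s))

  spec <- imagingSpec(seed = 79)
  a <- applyImaging(s, spec)
  b <- applyImaging(s, spec)
  expect_identical(voxelData(a), voxelData(b))
  c2 <- applyImaging(s, imagingSpec(seed = 80))
  expect_false(identical(voxelData(a), voxelData(c2)))
  # caller's RNG stream is not disturbed
  set.seed(81); before <- runif(3)
  set.seed(81); invisible(applyImaging(s, spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("depth attenuation and spill-over are part of the forward model", {
  s <- imageStack(array(100, c(20, 8, 8)), c(0.2, 0.1, 0.1))
  att <- applyImaging(s, imagingSpec(psf = NULL, attenuationLength = 10,
                                     poissonScale = 0, readNoiseSD = 0,
                                     background = 0, seed = 1))
  pm <- apply(voxelData(att)[1, , , ], 1, mean)
  z <- (seq_len(20) - 1) * 0.2
  expect_equal(pm, 100 * exp(-z / 10), tolerance = 1e-10)

  two <- imageStack(array(c(100, 0), c(2, 4, 4, 4)),
                    channelNames = c("A", "B"))
  M <- matrix(c(1, 0.3, 0, 1), 2, 2)
  mixed <- applyImaging(two, imagingSpec(psf = NULL, poissonScale = 0,
                                         readNoiseSD = 0, background = 0,
                                         mixing = M, seed = 1))
  expect_equal(unique(as.vector(voxelData(mixed)[2, , , ])), 30)
})
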