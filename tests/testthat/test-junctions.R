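test_that("connected-component detection honors connectivity and size filters", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(12, 20, 20)
  cell <- binaryVolume(array(TRUE, d), spc)
  fg <- array(FALSE, d)
  fg[3:5, 3:5, 3:5] <- TRUE           # blob 1
  fg[3:5, 8:10, 3:5] <- TRUE          # blob 2, 2-voxel gap in y
  cs <- detectClusters(binaryVolume(fg, spc), cell, "P", 26, 4)
  expect_equal(nClusters(cs), 2L)

  # corner-touching blobs: one cluster at 26, two at 6
  fg2 <- array(FALSE, d)
  fg2[3:4, 3:4, 3:4] <- TRUE
  fg2[5:6, 5:6, 5:6] <- TRUE
  cs26 <- detectClusters(binaryVolume(fg2, spc), cell, "P", 26, 1)
  cs6 <- detectClusters(binaryVolume(fg2, spc), cell, "P", 6, 1)
  expect_equal(nClusters(cs26), 1L)
  expect_equal(nClusters(cs6), 2L)

  # min size filter removes small specks
  fg3 <- fg; fg3[10, 15, 15] <- TRUE
  cs3 <- detectClusters(binaryVolume(fg3, spc), cell, "P", 26, 4)
  expect_equal(nClusters(cs3), 2L)
  # empty foreground: empty set, density 0
  cs0 <- detectClusters(binaryVolume(array(FALSE, d), spc), cell, "P")
  expect_equal(nClusters(cs0), 0L)
  expect_equal(clusterDensity(cs0), 0)
})

test_that("planted clusters are recovered by count and density", {
  set.seed(40)
  spc <- c(0.2, 0.1, 0.1)
  d <- c(30, 60, 60)
  cell <- array(FALSE, d); cell[3:28, 3:58, 3:58] <- TRUE
  spec <- junctionPhantomSpec(ltccDensity = 0.10, seed = 41)
  jp <- generateJunctionPhantom(spec, binaryVolume(cell, spc))
  fg <- binaryVolume(getChannel(jp$stack, "LTCC") > 50, spc)
  cs <- detectClusters(fg, binaryVolume(cell, spc), "LTCC")
  expect_equal(nClusters(cs), jp$truth$nLTCC, tolerance = 0.05)
  expect_equal(clusterDensity(cs), 0.10, tolerance = 0.1)
  # arithmetic check of the density definition
  expect_equal(clusterDensity(cs), nClusters(cs) / jp$truth$cellVolume)
})

test_that("co-localization fractions behave at the extremes", {
  set.seed(42)
  spc <- c(0.2, 0.1, 0.1)
  d <- c(20, 30, 30)
  cell <- binaryVolume(array(TRUE, d), spc)
  fg <- array(FALSE, d)
  fg[4:6, 4:6, 4:6] <- TRUE; fg[12:14, 20:22, 20:22] <- TRUE
  a <- detectClusters(binaryVolume(fg, spc), cell, "A")
  expect_equal(as.numeric(colocFraction(a, a)), 1)
  shift <- array(FALSE, d)
  shift[4:6, 12:14, 12:14] <- TRUE
  b <- detectClusters(binaryVolume(shift, spc), cell, "B")
  expect_equal(as.numeric(colocFraction(a, b)), 0)
  # empty reference set gives NA fraction
  e <- detectClusters(binaryVolume(array(FALSE, d), spc), cell, "E")
  expect_true(is.na(colocFraction(e, a)))
})

test_that("intact-junction fraction: bounds, extremes and planted recovery", {
  set.seed(43)
  spc <- c(0.2, 0.1, 0.1)
  d <- c(35, 70, 70)
  cell <- array(FALSE, d); cell[3:33, 3:68, 3:68] <- TRUE
  cellBV <- binaryVolume(cell, spc)
  spec <- junctionPhantomSpec(ltccDensity = 0.12, pTriple = 0.5,
                              pRyROnly = 0.2, pJPH2Only = 0.1, seed = 44)
  jp <- generateJunctionPhantom(spec, cellBV)
  th <- function(ch) binaryVolume(getChannel(jp$stack, ch) > 50, spc)
  ltcc <- detectClusters(th("LTCC"), cellBV, "LTCC")
  ryr <- detectClusters(th("RyR"), cellBV, "RyR")
  jph2 <- detectClusters(th("JPH2"), cellBV, "JPH2")
  ijf <- intactJunctionFraction(ltcc, ryr, jph2)
  # planted triple fraction recovered
  expect_equal(ijf, 100 * jp$truth$pTripleTrue, tolerance = 0.15)
  # invariant: intact fraction bounded by each pairwise fraction
  expect_lte(ijf, 100 * as.numeric(colocFraction(ltcc, ryr)) + 1e-9)
  expect_lte(ijf, 100 * as.numeric(colocFraction(ltcc, jph2)) + 1e-9)

  # JPH2 empty: 0%
  empty <- detectClusters(binaryVolume(array(FALSE, d), spc), cellBV, "JPH2")
  expect_equal(intactJunctionFraction(ltcc, ryr, empty), 0)
  # all-overlapping: 100%
  expect_equal(intactJunctionFraction(ltcc, ltcc, ltcc), 100)
  # no LTCC clusters: NA with warning
  expect_warning(res <- intactJunctionFraction(empty, ryr, jph2), "no LTCC")
  expect_true(is.na(res))
})

test_that("translation far beyond cluster size destroys co-localization", {
  spc <- c(0.2, 0.1, 0.1)
  d <- c(24, 60, 60)
  cell <- binaryVolume(array(TRUE, d), spc)
  # regular grid of clusters with 2 um pitch, radius 0.25 um
  ctr <- array(FALSE, d)
  ctr[12, seq(10, 50, by = 20), seq(10, 50, by = 20)] <- TRUE
  fg <- ttquant:::.edt(ctr, spc) <= 0.25
  a <- detectClusters(binaryVolume(fg, spc), cell, "A")
  expect_equal(as.numeric(colocFraction(a, a)), 1)
  # half-pitch translation (1 um >> cluster diameter): zero overlap
  shifted <- array(FALSE, d)
  shifted[, 11:60, ] <- fg[, 1:50, ]
  b <- detectClusters(binaryVolume(shifted, spc), cell, "B")
  expect_equal(as.numeric(colocFraction(a, b)), 0)
})
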