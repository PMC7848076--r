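test_that("denoise preserves constants, removes impulses, reduces noise", {
  const <- imageStack(array(7, c(8, 8, 8)))
  expect_equal(voxelData(denoise(const, "median", 1)), voxelData(const))
  expect_equal(voxelData(denoise(const, "gaussian", 1)), voxelData(const),
               tolerance = 1e-12)

  hot <- array(10, c(8, 8, 8)); hot[4, 4, 4] <- 1000
  dn <- denoise(imageStack(hot), "median", 1)
  expect_equal(max(voxelData(dn)), 10)

  # Poisson-corrupted phantom: MSE against the clean image must drop
  set.seed(11)
  ctr <- c(8.5, 8.5, 8.5)
  clean <- array(20, c(16, 16, 16))
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    clean[i, j, k] <- 20 + 300 * exp(-sum((c(i, j, k) - ctr)^2) / 18)
  noisy <- array(rpois(length(clean), clean), dim(clean))
  dn2 <- denoise(imageStack(noisy), "median", 1)
  mseBefore <- mean((noisy - clean)^2)
  mseAfter <- mean((voxelData(dn2)[1, , , ] - clean)^2)
  expect_lt(mseAfter, mseBefore)
  expect_error(denoise(const, "median", 0), "radius")
})

test_that("Richardson-Lucy: point sources sharpen and flux is conserved", {
  spc <- c(0.2, 0.1, 0.1)
  psf <- psfModel(0.2, 0.4)
  pt <- array(0, c(24, 32, 32)); pt[12, 16, 16] <- 1000
  blurred <- applyImaging(imageStack(pt, spc), imagingSpec(
    psf = psf, poissonScale = 0, readNoiseSD = 0, background = 0, seed = 1))
  dec <- richardsonLucy(blurred, psf, 25)
  b <- voxelData(blurred)[1, , , ]; e <- voxelData(dec)[1, , , ]
  expect_gt(max(e), max(b))                         # peak restored
  fwhmVox <- function(v) sum(v > max(v) / 2)
  expect_lt(fwhmVox(e[12, 16, ]), fwhmVox(b[12, 16, ]))  # lateral FWHM shrinks
  expect_true(all(e >= 0))
  expect_lt(abs(sum(e) - sum(b)) / sum(b), 0.01)    # flux conserved < 1%
})

test_that("Richardson-Lucy resolves a two-point pair at 0.4 um", {
  spc <- c(0.2, 0.1, 0.1)
  psf <- psfModel(0.2, 0.4)
  pair <- array(0, c(16, 32, 32))
  pair[8, 14, 16] <- 1000; pair[8, 18, 16] <- 1000  # 0.4 um apart in y
  blurred <- applyImaging(imageStack(pair, spc), imagingSpec(
    psf = psf, poissonScale = 0, readNoiseSD = 0, background = 0, seed = 1))
  dec <- richardsonLucy(blurred, psf, 60, stopTol = 0)
  prof <- voxelData(dec)[1, 8, , 16]
  valley <- min(prof[14:18]); peak <- max(prof[14:18])
  expect_lt(valley, 0.8 * peak)
  expect_error(richardsonLucy(blurred, psf, 0), "iterations")
})

test_that("depth correction flattens exponential attenuation", {
  spc <- c(0.2, 0.1, 0.1)
  nz <- 60
  slab <- array(0, c(nz, 24, 24))
  slab[, 5:20, 5:20] <- 100                    # homogeneous bright slab
  z_um <- (seq_len(nz) - 1) * spc[1L]
  att <- slab * array(rep(exp(-z_um / 20), 24 * 24), dim(slab))
  set.seed(12)
  att <- array(rpois(length(att), att), dim(att))  # shot noise
  st <- imageStack(att, spc)
  corr <- correctDepthAttenuation(st, "exponential_fit")
  g <- attr(corr, "depth_gains")[["1"]]
  expect_true(all(g >= 1 - 1e-12))
  # recovered decay length within 10% of 20 um
  fit <- lm(log(g) ~ z_um)
  expect_equal(1 / coef(fit)[[2]], 20, tolerance = 0.1)
  # corrected plane means flat within 5%
  pm <- apply(voxelData(corr)[1, , , ], 1, function(p) mean(p[p > 50]))
  expect_lt((max(pm) - min(pm)) / mean(pm), 0.05)
  # no monotone trend left
  expect_lt(abs(cor(pm, seq_len(nz), method = "spearman")), 0.2)
  # idempotence: a second pass changes almost nothing
  corr2 <- correctDepthAttenuation(corr, "exponential_fit")
  rms <- sqrt(mean((voxelData(corr2) - voxelData(corr))^2)) /
         sqrt(mean(voxelData(corr)^2))
  expect_lt(rms, 0.01)
})

test_that("depth correction is a no-op without attenuation", {
  spc <- c(0.2, 0.1, 0.1)
  slab <- array(0, c(12, 16, 16)); slab[, 4:12, 4:12] <- 100
  st <- imageStack(slab, spc)
  corr <- correctDepthAttenuation(st, "exponential_fit")
  expect_equal(voxelData(corr), voxelData(st), tolerance = 1e-6)
  expect_error(correctDepthAttenuation(imageStack(array(0, c(8, 4, 4)))),
               "all-zero")
})

test_that("linear unmixing inverts spill-over exactly in the noiseless case", {
  set.seed(3)
  d <- c(2, 6, 10, 10)
  pure <- array(0, d)
  pure[1, , 3:6, ] <- 100 * runif(6 * 4 * 10)
  pure[2, , 7:9, ] <- 80 * runif(6 * 3 * 10)
  s <- imageStack(pure, channelNames = c("A", "B"))

  M <- matrix(c(1, 0.3, 0, 1), 2, 2)  # column j = fluorophore j's spread
  mixed <- voxelData(s)
  X <- rbind(as.vector(mixed[1, , , ]), as.vector(mixed[2, , , ]))
  Xm <- M %*% X
  sm <- s
  vm <- voxelData(sm); vm[1, , , ] <- Xm[1, ]; vm[2, , , ] <- Xm[2, ]
  sm@voxels <- vm
  un <- linearUnmix(sm, M)
  expect_lt(max(abs(voxelData(un) - pure)) / max(pure), 1e-6)

  # identity matrix: no change
  expect_equal(voxelData(linearUnmix(s, diag(2))), voxelData(s))
  # symmetric strong mixing also inverts exactly
  M2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  Xm2 <- M2 %*% X
  vm[1, , , ] <- Xm2[1, ]; vm[2, , , ] <- Xm2[2, ]
  sm@voxels <- vm
  un2 <- linearUnmix(sm, M2)
  expect_lt(max(abs(voxelData(un2) - pure)) / max(pure), 1e-6)
  expect_error(linearUnmix(s, matrix(c(1, 1, 1, 1), 2, 2)), "singular")
})

test_that("RL with a delta PSF is the identity", {
  set.seed(4)
  s <- imageStack(array(runif(6 * 8 * 8, 0, 50), c(6, 8, 8)))
  delta <- psfModel(1e-4, 1e-4)  # kernel collapses to a single voxel
  dec <- richardsonLucy(s, delta, 10)
  expect_equal(voxelData(dec), voxelData(s), tolerance = 1e-8)
})
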