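test_that("integer stacks round-trip through TIFF bit-exactly", {
  set.seed(1)
  vox <- array(sample(0:65535, 2 * 6 * 8 * 10, replace = TRUE),
               c(2, 6, 8, 10))
  s <- imageStack(vox, spacing = c(0.2, 0.1, 0.1),
                  channelNames = c("membrane", "WGA"))
  path <- tempfile(fileext = ".tif")
  writeStack(s, path)
  r <- readStack(path)
  expect_identical(voxelData(r), voxelData(s))
  expect_equal(spacing(r), c(0.2, 0.1, 0.1))
  expect_equal(channelNames(r), c("membrane", "WGA"))
  unlink(c(path, paste0(path, ".json")))
})

test_that("float stacks round-trip within storage precision", {
  set.seed(2)
  vox <- array(runif(4 * 5 * 6, 0, 837.3), c(1, 4, 5, 6))
  s <- imageStack(vox)
  path <- tempfile(fileext = ".tif")
  writeStack(s, path)
  r <- readStack(path)
  expect_lt(max(abs(voxelData(r) - vox)) / max(vox), 1e-6)
  unlink(c(path, paste0(path, ".json")))
})

test_that("spacing resolution: override wins, absence errors", {
  m <- matrix(runif(64), 8, 8)
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, path)  # plain TIFF, no metadata
  r <- readStack(path, spacingOverride = c(0.3, 0.15, 0.15))
  expect_equal(spacing(r), c(0.3, 0.15, 0.15))
  expect_error(readStack(path), "spacing")
  expect_error(readStack(tempfile()), "not found")
  unlink(path)
})

test_that("OME-XML ImageDescription yields spacing and channel names", {
  desc <- paste0(
    '<?xml version="1.0"?><OME><Image><Pixels SizeC="2" SizeZ="4" ',
    'PhysicalSizeX="0.1" PhysicalSizeY="0.1" PhysicalSizeZ="0.2">',
    '<Channel Name="membrane"/><Channel Name="WGA"/>',
    '</Pixels></Image></OME>')
  meta <- ttquant:::.parseStackMetadata(desc)
  expect_equal(meta$spacing, c(0.2, 0.1, 0.1))
  expect_equal(meta$n_channels, 2L)
  expect_equal(meta$channel_names, c("membrane", "WGA"))
})

test_that("label volumes are relabeled to contiguous ids and round-trip", {
  arr <- array(0L, c(4, 6, 6))
  arr[1:2, 1:3, 1:3] <- 3L
  arr[3:4, 4:6, 4:6] <- 7L
  lv <- labelVolume(arr, spacing = c(0.2, 0.1, 0.1))
  expect_setequal(unique(as.integer(labelData(lv))), c(0L, 1L, 2L))
  path <- tempfile(fileext = ".tif")
  writeLabelVolume(lv, path)
  r <- readLabelVolume(path)
  expect_identical(labelData(r), labelData(lv))
  # import guard: grid mismatch must fail
  ref <- imageStack(array(0, c(5, 6, 6)))
  expect_error(importRefinedMasks(path, reference = ref), "shape")
  unlink(c(path, paste0(path, ".json")))
})

test_that("metrics tables validate and round-trip through CSV", {
  tab <- data.frame(cell_id = c("1", "1", "2"), sample_id = "s1",
                    group = "control",
                    metric_name = c("tt_distance_mean", "tt_density",
                                    "tt_distance_mean"),
                    value = c(0.9, 2.1, 1.3),
                    units = c("um", "%", "um"),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  writeMetrics(tab, path)
  back <- readMetrics(path)
  expect_equal(back, tab)
  # empty table: header-only CSV
  writeMetrics(tab[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  # contract violations
  bad <- tab; bad$units[1] <- "furlong"
  expect_error(writeMetrics(bad, path), "units")
  dup <- tab; dup$metric_name[3] <- "tt_density"; dup$cell_id[3] <- "1"
  expect_error(writeMetrics(dup, path), "unique")
  unlink(path)
})

test_that("accessors and validity catch malformed objects", {
  s <- imageStack(array(0, c(2, 4, 4)), channelNames = "membrane")
  expect_equal(dim(getChannel(s, "membrane")), c(2, 4, 4))
  expect_error(getChannel(s, "WGA"), "not found")
  expect_error(imageStack(array(0, c(1, 2, 2, 2)), spacing = c(0, 0.1, 0.1)),
               "spacing")
  expect_error(imageStack(array(0, c(1, 2, 2, 2)),
                          channelNames = c("a", "b")), "channel")
})
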