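#' Detect protein clusters by connected-component analysis
#'
#' Connected components of the thresholded protein channel inside the cell
#' mask, filtered by a minimum size. Labels are deterministic: clusters are
#' numbered by the `(z, y, x)` position of their first voxel.
#'
#' @param channelFg a [BinaryVolume]: thresholded protein channel.
#' @param cellMask a [BinaryVolume]: the cell footprint.
#' @param protein protein name stored in the result (e.g. `"LTCC"`).
#' @param connectivity 6 or 26 (default 26).
#' @param minClusterVoxels reject components smaller than this (default 4,
#'   which rejects single-voxel noise at 0.1 x 0.1 x 0.2 um spacing).
#' @return a [ClusterSet]; empty foreground gives an empty set.
#' @export
detectClusters <- function(channelFg, cellMask, protein = "protein",
                           connectivity = 26, minClusterVoxels = 4) {
  stopifnot(is(channelFg, "BinaryVolume"), is(cellMask, "BinaryVolume"))
  .checkSameGrid(channelFg@mask, cellMask@mask, "channelFg and cellMask")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  fg <- channelFg@mask & cellMask@mask
  d <- dim(fg)
  spc <- channelFg@spacing
  cellVol <- sum(cellMask@mask) * .voxelVolume(spc)
  lab <- cpp_label3d(fg, d, as.integer(connectivity))
  K <- max(lab)
  voxelIndex <- list()
  rows <- list()
  keep <- 0L
  if (K > 0L) {
    counts <- tabulate(lab[lab > 0L], K)
    ord <- which(counts >= minClusterVoxels)
    idxByLab <- split(which(lab > 0L), lab[lab > 0L])
    for (kk in ord) {
      idx <- idxByLab[[as.character(kk)]]
      keep <- keep + 1L
      iz <- (idx - 1L) %% d[1L]
      iy <- ((idx - 1L) %/% d[1L]) %% d[2L]
      ix <- (idx - 1L) %/% (d[1L] * d[2L])
      rows[[keep]] <- data.frame(
        id = keep, n_voxels = length(idx),
        volume = length(idx) * .voxelVolume(spc),
        cz = mean(iz) * spc[1L], cy = mean(iy) * spc[2L],
        cx = mean(ix) * spc[3L])
      voxelIndex[[keep]] <- as.integer(idx)
    }
  }
  clusters <- if (keep) do.call(rbind, rows) else
    data.frame(id = integer(0), n_voxels = integer(0), volume = numeric(0),
               cz = numeric(0), cy = numeric(0), cx = numeric(0))
  new("ClusterSet", protein = protein, clusters = clusters,
      voxelIndex = voxelIndex, dim = d, spacing = spc,
      cellVolume = cellVol)
}

#' Cluster density
#'
#' Number of clusters per cell volume, in clusters per um^3.
#'
#' @param cs a [ClusterSet].
#' @return density in um^-3.
#' @export
clusterDensity <- function(cs) {
  stopifnot(is(cs, "ClusterSet"))
  if (cs@cellVolume <= 0) stop("zero cell volume")
  nClusters(cs) / cs@cellVolume
}

#' Pairwise cluster co-localization fraction
#'
#' Fraction of clusters in `a` that share at least `minOverlapVoxels`
#' voxels with any cluster of `b`. Per-cluster overlap voxel counts and
#' overlap fractions (overlap / cluster volume) are returned in the
#' `"overlap"` attribute so that stricter criteria can be applied post hoc.
#'
#' @param a,b [ClusterSet] objects on the same grid (same cell).
#' @param minOverlapVoxels minimum shared voxels to call a pair
#'   co-localized (default 1: any shared voxel).
#' @return fraction in `[0, 1]` (NA when `a` is empty), with attribute
#'   `"overlap"` (data.frame: `id`, `overlap_voxels`, `overlap_fraction`).
#' @export
colocFraction <- function(a, b, minOverlapVoxels = 1) {
  stopifnot(is(a, "ClusterSet"), is(b, "ClusterSet"))
  if (!identical(a@dim, b@dim))
    stop("cluster sets live on different grids")
  occB <- logical(prod(a@dim))
  if (nClusters(b) > 0)
    occB[unlist(b@voxelIndex, use.names = FALSE)] <- TRUE
  nA <- nClusters(a)
  if (nA == 0) {
    out <- NA_real_
    attr(out, "overlap") <- data.frame(id = integer(0),
                                       overlap_voxels = integer(0),
                                       overlap_fraction = numeric(0))
    return(out)
  }
  ov <- vapply(a@voxelIndex, function(idx) sum(occB[idx]), integer(1L))
  hit <- ov >= minOverlapVoxels
  out <- mean(hit)
  attr(out, "overlap") <- data.frame(
    id = a@clusters$id, overlap_voxels = ov,
    overlap_fraction = ov / a@clusters$n_voxels)
  out
}

#' Intact EC-coupling junction fraction
#'
#' Percentage of LTCC clusters co-localized with at least one RyR cluster
#' and at least one JPH2 cluster: the measure of intact excitation-
#' contraction coupling junctions (dyads).
#'
#' @param ltcc,ryr,jph2 [ClusterSet] objects from the same cell.
#' @param minOverlapVoxels minimum shared voxels per pairing (default 1).
#' @return percentage in `[0, 100]`; `NA` with a warning when there are no
#'   LTCC clusters.
#' @export
intactJunctionFraction <- function(ltcc, ryr, jph2, minOverlapVoxels = 1) {
  stopifnot(is(ltcc, "ClusterSet"), is(ryr, "ClusterSet"),
            is(jph2, "ClusterSet"))
  if (nClusters(ltcc) == 0) {
    warning("no LTCC clusters: intact-junction fraction undefined")
    return(NA_real_)
  }
  ovR <- attr(colocFraction(ltcc, ryr, minOverlapVoxels), "overlap")
  ovJ <- attr(colocFraction(ltcc, jph2, minOverlapVoxels), "overlap")
  both <- ovR$overlap_voxels >= minOverlapVoxels &
          ovJ$overlap_voxels >= minOverlapVoxels
  100 * mean(both)
}

#' Process a raw three-channel junction stack for one cell
#'
#' The junction arm of the pipeline: median denoising, Richardson-Lucy
#' deconvolution (sub-resolution protein puncta lose most of their peak
#' intensity to the PSF, so deconvolution is required before thresholding),
#' per-channel Otsu threshold within the cell mask, speck removal and
#' connected-component cluster detection.
#'
#' @param stack a raw [ImageStack] with the protein channels.
#' @param cellMask a [BinaryVolume] cell footprint.
#' @param channels channel names (default `c("LTCC", "RyR", "JPH2")`).
#' @param rlIterations Richardson-Lucy iterations (default 30).
#' @param psf a [PSFModel].
#' @param denoiseRadius median filter radius (voxels).
#' @param minClusterVoxels,connectivity passed to [detectClusters()].
#' @param minOverlapVoxels passed to [junctionMetrics()].
#' @return list: `clusters` (named list of [ClusterSet]s) and `metrics`
#'   (see [junctionMetrics()]).
#' @export
processJunctionStack <- function(stack, cellMask,
                                 channels = c("LTCC", "RyR", "JPH2"),
                                 rlIterations = 30, psf = psfModel(),
                                 denoiseRadius = 1, minClusterVoxels = 4,
                                 connectivity = 26, minOverlapVoxels = 1) {
  stopifnot(is(stack, "ImageStack"), is(cellMask, "BinaryVolume"))
  pre <- stack
  if (denoiseRadius >= 1) pre <- denoise(pre, "median", denoiseRadius)
  if (rlIterations > 0) pre <- richardsonLucy(pre, psf, rlIterations,
                                              stopTol = 0)
  sets <- lapply(channels, function(ch) {
    v <- getChannel(pre, ch)
    fg <- v > .otsu(v[cellMask@mask])
    fg <- .dropSpecks(fg, minClusterVoxels)
    detectClusters(binaryVolume(fg, spacing(pre)), cellMask, protein = ch,
                   connectivity = connectivity,
                   minClusterVoxels = minClusterVoxels)
  })
  names(sets) <- channels
  metrics <- junctionMetrics(sets[[1L]], sets[[2L]], sets[[3L]],
                             minOverlapVoxels = minOverlapVoxels)
  list(clusters = sets, metrics = metrics)
}

#' Junction metrics for one cell
#'
#' Cluster densities per protein, pairwise co-localization fractions of
#' LTCC with RyR and JPH2, and the intact-junction percentage.
#'
#' @inheritParams intactJunctionFraction
#' @return named list: `density` (named numeric, um^-3), `coloc` (named
#'   numeric fractions), `intact_junction_fraction` (percent).
#' @export
junctionMetrics <- function(ltcc, ryr, jph2, minOverlapVoxels = 1) {
  dens <- c(LTCC = clusterDensity(ltcc), RyR = clusterDensity(ryr),
            JPH2 = clusterDensity(jph2))
  coloc <- c("LTCC->RyR" = as.numeric(colocFraction(ltcc, ryr,
                                                    minOverlapVoxels)),
             "LTCC->JPH2" = as.numeric(colocFraction(ltcc, jph2,
                                                     minOverlapVoxels)))
  ijf <- if (nClusters(ltcc) > 0)
    intactJunctionFraction(ltcc, ryr, jph2, minOverlapVoxels) else NA_real_
  list(density = dens, coloc = coloc, intact_junction_fraction = ijf)
}
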