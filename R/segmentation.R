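#' Histogram-based foreground threshold
#'
#' Separates signal from background by a global histogram threshold:
#' `"otsu"` (maximum between-class variance on a 256-bin histogram) for
#' membrane and protein channels, or `"mode_plus_k_sd"` (histogram mode plus
#' `k` standard deviations) as used for WGA-stained tissue. The threshold
#' used is recorded in the result's `metadata`.
#'
#' @param image 3D numeric array `(z, y, x)` or an [ImageStack] channel.
#' @param method `"otsu"` or `"mode_plus_k_sd"`.
#' @param k multiplier on the standard deviation for `"mode_plus_k_sd"`.
#' @param spacing `(dz, dy, dx)` um of `image`.
#' @return a [BinaryVolume]; voxels strictly above the threshold are
#'   foreground, and `metadata(threshold)` records the cut.
#' @export
histogramThreshold <- function(image, method = c("otsu", "mode_plus_k_sd"),
                               k = 1, spacing = c(0.2, 0.1, 0.1)) {
  method <- match.arg(method)
  stopifnot(length(dim(image)) == 3L)
  thr <- switch(method,
    otsu = .otsu(image),
    mode_plus_k_sd = .histMode(image) + k * stats::sd(image))
  binaryVolume(image > thr, spacing = spacing,
               metadata = list(threshold = thr, method = method))
}

#' Watershed segmentation of cells from a membrane channel
#'
#' Deterministic replacement for manually refined watershed segmentation.
#' Automatic seeding is topological: the membrane channel is thresholded
#' (Otsu), small specks are discarded, the extracellular bath is identified
#' as the non-membrane region connected to the stack border, and every
#' enclosed non-membrane component (a cell interior, regardless of how
#' dense its t-tubule network is) becomes one cell seed. A 3D priority-
#' flood watershed on the Gaussian-smoothed intensity then assigns every
#' voxel to a basin. Basins that cover a large share of the stack border
#' are the bath and are dropped, as are segments smaller than
#' `minCellVolume`.
#'
#' @param membrane 3D numeric array `(z, y, x)`: preprocessed membrane
#'   channel.
#' @param spacing `(dz, dy, dx)` in um.
#' @param seeds optional [LabelVolume] of markers (one per cell); labels are
#'   preserved up to renumbering.
#' @param minCellVolume minimum segment volume in um^3 (default 500).
#' @param smoothSigma Gaussian sigma in um for the flooding surface.
#' @param minSeedVolume discard enclosed seed pockets smaller than this
#'   (um^3).
#' @param sealRadius morphological closing radius (um) applied to the
#'   thresholded membrane before the bath/interior decomposition, sealing
#'   pinholes left by noise.
#' @param dropBorderBackground drop basins covering > 10% of the stack
#'   border (the extracellular bath).
#' @param claimMembrane after dropping the bath, re-flood membrane voxels
#'   that fell into the bath basin (the outer half of each surface shell)
#'   from the surviving cells, so a cell label covers its full footprint
#'   including the membrane. Disable to cut cells at the wall-intensity
#'   ridge instead (the choice made by the per-cell metrics pipeline, whose
#'   surface/t-system split assumes a ridge-cut mask).
#' @return a [LabelVolume] with one label per retained cell.
#' @export
watershedCells <- function(membrane, spacing = c(0.2, 0.1, 0.1), seeds = NULL,
                           minCellVolume = 500, smoothSigma = 0.8,
                           minSeedVolume = 1, sealRadius = 0.3,
                           dropBorderBackground = TRUE,
                           claimMembrane = TRUE) {
  stopifnot(length(dim(membrane)) == 3L)
  if (all(membrane == 0)) stop("empty membrane signal")
  d <- dim(membrane)
  sm <- .gaussSmooth(membrane, smoothSigma, spacing)
  if (is.null(seeds)) {
    fg <- membrane > .otsu(membrane)
    fg <- .dropSpecks(fg, 8L)
    # seal pinholes in the thresholded membrane so the bath cannot leak
    # into cell interiors through single-voxel noise gaps
    dil <- .edt(fg, spacing) <= sealRadius
    fg <- (.edt(!dil, spacing) > sealRadius) | fg
    open <- cpp_label3d(!fg, d, 6L)
    borderIds <- unique(c(open[1, , ], open[d[1L], , ], open[, 1, ],
                          open[, d[2L], ], open[, , 1], open[, , d[3L]]))
    borderIds <- borderIds[borderIds > 0L]
    ids <- seq_len(max(open))
    isBath <- ids %in% borderIds
    counts <- tabulate(open[open > 0L], max(open))
    bigEnough <- counts * .voxelVolume(spacing) >= minSeedVolume
    keepId <- ids[(!isBath & bigEnough) | isBath]
    if (!any(!isBath & bigEnough))
      stop("no enclosed cell interior found; supply seeds")
    remap <- integer(max(open))
    remap[keepId] <- seq_along(keepId)
    seedLab <- array(0L, d)
    pos <- open > 0L & open %in% keepId
    seedLab[pos] <- remap[open[pos]]
  } else {
    stopifnot(is(seeds, "LabelVolume"))
    .checkSameGrid(membrane, seeds@labels, "membrane and seeds")
    seedLab <- seeds@labels
  }
  lab <- cpp_watershed(sm, as.integer(seedLab), d)
  if (dropBorderBackground && is.null(seeds)) {
    border <- .borderLabels(lab)
    for (b in border$drop) lab[lab == b] <- 0L
    # membrane voxels lost to the bath basin (the outer half of each cell's
    # surface shell) are re-flooded from the surviving cell basins
    if (claimMembrane && length(border$drop) && max(lab) > 0L &&
        any(fg & lab == 0L)) {
      lab <- cpp_watershed(sm, lab, d, mask = fg & lab == 0L)
    }
  }
  voxVol <- .voxelVolume(spacing)
  if (max(lab) > 0L) {
    counts <- tabulate(lab[lab > 0L], max(lab))
    small <- which(counts * voxVol < minCellVolume)
    for (s in small) lab[lab == s] <- 0L
  }
  labelVolume(lab, spacing = spacing)
}

# Labels covering more than 10% of the stack border are the bath/background.
.borderLabels <- function(lab) {
  d <- dim(lab)
  borderVox <- c(lab[1, , ], lab[d[1L], , ], lab[, 1, ], lab[, d[2L], ],
                 lab[, , 1], lab[, , d[3L]])
  nBorder <- length(borderVox)
  tab <- table(borderVox[borderVox > 0L])
  drop <- as.integer(names(tab)[tab / nBorder > 0.10])
  list(drop = drop, counts = tab)
}

#' Import externally refined cell masks
#'
#' Reads a label TIFF (e.g. exported, manually refined and saved in an
#' external editor), validates its grid against a reference, and relabels
#' to contiguous integers.
#'
#' @param path label TIFF path.
#' @param reference optional [ImageStack] or [LabelVolume] whose spatial
#'   grid the file must match.
#' @param spacingOverride optional spacing when the file has no metadata.
#' @return a [LabelVolume].
#' @export
importRefinedMasks <- function(path, reference = NULL,
                               spacingOverride = NULL) {
  lab <- readLabelVolume(path, spacingOverride = spacingOverride)
  if (!is.null(reference)) {
    refDim <- if (is(reference, "ImageStack")) dim(reference@voxels)[-1L]
              else dim(reference@labels)
    if (!identical(dim(lab@labels), refDim))
      stop("imported mask shape (", paste(dim(lab@labels), collapse = "x"),
           ") does not match the reference stack (",
           paste(refDim, collapse = "x"), ")")
  }
  lab
}

#' Morphological closing of a cell mask with a Euclidean ball
#'
#' Closing (dilation followed by erosion) with a metric ball of radius
#' `radius` um. Both operations are realized through the anisotropic
#' Euclidean distance transform, so the structuring element is a true
#' physical sphere regardless of voxel anisotropy. The result always
#' contains the input.
#'
#' @param mask a [BinaryVolume].
#' @param radius closing radius in um (>= 0; 0 is the identity).
#' @return the closed [BinaryVolume].
#' @export
closeCellMask <- function(mask, radius) {
  stopifnot(is(mask, "BinaryVolume"), radius >= 0)
  if (radius == 0 || !any(mask@mask)) return(mask)
  dil <- .edt(mask@mask, mask@spacing) <= radius
  closed <- .edt(!dil, mask@spacing) > radius
  binaryVolume(closed | mask@mask, spacing = mask@spacing,
               metadata = c(mask@metadata, list(closed_radius_um = radius)))
}

#' Classify membrane voxels into surface sarcolemma vs t-system
#'
#' Membrane foreground inside the cell mask is split by depth below the mask
#' boundary: voxels within `shellDepth` um of the boundary are surface
#' membrane, deeper voxels are t-system. The two classes partition the
#' in-cell membrane foreground and are disjoint by construction; a larger
#' shell depth can only move voxels from t-system to surface.
#'
#' @param cellMask a [BinaryVolume]: the (closed) cell footprint.
#' @param membraneFg a [BinaryVolume]: membrane foreground from
#'   [histogramThreshold()].
#' @param shellDepth surface shell depth in um (default 0.5).
#' @param cellId integer id stored in the result.
#' @return a [CellSegmentation].
#' @export
classifyMembrane <- function(cellMask, membraneFg, shellDepth = 0.5,
                             cellId = 1L) {
  stopifnot(is(cellMask, "BinaryVolume"), is(membraneFg, "BinaryVolume"))
  .checkSameGrid(cellMask@mask, membraneFg@mask, "cellMask and membraneFg")
  if (!any(cellMask@mask)) stop("empty cell mask")
  depth <- .edt(!cellMask@mask, cellMask@spacing)  # distance to outside
  shell <- cellMask@mask & depth <= shellDepth
  mem <- membraneFg@mask & cellMask@mask
  surf <- mem & shell
  tsys <- mem & !shell
  new("CellSegmentation", cellId = as.integer(cellId),
      cellMask = cellMask,
      surfaceMembrane = binaryVolume(surf, cellMask@spacing),
      tSystem = binaryVolume(tsys, cellMask@spacing))
}

#' Extract one cell's closed mask from a label volume
#'
#' Convenience wrapper: selects label `id`, keeps its largest 26-connected
#' component and applies [closeCellMask()].
#'
#' @param labels a [LabelVolume].
#' @param id the cell label to extract.
#' @param closeRadius closing radius in um.
#' @return a [BinaryVolume].
#' @export
extractCellMask <- function(labels, id, closeRadius = 0.5) {
  stopifnot(is(labels, "LabelVolume"))
  m <- labels@labels == id
  if (!any(m)) stop("label ", id, " not present")
  m <- .largestComponent(m)
  closeCellMask(binaryVolume(m, labels@spacing), closeRadius)
}
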