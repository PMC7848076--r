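#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib ttquant, .registration = TRUE
NULL

.validSpacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    return("'spacing' must be three strictly positive finite numbers (dz, dy, dx) in micrometers")
  }
  NULL
}

#' ImageStack: a multichannel 3D voxel grid with physical spacing
#'
#' The universal carrier between pipeline stages. Voxels are stored as a 4D
#' array indexed `(channel, z, y, x)`; `z` is the optical (depth) axis.
#' Physical positions are voxel centers at `index * spacing` (0-based
#' indices), and spacing is `(dz, dy, dx)` in micrometers. The default
#' confocal geometry is anisotropic, `(0.2, 0.1, 0.1)` um.
#'
#' @slot voxels 4D numeric array `(channel, z, y, x)`, finite and
#'   non-negative intensities.
#' @slot spacing numeric(3), `(dz, dy, dx)` in um, all > 0.
#' @slot channelNames character vector, one name per channel (e.g.
#'   `"membrane"`, `"WGA"`, `"LTCC"`, `"RyR"`, `"JPH2"`).
#' @slot dtype character, the storage type the stack had on disk
#'   (`"uint8"`, `"uint16"` or `"float"`); intensities are always promoted
#'   to double in memory.
#'
#' @export
setClass("ImageStack",
  representation(voxels = "array", spacing = "numeric",
                 channelNames = "character", dtype = "character"),
  prototype(spacing = c(0.2, 0.1, 0.1), dtype = "float"))

setValidity("ImageStack", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 4L)
    msgs <- c(msgs, "'voxels' must be a 4D array (channel, z, y, x)")
  msgs <- c(msgs, .validSpacing(object@spacing))
  if (length(dim(object@voxels)) == 4L &&
      length(object@channelNames) != dim(object@voxels)[1L])
    msgs <- c(msgs, "length(channelNames) must equal the channel axis length")
  if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
    msgs <- c(msgs, "'voxels' must be finite")
  if (length(msgs)) msgs else TRUE
})

#' BinaryVolume: a 3D boolean mask with physical spacing
#'
#' @slot mask logical 3D array `(z, y, x)`.
#' @slot spacing numeric(3), `(dz, dy, dx)` in um.
#' @slot metadata list of provenance items (e.g. the threshold used).
#'
#' @export
setClass("BinaryVolume",
  representation(mask = "array", spacing = "numeric", metadata = "list"),
  prototype(spacing = c(0.2, 0.1, 0.1), metadata = list()))

setValidity("BinaryVolume", function(object) {
  msgs <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msgs <- c(msgs, "'mask' must be a logical 3D array (z, y, x)")
  msgs <- c(msgs, .validSpacing(object@spacing))
  if (length(msgs)) msgs else TRUE
})

#' LabelVolume: a 3D integer label image (0 = background)
#'
#' Labels identify segmented cells; the label set is always relabeled to
#' `{0} U {1..K}` on construction or import.
#'
#' @slot labels integer 3D array `(z, y, x)`, non-negative.
#' @slot spacing numeric(3), `(dz, dy, dx)` in um.
#'
#' @export
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric"),
  prototype(spacing = c(0.2, 0.1, 0.1)))

setValidity("LabelVolume", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "'labels' must be a 3D array (z, y, x)")
  if (anyNA(object@labels) || any(object@labels < 0))
    msgs <- c(msgs, "labels must be non-negative integers")
  u <- sort(unique(as.integer(object@labels)))
  u <- u[u > 0]
  if (length(u) && !identical(u, seq_along(u)))
    msgs <- c(msgs, "positive labels must be contiguous 1..K")
  msgs <- c(msgs, .validSpacing(object@spacing))
  if (length(msgs)) msgs else TRUE
})

#' CellSegmentation: one cell's mask and membrane classification
#'
#' Holds the morphologically closed cell footprint together with the
#' partition of its membrane foreground into surface sarcolemma (within a
#' shell of configurable depth below the mask boundary) and t-system
#' (membrane deeper inside the cell). The two membrane classes are disjoint
#' by construction.
#'
#' @slot cellId integer cell identifier.
#' @slot cellMask [BinaryVolume] closed cell footprint
#'   (single 26-connected component).
#' @slot surfaceMembrane [BinaryVolume] membrane voxels in the boundary shell.
#' @slot tSystem [BinaryVolume] membrane voxels in the cell interior.
#'
#' @export
setClass("CellSegmentation",
  representation(cellId = "integer", cellMask = "BinaryVolume",
                 surfaceMembrane = "BinaryVolume", tSystem = "BinaryVolume"))

setValidity("CellSegmentation", function(object) {
  msgs <- character()
  dm <- dim(object@cellMask@mask)
  if (!identical(dm, dim(object@surfaceMembrane@mask)) ||
      !identical(dm, dim(object@tSystem@mask)))
    msgs <- c(msgs, "cellMask, surfaceMembrane and tSystem must share one grid")
  if (any(object@surfaceMembrane@mask & object@tSystem@mask))
    msgs <- c(msgs, "surfaceMembrane and tSystem must be disjoint")
  if (any(object@tSystem@mask & !object@cellMask@mask))
    msgs <- c(msgs, "tSystem must lie inside cellMask")
  if (length(msgs)) msgs else TRUE
})

#' ClusterSet: connected components of one protein channel inside one cell
#'
#' @slot protein character, e.g. `"LTCC"`, `"RyR"` or `"JPH2"`.
#' @slot clusters data.frame with one row per cluster: `id`, `n_voxels`,
#'   `volume` (um^3) and centroid coordinates `cz`, `cy`, `cx` (um).
#' @slot voxelIndex list of integer vectors; linear voxel indices
#'   (into the `(z, y, x)` grid) of each cluster.
#' @slot dim integer(3), grid dimensions `(z, y, x)`.
#' @slot spacing numeric(3), `(dz, dy, dx)` in um.
#' @slot cellVolume numeric, cell volume in um^3.
#'
#' @export
setClass("ClusterSet",
  representation(protein = "character", clusters = "data.frame",
                 voxelIndex = "list", dim = "integer", spacing = "numeric",
                 cellVolume = "numeric"))

setValidity("ClusterSet", function(object) {
  msgs <- character()
  if (nrow(object@clusters) != length(object@voxelIndex))
    msgs <- c(msgs, "one voxelIndex entry per cluster row required")
  if (length(object@voxelIndex) > 1L) {
    all_idx <- unlist(object@voxelIndex, use.names = FALSE)
    if (anyDuplicated(all_idx))
      msgs <- c(msgs, "clusters must be pairwise disjoint")
  }
  msgs <- c(msgs, .validSpacing(object@spacing))
  if (length(msgs)) msgs else TRUE
})

#' PSFModel: anisotropic Gaussian point-spread-function model
#'
#' The restoration pipeline models the confocal PSF as an
#' anisotropic 3D Gaussian; defaults (`sigmaLateral` 0.15 um, `sigmaAxial`
#' 0.45 um) are typical for an NA 1.4 oil objective.
#'
#' @slot sigmaLateral numeric, lateral (x, y) standard deviation in um.
#' @slot sigmaAxial numeric, axial (z) standard deviation in um.
#' @slot truncate numeric, kernel truncation radius in multiples of sigma.
#'
#' @export
setClass("PSFModel",
  representation(sigmaLateral = "numeric", sigmaAxial = "numeric",
                 truncate = "numeric"),
  prototype(sigmaLateral = 0.15, sigmaAxial = 0.45, truncate = 3))

setValidity("PSFModel", function(object) {
  # zero sigmas denote a delta PSF (used by the imaging forward model)
  if (object@sigmaLateral < 0 || object@sigmaAxial < 0 ||
      object@truncate <= 0)
    "sigmas must be >= 0 and the truncation radius > 0" else TRUE
})

#' PSFModel constructor
#' @param sigmaLateral lateral standard deviation (um).
#' @param sigmaAxial axial standard deviation (um).
#' @param truncate truncation radius in multiples of sigma.
#' @return a [PSFModel] object.
#' @examples
#' psfModel(0.15, 0.45)
#' @export
psfModel <- function(sigmaLateral = 0.15, sigmaAxial = 0.45, truncate = 3) {
  new("PSFModel", sigmaLateral = sigmaLateral, sigmaAxial = sigmaAxial,
      truncate = truncate)
}

#' ImageStack constructor
#'
#' @param voxels 4D array `(channel, z, y, x)` or 3D array `(z, y, x)` for a
#'   single channel.
#' @param spacing `(dz, dy, dx)` in um.
#' @param channelNames channel names; defaults to `"ch1"`, ... .
#' @param dtype storage dtype tag.
#' @return an [ImageStack].
#' @examples
#' s <- imageStack(array(0, c(4, 8, 8)), spacing = c(0.2, 0.1, 0.1))
#' @export
imageStack <- function(voxels, spacing = c(0.2, 0.1, 0.1),
                       channelNames = NULL, dtype = "float") {
  if (length(dim(voxels)) == 3L)
    dim(voxels) <- c(1L, dim(voxels))
  storage.mode(voxels) <- "double"
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(voxels)[1L]))
  new("ImageStack", voxels = voxels, spacing = as.numeric(spacing),
      channelNames = as.character(channelNames), dtype = dtype)
}

#' BinaryVolume constructor
#' @param mask logical 3D array `(z, y, x)`.
#' @param spacing `(dz, dy, dx)` in um.
#' @param metadata optional provenance list.
#' @return a [BinaryVolume].
#' @export
binaryVolume <- function(mask, spacing = c(0.2, 0.1, 0.1), metadata = list()) {
  storage.mode(mask) <- "logical"
  new("BinaryVolume", mask = mask, spacing = as.numeric(spacing),
      metadata = metadata)
}

#' LabelVolume constructor
#' @param labels integer 3D array `(z, y, x)`; relabeled to contiguous 1..K.
#' @param spacing `(dz, dy, dx)` in um.
#' @return a [LabelVolume].
#' @export
labelVolume <- function(labels, spacing = c(0.2, 0.1, 0.1)) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(as.integer(labels)))
  u <- u[u > 0]
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
  }
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing))
}
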