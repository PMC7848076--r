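#' Accessors for ttquant data objects
#'
#' `spacing` returns the `(dz, dy, dx)` voxel spacing in um; `voxelData`,
#' `maskData` and `labelData` return the underlying arrays; `channelNames`
#' returns channel labels and `getChannel` extracts one channel as a 3D
#' array `(z, y, x)`.
#'
#' @param x a ttquant data object.
#' @param channel channel name or index.
#' @return the requested slot content (see Details above).
#' @name accessors
#' @aliases spacing
#' @examples
#' s <- imageStack(array(0, c(4, 8, 8)))
#' spacing(s)
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("surfaceMembrane", function(x) standardGeneric("surfaceMembrane"))
#' @rdname accessors
#' @export
setGeneric("tSystem", function(x) standardGeneric("tSystem"))

#' @rdname accessors
setMethod("spacing", "ImageStack", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "LabelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "CellSegmentation", function(x) x@cellMask@spacing)
#' @rdname accessors
setMethod("spacing", "ClusterSet", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelData", "ImageStack", function(x) x@voxels)
#' @rdname accessors
setMethod("maskData", "BinaryVolume", function(x) x@mask)
#' @rdname accessors
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)
#' @rdname accessors
setMethod("getChannel", "ImageStack", function(x, channel) {
  if (is.character(channel)) {
    i <- match(channel, x@channelNames)
    if (is.na(i))
      stop("channel '", channel, "' not found; available: ",
           paste(x@channelNames, collapse = ", "))
  } else {
    i <- as.integer(channel)
  }
  arr <- x@voxels[i, , , , drop = FALSE]
  dim(arr) <- dim(x@voxels)[-1L]
  arr
})
#' @rdname accessors
setMethod("nClusters", "ClusterSet", function(x) nrow(x@clusters))
#' @rdname accessors
setMethod("clusterTable", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
setMethod("cellMask", "CellSegmentation", function(x) x@cellMask)
#' @rdname accessors
setMethod("surfaceMembrane", "CellSegmentation", function(x) x@surfaceMembrane)
#' @rdname accessors
setMethod("tSystem", "CellSegmentation", function(x) x@tSystem)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack:", d[1L], "channel(s),",
      paste(d[-1L], collapse = " x "), "(z y x) voxels\n")
  cat("  spacing (dz, dy, dx):", paste(object@spacing, collapse = ", "),
      "um\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "BinaryVolume", function(object) {
  cat("BinaryVolume:", paste(dim(object@mask), collapse = " x "),
      "(z y x);", sum(object@mask), "foreground voxels\n")
  invisible(NULL)
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume:", paste(dim(object@labels), collapse = " x "),
      "(z y x);", max(object@labels), "label(s)\n")
  invisible(NULL)
})

setMethod("show", "CellSegmentation", function(object) {
  cat("CellSegmentation: cell", object@cellId, "\n")
  cat("  cell mask:", sum(object@cellMask@mask), "voxels; surface membrane:",
      sum(object@surfaceMembrane@mask), "voxels; t-system:",
      sum(object@tSystem@mask), "voxels\n")
  invisible(NULL)
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@clusters), object@protein,
      "cluster(s) in a", round(object@cellVolume, 1), "um^3 cell\n")
  invisible(NULL)
})

setMethod("show", "PSFModel", function(object) {
  cat("PSFModel: Gaussian, sigma lateral", object@sigmaLateral,
      "um, axial", object@sigmaAxial, "um\n")
  invisible(NULL)
})
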