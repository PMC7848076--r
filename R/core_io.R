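#' Read a multichannel 3D image stack from TIFF / OME-TIFF
#'
#' Pages are interpreted as planes ordered channel-fastest (all channels of
#' z = 1, then z = 2, ...). Voxel spacing and channel layout are resolved,
#' in order of precedence, from (1) an explicit `spacingOverride`, (2) a
#' `ttquant` JSON block or OME-XML in the TIFF ImageDescription tag, or
#' (3) a sidecar JSON file `<path>.json` as written by [writeStack()]. If
#' the spacing cannot be resolved from any of these sources, reading fails:
#' all downstream measurements are denominated in micrometers and silently
#' assuming a spacing would corrupt them.
#'
#' @param path TIFF file path.
#' @param spacingOverride optional `(dz, dy, dx)` in um, overriding metadata.
#' @param channelNames optional channel names, overriding metadata.
#' @return an [ImageStack]; intensities are promoted to double.
#' @seealso [writeStack()]
#' @export
readStack <- function(path, spacingOverride = NULL, channelNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("not a readable TIFF file: ", path,
                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  meta <- .resolveStackMeta(path, pages, spacingOverride, channelNames)

  nC <- meta$n_channels
  nP <- length(pages)
  if (nP %% nC != 0L)
    stop("page count (", nP, ") is not a multiple of channel count (", nC, ")")
  nZ <- nP %/% nC
  d2 <- dim(pages[[1L]])
  vox <- array(0, c(nC, nZ, d2[1L], d2[2L]))
  for (p in seq_len(nP)) {
    ch <- (p - 1L) %% nC + 1L
    z <- (p - 1L) %/% nC + 1L
    vox[ch, z, , ] <- pages[[p]]
  }
  # pages are read normalized to [0, 1]; undo the storage scaling
  if (identical(meta$dtype, "float")) {
    if (!is.null(meta$scale) && meta$scale != 1) vox <- vox * meta$scale
  } else {
    bits <- attr(pages[[1L]], "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    vox <- round(vox * (2^bits - 1))
  }
  imageStack(vox, spacing = meta$spacing, channelNames = meta$channel_names,
             dtype = meta$dtype)
}

.resolveStackMeta <- function(path, pages, spacingOverride, channelNames) {
  desc <- attr(pages[[1L]], "description")
  meta <- NULL
  if (!is.null(desc)) meta <- .parseStackMetadata(desc)
  if (is.null(meta)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar))
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (is.null(meta)) meta <- list()
  if (!is.null(spacingOverride)) meta$spacing <- as.numeric(spacingOverride)
  if (is.null(meta$spacing))
    stop("voxel spacing not present in metadata of '", path,
         "' and no spacingOverride given")
  if (is.null(meta$n_channels)) meta$n_channels <- 1L
  meta$n_channels <- as.integer(meta$n_channels)
  if (!is.null(channelNames)) meta$channel_names <- channelNames
  if (is.null(meta$channel_names))
    meta$channel_names <- paste0("ch", seq_len(meta$n_channels))
  if (is.null(meta$dtype)) meta$dtype <- "float"
  meta
}

# Parse a TIFF ImageDescription: either the ttquant JSON block or a minimal
# subset of OME-XML (PhysicalSizeX/Y/Z in um, SizeC, channel names).
.parseStackMetadata <- function(desc) {
  desc <- paste(desc, collapse = "\n")
  if (grepl("\"ttquant\"", desc, fixed = TRUE)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    return(meta)
  }
  if (grepl("<OME", desc, fixed = TRUE) || grepl("PhysicalSize", desc)) {
    px <- .omeAttr(desc, "PhysicalSizeX")
    py <- .omeAttr(desc, "PhysicalSizeY")
    pz <- .omeAttr(desc, "PhysicalSizeZ")
    sc <- .omeAttr(desc, "SizeC")
    if (is.na(px) || is.na(py) || is.na(pz)) return(NULL)
    nm <- regmatches(desc, gregexpr('Channel[^>]*Name="([^"]*)"', desc))[[1L]]
    nm <- sub('.*Name="([^"]*)".*', "\\1", nm)
    list(spacing = c(pz, py, px),
         n_channels = if (is.na(sc)) max(1L, length(nm)) else as.integer(sc),
         channel_names = if (length(nm)) nm else NULL,
         dtype = "float", scale = NULL)
  } else {
    NULL
  }
}

.omeAttr <- function(desc, name) {
  m <- regmatches(desc, regexpr(paste0(name, '="[^"]*"'), desc))
  if (!length(m)) return(NA_real_)
  as.numeric(sub('.*="([^"]*)"', "\\1", m))
}

#' Write an ImageStack to a multi-page TIFF with sidecar metadata
#'
#' Planes are written channel-fastest. Integer-valued stacks that fit into
#' 16 bits are stored losslessly as 16-bit TIFF (the read-back is bit-exact);
#' other stacks are stored as 32-bit float scaled to `[0, 1]` with the scale
#' recorded in the metadata. Spacing, channel names, dtype and scale go into
#' `<path>.json`, because the underlying TIFF writer does not support the
#' ImageDescription tag.
#'
#' @param stack an [ImageStack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  vox <- stack@voxels
  d <- dim(vox)
  isInt <- all(vox == round(vox)) && min(vox) >= 0 && max(vox) <= 65535
  if (isInt) {
    scale <- 65535
    bits <- 16L
    dtype <- if (max(vox) <= 255) "uint8" else "uint16"
  } else {
    scale <- max(abs(vox), 1e-12)
    bits <- 32L
    dtype <- "float"
  }
  pages <- vector("list", d[1L] * d[2L])
  p <- 1L
  for (z in seq_len(d[2L])) {
    for (ch in seq_len(d[1L])) {
      pages[[p]] <- matrix(vox[ch, z, , ] / scale, d[3L], d[4L])
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  meta <- list(ttquant = 1L, spacing = stack@spacing, n_channels = d[1L],
               channel_names = stack@channelNames, dtype = dtype,
               scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write label volumes as 16-bit TIFF
#'
#' @param path TIFF path (sidecar `<path>.json` carries spacing).
#' @param spacingOverride optional `(dz, dy, dx)` um when no metadata exists.
#' @return `readLabelVolume`: a [LabelVolume] (labels relabeled to 1..K).
#' @export
readLabelVolume <- function(path, spacingOverride = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vals <- unlist(pages, use.names = FALSE)
  if (any(vals != round(vals)))
    stop("label TIFF contains non-integer values")
  sidecar <- paste0(path, ".json")
  spc <- spacingOverride
  if (is.null(spc) && file.exists(sidecar))
    spc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$spacing
  if (is.null(spc))
    stop("voxel spacing not present for '", path, "' and no override given")
  d2 <- dim(pages[[1L]])
  arr <- array(0L, c(length(pages), d2[1L], d2[2L]))
  for (z in seq_along(pages)) arr[z, , ] <- as.integer(pages[[z]])
  labelVolume(arr, spacing = spc)
}

#' @rdname readLabelVolume
#' @param labels a [LabelVolume].
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  arr <- labels@labels
  if (max(arr) > 65535) stop("more than 65535 labels cannot be stored in 16-bit TIFF")
  d <- dim(arr)
  pages <- lapply(seq_len(d[1L]), function(z) matrix(arr[z, , ] / 65535, d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(ttquant = 1L, spacing = labels@spacing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.metricsUnits <- c("um", "%", "um^2", "um^-3", "um^3")

#' Per-cell metrics tables
#'
#' A metrics table is a plain `data.frame` with columns `cell_id`,
#' `sample_id`, `group`, `metric_name`, `value` and `units`
#' (units one of um, %, um^2, um^-3, um^3); `(cell_id, metric_name)` pairs
#' are unique. `validateMetricsTable` checks the contract, `writeMetrics`
#' writes CSV, `readMetrics` reads it back.
#'
#' @param table a metrics data.frame.
#' @param path CSV path.
#' @return `writeMetrics`: `path` invisibly; `readMetrics`: the validated
#'   data.frame.
#' @export
writeMetrics <- function(table, path) {
  validateMetricsTable(table)
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cell_id = "character",
                                        sample_id = "character",
                                        group = "character",
                                        metric_name = "character",
                                        value = "numeric",
                                        units = "character"))
  validateMetricsTable(tab)
  tab
}

#' @rdname writeMetrics
#' @export
validateMetricsTable <- function(table) {
  need <- c("cell_id", "sample_id", "group", "metric_name", "value", "units")
  if (!all(need %in% names(table)))
    stop("metrics table must have columns: ", paste(need, collapse = ", "))
  if (nrow(table)) {
    key <- paste(table$cell_id, table$metric_name)
    if (anyDuplicated(key))
      stop("(cell_id, metric_name) must be unique in a metrics table")
    bad <- setdiff(unique(table$units), .metricsUnits)
    if (length(bad))
      stop("unknown units: ", paste(bad, collapse = ", "),
           " (allowed: ", paste(.metricsUnits, collapse = ", "), ")")
  }
  invisible(table)
}
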