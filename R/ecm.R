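#' Extracellular matrix volume fraction from a WGA channel
#'
#' Thresholds the WGA-stained tissue image at `histogram mode + k * SD`
#' (both computed over the analyzed region; the mode on a 256-bin histogram
#' over the intensity range, ties broken toward the lower bin) and reports
#' the above-threshold volume fraction as the ECM fraction, a fibrosis
#' surrogate.
#'
#' @param wga 3D numeric array `(z, y, x)`: the WGA channel.
#' @param roi optional [BinaryVolume] restricting the analysis (e.g. to
#'   exclude nuclei); default: the whole field.
#' @param k multiplier on the standard deviation (default 1).
#' @param spacing `(dz, dy, dx)` um.
#' @return list of class `"ECMResult"`: `ecm_fraction` (percent),
#'   `threshold_used` (intensity), `analyzed_volume` (um^3).
#' @export
ecmFraction <- function(wga, roi = NULL, k = 1, spacing = c(0.2, 0.1, 0.1)) {
  stopifnot(length(dim(wga)) == 3L)
  if (is.null(roi)) {
    sel <- rep(TRUE, length(wga))
  } else {
    stopifnot(is(roi, "BinaryVolume"))
    .checkSameGrid(wga, roi@mask, "wga and roi")
    sel <- as.vector(roi@mask)
  }
  vals <- wga[sel]
  if (!length(vals)) stop("empty ROI")
  thr <- .histMode(vals) + k * stats::sd(vals)
  frac <- 100 * mean(vals > thr)
  structure(list(ecm_fraction = frac, threshold_used = thr,
                 analyzed_volume = sum(sel) * .voxelVolume(spacing)),
            class = "ECMResult")
}

#' @export
print.ECMResult <- function(x, ...) {
  cat(sprintf("ECM fraction: %.2f%% (threshold %.3g, %.0f um^3 analyzed)\n",
              x$ecm_fraction, x$threshold_used, x$analyzed_volume))
  invisible(x)
}
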