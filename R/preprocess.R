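#' Denoise a confocal stack
#'
#' Channel-wise 3D noise filtering. The default is an edge-preserving median
#' filter of radius 1 voxel, appropriate for confocal shot noise on
#' sub-resolution structures such as t-tubules; a Gaussian filter (radius
#' interpreted as sigma in voxels) is available for smoother targets.
#'
#' @param stack an [ImageStack].
#' @param method `"median"` or `"gaussian"`.
#' @param radius window radius (median) or sigma (Gaussian), in voxels.
#' @return an [ImageStack] of identical shape and spacing; intensities stay
#'   non-negative.
#' @export
denoise <- function(stack, method = c("median", "gaussian"), radius = 1) {
  stopifnot(is(stack, "ImageStack"))
  method <- match.arg(method)
  if (radius < 1) stop("radius must be >= 1 voxel")
  vox <- stack@voxels
  d <- dim(vox)
  for (ch in seq_len(d[1L])) {
    v <- getChannel(stack, ch)
    if (method == "median") {
      v <- cpp_median3d(v, dim(v), rep(as.integer(radius), 3L))
    } else {
      v <- .gaussSmooth(v, radius * stack@spacing, stack@spacing)
    }
    vox[ch, , , ] <- pmax(v, 0)
  }
  initialize(stack, voxels = vox)
}

#' Richardson-Lucy deconvolution
#'
#' Multiplicative Richardson-Lucy updates with a Gaussian PSF model,
#' implemented with FFT convolutions under periodic boundary conditions so
#' that total intensity is conserved. Iteration stops at `iterations` or
#' earlier when the relative update falls below `stopTol`.
#'
#' @param stack an [ImageStack].
#' @param psf a [PSFModel].
#' @param iterations maximum number of iterations (>= 1); default 30.
#' @param stopTol early-stop threshold on the mean relative update.
#' @return the deconvolved [ImageStack] (non-negative).
#' @export
richardsonLucy <- function(stack, psf, iterations = 30, stopTol = 1e-4) {
  stopifnot(is(stack, "ImageStack"), is(psf, "PSFModel"))
  if (iterations < 1) stop("iterations must be >= 1")
  if (psf@sigmaLateral <= 0 || psf@sigmaAxial <= 0)
    stop("deconvolution requires strictly positive PSF sigmas")
  vox <- stack@voxels
  d <- dim(vox)
  k <- .gaussKernels1d(psf, stack@spacing)
  for (ch in seq_len(d[1L])) {
    obs <- getChannel(stack, ch)
    if (all(obs == 0)) next
    # symmetric Gaussian kernel: the flipped kernel equals the kernel
    est <- cpp_richardson_lucy(obs, dim(obs), k[[1L]], k[[2L]], k[[3L]],
                               as.integer(iterations), stopTol)
    vox[ch, , , ] <- est
  }
  initialize(stack, voxels = vox)
}

#' Correct depth-dependent signal attenuation
#'
#' Estimates per-plane foreground intensity (voxels above the per-plane Otsu
#' threshold) along the optical axis and applies a gain per z-plane.
#' `"exponential_fit"` fits `log(mean_z) ~ z` and applies the inverse
#' exponential; `"per_plane_normalization"` scales every plane to the
#' brightest plane's foreground mean. Gains are normalized so the minimum
#' gain is 1, i.e. intensity is only ever amplified.
#'
#' @param stack an [ImageStack].
#' @param mode `"exponential_fit"` (default) or `"per_plane_normalization"`.
#' @param channels channels to estimate and correct (default: all).
#' @return an [ImageStack] with the per-channel gains recorded in the
#'   attribute `"depth_gains"`.
#' @export
correctDepthAttenuation <- function(stack,
                                    mode = c("exponential_fit",
                                             "per_plane_normalization"),
                                    channels = NULL) {
  stopifnot(is(stack, "ImageStack"))
  mode <- match.arg(mode)
  if (all(stack@voxels == 0)) stop("all-zero stack: nothing to correct")
  d <- dim(stack@voxels)
  nz <- d[2L]
  if (nz < 4L) stop("need >= 4 z-planes for depth correction")
  if (is.null(channels)) channels <- seq_len(d[1L])
  vox <- stack@voxels
  gains <- list()
  for (ch in channels) {
    v <- getChannel(stack, ch)
    pm <- .planeForegroundMeans(v)
    ok <- is.finite(pm) & pm > 0
    if (sum(ok) < 4L) next
    if (mode == "exponential_fit") {
      z_um <- (seq_len(nz) - 1) * stack@spacing[1L]
      fit <- stats::lm(log(pm[ok]) ~ z_um[ok])
      slope <- stats::coef(fit)[[2L]]
      # only compensate decay; a non-attenuating stack gets unit gains
      g <- if (slope < 0) exp(-slope * z_um) else rep(1, nz)
    } else {
      g <- max(pm[ok]) / pm
      g[!ok] <- 1
    }
    g <- g / min(g)
    vox[ch, , , ] <- v * rep(g, times = prod(d[3:4]))
    gains[[as.character(ch)]] <- g
  }
  out <- initialize(stack, voxels = vox)
  attr(out, "depth_gains") <- gains
  out
}

.planeForegroundMeans <- function(v) {
  nz <- dim(v)[1L]
  vapply(seq_len(nz), function(z) {
    plane <- v[z, , ]
    if (diff(range(plane)) == 0) return(NA_real_)
    thr <- .otsu(plane)
    fg <- plane[plane > thr]
    if (!length(fg)) NA_real_ else mean(fg)
  }, numeric(1L))
}

#' Linear spectral unmixing
#'
#' Removes spill-over between fluorophores by applying the inverse of a
#' user-supplied mixing matrix `M` voxel-wise, where `M[i, j]` is the
#' fraction of fluorophore `j`'s signal recorded in channel `i`. Negative
#' unmixed intensities are clipped to 0; channels outside `channels` are
#' untouched.
#'
#' @param stack an [ImageStack].
#' @param M square mixing matrix (invertible, non-negative entries,
#'   positive diagonal).
#' @param channels the channels `M` refers to (names or indices); default:
#'   the first `ncol(M)` channels.
#' @return the unmixed [ImageStack].
#' @export
linearUnmix <- function(stack, M, channels = NULL) {
  stopifnot(is(stack, "ImageStack"))
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("mixing matrix must be square")
  if (any(M < 0) || any(diag(M) <= 0))
    stop("mixing matrix must have non-negative entries and a positive diagonal")
  Minv <- tryCatch(solve(M), error = function(e)
    stop("mixing matrix is singular and cannot be inverted"))
  if (is.null(channels)) channels <- seq_len(ncol(M))
  if (is.character(channels)) channels <- match(channels, stack@channelNames)
  if (length(channels) != ncol(M) || anyNA(channels))
    stop("channel subset must match the dimension of the mixing matrix")
  d <- dim(stack@voxels)
  n <- prod(d[-1L])
  X <- matrix(0, length(channels), n)
  for (k in seq_along(channels))
    X[k, ] <- stack@voxels[channels[k], , , ]
  U <- Minv %*% X
  U[U < 0] <- 0
  vox <- stack@voxels
  for (k in seq_along(channels))
    vox[channels[k], , , ] <- array(U[k, ], d[-1L])
  initialize(stack, voxels = vox)
}
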