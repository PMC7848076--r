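# Internal numerical helpers shared across modules.

# Anisotropic Euclidean distance transform: distance (um) from every voxel
# to the nearest TRUE voxel of `target`, honoring per-axis spacing.
.edt <- function(target, spacing) {
  stopifnot(length(dim(target)) == 3L)
  cpp_edt(as.logical(target), dim(target), as.numeric(spacing))
}

# The three 1D factors of the anisotropic Gaussian PSF kernel, each
# normalized to sum 1 (their outer product is the 3D kernel).
.gaussKernels1d <- function(psf, spacing) {
  sig <- c(psf@sigmaAxial, psf@sigmaLateral, psf@sigmaLateral)
  lapply(1:3, function(a) {
    r <- max(1L, ceiling(psf@truncate * sig[a] / spacing[a]))
    x <- (-r:r) * spacing[a]
    w <- exp(-x^2 / (2 * sig[a]^2))
    w / sum(w)
  })
}

# Gaussian PSF convolution with periodic boundaries (separable, in C++);
# numerically equivalent to the FFT product and flux-conserving.
.convGauss <- function(vol, psf, spacing) {
  k <- .gaussKernels1d(psf, spacing)
  cpp_conv_sep(vol, dim(vol), k[[1L]], k[[2L]], k[[3L]])
}

# Separable Gaussian smoothing with sigma given in um (scalar or per-axis).
.gaussSmooth <- function(vol, sigma_um, spacing) {
  if (length(sigma_um) == 1L) sigma_um <- rep(sigma_um, 3L)
  psfk <- list()
  d <- dim(vol)
  for (a in 1:3) {
    if (sigma_um[a] <= 0) next
    r <- max(1L, ceiling(3 * sigma_um[a] / spacing[a]))
    x <- (-r:r) * spacing[a]
    w <- exp(-x^2 / (2 * sigma_um[a]^2))
    w <- w / sum(w)
    vol <- .filterAlong(vol, w, a)
  }
  vol
}

# Apply a 1D kernel along axis `a` of a 3D array with replicated edges.
.filterAlong <- function(vol, w, a) {
  d <- dim(vol)
  r <- (length(w) - 1L) %/% 2L
  perm <- switch(a, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1L])
  # replicate edges
  padTop <- m[rep(1L, r), , drop = FALSE]
  padBot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(padTop, m, padBot)
  out <- matrix(0, nrow = nrow(m), ncol = ncol(m))
  for (k in seq_along(w))
    out <- out + w[k] * mp[(k - 1L) + seq_len(nrow(m)), , drop = FALSE]
  dim(out) <- dv
  aperm(out, order(perm))
}

# Otsu threshold on a 256-bin histogram. Returns the threshold value;
# voxels strictly above it are foreground.
.otsu <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0)
    stop("Otsu threshold undefined for a constant image")
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  denom <- omega * (1 - omega)
  sigmaB <- (muT * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigmaB)
  mids[k]
}

# Histogram mode on a 256-bin histogram over the data range; ties break
# toward the lower bin. Returns the modal bin midpoint.
.histMode <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  k <- which.max(h)  # which.max takes the first (lower) bin on ties
  (br[k] + br[k + 1L]) / 2
}

# Remove 26-connected foreground components smaller than minVoxels.
.dropSpecks <- function(mask, minVoxels) {
  lab <- cpp_label3d(as.logical(mask), dim(mask), 26L)
  if (max(lab) == 0L) return(mask & TRUE)
  cnt <- tabulate(lab[lab > 0L], max(lab))
  keep <- which(cnt >= minVoxels)
  out <- array(lab %in% keep, dim(mask))
  out
}

# Largest 26-connected component of a logical volume.
.largestComponent <- function(mask) {
  lab <- cpp_label3d(as.logical(mask), dim(mask), 26L)
  if (max(lab) <= 1L) return(mask & TRUE)
  counts <- tabulate(lab[lab > 0L], max(lab))
  lab == which.max(counts)
}

.voxelVolume <- function(spacing) prod(spacing)

.checkSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must share the same grid: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
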