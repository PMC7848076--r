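#' ImagingSpec: confocal acquisition forward model
#'
#' Describes how a ground-truth phantom is turned into a realistic raw
#' stack: PSF blur, optional exponential depth attenuation (the inverse of
#' in-acquisition laser-power compensation), optional spectral spill-over,
#' then Poisson shot noise and Gaussian read noise on top of a constant
#' background. All randomness is drawn from a single RNG seeded per spec,
#' so identical specs give bit-identical stacks.
#'
#' @slot psf a [PSFModel] (a zero-width PSF is represented by
#'   `sigmaLateral = sigmaAxial = 0`, meaning no blur).
#' @slot attenuationLength exponential decay length in um along z
#'   (`Inf` = no attenuation).
#' @slot poissonScale photons per intensity unit (0 = no shot noise). At the
#'   default intensity scale of 100 a `poissonScale` of 1 gives a
#'   signal-to-noise ratio of about 10 on foreground structures.
#' @slot readNoiseSD Gaussian read-noise standard deviation (0 = none).
#' @slot background constant background offset added before noise.
#' @slot mixing optional spill-over mixing matrix (empty = none).
#' @slot seed RNG seed.
#'
#' @export
setClass("ImagingSpec",
  representation(psf = "PSFModel", attenuationLength = "numeric",
                 poissonScale = "numeric", readNoiseSD = "numeric",
                 background = "numeric", mixing = "matrix", seed = "integer"),
  prototype(attenuationLength = Inf, poissonScale = 1, readNoiseSD = 3,
            background = 5, mixing = matrix(numeric(0), 0, 0), seed = 1L))

setValidity("ImagingSpec", function(object) {
  msgs <- character()
  if (object@poissonScale < 0 || object@readNoiseSD < 0 ||
      object@background < 0)
    msgs <- c(msgs, "noise parameters must be >= 0")
  if (object@attenuationLength <= 0)
    msgs <- c(msgs, "attenuation length must be > 0 (Inf disables)")
  if (length(msgs)) msgs else TRUE
})

#' ImagingSpec constructor
#' @param psf a [PSFModel]; `NULL` means a delta PSF (no blur).
#' @param attenuationLength decay length in um (`Inf` = none).
#' @param poissonScale photons per intensity unit (0 = none).
#' @param readNoiseSD Gaussian read noise SD (0 = none).
#' @param background constant offset.
#' @param mixing optional square spill-over matrix.
#' @param seed RNG seed.
#' @return an [ImagingSpec].
#' @examples
#' imagingSpec(psfModel(0.15, 0.45), seed = 7)
#' @export
imagingSpec <- function(psf = psfModel(), attenuationLength = Inf,
                        poissonScale = 1, readNoiseSD = 3, background = 5,
                        mixing = NULL, seed = 1) {
  if (is.null(psf)) psf <- new("PSFModel", sigmaLateral = 0,
                               sigmaAxial = 0, truncate = 3)
  new("ImagingSpec", psf = psf, attenuationLength = attenuationLength,
      poissonScale = poissonScale, readNoiseSD = readNoiseSD,
      background = background,
      mixing = if (is.null(mixing)) matrix(numeric(0), 0, 0)
               else as.matrix(mixing),
      seed = as.integer(seed))
}

#' A noise-free, blur-free ImagingSpec (identity forward model)
#' @param seed RNG seed (unused, kept for interface symmetry).
#' @return an [ImagingSpec] that maps a stack to itself.
#' @export
identityImagingSpec <- function(seed = 1) {
  imagingSpec(psf = NULL, attenuationLength = Inf, poissonScale = 0,
              readNoiseSD = 0, background = 0, seed = seed)
}

#' Apply the confocal imaging forward model
#'
#' PSF convolution, then optional depth attenuation `exp(-z / L)`, optional
#' spill-over mixing, then background + Poisson + Gaussian noise.
#' Deterministic given `spec@seed`; the caller's RNG state is preserved.
#'
#' @param stack a ground-truth [ImageStack].
#' @param spec an [ImagingSpec].
#' @return the simulated raw [ImageStack].
#' @export
applyImaging <- function(stack, spec) {
  stopifnot(is(stack, "ImageStack"), is(spec, "ImagingSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)
  vox <- stack@voxels
  d <- dim(vox)
  blur <- spec@psf@sigmaLateral > 0 || spec@psf@sigmaAxial > 0
  for (ch in seq_len(d[1L])) {
    v <- getChannel(stack, ch)
    if (blur && spec@psf@sigmaLateral > 0 && spec@psf@sigmaAxial > 0) {
      v <- pmax(.convGauss(v, spec@psf, stack@spacing), 0)
    } else if (blur) {
      sig <- c(spec@psf@sigmaAxial, spec@psf@sigmaLateral,
               spec@psf@sigmaLateral)
      v <- .gaussSmooth(v, sig, stack@spacing)
    }
    if (is.finite(spec@attenuationLength)) {
      z_um <- (seq_len(d[2L]) - 1) * stack@spacing[1L]
      v <- v * rep(exp(-z_um / spec@attenuationLength),
                   times = prod(d[3:4]))
    }
    vox[ch, , , ] <- v
  }
  if (length(spec@mixing)) {
    mixed <- imageStack(vox, spacing = stack@spacing,
                        channelNames = stack@channelNames)
    n <- prod(d[-1L])
    X <- matrix(0, nrow(spec@mixing), n)
    for (k in seq_len(nrow(spec@mixing))) X[k, ] <- vox[k, , , ]
    Xm <- spec@mixing %*% X
    for (k in seq_len(nrow(spec@mixing))) vox[k, , , ] <- array(Xm[k, ], d[-1L])
  }
  vox <- vox + spec@background
  if (spec@poissonScale > 0) {
    lam <- vox * spec@poissonScale
    vox <- array(stats::rpois(length(lam), lam) / spec@poissonScale, d)
  }
  if (spec@readNoiseSD > 0)
    vox <- vox + array(stats::rnorm(length(vox), 0, spec@readNoiseSD), d)
  vox[vox < 0] <- 0
  initialize(stack, voxels = vox)
}
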