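#' CellPhantomSpec: parameters of the ground-truthed cardiomyocyte phantom
#'
#' The phantom models a cardiomyocyte as an elliptic cylinder (long axis =
#' x) with a surface membrane shell and a t-tubule network of transverse
#' line segments arranged in planes at the sarcomere period, plus sparse
#' axial connectors. Disease-like remodeling is controlled by
#' `keepProb` (random t-tubule loss) and `sheetFraction` / `sheetWidth`
#' (dilation of selected tubules into longitudinally extended t-sheets).
#' Every stochastic choice is drawn from one RNG seeded with `seed`, in
#' documented order (planes by increasing x; within a plane, y-directed
#' tubules by increasing z, then z-directed tubules by increasing y; keep
#' then sheet per segment; axial connectors last), so a spec is fully
#' reproducible.
#'
#' @slot lengthUm cell length along x (um).
#' @slot semiAxisY,semiAxisZ cross-section semi-axes (um).
#' @slot sarcomerePeriod spacing of transverse tubule planes along x (um).
#' @slot tubuleSpacing in-plane spacing of the tubule grid (um).
#' @slot tubuleRadius tubule radius (um).
#' @slot keepProb probability a lattice tubule is present (1 = intact).
#' @slot sheetFraction fraction of present tubules dilated into t-sheets.
#' @slot sheetWidth longitudinal (x) full width of a t-sheet (um).
#' @slot axialConnectorProb probability of an axial connector per lattice
#'   node and plane pair.
#' @slot seed RNG seed.
#'
#' @export
setClass("CellPhantomSpec",
  representation(lengthUm = "numeric", semiAxisY = "numeric",
                 semiAxisZ = "numeric", sarcomerePeriod = "numeric",
                 tubuleSpacing = "numeric", tubuleRadius = "numeric",
                 keepProb = "numeric", sheetFraction = "numeric",
                 sheetWidth = "numeric", axialConnectorProb = "numeric",
                 seed = "integer"))

setValidity("CellPhantomSpec", function(object) {
  msgs <- character()
  lens <- c(object@lengthUm, object@semiAxisY, object@semiAxisZ,
            object@sarcomerePeriod, object@tubuleSpacing,
            object@tubuleRadius, object@sheetWidth)
  if (any(lens <= 0)) msgs <- c(msgs, "all lengths must be > 0")
  pr <- c(object@keepProb, object@sheetFraction, object@axialConnectorProb)
  if (any(pr < 0 | pr > 1)) msgs <- c(msgs, "probabilities must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' CellPhantomSpec constructor
#' @param lengthUm,semiAxisY,semiAxisZ cell geometry (um).
#' @param sarcomerePeriod transverse plane spacing (um), default 2.0.
#' @param tubuleSpacing in-plane tubule grid spacing (um).
#' @param tubuleRadius tubule radius (um).
#' @param keepProb tubule keep probability.
#' @param sheetFraction fraction of kept tubules dilated to t-sheets.
#' @param sheetWidth t-sheet longitudinal width (um).
#' @param axialConnectorProb axial connector probability.
#' @param seed RNG seed.
#' @return a [CellPhantomSpec].
#' @examples
#' cellPhantomSpec(seed = 3, keepProb = 0.5, sheetFraction = 0.3)
#' @export
cellPhantomSpec <- function(lengthUm = 18, semiAxisY = 5, semiAxisZ = 4,
                            sarcomerePeriod = 2.0, tubuleSpacing = 3.5,
                            tubuleRadius = 0.15, keepProb = 1,
                            sheetFraction = 0, sheetWidth = 1.5,
                            axialConnectorProb = 0.15, seed = 1) {
  new("CellPhantomSpec", lengthUm = lengthUm, semiAxisY = semiAxisY,
      semiAxisZ = semiAxisZ, sarcomerePeriod = sarcomerePeriod,
      tubuleSpacing = tubuleSpacing, tubuleRadius = tubuleRadius,
      keepProb = keepProb, sheetFraction = sheetFraction,
      sheetWidth = sheetWidth, axialConnectorProb = axialConnectorProb,
      seed = as.integer(seed))
}

#' Spec presets for the two study conditions
#'
#' `"control"` is an intact, regularly tubulated cell; `"myocarditis"`
#' combines t-tubule loss (`keepProb` 0.5) with dilation of 30% of the
#' remaining tubules into t-sheets, the qualitative fingerprint of failing
#' myocardium. The default sheet width (1.5 um) is calibrated on the truth
#' geometry so that sheet dilation compensates tubule loss in expectation:
#' the disease family is density-matched to the control family, as in the
#' remodeling pattern it emulates (fewer but dilated tubules at unchanged
#' volume density).
#'
#' @param preset `"control"` or `"myocarditis"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [cellPhantomSpec()].
#' @return a [CellPhantomSpec].
#' @export
phantomPreset <- function(preset = c("control", "myocarditis"), seed = 1,
                          ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    control = list(keepProb = 1, sheetFraction = 0),
    myocarditis = list(keepProb = 0.5, sheetFraction = 0.3))
  args <- utils::modifyList(args, list(...))
  do.call(cellPhantomSpec, c(args, list(seed = seed)))
}

#' Generate a ground-truthed cardiomyocyte phantom
#'
#' Builds the noise-free membrane-channel stack and the exact ground truth:
#' cell mask, surface shell, t-system voxels, the per-segment planting
#' record and the analytic centerline length (sum of the generating segment
#' lengths, each clipped to the cell cross-section).
#'
#' @param spec a [CellPhantomSpec].
#' @param spacing `(dz, dy, dx)` um; the tubule radius must be at least 1.5
#'   lateral voxels, otherwise the geometry is not resolvable.
#' @param margin empty border around the cell (um).
#' @return list with `stack` (single-channel [ImageStack], channel
#'   `"membrane"`) and `truth` (list: `cellMask`, `surface`, `tubules`
#'   [BinaryVolume]s, `segments` data.frame, `centerlineLength` um,
#'   `ttDensity` %, `tubuleVolume` um^3, `spec`).
#' @export
generateCellPhantom <- function(spec, spacing = c(0.2, 0.1, 0.1),
                                margin = 1.0) {
  stopifnot(is(spec, "CellPhantomSpec"))
  if (spec@tubuleRadius < 1.5 * max(spacing[2:3]) - 1e-9)
    stop("tubule radius below resolvable size (need >= 1.5 lateral voxels)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)

  ry <- spec@semiAxisY; rz <- spec@semiAxisZ; L <- spec@lengthUm
  d <- c(ceiling((2 * rz + 2 * margin) / spacing[1L]),
         ceiling((2 * ry + 2 * margin) / spacing[2L]),
         ceiling((L + 2 * margin) / spacing[3L]))
  zc <- (seq_len(d[1L]) - 1) * spacing[1L]
  yc <- (seq_len(d[2L]) - 1) * spacing[2L]
  xc <- (seq_len(d[3L]) - 1) * spacing[3L]
  cz <- mean(range(zc)); cy <- mean(range(yc))
  x0 <- margin; x1 <- margin + L

  ell <- outer((zc - cz)^2 / rz^2, (yc - cy)^2 / ry^2, `+`) <= 1  # (z, y)
  inX <- xc >= x0 & xc <= x1
  cell <- array(FALSE, d)
  cell[, , inX] <- array(rep(ell, sum(inX)), c(d[1:2], sum(inX)))

  depth <- .edt(!cell, spacing)
  shell <- cell & depth <= 0.25

  # tubule lattice: transverse planes at the sarcomere period
  planesX <- seq(x0 + spec@sarcomerePeriod / 2, x1 - 1e-9,
                 by = spec@sarcomerePeriod)
  offs <- function(r) {
    J <- floor((r - 0.3) / spec@tubuleSpacing)
    if (J < 0) return(numeric(0))
    seq(-J, J) * spec@tubuleSpacing
  }
  zOffs <- offs(rz); yOffs <- offs(ry)

  clNormal <- array(FALSE, d)
  clSheet <- array(FALSE, d)
  segs <- list(); si <- 0L
  addSeg <- function(type, plane, offset, len, sheet) {
    si <<- si + 1L
    segs[[si]] <<- data.frame(type = type, plane_x = plane,
                              offset = offset, length = len, sheet = sheet)
  }
  for (px in planesX) {
    ix <- round(px / spacing[3L]) + 1L
    if (ix < 1L || ix > d[3L]) next
    for (zo in zOffs) {           # tubules running along y at height zo
      keep <- stats::runif(1) < spec@keepProb
      sheet <- keep && stats::runif(1) < spec@sheetFraction
      if (!keep) { addSeg("y", px, zo, 0, FALSE); next }
      iz <- round((cz + zo) / spacing[1L]) + 1L
      zr <- zc[iz] - cz
      if (abs(zr) >= rz) { addSeg("y", px, zo, 0, FALSE); next }
      h <- ry * sqrt(1 - (zr / rz)^2)
      iy <- which(abs(yc - cy) <= h)
      if (!length(iy)) { addSeg("y", px, zo, 0, FALSE); next }
      if (sheet) clSheet[iz, iy, ix] <- TRUE else clNormal[iz, iy, ix] <- TRUE
      addSeg("y", px, zo, 2 * h, sheet)
    }
    for (yo in yOffs) {           # tubules running along z at offset yo
      keep <- stats::runif(1) < spec@keepProb
      sheet <- keep && stats::runif(1) < spec@sheetFraction
      if (!keep) { addSeg("z", px, yo, 0, FALSE); next }
      iy <- round((cy + yo) / spacing[2L]) + 1L
      yr <- yc[iy] - cy
      if (abs(yr) >= ry) { addSeg("z", px, yo, 0, FALSE); next }
      h <- rz * sqrt(1 - (yr / ry)^2)
      iz <- which(abs(zc - cz) <= h)
      if (!length(iz)) { addSeg("z", px, yo, 0, FALSE); next }
      if (sheet) clSheet[iz, iy, ix] <- TRUE else clNormal[iz, iy, ix] <- TRUE
      addSeg("z", px, yo, 2 * h, sheet)
    }
  }
  # sparse axial connectors between adjacent planes at lattice nodes
  if (length(planesX) > 1L) {
    for (k in seq_len(length(planesX) - 1L)) {
      ixa <- round(planesX[k] / spacing[3L]) + 1L
      ixb <- round(planesX[k + 1L] / spacing[3L]) + 1L
      for (zo in zOffs) for (yo in yOffs) {
        if (stats::runif(1) >= spec@axialConnectorProb) next
        if ((zo / rz)^2 + (yo / ry)^2 >= 0.8^2) next  # stay interior
        iz <- round((cz + zo) / spacing[1L]) + 1L
        iy <- round((cy + yo) / spacing[2L]) + 1L
        clNormal[iz, iy, ixa:ixb] <- TRUE
        addSeg("x", planesX[k], NA_real_, planesX[k + 1L] - planesX[k],
               FALSE)
      }
    }
  }

  r <- spec@tubuleRadius
  tub <- array(FALSE, d)
  if (any(clNormal)) tub <- .edt(clNormal, spacing) <= r
  if (any(clSheet)) {
    # scale the x axis so the r-ball becomes an x-elongated ellipsoid:
    # cross-section (z, y) radius r, longitudinal half-width sheetWidth / 2
    spacingSheet <- c(spacing[1:2], spacing[3L] * 2 * r / spec@sheetWidth)
    tub <- tub | (.edt(clSheet, spacingSheet) <= r)
  }
  tub <- tub & cell

  segments <- if (si) do.call(rbind, segs) else
    data.frame(type = character(0), plane_x = numeric(0),
               offset = numeric(0), length = numeric(0), sheet = logical(0))
  clLen <- sum(segments$length)

  mem <- array(0, d)
  mem[shell | tub] <- 100
  stack <- imageStack(mem, spacing = spacing, channelNames = "membrane")
  truth <- list(
    cellMask = binaryVolume(cell, spacing),
    surface = binaryVolume(shell, spacing),
    tubules = binaryVolume(tub, spacing),
    segments = segments,
    centerlineLength = clLen,
    tubuleVolume = sum(tub) * .voxelVolume(spacing),
    ttDensity = 100 * sum(tub) / sum(cell),
    spec = spec)
  list(stack = stack, truth = truth)
}

#' Ground-truth segmentation of a phantom
#'
#' Assembles a [CellSegmentation] directly from phantom truth masks (no
#' imaging, no thresholding): the reference against which the pipeline's
#' recovered metrics are scored. The t-system / surface split uses the same
#' shell-depth rule as [classifyMembrane()].
#'
#' @param truth the `truth` element of [generateCellPhantom()].
#' @param shellDepth surface shell depth in um.
#' @return a [CellSegmentation].
#' @export
truthSegmentation <- function(truth, shellDepth = 0.5) {
  mem <- binaryVolume(truth$surface@mask | truth$tubules@mask,
                      truth$cellMask@spacing)
  classifyMembrane(truth$cellMask, mem, shellDepth = shellDepth)
}

#' JunctionPhantomSpec: planted EC-coupling cluster geometry
#'
#' LTCC clusters are planted uniformly in the cell interior at a target
#' density with a hard-core minimum separation. Each LTCC cluster receives,
#' with probability `pTriple`, overlapping RyR and JPH2 partner clusters
#' (jittered by `jitter`); with probabilities `pRyROnly` / `pJPH2Only` only
#' one partner overlaps; otherwise partners are displaced by at least 3
#' cluster radii (no overlap). The planting record is the ground truth for
#' co-localization scoring.
#'
#' @slot ltccDensity clusters per um^3.
#' @slot clusterRadius cluster radius (um).
#' @slot pTriple,pRyROnly,pJPH2Only coupling probabilities (sum <= 1).
#' @slot jitter SD of the partner-center jitter (um).
#' @slot minSeparation minimum LTCC center separation (um).
#' @slot amplitude cluster intensity in the noise-free stack. Sub-resolution
#'   puncta lose most of their peak intensity to PSF blur, so the default
#'   (1000, against a background of ~5) leaves a post-blur peak
#'   signal-to-noise ratio of about 10 under the default imaging model.
#' @slot seed RNG seed.
#'
#' @export
setClass("JunctionPhantomSpec",
  representation(ltccDensity = "numeric", clusterRadius = "numeric",
                 pTriple = "numeric", pRyROnly = "numeric",
                 pJPH2Only = "numeric", jitter = "numeric",
                 minSeparation = "numeric", amplitude = "numeric",
                 seed = "integer"))

setValidity("JunctionPhantomSpec", function(object) {
  msgs <- character()
  if (object@ltccDensity < 0) msgs <- c(msgs, "density must be >= 0")
  pr <- c(object@pTriple, object@pRyROnly, object@pJPH2Only)
  if (any(pr < 0) || sum(pr) > 1)
    msgs <- c(msgs, "coupling probabilities must be >= 0 and sum to <= 1")
  if (length(msgs)) msgs else TRUE
})

#' JunctionPhantomSpec constructor
#' @param ltccDensity planted LTCC cluster density (um^-3).
#' @param clusterRadius cluster radius (um).
#' @param pTriple probability of overlapping RyR and JPH2 partners.
#' @param pRyROnly,pJPH2Only probabilities of a single overlapping partner.
#' @param jitter partner-center jitter SD (um).
#' @param minSeparation hard-core LTCC separation (um).
#' @param amplitude cluster intensity (see the class slot documentation).
#' @param seed RNG seed.
#' @return a [JunctionPhantomSpec].
#' @export
junctionPhantomSpec <- function(ltccDensity = 0.10, clusterRadius = 0.2,
                                pTriple = 0.2, pRyROnly = 0.15,
                                pJPH2Only = 0.15, jitter = 0.05,
                                minSeparation = 0.7, amplitude = 1000,
                                seed = 1) {
  new("JunctionPhantomSpec", ltccDensity = ltccDensity,
      clusterRadius = clusterRadius, pTriple = pTriple,
      pRyROnly = pRyROnly, pJPH2Only = pJPH2Only, jitter = jitter,
      minSeparation = minSeparation, amplitude = amplitude,
      seed = as.integer(seed))
}

#' Generate a three-channel EC-coupling junction phantom
#'
#' @param spec a [JunctionPhantomSpec].
#' @param cellMask a [BinaryVolume] cell footprint (e.g. from a cell
#'   phantom's truth).
#' @return list with `stack` (channels `"LTCC"`, `"RyR"`, `"JPH2"`) and
#'   `truth` (data.frame `clusters`: per-LTCC center and coupling type;
#'   `nLTCC`; `pTripleTrue` = realized fraction; `cellVolume`).
#' @export
generateJunctionPhantom <- function(spec, cellMask) {
  stopifnot(is(spec, "JunctionPhantomSpec"), is(cellMask, "BinaryVolume"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)
  spc <- cellMask@spacing
  d <- dim(cellMask@mask)
  r <- spec@clusterRadius
  depth <- .edt(!cellMask@mask, spc)
  interior <- which(depth > r + 0.1)
  if (!length(interior)) stop("cell interior too small for cluster radius")
  cellVol <- sum(cellMask@mask) * .voxelVolume(spc)
  nTarget <- round(spec@ltccDensity * cellVol)
  iz <- (interior - 1L) %% d[1L]
  iy <- ((interior - 1L) %/% d[1L]) %% d[2L]
  ix <- (interior - 1L) %/% (d[1L] * d[2L])
  coords <- cbind(iz * spc[1L], iy * spc[2L], ix * spc[3L])

  centers <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(centers) < nTarget && tries < 50L * nTarget) {
    tries <- tries + 1L
    cand <- coords[sample.int(nrow(coords), 1L), ]
    if (nrow(centers)) {
      dd <- sqrt(colSums((t(centers) - cand)^2))
      if (min(dd) < spec@minSeparation) next
    }
    centers <- rbind(centers, cand)
  }
  n <- nrow(centers)
  if (n < nTarget)
    warning("placed ", n, " of ", nTarget,
            " clusters; density too high for the hard-core separation")

  u <- stats::runif(n)
  type <- ifelse(u < spec@pTriple, "triple",
          ifelse(u < spec@pTriple + spec@pRyROnly, "ryr_only",
          ifelse(u < spec@pTriple + spec@pRyROnly + spec@pJPH2Only,
                 "jph2_only", "none")))

  ball <- function(center) {
    lo <- pmax(floor((center - r) / spc), 0)
    hi <- pmin(ceiling((center + r) / spc), d - 1L)
    zz <- lo[1L]:hi[1L]; yy <- lo[2L]:hi[2L]; xx <- lo[3L]:hi[3L]
    dz2 <- (zz * spc[1L] - center[1L])^2
    dy2 <- (yy * spc[2L] - center[2L])^2
    dx2 <- (xx * spc[3L] - center[3L])^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
    idx <- which(inside)
    izb <- zz[(idx - 1L) %% length(zz) + 1L]
    iyb <- yy[((idx - 1L) %/% length(zz)) %% length(yy) + 1L]
    ixb <- xx[(idx - 1L) %/% (length(zz) * length(yy)) + 1L]
    izb + d[1L] * (iyb + d[2L] * ixb) + 1L
  }
  displaced <- function(center) {
    for (tr in 1:20) {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2)) * 3.5 * r
      cand <- center + v
      i <- round(cand / spc) + 1L
      if (all(i >= 1L) && all(i <= d) &&
          cellMask@mask[i[1L], i[2L], i[3L]]) return(cand)
    }
    NULL
  }

  mL <- array(FALSE, d); mR <- array(FALSE, d); mJ <- array(FALSE, d)
  for (i in seq_len(n)) {
    ctr <- centers[i, ]
    mL[ball(ctr)] <- TRUE
    partner <- function(overlapping) {
      if (overlapping) ctr + stats::rnorm(3, 0, spec@jitter)
      else displaced(ctr)
    }
    pR <- partner(type[i] %in% c("triple", "ryr_only"))
    pJ <- partner(type[i] %in% c("triple", "jph2_only"))
    if (!is.null(pR)) mR[ball(pR)] <- TRUE
    if (!is.null(pJ)) mJ[ball(pJ)] <- TRUE
  }

  vox <- array(0, c(3L, d))
  vox[1L, , , ] <- spec@amplitude * mL
  vox[2L, , , ] <- spec@amplitude * mR
  vox[3L, , , ] <- spec@amplitude * mJ
  stack <- imageStack(vox, spacing = spc,
                      channelNames = c("LTCC", "RyR", "JPH2"))
  truth <- list(
    clusters = data.frame(cz = centers[, 1L], cy = centers[, 2L],
                          cx = centers[, 3L], type = type),
    nLTCC = n, pTripleTrue = mean(type == "triple"),
    cellVolume = cellVol, spec = spec)
  list(stack = stack, truth = truth)
}

#' Generate a WGA-stained tissue phantom with known ECM fraction
#'
#' Packs cardiomyocyte cross-sections (nearest-center regions of a jittered
#' grid, extruded along z) separated by a bright interstitial matrix band.
#' The band width is solved by bisection so the realized ECM fraction hits
#' the target; the exact realized fraction is recorded in the truth.
#'
#' @param targetEcmFraction target ECM volume fraction in percent,
#'   in (0, 100).
#' @param fieldUm field size `(z, y, x)` in um.
#' @param cellDiameter typical myocyte cross-section diameter (um).
#' @param spacing `(dz, dy, dx)` um.
#' @param seed RNG seed.
#' @return list with `stack` (channel `"WGA"`; ECM intensity 150, cell
#'   interior 30) and `truth` (`ecmMask` [BinaryVolume],
#'   `ecmFraction` realized %, `wallWidth` um).
#' @export
generateTissuePhantom <- function(targetEcmFraction = 25,
                                  fieldUm = c(4, 32, 32),
                                  cellDiameter = 10,
                                  spacing = c(0.2, 0.1, 0.1), seed = 1) {
  if (targetEcmFraction <= 0 || targetEcmFraction >= 100)
    stop("target ECM fraction must be in (0, 100)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- ceiling(fieldUm / spacing)
  yc <- (seq_len(d[2L]) - 1) * spacing[2L]
  xc <- (seq_len(d[3L]) - 1) * spacing[3L]
  gy <- seq(cellDiameter / 2, fieldUm[2L], by = cellDiameter)
  gx <- seq(cellDiameter / 2, fieldUm[3L], by = cellDiameter)
  ctrs <- expand.grid(y = gy, x = gx)
  ctrs$y <- ctrs$y + stats::runif(nrow(ctrs), -0.2, 0.2) * cellDiameter
  ctrs$x <- ctrs$x + stats::runif(nrow(ctrs), -0.2, 0.2) * cellDiameter

  # per 2D pixel: distance to nearest and second-nearest center
  D <- array(Inf, c(d[2L], d[3L], 2L))
  for (i in seq_len(nrow(ctrs))) {
    di <- outer((yc - ctrs$y[i])^2, (xc - ctrs$x[i])^2, `+`)
    closer <- di < D[, , 1L]
    D[, , 2L][closer] <- D[, , 1L][closer]
    D[, , 1L][closer] <- di[closer]
    second <- !closer & di < D[, , 2L]
    D[, , 2L][second] <- di[second]
  }
  margin2d <- sqrt(D[, , 2L]) - sqrt(D[, , 1L])  # 0 on boundaries

  target <- targetEcmFraction / 100
  lo <- 0; hi <- max(margin2d)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(margin2d <= mid) < target) lo <- mid else hi <- mid
  }
  w <- hi
  ecm2d <- margin2d <= w
  realized <- 100 * mean(ecm2d)

  ecm <- array(rep(ecm2d, each = d[1L]), d)
  wga <- array(30, d)
  wga[ecm] <- 150
  stack <- imageStack(wga, spacing = spacing, channelNames = "WGA")
  truth <- list(ecmMask = binaryVolume(ecm, spacing),
                ecmFraction = realized, wallWidth = w,
                centers = ctrs)
  list(stack = stack, truth = truth)
}
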