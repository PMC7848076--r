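# Independent oracles and small geometry builders used across tests.

# Brute-force anisotropic nearest-target distance: O(N * M).
bruteForceDistance <- function(target, spacing, queryIdx = NULL) {
  d <- dim(target)
  w <- which(target, arr.ind = TRUE)
  P <- sweep(w - 1, 2, spacing, `*`)
  if (is.null(queryIdx)) queryIdx <- seq_len(prod(d))
  iz <- (queryIdx - 1) %% d[1L]
  iy <- ((queryIdx - 1) %/% d[1L]) %% d[2L]
  ix <- (queryIdx - 1) %/% (d[1L] * d[2L])
  q <- cbind(iz * spacing[1L], iy * spacing[2L], ix * spacing[3L])
  vapply(seq_len(nrow(q)), function(i) {
    sqrt(min((P[, 1L] - q[i, 1L])^2 + (P[, 2L] - q[i, 2L])^2 +
             (P[, 3L] - q[i, 3L])^2))
  }, numeric(1L))
}

# Welch t statistic, Satterthwaite df and two-sided p from first principles.
welchOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# One-way ANOVA F from the textbook sum-of-squares decomposition.
anovaOracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fst, df = c(k - 1, N - k),
       p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE))
}

# Holm step-down adjustment by direct enumeration of the definition:
# adjusted p at sorted rank j = max_{i <= j} min(1, (m - i + 1) * p_(i)).
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, (m - i + 1) * ps[i]))
    adj[i] <- run
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Digitized cylinder along x: radius r um, x index range, grid dims/spacing.
makeCylinderX <- function(r, d = c(13, 13, 106), spacing = c(0.2, 0.1, 0.1),
                          xRange = 3:103) {
  zc <- (seq_len(d[1L]) - 1) * spacing[1L]
  yc <- (seq_len(d[2L]) - 1) * spacing[2L]
  cross <- outer((zc - mean(range(zc)))^2, (yc - mean(range(yc)))^2, `+`) <= r^2
  cyl <- array(FALSE, d)
  for (ix in xRange) cyl[, , ix][cross] <- TRUE
  cyl
}

# A quick single-cell segmentation built from phantom truth plus a given
# t-system mask (used for metric-level tests without imaging).
segFromMasks <- function(cellMask, tsys, spacing = c(0.2, 0.1, 0.1)) {
  new("CellSegmentation", cellId = 1L,
      cellMask = binaryVolume(cellMask, spacing),
      surfaceMembrane = binaryVolume(array(FALSE, dim(cellMask)), spacing),
      tSystem = binaryVolume(tsys & cellMask, spacing))
}
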