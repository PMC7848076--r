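#' Process one single-cell membrane stack into t-system metrics
#'
#' The standard per-cell chain: denoise, optional Richardson-Lucy
#' deconvolution, optional depth correction; watershed cell segmentation on
#' the membrane channel; morphological closing; Otsu membrane threshold
#' within the cell bounding box; surface/t-system classification; t-system
#' morphometry.
#'
#' @param stack a raw [ImageStack] containing a membrane channel.
#' @param membraneChannel channel name or index.
#' @param rlIterations Richardson-Lucy iterations (0 = skip).
#' @param psf [PSFModel] for deconvolution.
#' @param denoiseRadius median-filter radius in voxels (0 = skip).
#' @param depthCorrect apply [correctDepthAttenuation()].
#' @param closeRadius cell-mask closing radius (um).
#' @param shellDepth surface shell depth (um).
#' @param minCellVolume minimum watershed segment volume (um^3).
#' @param minForegroundVoxels drop membrane-foreground specks (26-connected
#'   components) smaller than this many voxels; rejects deconvolution noise.
#' @param cellId,sampleId,group identifiers for the metrics rows.
#' @return list: `segmentation` ([CellSegmentation]), `metrics`
#'   (metrics-table rows), `membraneFg` ([BinaryVolume]).
#' @export
processCellStack <- function(stack, membraneChannel = "membrane",
                             rlIterations = 0, psf = psfModel(),
                             denoiseRadius = 1, depthCorrect = FALSE,
                             closeRadius = 0.5, shellDepth = 0.5,
                             minCellVolume = 500, minForegroundVoxels = 8,
                             cellId = 1L, sampleId = "sample1",
                             group = "group1") {
  stopifnot(is(stack, "ImageStack"))
  pre <- stack
  if (denoiseRadius >= 1) pre <- denoise(pre, "median", denoiseRadius)
  if (rlIterations > 0) pre <- richardsonLucy(pre, psf, rlIterations,
                                              stopTol = 0)
  if (depthCorrect) pre <- correctDepthAttenuation(pre)
  mem <- getChannel(pre, membraneChannel)
  spc <- spacing(pre)

  # ridge-cut masks: the surface/t-system classification assumes the mask
  # boundary runs along the membrane-intensity ridge
  labels <- watershedCells(mem, spacing = spc, minCellVolume = minCellVolume,
                           claimMembrane = FALSE)
  if (max(labels@labels) == 0L)
    stop("segmentation found no cell in the stack")
  counts <- tabulate(labels@labels[labels@labels > 0L], max(labels@labels))
  cellLab <- which.max(counts)
  cmask <- extractCellMask(labels, cellLab, closeRadius = closeRadius)

  # threshold the membrane inside the cell's bounding box
  bb <- .bbox(cmask@mask)
  sub <- mem[bb$z, bb$y, bb$x]
  thr <- .otsu(sub)
  fg <- mem > thr
  if (minForegroundVoxels > 1) fg <- .dropSpecks(fg, minForegroundVoxels)
  memFg <- binaryVolume(fg, spc, metadata = list(threshold = thr))
  seg <- classifyMembrane(cmask, memFg, shellDepth = shellDepth,
                          cellId = cellId)
  metrics <- ttMetrics(seg, cellId = cellId, sampleId = sampleId,
                       group = group)
  list(segmentation = seg, metrics = metrics, membraneFg = memFg)
}

.bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  list(z = min(w[, 1L]):max(w[, 1L]), y = min(w[, 2L]):max(w[, 2L]),
       x = min(w[, 3L]):max(w[, 3L]))
}

#' Simulate and analyze a two-group phantom study
#'
#' Generates `nSamples` pseudo-samples per group (presets `"control"` and
#' `"myocarditis"`), each contributing `cellsPerSample` phantom cells with
#' mild sample-level parameter variability (tubule-spacing and keep-
#' probability jitter, giving each pseudo-sample its own intercept), images
#' every cell with the forward model, runs the full per-cell pipeline and
#' fits the statistics layer per metric: the linear mixed model
#' `value ~ group + (1 | sample)`, a one-way ANOVA across samples, and
#' Holm-Bonferroni correction over the three t-system endpoints.
#'
#' @param nSamples samples per group.
#' @param cellsPerSample cells per sample.
#' @param seed master seed; all per-cell seeds derive from it.
#' @param imaging an [ImagingSpec] template (its seed is re-derived per
#'   cell).
#' @param rlIterations Richardson-Lucy iterations in the per-cell pipeline.
#' @param tubuleSpacing base in-plane tubule lattice spacing (um), jittered
#'   per sample; when the cell cross-section is scaled down for quick runs,
#'   scale this down with it so the lattice keeps the same number of
#'   tubules per plane as the full-size geometry.
#' @param cellArgs extra arguments for [cellPhantomSpec()] shared by both
#'   groups (e.g. a smaller `lengthUm` for quick runs).
#' @return list of class `"StudyReport"`: `metrics` (per-cell table),
#'   `sampleMeans`, `groupSummary`, `stats` (per-metric LMM and ANOVA with
#'   Holm-adjusted LMM p-values), `truth` (per-cell truth metrics).
#' @export
runPhantomStudy <- function(nSamples = 5, cellsPerSample = 8, seed = 1,
                            imaging = imagingSpec(),
                            rlIterations = 0,
                            tubuleSpacing = 3.5,
                            cellArgs = list()) {
  groups <- c("control", "myocarditis")
  rows <- list(); truthRows <- list(); k <- 0L
  baseSeed <- as.integer(seed) %% 100000L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (s in seq_len(nSamples)) {
      sampleId <- sprintf("%s_s%d", g, s)
      # sample-level biological variability, seeded deterministically
      set.seed(baseSeed + 1000L * gi + s)
      spacJit <- stats::runif(1, 0.93, 1.07)
      keepJit <- stats::runif(1, -0.04, 0.04)
      perJit <- stats::runif(1, 0.95, 1.05)
      for (ci in seq_len(cellsPerSample)) {
        k <- k + 1L
        cellSeed <- baseSeed + 10000L * gi + 100L * s + ci
        args <- list(seed = cellSeed,
                     tubuleSpacing = tubuleSpacing * spacJit,
                     sarcomerePeriod = 2.0 * perJit)
        args <- utils::modifyList(args, cellArgs)
        spec <- do.call(phantomPreset,
                        c(list(preset = g), args))
        spec@keepProb <- min(1, max(0.05, spec@keepProb + keepJit))
        ph <- generateCellPhantom(spec)
        img <- initialize(imaging, seed = cellSeed + 7L)
        raw <- applyImaging(ph$stack, img)
        # slivers: anything below 40% of the nominal phantom cell volume
        minVol <- 0.4 * pi * spec@semiAxisY * spec@semiAxisZ * spec@lengthUm
        res <- tryCatch(
          processCellStack(raw, rlIterations = rlIterations,
                           minCellVolume = minVol,
                           cellId = k, sampleId = sampleId, group = g),
          error = function(e) {
            warning("cell ", k, " (", sampleId, ") skipped: ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(res)) next
        rows[[k]] <- res$metrics
        tseg <- truthSegmentation(ph$truth)
        truthRows[[k]] <- data.frame(
          cell_id = as.character(k), sample_id = sampleId, group = g,
          tt_distance_mean = ttDistanceMean(tseg),
          tt_density = ttDensity(tseg),
          stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  report <- .studyStats(metrics)
  report$truth <- do.call(rbind, truthRows)
  report
}

.studyStats <- function(metrics) {
  endpoints <- c("tt_distance_mean", "tt_density", "tt_volume_length_ratio")
  statsOut <- list()
  for (m in intersect(endpoints, unique(metrics$metric_name))) {
    sub <- metrics[metrics$metric_name == m, ]
    # single-group or minimal designs cannot support the models; the report
    # then carries the metrics without inferential results
    lmm <- tryCatch(fitLMM(sub, response = "value", fixed = "group",
                           grouping = "sample_id"),
                    error = function(e) NULL)
    aov1 <- tryCatch(anovaOneway(sub$value, sub$sample_id),
                     error = function(e) NULL)
    statsOut[[m]] <- list(lmm = lmm, anova_samples = aov1)
  }
  haveLmm <- vapply(statsOut, function(x) !is.null(x$lmm), logical(1L))
  if (any(haveLmm)) {
    praw <- vapply(statsOut[haveLmm], function(x) x$lmm$p_value, numeric(1L))
    padj <- holmBonferroni(praw)
    j <- 0L
    for (i in seq_along(statsOut)) {
      if (!haveLmm[i]) next
      j <- j + 1L
      statsOut[[i]]$lmm_p_holm <- padj[[j]]
    }
  }
  structure(list(metrics = metrics,
                 sampleMeans = summarizeSamples(metrics),
                 groupSummary = summarizeGroups(metrics),
                 stats = statsOut), class = "StudyReport")
}

#' Group-level summaries (mean +/- SEM)
#'
#' @param table a metrics table (see [writeMetrics()]).
#' @return data.frame with `group`, `metric_name`, `mean`, `sem`
#'   (`NA` for n = 1), `n`.
#' @export
summarizeGroups <- function(table) {
  validateMetricsTable(table)
  if (!nrow(table)) stop("empty metrics table")
  agg <- function(v) c(mean = mean(v),
                       sem = if (length(v) > 1L)
                         stats::sd(v) / sqrt(length(v)) else NA_real_,
                       n = length(v))
  sp <- split(table$value, list(table$group, table$metric_name), drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    v <- sp[[nm]]
    data.frame(group = parts[1L],
               metric_name = paste(parts[-1L], collapse = "."),
               mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out[order(out$metric_name, out$group), , drop = FALSE]
}

#' Per-sample mean metrics
#'
#' @param table a metrics table.
#' @return data.frame with `sample_id`, `group`, `metric_name`, `mean`, `n`.
#' @export
summarizeSamples <- function(table) {
  validateMetricsTable(table)
  sp <- split(seq_len(nrow(table)),
              list(table$sample_id, table$metric_name), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(sample_id = table$sample_id[i[1L]],
               group = table$group[i[1L]],
               metric_name = table$metric_name[i[1L]],
               mean = mean(table$value[i]), n = length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$metric_name, out$group, out$sample_id), , drop = FALSE]
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport:", length(unique(x$metrics$cell_id)), "cells,",
      length(unique(x$metrics$sample_id)), "samples,",
      length(unique(x$metrics$group)), "groups\n\n")
  gs <- x$groupSummary
  for (m in unique(gs$metric_name)) {
    sub <- gs[gs$metric_name == m, ]
    cat(sprintf("  %s: %s\n", m,
        paste(sprintf("%s %.3g +/- %.2g (n=%d)", sub$group, sub$mean,
                      sub$sem, sub$n), collapse = " | ")))
  }
  cat("\n")
  for (m in names(x$stats)) {
    st <- x$stats[[m]]
    cat(sprintf("  LMM %s: effect %.3g, p = %.3g (Holm %.3g)\n", m,
                st$lmm$fixed_effect, st$lmm$p_value, st$lmm_p_holm))
  }
  invisible(x)
}

#' Run a configured pipeline end-to-end
#'
#' Configuration is a YAML/JSON file or an equivalent list. Two study modes
#' are supported: `mode: phantom` (simulate a two-group phantom study; keys
#' `n_samples`, `cells_per_sample`, `seed`, `rl_iterations`, optional
#' `cell` overrides for the phantom geometry and `imaging` overrides for
#' the forward model) and `mode: files` (process per-cell stacks listed
#' under `inputs:` with `path`, `sample_id`, `group` and an optional
#' `membrane_channel`). Writes `metrics.csv`, `group_summary.csv` and
#' `report.json` when `outDir` is given.
#'
#' @param config path to a YAML/JSON config or a list.
#' @param outDir optional output directory.
#' @return a `"StudyReport"` (invisibly when `outDir` is given).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  mode <- config$mode %||% "phantom"
  if (mode == "phantom") {
    imgArgs <- config$imaging %||% list()
    imaging <- do.call(imagingSpec, imgArgs)
    report <- runPhantomStudy(
      nSamples = config$n_samples %||% 5,
      cellsPerSample = config$cells_per_sample %||% 8,
      seed = config$seed %||% 1,
      imaging = imaging,
      rlIterations = config$rl_iterations %||% 0,
      tubuleSpacing = config$tubule_spacing %||% 3.5,
      cellArgs = config$cell %||% list())
  } else if (mode == "files") {
    inputs <- config$inputs
    if (is.null(inputs) || !length(inputs))
      stop("config mode 'files' requires an 'inputs' list")
    if (is.data.frame(inputs))
      inputs <- split(inputs, seq_len(nrow(inputs)))
    rows <- list()
    for (i in seq_along(inputs)) {
      inp <- as.list(inputs[[i]])
      if (is.null(inp$path)) stop("input ", i, " has no 'path'")
      st <- readStack(inp$path,
                      spacingOverride = inp$spacing,
                      channelNames = inp$channel_names)
      ch <- inp$membrane_channel %||% "membrane"
      if (!ch %in% channelNames(st) && is.character(ch))
        stop("missing channel '", ch, "' in ", inp$path)
      res <- processCellStack(st, membraneChannel = ch,
                              rlIterations = config$rl_iterations %||% 0,
                              minCellVolume = config$min_cell_volume %||% 500,
                              cellId = i,
                              sampleId = inp$sample_id %||% "sample1",
                              group = inp$group %||% "group1")
      rows[[i]] <- res$metrics
    }
    report <- .studyStats(do.call(rbind, rows))
  } else {
    stop("unknown pipeline mode: ", mode)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMetrics(report$metrics, file.path(outDir, "metrics.csv"))
    utils::write.csv(report$groupSummary,
                     file.path(outDir, "group_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(.reportJSON(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.reportJSON <- function(report) {
  statsOut <- lapply(report$stats, function(st) list(
    lmm = if (is.null(st$lmm)) NULL else
      st$lmm[c("fixed_intercept", "fixed_effect", "se", "statistic", "df",
               "df_method", "p_value", "random_intercept_sd", "residual_sd",
               "n_obs", "n_groups", "singular")],
    lmm_p_holm = st$lmm_p_holm,
    anova_samples = if (is.null(st$anova_samples)) NULL else
      st$anova_samples[c("statistic", "df", "p_raw")]))
  list(group_summary = report$groupSummary,
       sample_means = report$sampleMeans,
       stats = statsOut)
}
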