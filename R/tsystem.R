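#' Intracellular t-tubule distance map
#'
#' Anisotropic Euclidean distance (um) from every voxel inside the cell mask
#' to the nearest t-system voxel; with `includeSurface = TRUE` the surface
#' sarcolemma is included in the target set, a variant used in part of the
#' t-system literature. Values are exactly 0 on target voxels and `NA`
#' outside the cell mask.
#'
#' @param seg a [CellSegmentation].
#' @param includeSurface include surface membrane in the distance targets.
#' @return 3D numeric array `(z, y, x)` of distances in um (`NA` outside the
#'   cell).
#' @export
ttDistanceMap <- function(seg, includeSurface = FALSE) {
  stopifnot(is(seg, "CellSegmentation"))
  target <- seg@tSystem@mask
  if (includeSurface) target <- target | seg@surfaceMembrane@mask
  if (!any(target))
    stop("no reference membrane: t-system empty and includeSurface is FALSE")
  d <- .edt(target, spacing(seg))
  d[!seg@cellMask@mask] <- NA_real_
  d
}

#' Mean intracellular t-tubule distance
#'
#' Mean of the distance map over cytosolic voxels: interior voxels of the
#' cell mask excluding the membrane targets themselves, so that the zeros on
#' tubule voxels do not dilute the mean. Set `includeTargets = TRUE` to
#' average over every in-cell voxel instead.
#'
#' @inheritParams ttDistanceMap
#' @param includeTargets also average over target (distance-0) voxels.
#' @return mean distance in um.
#' @export
ttDistanceMean <- function(seg, includeSurface = FALSE,
                           includeTargets = FALSE) {
  dmap <- ttDistanceMap(seg, includeSurface = includeSurface)
  sel <- !is.na(dmap)
  if (!includeTargets) sel <- sel & dmap > 0
  if (!any(sel)) return(0)
  mean(dmap[sel])
}

#' Distance-map summary statistics
#'
#' @inheritParams ttDistanceMean
#' @return named numeric: `mean`, `median` and `p95` of the cytosolic
#'   distance map, in um.
#' @export
ttDistanceSummary <- function(seg, includeSurface = FALSE,
                              includeTargets = FALSE) {
  dmap <- ttDistanceMap(seg, includeSurface = includeSurface)
  sel <- !is.na(dmap)
  if (!includeTargets) sel <- sel & dmap > 0
  v <- dmap[sel]
  if (!length(v)) v <- 0
  c(mean = mean(v), median = stats::median(v),
    p95 = unname(stats::quantile(v, 0.95)))
}

#' T-tubule volume density
#'
#' T-system volume as a percentage of cell volume. Voxel counts are used
#' directly (the spacing cancels).
#'
#' @param seg a [CellSegmentation].
#' @return density in percent, in `[0, 100]`.
#' @export
ttDensity <- function(seg) {
  stopifnot(is(seg, "CellSegmentation"))
  nCell <- sum(seg@cellMask@mask)
  if (nCell == 0) stop("empty cell mask")
  100 * sum(seg@tSystem@mask) / nCell
}

#' Skeleton length of a tubular network
#'
#' Thins the volume to a 3D curve skeleton (topology-preserving iterative
#' thinning) and measures length on the skeleton's 26-adjacency graph with
#' edges weighted by the physical distance between voxel centers. Per
#' connected component the length is the weight of the graph's minimum
#' spanning tree, which counts each digitized centerline step once and is
#' robust against spurious diagonal chords at corners; spur branches shorter
#' than `pruneSpurs` um are removed beforehand. Single-voxel components have
#' length 0 and are flagged via the `"n_degenerate"` attribute.
#'
#' @param tSystem a [BinaryVolume] (or logical 3D array) of tubule voxels.
#' @param spacing `(dz, dy, dx)` um; taken from the volume when omitted.
#' @param pruneSpurs prune terminal branches shorter than this length (um).
#' @return total skeleton length in um, with attributes `"n_skeleton_voxels"`
#'   and `"n_degenerate"`.
#' @export
skeletonLength <- function(tSystem, spacing = NULL, pruneSpurs = 0.3) {
  if (is(tSystem, "BinaryVolume")) {
    if (is.null(spacing)) spacing <- tSystem@spacing
    tSystem <- tSystem@mask
  }
  if (is.null(spacing)) stop("spacing required")
  if (!any(tSystem)) stop("empty volume: no skeleton")
  skel <- cpp_skeletonize3d(as.logical(tSystem), dim(tSystem))
  g <- .skeletonGraph(skel, spacing)
  if (pruneSpurs > 0 && igraph::vcount(g$graph) > 1L)
    g <- .pruneSpurs(g, pruneSpurs)
  len <- 0
  nDegen <- 0L
  comps <- igraph::components(g$graph)
  for (ci in seq_len(comps$no)) {
    vids <- which(comps$membership == ci)
    if (length(vids) == 1L) {
      nDegen <- nDegen + 1L
      next
    }
    sub <- igraph::induced_subgraph(g$graph, vids)
    mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
    len <- len + sum(igraph::E(mst)$weight)
    len <- len + .endCapLength(mst, g$coords, tSystem, spacing)
  }
  structure(len, n_skeleton_voxels = sum(skel), n_degenerate = nDegen)
}

# Build the weighted 26-adjacency graph of skeleton voxels.
.skeletonGraph <- function(skel, spacing) {
  d <- dim(skel)
  idx <- which(skel)
  vid <- integer(prod(d))
  vid[idx] <- seq_along(idx)
  iz <- (idx - 1L) %% d[1L]
  iy <- ((idx - 1L) %/% d[1L]) %% d[2L]
  ix <- (idx - 1L) %/% (d[1L] * d[2L])
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    key <- dz + 3L * dy + 9L * dx
    if (key <= 0L) next  # each unordered pair once
    jz <- iz + dz; jy <- iy + dy; jx <- ix + dx
    ok <- jz >= 0L & jz < d[1L] & jy >= 0L & jy < d[2L] &
          jx >= 0L & jx < d[3L]
    jdx <- jz[ok] + d[1L] * (jy[ok] + d[2L] * jx[ok]) + 1L
    hit <- vid[jdx] > 0L
    if (!any(hit)) next
    from <- c(from, vid[idx[ok]][hit])
    to <- c(to, vid[jdx][hit])
    w <- c(w, rep(sqrt(sum((c(dz, dy, dx) * spacing)^2)), sum(hit)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  list(graph = g, coords = cbind(iz, iy, ix))
}

# Thinning consumes the end caps of thick tubes before endpoint protection
# can engage, so terminal vertices sit up to a few voxels short of the true
# tube end. Compensate by walking from each degree-1 vertex along its
# outgoing direction through the original mask and adding the walked length.
.endCapLength <- function(mst, coords, mask, spacing) {
  d <- dim(mask)
  deg <- igraph::degree(mst)
  ends <- which(deg == 1L)
  extra <- 0
  for (v in ends) {
    nb <- as.integer(igraph::neighbors(mst, v))
    vi <- as.integer(igraph::V(mst)$name[v])
    ni <- as.integer(igraph::V(mst)$name[nb[1L]])
    dir <- sign(coords[vi, ] - coords[ni, ])  # voxel step out of the curve
    if (all(dir == 0)) next
    stepLen <- sqrt(sum((dir * spacing)^2))
    pos <- coords[vi, ]
    for (s in 1:50) {
      pos <- pos + dir
      if (any(pos < 0) || any(pos >= d)) break
      if (!mask[pos[1L] + 1L, pos[2L] + 1L, pos[3L] + 1L]) break
      extra <- extra + stepLen
    }
  }
  extra
}

# Remove terminal (leaf) branches shorter than minLen um, iteratively.
.pruneSpurs <- function(g, minLen) {
  graph <- g$graph
  repeat {
    deg <- igraph::degree(graph)
    leaves <- which(deg == 1L)
    if (!length(leaves)) break
    removed <- FALSE
    drop <- integer(0)
    for (lf in leaves) {
      # walk from the leaf to the first branch point or other leaf
      path <- lf
      len <- 0
      cur <- lf
      prev <- -1L
      repeat {
        nbs <- as.integer(igraph::neighbors(graph, cur))
        nbs <- setdiff(nbs, prev)
        if (length(nbs) != 1L) break
        e <- igraph::get_edge_ids(graph, c(cur, nbs))
        len <- len + igraph::E(graph)$weight[e]
        prev <- cur
        cur <- nbs
        if (igraph::degree(graph, cur) > 2L || len >= minLen) break
        path <- c(path, cur)
      }
      if (len < minLen && igraph::degree(graph, cur) > 2L) {
        drop <- c(drop, path)
        removed <- TRUE
      }
    }
    if (!removed) break
    graph <- igraph::delete_vertices(graph, unique(drop))
  }
  list(graph = graph, coords = g$coords)
}

#' T-tubule volume-to-length ratio
#'
#' T-system volume divided by skeleton length: an estimate of the mean
#' t-tubule cross-sectional area (um^2) and an indicator of tubule dilation
#' towards t-sheets.
#'
#' @param seg a [CellSegmentation].
#' @param pruneSpurs passed to [skeletonLength()].
#' @return ratio in um^2.
#' @export
ttVolumeLengthRatio <- function(seg, pruneSpurs = 0.3) {
  stopifnot(is(seg, "CellSegmentation"))
  nT <- sum(seg@tSystem@mask)
  if (nT == 0) stop("empty t-system")
  len <- skeletonLength(seg@tSystem, pruneSpurs = pruneSpurs)
  if (len <= 0) stop("zero skeleton length")
  nT * .voxelVolume(spacing(seg)) / as.numeric(len)
}

#' Cell area at the largest optical section
#'
#' @param seg a [CellSegmentation].
#' @return max over z-planes of in-plane mask area, in um^2.
#' @export
cellArea <- function(seg) {
  stopifnot(is(seg, "CellSegmentation"))
  m <- seg@cellMask@mask
  if (!any(m)) stop("empty cell mask")
  perPlane <- apply(m, 1L, sum)
  max(perPlane) * spacing(seg)[2L] * spacing(seg)[3L]
}

#' Cell volume
#'
#' @param seg a [CellSegmentation].
#' @return cell mask volume in um^3.
#' @export
cellVolume <- function(seg) {
  stopifnot(is(seg, "CellSegmentation"))
  sum(seg@cellMask@mask) * .voxelVolume(spacing(seg))
}

#' All t-system metrics for one cell
#'
#' Computes the three t-system measures (TT distance, TT density, TT
#' volume/length ratio) plus cell area and volume and returns them as
#' metrics-table rows (see [writeMetrics()]).
#'
#' @param seg a [CellSegmentation].
#' @param cellId,sampleId,group identifiers for the output rows.
#' @param includeSurface passed to [ttDistanceMean()].
#' @return a metrics `data.frame`.
#' @export
ttMetrics <- function(seg, cellId = seg@cellId, sampleId = "sample1",
                      group = "group1", includeSurface = FALSE) {
  vals <- c(tt_distance_mean = ttDistanceMean(seg, includeSurface),
            tt_density = ttDensity(seg),
            tt_volume_length_ratio = ttVolumeLengthRatio(seg),
            cell_area = cellArea(seg),
            cell_volume = cellVolume(seg))
  units <- c("um", "%", "um^2", "um^2", "um^3")
  data.frame(cell_id = as.character(cellId), sample_id = sampleId,
             group = group, metric_name = names(vals),
             value = unname(vals), units = units,
             stringsAsFactors = FALSE, row.names = NULL)
}
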