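#' Uniformly resample tree segments
#'
#' Replaces every parent-to-child straight segment by points spaced at most
#' `step` micrometres apart (endpoints included), so that node density is
#' uniform along the cable. Used before centroid and scatter computations so
#' that sparse long segments do not bias spatial statistics.
#'
#' @param p0,p1 n x 3 matrices of segment start and end points (micrometres),
#'   e.g. from a neuron's parent/child node pairs.
#' @param step maximum spacing between consecutive points, micrometres.
#' @param dedup drop the duplicated shared start point of each segment
#'   (keeps interior + end points only, plus each unique start once); with
#'   the default FALSE both endpoints of every segment are emitted.
#' @return m x 3 matrix of resampled points, m >= number of input nodes.
#' @export
resample_segments <- function(p0, p1, step = 1, dedup = FALSE) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  p0 <- rbind3(p0); p1 <- rbind3(p1)
  stopifnot(nrow(p0) == nrow(p1))
  len <- sqrt(rowSums((p1 - p0)^2))
  nsub <- pmax(1L, ceiling(len / step))
  out <- vector("list", nrow(p0))
  for (s in seq_len(nrow(p0))) {
    t0 <- if (dedup) 1L else 0L
    tt <- seq(t0, nsub[s], by = 1L) / nsub[s]
    out[[s]] <- cbind(p0[s, 1] + tt * (p1[s, 1] - p0[s, 1]),
                      p0[s, 2] + tt * (p1[s, 2] - p0[s, 2]),
                      p0[s, 3] + tt * (p1[s, 3] - p0[s, 3]))
  }
  do.call(rbind, out)
}

#' Resample a neuron compartment to uniform point density
#'
#' Convenience wrapper over [resample_segments()] emitting each node once
#' plus interpolated points: every root/entry point appears once and each
#' segment contributes its interior and child points.
#'
#' @param nrn a `"neuron"` object.
#' @param compartment compartment name or code (NULL = whole cell).
#' @param step maximum point spacing, micrometres.
#' @return m x 3 matrix of points.
#' @export
resample_neuron <- function(nrn, compartment = NULL, step = 1) {
  ed <- compartment_edges(nrn, compartment)
  if (!length(ed$child)) return(matrix(numeric(0), ncol = 3L))
  # entry points: parents that are not themselves children in this edge set
  entry <- setdiff(ed$parent, ed$child)
  entry_pts <- as.matrix(nrn$nodes[entry, c("x", "y", "z"), drop = FALSE])
  rbind(entry_pts, resample_segments(ed$p0, ed$p1, step, dedup = TRUE))
}

#' Rasterize segments onto a Cartesian grid
#'
#' Returns every grid cell traversed by each straight segment (3D
#' amanatides-woo style voxel walk), so that the point set used for scatter
#' matrices includes every Cartesian grid cell on the straight path between
#' connected nodes. Cells are identified by 0-based integer indices relative
#' to `origin`; a zero-length segment contributes the single cell containing
#' it. Duplicate cells are removed (set semantics).
#'
#' @param p0,p1 n x 3 matrices of segment endpoints (micrometres).
#' @param grid_spacing grid cell edge length, micrometres (scalar or 3).
#' @param origin grid origin, micrometres.
#' @return data.frame with integer columns `i`, `j`, `k` (unique cells).
#' @export
rasterize_segments <- function(p0, p1, grid_spacing = 10, origin = c(0, 0, 0)) {
  grid_spacing <- rep_len(as.numeric(grid_spacing), 3L)
  if (any(grid_spacing <= 0)) stop("grid_spacing must be > 0", call. = FALSE)
  p0 <- rbind3(p0); p1 <- rbind3(p1)
  stopifnot(nrow(p0) == nrow(p1))
  cells <- vector("list", nrow(p0))
  for (s in seq_len(nrow(p0))) {
    a <- (p0[s, ] - origin) / grid_spacing
    b <- (p1[s, ] - origin) / grid_spacing
    cells[[s]] <- walk_voxels(a, b)
  }
  cells <- do.call(rbind, cells)
  unique(as.data.frame(cells))
}

# voxel traversal in unit-grid coordinates; returns matrix of 0-based ijk
walk_voxels <- function(a, b) {
  cur <- floor(a)
  end <- floor(b)
  d <- b - a
  out <- matrix(cur, ncol = 3L)
  if (all(cur == end)) {
    colnames(out) <- c("i", "j", "k")
    return(out)
  }
  stp <- sign(d)
  # parametric distance to next grid plane along each axis
  tmax <- rep(Inf, 3)
  tdelta <- rep(Inf, 3)
  for (ax in 1:3) {
    if (d[ax] > 0) {
      tmax[ax] <- (cur[ax] + 1 - a[ax]) / d[ax]
      tdelta[ax] <- 1 / d[ax]
    } else if (d[ax] < 0) {
      tmax[ax] <- (cur[ax] - a[ax]) / d[ax]
      tdelta[ax] <- -1 / d[ax]
    }
  }
  res <- list(out)
  guard <- sum(abs(end - cur)) + 3
  it <- 0
  while (any(cur != end) && it < guard * 2) {
    ax <- which.min(tmax)
    cur[ax] <- cur[ax] + stp[ax]
    tmax[ax] <- tmax[ax] + tdelta[ax]
    res[[length(res) + 1L]] <- matrix(cur, ncol = 3L)
    it <- it + 1
  }
  out <- do.call(rbind, res)
  colnames(out) <- c("i", "j", "k")
  out
}

#' Rasterized axon point cloud of a neuron within a region
#'
#' Grid-cell centres traversed by the neuron's axonal segments whose child
#' node lies in `region_id` (and hemisphere, if given), in micrometre
#' coordinates. This is the grid-interpolated point set used for overlap
#' scores.
#'
#' @param nrn a `"neuron"`.
#' @param atlas a `"region_atlas"`.
#' @param region_id target region label.
#' @param hemisphere optional `"left"`/`"right"` restriction.
#' @param grid_spacing raster grid spacing, micrometres.
#' @return m x 3 matrix of cell-centre coordinates.
#' @export
axon_cloud_points <- function(nrn, atlas, region_id, hemisphere = NULL,
                              grid_spacing = 10) {
  ed <- compartment_edges(nrn, "axon")
  if (!length(ed$child)) return(matrix(numeric(0), ncol = 3L))
  reg <- lookup_region(atlas, ed$p1)
  keep <- reg == region_id
  if (!is.null(hemisphere))
    keep <- keep & hemisphere_of(atlas, ed$p1) == hemisphere
  if (!any(keep)) return(matrix(numeric(0), ncol = 3L))
  cells <- rasterize_segments(ed$p0[keep, , drop = FALSE],
                              ed$p1[keep, , drop = FALSE],
                              grid_spacing = grid_spacing,
                              origin = atlas$origin)
  sweep(as.matrix(cells) + 0.5, 2, rep_len(grid_spacing, 3L), "*") +
    matrix(atlas$origin, nrow(cells), 3L, byrow = TRUE)
}
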