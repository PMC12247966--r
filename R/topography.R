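#' Centroid of an arbor after uniform resampling
#'
#' Mean of the arbor's points after resampling every segment to uniform
#' density, so long sparse segments are weighted by their length rather
#' than their node count. As the resampling step shrinks, this converges to
#' the length-weighted segment-midpoint centroid.
#'
#' @param p0,p1 segment endpoint matrices (micrometres).
#' @param step resampling step, micrometres.
#' @return length-3 centroid.
#' @export
arbor_centroid <- function(p0, p1, step = 1) {
  p0 <- rbind3(p0); p1 <- rbind3(p1)
  if (!nrow(p0)) stop("empty arbor", call. = FALSE)
  colMeans(resample_segments(p0, p1, step = step))
}

#' Centroid of a neuron's arbor in a region
#'
#' @param nrn a `"neuron"`.
#' @param atlas a `"region_atlas"`.
#' @param region_id region label.
#' @param hemisphere optional `"left"`/`"right"` side restriction.
#' @param step resampling step, micrometres.
#' @return length-3 centroid, or NULL when the neuron has no axon in the
#'   region.
#' @export
region_arbor_centroid <- function(nrn, atlas, region_id, hemisphere = NULL,
                                  step = 1) {
  ed <- compartment_edges(nrn, "axon")
  if (!length(ed$child)) return(NULL)
  reg <- lookup_region(atlas, ed$p1)
  keep <- reg == region_id
  if (!is.null(hemisphere))
    keep <- keep & hemisphere_of(atlas, ed$p1) == hemisphere
  if (!any(keep)) return(NULL)
  arbor_centroid(ed$p0[keep, , drop = FALSE], ed$p1[keep, , drop = FALSE],
                 step = step)
}

#' First principal axis of a point set
#'
#' Leading eigenvector of the covariance matrix (Hotelling transform). The
#' eigenvector sign is ambiguous, so it is fixed deterministically: the
#' component of largest magnitude is made positive (smallest index on ties,
#' flagged). Tied leading eigenvalues are resolved by taking the first
#' eigenvector returned, flagged.
#'
#' @param points n x 3 matrix, n >= 3.
#' @return unit length-3 vector with attributes `tied_eigenvalues` and
#'   `tied_components` (logical flags).
#' @export
principal_axis <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 3L) stop("need >= 3 points", call. = FALSE)
  cv <- stats::cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  tied_ev <- length(eg$values) > 1 &&
    isTRUE(all.equal(eg$values[1], eg$values[2]))
  mags <- abs(v)
  lead <- which(mags == max(mags))
  tied_comp <- length(lead) > 1L
  lead <- lead[1L]
  if (v[lead] < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  attr(v, "tied_eigenvalues") <- tied_ev
  attr(v, "tied_components") <- tied_comp
  v
}

#' Topographic alignment of somata and arbor centroids
#'
#' Projects the soma set S and the paired centroid set C each onto its own
#' first principal axis and reports Spearman's rank correlation rho of the
#' projections (average ranks on ties). rho near +1 means somata and
#' arborizations align in the same spatial order along the dominant axes;
#' negative rho means they align in the opposite order.
#'
#' @param somas n x 3 matrix of soma positions (micrometres).
#' @param centroids n x 3 matrix of paired arbor centroids, same row order.
#' @param n_total optional number of cells in the source group (for the
#'   projecting fraction; default `nrow(somas)`).
#' @return list of class `"topography"`: `rho`, `n_cells`,
#'   `projecting_fraction`, `axis_S`, `axis_C`, `proj_S`, `proj_C`,
#'   `degenerate` (TRUE when a projection is constant; rho then NA).
#' @export
topography_rho <- function(somas, centroids, n_total = NULL) {
  S <- rbind3(somas); C <- rbind3(centroids)
  if (nrow(S) != nrow(C)) stop("somas and centroids must be paired",
                               call. = FALSE)
  if (nrow(S) < 3L) stop("need >= 3 paired cells", call. = FALSE)
  if (is.null(n_total)) n_total <- nrow(S)
  ax_s <- principal_axis(S)
  ax_c <- principal_axis(C)
  ps <- as.vector(S %*% ax_s)
  pc <- as.vector(C %*% ax_c)
  degen <- stats::sd(ps) == 0 || stats::sd(pc) == 0
  rho <- if (degen) NA_real_ else
    stats::cor(ps, pc, method = "spearman")
  structure(list(rho = rho, n_cells = nrow(S),
                 projecting_fraction = nrow(S) / n_total,
                 axis_S = as.vector(ax_s), axis_C = as.vector(ax_c),
                 proj_S = ps, proj_C = pc, degenerate = degen),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat("<topography> rho =", sprintf("%.3f", x$rho), "over", x$n_cells,
      "cells (projecting fraction",
      sprintf("%.2f", x$projecting_fraction), ")\n")
  invisible(x)
}

#' Population topography for a source area and target region
#'
#' Collects soma positions and per-cell arbor centroids (cells without a
#' passing arbor in the target are excluded from the pairing and counted in
#' the projecting fraction), then runs [topography_rho()].
#'
#' @param neurons list of `"neuron"` objects from one source area.
#' @param atlas a `"region_atlas"`.
#' @param region_id target region label.
#' @param hemisphere optional side restriction (`"left"`/`"right"`).
#' @param step centroid resampling step, micrometres.
#' @param long_threshold,short_threshold target filter thresholds.
#' @return a `"topography"` result, or NULL if fewer than 3 cells project.
#' @export
population_topography <- function(neurons, atlas, region_id,
                                  hemisphere = NULL, step = 2,
                                  long_threshold = 1000,
                                  short_threshold = 20) {
  somas <- list(); cents <- list()
  for (nrn in neurons) {
    arb <- decompose_arbors(nrn, atlas)
    if (!is.null(hemisphere)) arb <- arb[arb$side == hemisphere, ,
                                         drop = FALSE]
    arb <- arb[arb$region_id == region_id, , drop = FALSE]
    if (!nrow(arb)) next
    pass <- call_target(arb$axon_length, arb$n_terminals,
                        arb$max_branch_order_within,
                        long_threshold, short_threshold)
    if (!any(pass)) next
    ctr <- region_arbor_centroid(nrn, atlas, region_id, hemisphere, step)
    if (is.null(ctr)) next
    somas[[length(somas) + 1L]] <- soma_position(nrn)
    cents[[length(cents) + 1L]] <- ctr
  }
  if (length(somas) < 3L) return(NULL)
  topography_rho(do.call(rbind, somas), do.call(rbind, cents),
                 n_total = length(neurons))
}
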