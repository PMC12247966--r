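#' Axon-cloud overlap score
#'
#' Class-separability-based overlap between two axon point clouds (the
#' clouds should be grid-interpolated, see [axon_cloud_points()]). With the
#' two clouds as classes, the separability is
#' \deqn{S = tr(S_B) / tr(S_W)} where \eqn{S_B = \sum_i n_i (m_i - \bar m)
#' (m_i - \bar m)^T} is the between-class scatter matrix and
#' \eqn{S_W = \sum_i \sum_j (x_{ij} - m_i)(x_{ij} - m_i)^T} the
#' within-class scatter matrix; the overlap is \eqn{O = \max(0, 1 - S)},
#' 1 for coincident clouds and 0 for fully separable ones.
#'
#' Degenerate case (tr(S_W) = 0, all points identical within each cloud):
#' O = 1 if the two class means also coincide, else O = 0, flagged.
#'
#' @param cloud_a,cloud_b n x 3 (or n x d) point matrices.
#' @return list: `S`, `O`, `n` (per-class point counts), `degenerate`.
#' @export
overlap_score <- function(cloud_a, cloud_b) {
  a <- rbind3(cloud_a); b <- rbind3(cloud_b)
  if (!nrow(a) || !nrow(b)) stop("empty cloud", call. = FALSE)
  ma <- colMeans(a); mb <- colMeans(b)
  na <- nrow(a); nb <- nrow(b)
  m <- (na * ma + nb * mb) / (na + nb)
  tr_b <- na * sum((ma - m)^2) + nb * sum((mb - m)^2)
  tr_w <- sum(sweep(a, 2, ma)^2) + sum(sweep(b, 2, mb)^2)
  if (tr_w == 0) {
    O <- if (sum((ma - mb)^2) == 0) 1 else 0
    return(list(S = if (O == 1) 0 else Inf, O = O, n = c(na, nb),
                degenerate = TRUE))
  }
  S <- tr_b / tr_w
  list(S = S, O = max(0, 1 - S), n = c(na, nb), degenerate = FALSE)
}

#' Pairwise overlap matrix across source areas
#'
#' Overlap scores for all pairs of axon clouds converging in one region,
#' with a summary of the distribution. Sources whose cloud is empty are
#' reported as missing (NA), not as zero overlap.
#'
#' @param clouds named list of point matrices, one per source area.
#' @return list: `O` (symmetric matrix, unit diagonal, NA for missing
#'   sources), `summary` (mean, se over off-diagonal present pairs,
#'   `frac_above_0.5`, `frac_zero`).
#' @export
overlap_matrix <- function(clouds) {
  ok <- vapply(clouds, function(p) !is.null(p) && nrow(rbind3(p)) > 0,
               logical(1))
  if (sum(ok) < 2L) stop("need >= 2 sources with nonempty clouds",
                         call. = FALSE)
  k <- length(clouds)
  O <- matrix(NA_real_, k, k, dimnames = list(names(clouds), names(clouds)))
  diag(O)[ok] <- 1
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (ok[i] && ok[j]) {
      o <- overlap_score(clouds[[i]], clouds[[j]])$O
      O[i, j] <- O[j, i] <- o
    }
  }
  off <- O[upper.tri(O)]
  off <- off[!is.na(off)]
  list(O = O,
       summary = list(mean = mean(off),
                      se = stats::sd(off) / sqrt(length(off)),
                      frac_above_0.5 = mean(off > 0.5),
                      frac_zero = mean(off == 0),
                      n_pairs = length(off)))
}

#' 3D Gaussian kernel density of an axon cloud
#'
#' Kernel density estimate of an axon point cloud, evaluated on the atlas
#' voxel grid restricted to the cloud's bounding box. The bandwidth (default
#' 0.3) is applied in per-axis standardized coordinates (points centred and
#' scaled to unit standard deviation), since it is a unitless smoothing
#' parameter; set `standardize = FALSE` to interpret it in micrometres.
#'
#' @param points n x 3 point matrix (micrometres), n >= 10.
#' @param bandwidth Gaussian kernel bandwidth (default 0.3).
#' @param voxel_size evaluation grid spacing, micrometres.
#' @param standardize apply bandwidth in standardized coordinates.
#' @param pad bounding-box padding in voxels.
#' @return list of class `"axon_kde"`: `density` (3D array, mean kernel
#'   density), `grid` (list of axis coordinate vectors), `voxel_size`.
#' @export
kde_cloud <- function(points, bandwidth = 0.3, voxel_size = 10,
                      standardize = TRUE, pad = 2L) {
  points <- rbind3(points)
  if (nrow(points) < 10L) stop("need >= 10 points", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  ctr <- colMeans(points)
  scl <- apply(points, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  if (!standardize) { ctr <- c(0, 0, 0); scl <- c(1, 1, 1) }
  grid <- lapply(1:3, function(ax) {
    lo <- floor(min(points[, ax]) / voxel_size[ax]) - pad
    hi <- ceiling(max(points[, ax]) / voxel_size[ax]) + pad
    (seq(lo, hi) + 0.5) * voxel_size[ax]
  })
  # separable product kernel: K_ax[g, p] = phi((grid - x_p)/h) per axis
  K <- lapply(1:3, function(ax) {
    u <- outer((grid[[ax]] - ctr[ax]) / scl[ax],
               (points[, ax] - ctr[ax]) / scl[ax], "-") / bandwidth
    stats::dnorm(u)
  })
  nx <- length(grid[[1]]); ny <- length(grid[[2]]); nz <- length(grid[[3]])
  dens <- array(0, dim = c(nx, ny, nz))
  tKy <- t(K[[2]])
  for (k in seq_len(nz))
    dens[, , k] <- K[[1]] %*% (K[[3]][k, ] * tKy)
  dens <- dens / nrow(points)
  structure(list(density = dens, grid = grid, voxel_size = voxel_size),
            class = "axon_kde")
}

#' Axon cloud volume and mean axon density
#'
#' Volume is the number of voxels with density at or above
#' `rel_threshold` times the maximum density, times the voxel volume
#' (the density threshold is relative to the cloud's own maximum).
#' Mean axon density is total axonal length divided by that volume
#' (um/um^3).
#'
#' @param kde an `"axon_kde"` from [kde_cloud()].
#' @param total_length total axonal length of the cloud, micrometres
#'   (NA to skip the density).
#' @param rel_threshold relative density threshold (default 0.01, i.e. 1%).
#' @return list: `volume_um3`, `n_voxels`, `mean_density` (um/um^3, NA when
#'   volume is zero or length not given), `degenerate` flag.
#' @export
cloud_volume <- function(kde, total_length = NA_real_, rel_threshold = 0.01) {
  mx <- max(kde$density)
  nvox <- sum(kde$density >= rel_threshold * mx)
  vol <- nvox * prod(kde$voxel_size)
  dens <- if (vol > 0 && is.finite(total_length)) total_length / vol
          else NA_real_
  list(volume_um3 = vol, n_voxels = nvox, mean_density = dens,
       degenerate = vol == 0)
}

#' Cluster convergent-region targets by axonal composition
#'
#' Rows of `composition` are target (sub)regions; columns are
#' (cell type, source area) contributors; entries are summed axonal lengths.
#' Rows are normalized to proportions, then targets and contributors are
#' hierarchically clustered with the one-minus-Pearson metric and average
#' linkage; cosine similarity matrices are returned for both.
#'
#' @param composition nonnegative numeric matrix with row/col names.
#' @return list: `proportions`, `target_hclust`, `type_hclust`
#'   (stats::hclust objects), `target_similarity`, `type_similarity`
#'   (cosine similarity matrices), `dropped` (all-zero rows removed).
#' @export
composition_cluster <- function(composition) {
  composition <- as.matrix(composition)
  if (any(composition < 0)) stop("composition must be nonnegative",
                                 call. = FALSE)
  zero <- rowSums(composition) == 0
  if (any(zero)) warning("dropping all-zero row(s): ",
                         paste(rownames(composition)[zero], collapse = ", "))
  comp <- composition[!zero, , drop = FALSE]
  prop <- comp / rowSums(comp)
  cosine <- function(m) {
    nm <- m / sqrt(rowSums(m^2))
    s <- tcrossprod(nm)
    diag(s) <- 1
    s
  }
  list(proportions = prop,
       target_hclust = hclust_pearson(prop),
       type_hclust = hclust_pearson(t(prop)),
       target_similarity = cosine(prop),
       type_similarity = cosine(t(prop)),
       dropped = rownames(composition)[zero])
}

# one-minus-Pearson distance between rows, average linkage
hclust_pearson <- function(m) {
  d <- 1 - stats::cor(t(m))
  d[!is.finite(d)] <- 2  # constant rows: maximally distant
  stats::hclust(stats::as.dist(d), method = "average")
}
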