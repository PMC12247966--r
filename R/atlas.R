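#' Construct a region atlas
#'
#' A region atlas is a 3D integer label volume with voxel size and origin in
#' micrometres, a midline plane splitting the two hemispheres along the x
#' axis, and a region metadata table. Voxel `(i, j, k)` (0-based) covers the
#' half-open box `[origin + i * voxel, origin + (i + 1) * voxel)`.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param voxel_size voxel edge length(s) in micrometres (scalar or length 3).
#' @param origin coordinate of the corner of voxel (0,0,0), micrometres.
#' @param midline x coordinate of the hemispheric midline plane, micrometres.
#' @param regions data.frame with columns `region_id`, `name`, `layer`,
#'   `group`, `hierarchy_level` (layer and hierarchy_level may be NA).
#' @return an object of class `"region_atlas"`.
#' @export
region_atlas <- function(labels, voxel_size, origin = c(0, 0, 0),
                         midline, regions) {
  stopifnot(length(dim(labels)) == 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0", call. = FALSE)
  need <- c("region_id", "name", "layer", "group", "hierarchy_level")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("regions table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lab <- sort(unique(as.vector(labels)))
  lab <- lab[lab != 0L]
  unknown <- setdiff(lab, regions$region_id)
  if (length(unknown))
    stop("labels not in regions table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, voxel_size = voxel_size,
                 origin = as.numeric(origin), midline = as.numeric(midline),
                 regions = as.data.frame(regions)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas>", paste(dim(x$labels), collapse = "x"), "voxels @",
      paste(x$voxel_size, collapse = "x"), "um;",
      nrow(x$regions), "regions\n")
  invisible(x)
}

#' Voxel index of points (0-based)
#'
#' @param atlas a `"region_atlas"`.
#' @param points n x 3 matrix of coordinates in micrometres.
#' @return n x 3 integer matrix of 0-based voxel indices (may lie outside
#'   the volume).
#' @export
voxel_index <- function(atlas, points) {
  points <- rbind3(points)
  idx <- floor(sweep(sweep(points, 2, atlas$origin, "-"),
                     2, atlas$voxel_size, "/"))
  storage.mode(idx) <- "integer"
  idx
}

# coerce a 3-vector or n x 3 matrix to matrix
rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  as.matrix(points)
}

#' Region label at points
#'
#' Points outside the label volume map to region 0 (background).
#'
#' @inheritParams voxel_index
#' @return integer vector of region labels.
#' @export
lookup_region <- function(atlas, points) {
  idx <- voxel_index(atlas, points)
  dm <- dim(atlas$labels)
  inside <- idx[, 1] >= 0L & idx[, 1] < dm[1] &
    idx[, 2] >= 0L & idx[, 2] < dm[2] &
    idx[, 3] >= 0L & idx[, 3] < dm[3]
  out <- integer(nrow(idx))
  if (any(inside))
    out[inside] <- atlas$labels[idx[inside, , drop = FALSE] + 1L]
  out
}

#' Hemisphere of points
#'
#' Deterministic split at the atlas midline plane: x < midline is `"left"`,
#' x >= midline is `"right"`.
#'
#' @inheritParams voxel_index
#' @return character vector `"left"`/`"right"`.
#' @export
hemisphere_of <- function(atlas, points) {
  points <- rbind3(points)
  ifelse(points[, 1] < atlas$midline, "left", "right")
}

#' Read / write the region metadata table
#'
#' Plain TSV with columns `region_id`, `name`, `layer`, `group`,
#' `hierarchy_level`.
#'
#' @param path file path.
#' @return `read_region_table`: the data.frame.
#' @export
read_region_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_region_table
#' @param regions region metadata data.frame.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Atlas label-volume I/O via NIfTI
#'
#' Writes the label volume as NIfTI-1 (with isotropic pixdim set to the
#' voxel size) plus the region table as a sibling TSV; reads them back.
#' Requires the RNifti package.
#'
#' @param atlas a `"region_atlas"`.
#' @param path output path for the `.nii.gz` volume; the region table is
#'   written to `<path>.regions.tsv`.
#' @return `read_atlas_nifti`: a `"region_atlas"`.
#' @export
write_atlas_nifti <- function(atlas, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti not available", call. = FALSE)
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$voxel_size
  RNifti::writeNifti(img, path)
  write_region_table(atlas$regions, paste0(path, ".regions.tsv"))
  meta <- data.frame(origin_x = atlas$origin[1], origin_y = atlas$origin[2],
                     origin_z = atlas$origin[3], midline = atlas$midline,
                     voxel_x = atlas$voxel_size[1],
                     voxel_y = atlas$voxel_size[2],
                     voxel_z = atlas$voxel_size[3])
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti not available", call. = FALSE)
  img <- RNifti::readNifti(path)
  regions <- read_region_table(paste0(path, ".regions.tsv"))
  meta <- utils::read.delim(paste0(path, ".meta.tsv"))
  lab <- array(as.integer(round(as.array(img))), dim = dim(img))
  region_atlas(lab, voxel_size = c(meta$voxel_x, meta$voxel_y, meta$voxel_z),
               origin = c(meta$origin_x, meta$origin_y, meta$origin_z),
               midline = meta$midline, regions = regions)
}
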