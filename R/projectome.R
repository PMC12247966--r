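#' Projection target filter
#'
#' Decides whether an arbor counts as a genuine projection target. Criteria:
#' arbors with axonal length above `long_threshold` need at least one
#' terminal node (this excludes passing fibers, which have length but no
#' endings); arbors with length in `[short_threshold, long_threshold]` need
#' at least one terminal node and a second-order bifurcation (a branch point
#' downstream of another branch point within the arbor, i.e. maximum
#' within-arbor branch order of at least 2); shorter arbors never pass.
#'
#' @param axon_length arbor axonal length, micrometres (vectorized).
#' @param n_terminals terminal node count (vectorized).
#' @param max_branch_order maximum within-arbor branch order (vectorized).
#' @param long_threshold,short_threshold band limits, micrometres
#'   (defaults 1000 and 20).
#' @return logical vector: passes the target filter.
#' @export
call_target <- function(axon_length, n_terminals, max_branch_order,
                        long_threshold = 1000, short_threshold = 20) {
  long_pass <- axon_length > long_threshold & n_terminals >= 1L
  band_pass <- axon_length >= short_threshold &
    axon_length <= long_threshold &
    n_terminals >= 1L & max_branch_order >= 2L
  long_pass | band_pass
}

#' Apply the target filter to an arbor table
#'
#' Adds a `passes_filter` column to the output of
#' [decompose_population()].
#'
#' @param arbors arbor table with `axon_length`, `n_terminals`,
#'   `max_branch_order_within` columns.
#' @inheritParams call_target
#' @return the table with a logical `passes_filter` column.
#' @export
filter_targets <- function(arbors, long_threshold = 1000,
                           short_threshold = 20) {
  arbors$passes_filter <- call_target(arbors$axon_length, arbors$n_terminals,
                                      arbors$max_branch_order_within,
                                      long_threshold, short_threshold)
  arbors
}

#' Build TargProb/TargStren connectome matrices
#'
#' Rows are (cell type, source area) groups; columns are (target region,
#' hemisphere) pairs. TargProb is the percentage of the row group's cells
#' with a passing arbor in the column; TargStren is the mean arbor axonal
#' length (um) over those passing cells ("AxL/C"), defined only where
#' TargProb > 0.
#'
#' @param arbors arbor table from [decompose_population()], one row per
#'   (cell, region, side); must carry `cell_type` and `source_area`.
#' @param cells optional data.frame of all cells (`cell_id`, `cell_type`,
#'   `source_area`): cells with no arbor rows still count in denominators.
#'   Defaults to the distinct cells present in `arbors`.
#' @param by_hemisphere keep ipsi/contra as separate columns (default TRUE).
#' @inheritParams call_target
#' @return object of class `"connectome"`: a list with `table` (tidy
#'   data.frame: cell_type, source_area, region_id, hemisphere, n_cells,
#'   n_passing, targ_prob [percent], targ_stren [um]), and `rows` (per-row
#'   n_cells and target_number = number of columns with TargProb > 0).
#' @export
build_connectome <- function(arbors, cells = NULL, by_hemisphere = TRUE,
                             long_threshold = 1000, short_threshold = 20) {
  if (!nrow(arbors)) stop("empty arbor table", call. = FALSE)
  if (!"passes_filter" %in% names(arbors))
    arbors <- filter_targets(arbors, long_threshold, short_threshold)
  if (is.null(cells))
    cells <- unique(arbors[, c("cell_id", "cell_type", "source_area")])
  cells$row <- paste(cells$cell_type, cells$source_area, sep = "|")
  n_cells <- table(cells$row)
  drop <- names(n_cells)[n_cells == 0L]
  if (length(drop)) warning("empty row group(s) excluded")

  hemi <- if (by_hemisphere) arbors$hemisphere else "both"
  pass <- arbors[arbors$passes_filter, , drop = FALSE]
  ph <- if (by_hemisphere) pass$hemisphere else "both"
  key <- factor(paste(pass$cell_type, pass$source_area, pass$region_id, ph,
                      sep = "\r"))
  agg <- data.frame(key = levels(key),
                    n_passing = as.integer(tapply(pass$cell_id, key,
                                                  function(z) length(unique(z)))),
                    targ_stren = as.numeric(tapply(pass$axon_length, key, mean)))
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  tab <- data.frame(cell_type = parts[, 1], source_area = parts[, 2],
                    region_id = as.integer(parts[, 3]),
                    hemisphere = parts[, 4],
                    n_passing = agg$n_passing,
                    targ_stren = agg$targ_stren)
  tab$row <- paste(tab$cell_type, tab$source_area, sep = "|")
  tab$n_cells <- as.integer(n_cells[tab$row])
  tab$targ_prob <- 100 * tab$n_passing / tab$n_cells
  tab <- tab[, c("cell_type", "source_area", "region_id", "hemisphere",
                 "n_cells", "n_passing", "targ_prob", "targ_stren")]
  tab <- tab[order(tab$cell_type, tab$source_area, tab$region_id,
                   tab$hemisphere), ]
  rownames(tab) <- NULL
  rows <- aggregate(cbind(target_number = targ_prob > 0) ~
                      cell_type + source_area, data = tab, FUN = sum)
  rows$n_cells <- as.integer(
    n_cells[paste(rows$cell_type, rows$source_area, sep = "|")])
  structure(list(table = tab, rows = rows), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", nrow(x$rows), "row group(s),",
      nrow(x$table), "targets\n")
  invisible(x)
}

#' Summarize weak targets
#'
#' Fractions of targets (TargProb > 0 cells of the connectome) whose
#' targeting strength exceeds `axl_cut` and whose targeting probability
#' exceeds `prob_cut`. Defaults follow the cortico-cortical weak-target
#' thresholds (1000 um, 2.4%).
#'
#' @param connectome a `"connectome"` object.
#' @param axl_cut targeting-strength cut, micrometres.
#' @param prob_cut targeting-probability cut, percent.
#' @return list: `n_targets`, `frac_axl_above`, `frac_prob_above`.
#' @export
weak_target_summary <- function(connectome, axl_cut = 1000, prob_cut = 2.4) {
  tab <- connectome$table
  tab <- tab[tab$targ_prob > 0, , drop = FALSE]
  if (!nrow(tab)) stop("connectome has no targets", call. = FALSE)
  list(n_targets = nrow(tab),
       frac_axl_above = mean(tab$targ_stren > axl_cut),
       frac_prob_above = mean(tab$targ_prob > prob_cut))
}

#' Laminar targeting profile
#'
#' Per-layer TargProb within one target area, normalized to the maximum
#' laminar TargProb of that area so the preferred layer scores exactly 1.
#'
#' @param connectome a `"connectome"` object built over layer-resolved
#'   region labels.
#' @param atlas a `"region_atlas"` whose regions table maps labels to
#'   `name` and `layer`.
#' @param target_area area name (regions of this area across layers form
#'   the profile).
#' @param cell_type,source_area row group selectors.
#' @param hemisphere `"ipsi"` (default) or `"contra"`.
#' @return data.frame `layer`, `targ_prob`, `norm_prob`, with attribute
#'   `all_zero` TRUE when no layer is targeted (profile returned as zeros).
#' @export
laminar_profile <- function(connectome, atlas, target_area, cell_type,
                            source_area, hemisphere = "ipsi") {
  reg <- atlas$regions
  area_rows <- reg[!is.na(reg$layer) & reg$name == target_area, ,
                   drop = FALSE]
  if (!nrow(area_rows))
    stop("target area has no layer subregions: ", target_area, call. = FALSE)
  tab <- connectome$table
  tab <- tab[tab$cell_type == cell_type & tab$source_area == source_area &
               tab$hemisphere == hemisphere &
               tab$region_id %in% area_rows$region_id, , drop = FALSE]
  layers <- unique(area_rows$layer)
  prob <- setNames(rep(0, length(layers)), layers)
  if (nrow(tab)) {
    lay <- area_rows$layer[match(tab$region_id, area_rows$region_id)]
    agg <- tapply(tab$targ_prob, lay, sum)
    prob[names(agg)] <- agg
  }
  mx <- max(prob)
  out <- data.frame(layer = names(prob), targ_prob = unname(prob),
                    norm_prob = if (mx > 0) unname(prob) / mx else
                      unname(prob))
  attr(out, "all_zero") <- mx == 0
  out
}

#' Hemispheric symmetry of targeting patterns
#'
#' Pearson correlation between a row group's ipsilateral and contralateral
#' TargProb vectors over paired target regions, with a seeded permutation
#' p-value.
#'
#' @param connectome a `"connectome"` object.
#' @param cell_type,source_area row group selectors.
#' @param region_key optional named vector mapping region ids to an
#'   area key shared by the mirror-image regions of the two hemispheres
#'   (e.g. "A2 L5" for both side-specific labels); identity when NULL,
#'   which assumes region ids are already side-agnostic.
#' @param n_perm number of permutations for the p-value.
#' @param seed RNG seed.
#' @return list: `r`, `p_value`, `n_regions`, `degenerate` (TRUE when a
#'   vector has zero variance; `r` is then NA).
#' @export
hemispheric_symmetry <- function(connectome, cell_type, source_area,
                                 region_key = NULL, n_perm = 1e4,
                                 seed = 1L) {
  tab <- connectome$table
  tab <- tab[tab$cell_type == cell_type & tab$source_area == source_area, ,
             drop = FALSE]
  key <- if (is.null(region_key)) as.character(tab$region_id)
         else unname(region_key[as.character(tab$region_id)])
  regions <- unique(key)
  ipsi <- setNames(rep(0, length(regions)), regions)
  contra <- ipsi
  ti <- tapply(tab$targ_prob[tab$hemisphere == "ipsi"],
               key[tab$hemisphere == "ipsi"], sum)
  tc <- tapply(tab$targ_prob[tab$hemisphere == "contra"],
               key[tab$hemisphere == "contra"], sum)
  ipsi[names(ti)] <- ti
  contra[names(tc)] <- tc
  if (length(regions) < 3L)
    stop("need at least 3 paired regions", call. = FALSE)
  if (stats::sd(ipsi) == 0 || stats::sd(contra) == 0)
    return(list(r = NA_real_, p_value = NA_real_,
                n_regions = length(regions), degenerate = TRUE))
  r <- stats::cor(ipsi, contra)
  set.seed(seed)
  null_r <- replicate(n_perm, stats::cor(ipsi, sample(contra)))
  p <- (1 + sum(abs(null_r) >= abs(r))) / (n_perm + 1)
  list(r = r, p_value = p, n_regions = length(regions), degenerate = FALSE)
}
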