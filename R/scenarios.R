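#' Canned synthetic study scenarios
#'
#' Ready-made generator configurations exercising each stage of the
#' pipeline. All return `list(atlas, types)` ready for
#' [generate_population()].
#'
#' `scenario_basic()`: a layered 3-area cortex with two subcortical blocks
#' and three cell types — an IT-like type targeting other cortical areas
#' bilaterally, an ET-like type targeting subcortex, and a CT-like type
#' with a local target plus a terminal-free passing fiber through a
#' non-target area (for filter-specificity checks).
#'
#' @param n_per_type cells per type.
#' @return list with elements `atlas` and `types`.
#' @export
scenario_basic <- function(n_per_type = 25) {
  atlas <- synth_atlas(n_areas = 3, layers = c("L2/3", "L5", "L6"),
                       n_sub = 2)
  types <- list(
    cell_type_spec("IT", n_per_type, "A1", soma_depth = 300,
                   dendrite = "tufted",
                   targets = data.frame(
                     area = c("A1", "A2", "A3"),
                     layer = c("L5", "L2/3", "L5"),
                     prob = c(1, 0.8, 0.5),
                     mean_axl = c(3000, 1800, 1200),
                     contra_prob = c(0.9, 0.5, 0.25),
                     contra_axl_scale = c(0.5, 0.6, 0.6))),
    cell_type_spec("ET", n_per_type, "A2", soma_depth = 320,
                   dendrite = "tufted", dendrite_scale = 1.4,
                   targets = data.frame(
                     area = c("A2", "S1", "S2"),
                     layer = c("L5", NA, NA),
                     prob = c(1, 0.9, 0.6),
                     mean_axl = c(2500, 2200, 1500))),
    cell_type_spec("CT", n_per_type, "A3", soma_depth = 500,
                   dendrite = "untufted",
                   targets = data.frame(
                     area = c("A3", "S2"), layer = c("L6", NA),
                     prob = c(1, 0.8), mean_axl = c(2000, 1600)),
                   fiber_through = "A2"))
  list(atlas = atlas, types = types)
}

#' @rdname scenario_basic
#' @param mode topographic mode, `"aligned"` or `"reversed"`.
#' @param n_cells cells in the source area.
#' @param sigma topographic noise sd, micrometres.
#' @export
scenario_topography <- function(mode = "aligned", n_cells = 50, sigma = 30) {
  atlas <- synth_atlas(n_areas = 3, layers = NULL, layer_thickness = 600,
                       n_sub = 1)
  types <- list(
    cell_type_spec("PT", n_cells, "A1", soma_depth = 300,
                   dendrite = "untufted",
                   targets = data.frame(area = "A3", prob = 1,
                                        mean_axl = 1500),
                   topography = mode, topo_sigma = sigma,
                   soma_xz_frac = c(0.15, 1), arbor_radius = 80))
  list(atlas = atlas, types = types)
}

#' @rdname scenario_basic
#' @param n_levels number of cortical areas / planted hierarchy levels.
#' @param prob_base,prob_slope targeting probability of a level-h target is
#'   `prob_base + prob_slope * h` (the planted hierarchy drives how often a
#'   region is targeted).
#' @export
scenario_hierarchy <- function(n_per_type = 200, n_levels = 5,
                               prob_base = 0.1, prob_slope = 0.15) {
  atlas <- synth_atlas(n_areas = n_levels, layers = NULL,
                       layer_thickness = 600, n_sub = 0,
                       hierarchy_levels = seq_len(n_levels))
  areas <- paste0("A", seq_len(n_levels))
  types <- lapply(seq_len(n_levels), function(a) {
    tgt <- setdiff(seq_len(n_levels), a)
    cell_type_spec(paste0("T", a), n_per_type, areas[a], soma_depth = 300,
                   dendrite = "untufted",
                   targets = data.frame(
                     area = areas[tgt],
                     prob = pmin(1, prob_base + prob_slope * tgt),
                     mean_axl = 1500))
  })
  list(atlas = atlas, types = types)
}

#' @rdname scenario_basic
#' @param prob,mean_axl,contra_prob,contra_axl_scale planted projection
#'   parameters for the single-target recovery scenario.
#' @export
scenario_recovery <- function(n_per_type = 200, prob = 0.7,
                              mean_axl = 2000, contra_prob = 0.5,
                              contra_axl_scale = 0.6) {
  atlas <- synth_atlas(n_areas = 2, layers = NULL, layer_thickness = 600,
                       n_sub = 1)
  types <- list(
    cell_type_spec("IT", n_per_type, "A1", soma_depth = 300,
                   dendrite = "untufted",
                   targets = data.frame(area = "A2", prob = prob,
                                        mean_axl = mean_axl,
                                        contra_prob = contra_prob,
                                        contra_axl_scale = contra_axl_scale)))
  list(atlas = atlas, types = types)
}

#' Planted-class Gaussian feature table
#'
#' Synthetic morphometric feature matrix with `k` classes whose class
#' means are separated by `sep` within-class standard deviations along
#' every feature — the regime in which both hierarchical clustering and a
#' random-forest classifier should recover the planted types.
#'
#' @param n_per_class cells per class; `k` classes; `p` features;
#'   `sep` separation in SD units; `seed` RNG seed.
#' @return list: `features` (data.frame), `labels` (factor).
#' @export
planted_feature_table <- function(n_per_class = 40, k = 4, p = 9, sep = 3,
                                  seed = 1L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * p), k, p)
  # rescale so every pair of class means differs by >= sep SDs per feature
  for (jj in seq_len(p)) {
    ord <- order(centers[, jj])
    centers[ord, jj] <- seq(0, by = sep, length.out = k)
  }
  X <- do.call(rbind, lapply(seq_len(k), function(cl) {
    matrix(stats::rnorm(n_per_class * p, mean = rep(centers[cl, ],
                                                    each = n_per_class)),
           n_per_class, p)
  }))
  colnames(X) <- paste0("f", seq_len(p))
  list(features = as.data.frame(X),
       labels = factor(rep(paste0("type", seq_len(k)), each = n_per_class)))
}
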