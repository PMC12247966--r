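#' Decompose a neuron's axon into per-region arbors
#'
#' Every axonal parent-to-child segment is assigned to the atlas region and
#' hemisphere of its child node (no sub-segment clipping, so summed arbor
#' lengths conserve total axonal length exactly). Per (region, hemisphere)
#' the arbor aggregates axonal length, terminal count (axon terminals whose
#' node lies in the region) and the maximum within-arbor branch order,
#' recomputed from the arbor's own entry nodes. Out-of-atlas nodes map to
#' region 0 and are reported under that label.
#'
#' Note the caller contract: neuron and atlas must share coordinate units
#' (micrometres); a unit mismatch cannot be detected here.
#'
#' @param nrn a `"neuron"`.
#' @param atlas a `"region_atlas"`.
#' @return data.frame with one row per arbor: `cell_id`, `region_id`,
#'   `side` (left/right), `hemisphere` (ipsi/contra relative to the soma),
#'   `axon_length` (um), `n_terminals`, `max_branch_order_within`,
#'   `n_nodes`, and a list column `node_ids`.
#' @export
decompose_arbors <- function(nrn, atlas) {
  ed <- compartment_edges(nrn, "axon")
  soma <- soma_position(nrn)
  soma_side <- hemisphere_of(atlas, soma)
  empty <- data.frame(cell_id = character(0), region_id = integer(0),
                      side = character(0), hemisphere = character(0),
                      axon_length = numeric(0), n_terminals = integer(0),
                      max_branch_order_within = integer(0),
                      n_nodes = integer(0))
  if (!length(ed$child)) return(empty)

  nd <- nrn$nodes
  axon_ids <- nd$id[nd$type == SWC_TYPES[["axon"]]]
  pts <- as.matrix(nd[axon_ids, c("x", "y", "z"), drop = FALSE])
  node_region <- lookup_region(atlas, pts)
  node_side <- hemisphere_of(atlas, pts)
  key <- paste(node_region, node_side)

  # segment -> (region, side) of child node
  ch_pos <- match(ed$child, axon_ids)
  seg_key <- key[ch_pos]

  # terminals among axon nodes (no axon children anywhere in the cell)
  bo_all <- branch_orders(nrn, "axon")
  term <- bo_all$is_terminal[match(axon_ids, bo_all$id)]

  res <- lapply(unique(seg_key), function(kk) {
    in_arbor <- key == kk
    ids <- axon_ids[in_arbor]
    bo <- branch_orders(nrn, "axon", subset = ids)
    data.frame(cell_id = nrn$cell_id,
               region_id = node_region[in_arbor][1L],
               side = node_side[in_arbor][1L],
               axon_length = sum(ed$length[seg_key == kk]),
               n_terminals = sum(term[in_arbor]),
               max_branch_order_within = if (nrow(bo)) max(bo$order) else 0L,
               n_nodes = length(ids))
  })
  out <- do.call(rbind, res)
  out$hemisphere <- ifelse(out$side == soma_side, "ipsi", "contra")
  out$node_ids <- lapply(unique(seg_key), function(kk) axon_ids[key == kk])
  rownames(out) <- NULL
  out[, c("cell_id", "region_id", "side", "hemisphere", "axon_length",
          "n_terminals", "max_branch_order_within", "n_nodes", "node_ids")]
}

#' Decompose arbors for a population of neurons
#'
#' @param neurons list of `"neuron"` objects.
#' @param atlas a `"region_atlas"`.
#' @param drop_background drop arbors in region 0 (outside any region).
#' @return combined arbor table (without the `node_ids` list column), with
#'   `cell_type` and `source_area` taken from each neuron's metadata.
#' @export
decompose_population <- function(neurons, atlas, drop_background = TRUE) {
  tabs <- lapply(neurons, function(n) {
    a <- decompose_arbors(n, atlas)
    a$node_ids <- NULL
    if (nrow(a)) {
      a$cell_type <- n$metadata$cell_type
      a$source_area <- n$metadata$source_area
    } else {
      a$cell_type <- character(0); a$source_area <- character(0)
    }
    a
  })
  out <- do.call(rbind, tabs)
  if (drop_background) out <- out[out$region_id != 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
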