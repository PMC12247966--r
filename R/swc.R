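#' @keywords internal
#' @importFrom randomForest randomForest
#' @importFrom stats cor sd median
"_PACKAGE"

# SWC compartment codes (standard dialect)
SWC_TYPES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)

swc_type_code <- function(compartment) {
  if (is.numeric(compartment)) {
    code <- as.integer(compartment)
  } else {
    if (!compartment %in% names(SWC_TYPES))
      stop("unknown compartment: ", compartment, call. = FALSE)
    code <- SWC_TYPES[[compartment]]
  }
  if (!code %in% SWC_TYPES)
    stop("unknown compartment code: ", code, call. = FALSE)
  code
}

#' Construct a neuron reconstruction
#'
#' A neuron is a rooted tree of typed nodes (soma, axon, basal dendrite,
#' apical dendrite) with 3D coordinates in micrometres. Node ids must be
#' unique; the root has `parent = -1`.
#'
#' @param cell_id character scalar identifying the cell.
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param cell_type,source_area,hemisphere optional metadata labels.
#' @param validate logical; check tree invariants (default TRUE).
#' @return an object of class `"neuron"`.
#' @export
neuron <- function(cell_id, nodes, cell_type = NA_character_,
                   source_area = NA_character_, hemisphere = NA_character_,
                   validate = TRUE) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("nodes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  nodes <- as.data.frame(nodes)[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  obj <- structure(
    list(cell_id = as.character(cell_id), nodes = nodes,
         metadata = list(cell_type = cell_type, source_area = source_area,
                         hemisphere = hemisphere,
                         original_ids = nodes$id)),
    class = "neuron")
  obj <- remap_node_ids(obj)
  if (validate) validate_neuron(obj)
  obj
}

# remap node ids to 1..n preserving originals in metadata$original_ids
remap_node_ids <- function(nrn) {
  nd <- nrn$nodes
  orig <- nd$id
  new <- seq_len(nrow(nd))
  idx <- match(nd$parent, orig)
  if (any(is.na(idx) & nd$parent != -1L))
    stop("structure error: parent id(s) ",
         paste(unique(nd$parent[is.na(idx) & nd$parent != -1L]),
               collapse = ", "),
         " reference missing nodes", call. = FALSE)
  nd$id <- new
  nd$parent <- ifelse(nd$parent == -1L, -1L, idx)
  nd$parent <- as.integer(nd$parent)
  nrn$nodes <- nd
  nrn$metadata$original_ids <- orig
  nrn
}

#' Validate neuron tree invariants
#'
#' Checks: unique node ids, exactly one root, all parent links resolve,
#' no cycles (every node reachable from the root), finite coordinates and
#' non-negative radii.
#'
#' @param nrn a `"neuron"` object.
#' @return invisibly TRUE; stops with an informative error otherwise.
#' @export
validate_neuron <- function(nrn) {
  nd <- nrn$nodes
  if (anyDuplicated(nd$id))
    stop("structure error: duplicate node ids", call. = FALSE)
  roots <- which(nd$parent == -1L)
  if (length(roots) != 1L)
    stop("structure error: expected exactly one root, found ",
         length(roots), call. = FALSE)
  if (any(nd$parent != -1L & !(nd$parent %in% nd$id)))
    stop("structure error: orphan parent id", call. = FALSE)
  coords <- as.matrix(nd[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("invalid coordinates: non-finite values", call. = FALSE)
  if (any(nd$radius < 0))
    stop("invalid radius: negative values", call. = FALSE)
  # reachability from root (cycle check)
  ord <- topo_order(nd)
  if (length(ord) != nrow(nd))
    stop("structure error: cycle or disconnected nodes", call. = FALSE)
  invisible(TRUE)
}

# children-before-parents breadth-first order starting at the root(s);
# returns row indices in an order where every parent precedes its children
topo_order <- function(nd) {
  n <- nrow(nd)
  kids <- split(seq_len(n), factor(nd$parent, levels = seq_len(n)))
  ord <- integer(0)
  frontier <- which(nd$parent == -1L)
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
  }
  ord
}

#' Read an SWC reconstruction file
#'
#' Parses the standard 7-column whitespace-separated SWC dialect
#' (id, type, x, y, z, radius, parent; `#` comment lines allowed).
#' Node ids are remapped to a dense 1..n range; the original ids are kept
#' in `metadata$original_ids`.
#'
#' @param path path to an SWC file.
#' @param cell_id cell identifier; defaults to the file name without
#'   extension.
#' @inheritParams neuron
#' @return a validated `"neuron"` object.
#' @export
read_swc <- function(path, cell_id = NULL, cell_type = NA_character_,
                     source_area = NA_character_,
                     hemisphere = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(cell_id)) cell_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("parse error: no node records in ", path,
                           call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield != 7L))
    stop("parse error at line ", lineno[which(nfield != 7L)[1L]],
         ": expected 7 columns, got ", nfield[which(nfield != 7L)[1L]],
         call. = FALSE)
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = 7L, byrow = TRUE))
  if (any(!is.finite(vals[, c(1:5, 7)]))) {
    bad <- which(rowSums(!is.finite(vals[, c(1:5, 7), drop = FALSE])) > 0)[1L]
    stop("parse error at line ", lineno[bad], ": non-numeric field",
         call. = FALSE)
  }
  nodes <- data.frame(id = as.integer(vals[, 1]), type = as.integer(vals[, 2]),
                      x = vals[, 3], y = vals[, 4], z = vals[, 5],
                      radius = vals[, 6], parent = as.integer(vals[, 7]))
  neuron(cell_id, nodes, cell_type = cell_type, source_area = source_area,
         hemisphere = hemisphere)
}

#' Write a neuron to an SWC file
#'
#' @param nrn a `"neuron"` object.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_swc <- function(nrn, path) {
  nd <- nrn$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell_id %s", nrn$cell_id), con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent),
             con)
  invisible(path)
}

#' @export
print.neuron <- function(x, ...) {
  nd <- x$nodes
  cat("<neuron>", x$cell_id, "-", nrow(nd), "nodes;",
      "axon length", sprintf("%.1f", total_length(x, "axon")), "um\n")
  invisible(x)
}

#' Soma position of a neuron
#'
#' The position of the root node if it is a soma node, otherwise the first
#' soma-typed node, otherwise the root.
#'
#' @param nrn a `"neuron"` object.
#' @return numeric length-3 vector (x, y, z) in micrometres.
#' @export
soma_position <- function(nrn) {
  nd <- nrn$nodes
  i <- which(nd$type == SWC_TYPES[["soma"]])
  if (!length(i)) i <- which(nd$parent == -1L)
  unlist(nd[i[1L], c("x", "y", "z")], use.names = TRUE)
}

# edges of a compartment: child rows whose own type matches `code`
# (segment belongs to the compartment of its child node)
compartment_edges <- function(nrn, compartment = NULL) {
  nd <- nrn$nodes
  has_parent <- nd$parent != -1L
  if (!is.null(compartment)) {
    code <- swc_type_code(compartment)
    has_parent <- has_parent & nd$type == code
  }
  ch <- which(has_parent)
  pa <- nd$parent[ch]
  p0 <- as.matrix(nd[pa, c("x", "y", "z"), drop = FALSE])
  p1 <- as.matrix(nd[ch, c("x", "y", "z"), drop = FALSE])
  len <- sqrt(rowSums((p1 - p0)^2))
  list(parent = pa, child = ch, p0 = p0, p1 = p1, length = len)
}

#' Total cable length of a compartment
#'
#' Sum of Euclidean lengths of all parent-to-child segments whose child node
#' belongs to the compartment.
#'
#' @param nrn a `"neuron"` object.
#' @param compartment `"soma"`, `"axon"`, `"basal"`, `"apical"`, a numeric
#'   SWC type code, or NULL for all segments.
#' @return length in micrometres.
#' @export
total_length <- function(nrn, compartment = NULL) {
  sum(compartment_edges(nrn, compartment)$length)
}

#' Branch orders and terminals within a compartment
#'
#' The compartment's nodes form a forest rooted at its entry nodes (nodes
#' whose parent is absent or belongs to another compartment). Entry nodes
#' have order 0; the order increments by one for nodes downstream of a
#' bifurcation (a node with two or more children in the compartment).
#' Terminals are nodes with no children in the compartment.
#'
#' @param nrn a `"neuron"` object.
#' @param compartment compartment name or SWC type code.
#' @param subset optional integer vector of node ids restricting the forest
#'   (e.g. the nodes of one region); orders are then computed from the entry
#'   nodes of the subset.
#' @return data.frame with columns `id`, `order`, `is_terminal`,
#'   `is_bifurcation`.
#' @export
branch_orders <- function(nrn, compartment, subset = NULL) {
  code <- swc_type_code(compartment)
  nd <- nrn$nodes
  in_set <- nd$type == code
  if (!is.null(subset)) in_set <- in_set & nd$id %in% subset
  ids <- nd$id[in_set]
  if (!length(ids))
    return(data.frame(id = integer(0), order = integer(0),
                      is_terminal = logical(0), is_bifurcation = logical(0)))
  parent <- nd$parent
  # parent within the forest, else 0 (entry)
  par_in <- ifelse(parent %in% ids, parent, 0L)[in_set]
  nkids <- tabulate(par_in[par_in > 0L], nbins = nrow(nd))[ids]
  is_bif <- nkids >= 2L
  is_term <- nkids == 0L
  ord <- integer(length(ids))
  names(ord) <- ids
  bif <- logical(nrow(nd)); bif[ids[is_bif]] <- TRUE
  # process parents before children
  pos <- match(topo_order(nd), which(in_set))
  for (k in pos[!is.na(pos)]) {
    p <- par_in[k]
    if (p == 0L) ord[k] <- 0L
    else ord[k] <- ord[as.character(p)] + if (bif[p]) 1L else 0L
  }
  data.frame(id = ids, order = unname(ord), is_terminal = is_term,
             is_bifurcation = is_bif)
}
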