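#' Morphometric features of a compartment tree
#'
#' Extracts the nine-feature morphometric panel from one compartment of a
#' neuron: height (extent along the cortical-depth axis), max Euclidean
#' distance from soma, max along-tree pathway length from soma, total
#' pathway efficiency (mean over tips of Euclidean distance / path length;
#' 1 for perfectly straight paths), average bifurcation angle (degrees,
#' between the two daughter directions at each branch point), average
#' segment length (a segment is an unbranched run between branch
#' points/tips), number of segments, number of bifurcations, number of
#' tips. An empty compartment yields NAs; trees without bifurcations report
#' NA for the angle.
#'
#' @param nrn a `"neuron"`.
#' @param compartment compartment name or SWC code (e.g. `"apical"`).
#' @param depth_axis axis index along which height is measured (default 2
#'   = y); rigid rotations change this feature, translations do not.
#' @return one-row data.frame of the nine features.
#' @export
extract_features <- function(nrn, compartment = "apical", depth_axis = 2L) {
  feat <- c("height", "max_dist_soma", "max_path_soma", "path_efficiency",
            "avg_bif_angle", "avg_seg_length", "n_segments",
            "n_bifurcations", "n_tips")
  out <- as.data.frame(as.list(setNames(rep(NA_real_, length(feat)), feat)))
  code <- swc_type_code(compartment)
  nd <- nrn$nodes
  sel <- nd$type == code
  if (!any(sel)) return(out)
  soma <- soma_position(nrn)
  pts <- as.matrix(nd[sel, c("x", "y", "z"), drop = FALSE])
  # the extent includes the attachment points (usually the soma) so a
  # straight vertical trunk of length L has height L
  entry_par <- nd$parent[sel][!(nd$parent[sel] %in% nd$id[sel])]
  entry_par <- entry_par[entry_par != -1L]
  ext <- c(pts[, depth_axis], nd[entry_par, c("x", "y", "z")][, depth_axis])
  out$height <- diff(range(ext))
  out$max_dist_soma <- sqrt(max(colSums((t(pts) - soma)^2)))

  bo <- branch_orders(nrn, compartment)
  out$n_tips <- sum(bo$is_terminal)
  out$n_bifurcations <- sum(bo$is_bifurcation)

  # path length from soma: accumulate along the tree (entry nodes start at
  # their straight-line distance from the soma so detached compartments
  # still measure from the cell body)
  ed <- compartment_edges(nrn, compartment)
  plen <- numeric(nrow(nd))
  coords <- as.matrix(nd[, c("x", "y", "z")])
  for (i in topo_order(nd)) {
    if (!sel[i]) next
    p <- nd$parent[i]
    if (p != -1L && sel[p]) {
      plen[i] <- plen[p] + sqrt(sum((coords[i, ] - coords[p, ])^2))
    } else {
      plen[i] <- sqrt(sum((coords[i, ] - soma)^2))
    }
  }
  out$max_path_soma <- max(plen[sel])
  tips <- bo$id[bo$is_terminal]
  eff <- sqrt(colSums((t(coords[tips, , drop = FALSE]) - soma)^2)) /
    pmax(plen[tips], .Machine$double.eps)
  out$path_efficiency <- mean(pmin(eff, 1))

  # segments: unbranched runs; each run ends at a bifurcation or tip
  run_ends <- bo$id[bo$is_terminal | bo$is_bifurcation]
  out$n_segments <- length(run_ends)
  out$avg_seg_length <- if (length(ed$length)) {
    sum(ed$length) / max(1L, length(run_ends))
  } else 0

  # bifurcation angles between daughter initial directions
  bif_ids <- bo$id[bo$is_bifurcation]
  if (length(bif_ids)) {
    angs <- vapply(bif_ids, function(b) {
      kids <- nd$id[sel & nd$parent == b]
      if (length(kids) < 2L) return(NA_real_)
      d1 <- coords[kids[1L], ] - coords[b, ]
      d2 <- coords[kids[2L], ] - coords[b, ]
      n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
      if (n1 == 0 || n2 == 0) return(NA_real_)
      acos(pmin(1, pmax(-1, sum(d1 * d2) / (n1 * n2)))) * 180 / pi
    }, numeric(1))
    out$avg_bif_angle <- mean(angs, na.rm = TRUE)
  }
  out
}

#' Feature table for a population
#'
#' @param neurons list of `"neuron"` objects.
#' @param compartment compartment for [extract_features()].
#' @param depth_axis depth axis index.
#' @return data.frame with `cell_id`, `cell_type`, `source_area` and the
#'   nine features.
#' @export
feature_table <- function(neurons, compartment = "apical", depth_axis = 2L) {
  rows <- lapply(neurons, function(n) {
    cbind(data.frame(cell_id = n$cell_id,
                     cell_type = n$metadata$cell_type,
                     source_area = n$metadata$source_area),
          extract_features(n, compartment, depth_axis))
  })
  do.call(rbind, rows)
}

#' Min-max normalization of a feature table
#'
#' Rescales each numeric feature to [0, 1] via (x - min) / (max - min).
#' Constant features cannot be rescaled and are dropped with a warning.
#'
#' @param x data.frame or matrix of features (numeric columns only are
#'   rescaled; others are passed through).
#' @return the table with numeric columns rescaled; dropped constant
#'   columns recorded in attribute `dropped`.
#' @export
minmax_normalize <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  dropped <- character(0)
  for (cl in names(x)[num]) {
    rng <- range(x[[cl]], na.rm = TRUE)
    if (!all(is.finite(rng)) || rng[1] == rng[2]) {
      dropped <- c(dropped, cl)
      x[[cl]] <- NULL
    } else {
      x[[cl]] <- (x[[cl]] - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(dropped))
    warning("dropped constant feature(s): ", paste(dropped, collapse = ", "))
  attr(x, "dropped") <- dropped
  x
}

#' Hierarchical clustering of cells by morphometric features
#'
#' One-minus-Pearson distance between cells' feature vectors, average
#' linkage, cut at `k` clusters.
#'
#' @param features numeric matrix/data.frame, one row per cell (normalize
#'   first with [minmax_normalize()]).
#' @param k number of clusters.
#' @return integer cluster labels with the `"hclust"` object as attribute
#'   `tree`.
#' @export
hcluster <- function(features, k) {
  m <- as.matrix(features[vapply(as.data.frame(features), is.numeric,
                                 logical(1))])
  if (k > nrow(m)) stop("k exceeds number of cells", call. = FALSE)
  tree <- hclust_pearson(m)
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Clustering accuracy against known cell types
#'
#' Fraction of correctly clustered cells after the best one-to-one
#' assignment of clusters to type labels (exhaustive over cluster
#' permutations for up to 8 clusters, greedy beyond that).
#'
#' @param truth vector of true type labels.
#' @param clusters vector of cluster labels.
#' @return accuracy in [0, 1].
#' @export
clustering_accuracy <- function(truth, clusters) {
  ct <- table(clusters, truth)
  k <- nrow(ct); g <- ncol(ct)
  n <- max(k, g)
  if (n <= 8L) {
    sq <- matrix(0L, n, n)
    sq[seq_len(k), seq_len(g)] <- ct
    best <- 0L
    for (p in perm_enum(seq_len(n))) {
      hit <- sum(sq[cbind(seq_len(n), p)])
      if (hit > best) best <- hit
    }
  } else {
    best <- 0L
    ctt <- ct
    for (i in seq_len(min(k, g))) {
      w <- which(ctt == max(ctt), arr.ind = TRUE)[1, ]
      best <- best + ctt[w[1], w[2]]
      ctt[w[1], ] <- -1L; ctt[, w[2]] <- -1L
    }
  }
  as.numeric(best) / length(truth)
}

perm_enum <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perm_enum(v[-i]), function(p) c(v[i], p)))
  out
}

#' Random-forest cell-type classifier
#'
#' Trains a random forest (500 trees) on a stratified 80/20 train/test
#' split of the feature table and reports test accuracy, overall and per
#' source area.
#'
#' @param features numeric feature data.frame/matrix, one row per cell.
#' @param labels cell-type labels (factor or character).
#' @param source_area optional per-cell area labels for per-area accuracy.
#' @param train_frac training fraction (default 0.8).
#' @param seed RNG seed (split and forest are deterministic given it).
#' @param ntree number of trees.
#' @return list: `accuracy`, `per_area` (data.frame or NULL), `confusion`,
#'   `model`, `test_idx`.
#' @export
train_classifier <- function(features, labels, source_area = NULL,
                             train_frac = 0.8, seed = 1L, ntree = 500L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("stratification error: every class needs >= 2 cells",
         call. = FALSE)
  m <- as.data.frame(features)
  m <- m[vapply(m, is.numeric, logical(1))]
  set.seed(seed)
  train <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(train_frac * length(idx))))
  }))
  test <- setdiff(seq_along(labels), train)
  if (!length(test)) stop("empty test split", call. = FALSE)
  if (nlevels(droplevels(labels[train])) < nlevels(labels))
    stop("stratification error: class absent from training split",
         call. = FALSE)
  fit <- randomForest::randomForest(x = m[train, , drop = FALSE],
                                    y = labels[train], ntree = ntree)
  pred <- stats::predict(fit, m[test, , drop = FALSE])
  acc <- mean(pred == labels[test])
  per_area <- NULL
  if (!is.null(source_area)) {
    sa <- source_area[test]
    per_area <- aggregate(correct ~ area,
                          data = data.frame(area = sa,
                                            correct = pred == labels[test]),
                          FUN = mean)
    names(per_area)[2] <- "accuracy"
  }
  list(accuracy = acc, per_area = per_area,
       confusion = table(predicted = pred, truth = labels[test]),
       model = fit, test_idx = test)
}
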