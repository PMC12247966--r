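#' Region hierarchy scores
#'
#' The hierarchy score of target region j is the targeting probability from
#' each source region i, normalized by the average targeting length of the
#' i -> j projection (which reflects the spatial extent of the axonal
#' cluster rather than the size of the target region), summed over sources:
#' \deqn{score_j = \sum_{i \ne j} P_{ij} / \bar L_{ij}.}
#' P is the targeting probability as a fraction in [0, 1]; L-bar is in
#' micrometres (computed over passing cells, like targeting strength).
#' Regions never targeted score 0.
#'
#' @param P source x target matrix of targeting probabilities (fractions);
#'   dimnames identify regions. Square matrices exclude the diagonal; for
#'   non-square matrices shared row/column names are excluded pairwise.
#' @param Lbar matrix of mean targeting lengths (um), same shape as `P`;
#'   must be positive wherever `P > 0`.
#' @return object of class `"hierarchy_table"`: data.frame `region`,
#'   `score`, `rank` (1 = highest score).
#' @export
hierarchy_score <- function(P, Lbar) {
  P <- as.matrix(P); Lbar <- as.matrix(Lbar)
  stopifnot(all(dim(P) == dim(Lbar)))
  bad <- which(P > 0 & (!is.finite(Lbar) | Lbar <= 0), arr.ind = TRUE)
  if (nrow(bad))
    stop("P > 0 with missing/nonpositive mean length for pair (",
         rownames(P)[bad[1, 1]] %||% bad[1, 1], ", ",
         colnames(P)[bad[1, 2]] %||% bad[1, 2], ")", call. = FALSE)
  ratio <- ifelse(P > 0, P / Lbar, 0)
  # exclude self-projections i == j
  rn <- rownames(P); cn <- colnames(P)
  if (!is.null(rn) && !is.null(cn)) {
    self <- outer(rn, cn, "==")
    ratio[self] <- 0
  } else if (nrow(P) == ncol(P)) {
    diag(ratio) <- 0
  }
  score <- colSums(ratio)
  out <- data.frame(region = cn %||% as.character(seq_along(score)),
                    score = unname(score))
  out$rank <- rank(-out$score, ties.method = "min")
  structure(out, class = c("hierarchy_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Connectome-derived targeting matrices
#'
#' Pivots a connectome table into source x target matrices of targeting
#' probability (fraction) and mean targeting length, aggregating over cell
#' types (cells pooled per source area) and, by default, hemispheres.
#'
#' @param connectome a `"connectome"` built with cell_type set to a single
#'   pooled label, or any connectome (rows are pooled by source area with
#'   cell-count weights).
#' @param source_region_id named vector mapping source_area labels to the
#'   region ids they occupy (for the self-projection exclusion).
#' @param hemisphere optional hemisphere restriction (`"ipsi"`/`"contra"`).
#' @return list: `P` (fractions), `Lbar` (um); rows named by source region
#'   id, columns by target region id.
#' @export
targeting_matrices <- function(connectome, source_region_id,
                               hemisphere = NULL) {
  tab <- connectome$table
  if (!is.null(hemisphere))
    tab <- tab[tab$hemisphere == hemisphere, , drop = FALSE]
  src <- sort(unique(tab$source_area))
  tgt <- sort(unique(tab$region_id))
  P <- matrix(0, length(src), length(tgt),
              dimnames = list(as.character(source_region_id[src]),
                              as.character(tgt)))
  L <- matrix(NA_real_, length(src), length(tgt), dimnames = dimnames(P))
  for (s in seq_along(src)) {
    sub <- tab[tab$source_area == src[s], , drop = FALSE]
    # pool cell types: passing cells / total cells, length-weighted mean
    n_pass <- tapply(sub$n_passing, sub$region_id, sum)
    n_cell <- sum(unique(sub[, c("cell_type", "n_cells")])$n_cells)
    wlen <- tapply(sub$n_passing * sub$targ_stren, sub$region_id, sum)
    j <- match(names(n_pass), as.character(tgt))
    P[s, j] <- as.numeric(n_pass) / n_cell
    L[s, j] <- as.numeric(wlen) / as.numeric(n_pass)
  }
  list(P = P, Lbar = L)
}

#' Correlates of the hierarchy score
#'
#' Pearson correlations of region hierarchy scores against three per-region
#' targeting summaries: target number (number of source regions with a
#' passing projection into the region), mean targeting probability, and
#' mean targeting strength (both over targeting sources). P-values are
#' seeded permutation p-values.
#'
#' @param table a `"hierarchy_table"` from [hierarchy_score()].
#' @param P,Lbar the matrices used to build it.
#' @param n_perm permutations; `seed` RNG seed.
#' @return data.frame: `measure`, `r`, `p_value`, `degenerate`.
#' @export
score_correlates <- function(table, P, Lbar, n_perm = 1e4, seed = 1L) {
  if (nrow(table) < 5L) stop("need >= 5 regions", call. = FALSE)
  j <- match(table$region, colnames(P))
  targets <- colSums(P > 0)[j]
  meanP <- apply(P, 2, function(p) if (any(p > 0)) mean(p[p > 0]) else 0)[j]
  meanL <- vapply(seq_len(ncol(P)), function(jj) {
    sel <- P[, jj] > 0
    if (any(sel)) mean(Lbar[sel, jj]) else 0
  }, numeric(1))[j]
  set.seed(seed)
  one <- function(x, label) {
    if (stats::sd(x) == 0 || stats::sd(table$score) == 0)
      return(data.frame(measure = label, r = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    r <- stats::cor(table$score, x)
    null_r <- replicate(n_perm, stats::cor(table$score, sample(x)))
    data.frame(measure = label, r = r,
               p_value = (1 + sum(abs(null_r) >= abs(r))) / (n_perm + 1),
               degenerate = FALSE)
  }
  rbind(one(targets, "target_number"), one(meanP, "mean_targ_prob"),
        one(meanL, "mean_targ_stren"))
}

# Two-sided normal-approximation rank-sum p-values of x against each column
# of ymat (continuity-corrected, tie correction for ties within x only);
# matches wilcox.test(exact = FALSE, correct = TRUE) for continuous y.
ranksum_p <- function(x, ymat) {
  n1 <- length(x); n2 <- nrow(ymat)
  xs <- sort(x)
  N <- n1 + n2
  cnt <- matrix(findInterval(ymat, xs), nrow = n2)
  U <- n1 * n2 - colSums(cnt)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sigma
  pmin(1, 2 * stats::pnorm(-abs(z)))
}

#' Test one hierarchy-difference distribution against a matched Gaussian
#'
#' Core test behind [fffb_classify()]: compares a sample of hierarchy
#' differences dh with a variance-matched Gaussian centred at zero, via
#' `n_ref` seeded Gaussian reference draws, a two-sample Wilcoxon rank-sum
#' test against each, and median-p aggregation.
#'
#' @param dh numeric sample of hierarchy differences.
#' @param n_ref number of reference draws.
#' @param seed RNG seed.
#' @param method `"gaussian_ref"` or `"signed_rank"` (one-sample Wilcoxon
#'   signed-rank against zero).
#' @return list: `p_value`, `mean_dh`, `se_dh`, `n`, `degenerate`.
#' @export
fffb_test <- function(dh, n_ref = 1000L, seed = 1L,
                      method = c("gaussian_ref", "signed_rank")) {
  method <- match.arg(method)
  n <- length(dh)
  s <- stats::sd(dh)
  if (n < 5L || s == 0) {
    # constant sample: the matched reference collapses to the point mass
    # at zero, so a nonzero mean forces significance
    p <- if (n >= 5L && mean(dh) != 0) 0 else NA_real_
    return(list(p_value = p, mean_dh = mean(dh),
                se_dh = if (n > 1) s / sqrt(n) else NA_real_, n = n,
                degenerate = TRUE))
  }
  set.seed(seed)
  p <- if (method == "gaussian_ref") {
    refs <- matrix(stats::rnorm(n * n_ref, 0, s), nrow = n)
    stats::median(ranksum_p(dh, refs))
  } else {
    stats::wilcox.test(dh, mu = 0, exact = FALSE)$p.value
  }
  list(p_value = p, mean_dh = mean(dh), se_dh = s / sqrt(n), n = n,
       degenerate = FALSE)
}

#' Feedforward/feedback classification of cell-type projections
#'
#' For each connection from source region j to target region i of a cell
#' type, the hierarchy difference is dh = h_i - h_j. Each cell type's dh
#' distribution is compared with a variance-matched Gaussian centred at
#' zero: `n_ref` seeded Gaussian reference samples (mean 0, sd = sample sd,
#' same size) are drawn and a two-sample Wilcoxon rank-sum test is run
#' against each, reporting the median p-value. P-values are
#' Benjamini-Hochberg adjusted across cell types; a type is called FF
#' (feedforward) when the adjusted p is below `alpha` with positive mean
#' dh, FB with negative mean dh, and unclassified otherwise.
#'
#' @param connections data.frame with columns `cell_type`, `source`,
#'   `target` (region identifiers), one row per passing connection.
#' @param levels named numeric vector of region hierarchy levels h.
#' @param alpha significance level after BH adjustment (default 0.05).
#' @param n_ref number of Gaussian reference draws (default 1000).
#' @param seed RNG seed.
#' @param method `"gaussian_ref"` (default, as described) or
#'   `"signed_rank"` (one-sample Wilcoxon signed-rank test against 0).
#' @return data.frame per cell type: `cell_type`, `n`, `mean_dh`, `se_dh`,
#'   `p_value`, `p_adj`, `verdict` ("FF"/"FB"/"none"), `degenerate`.
#' @export
fffb_classify <- function(connections, levels, alpha = 0.05, n_ref = 1000L,
                          seed = 1L, method = c("gaussian_ref",
                                                "signed_rank")) {
  method <- match.arg(method)
  miss <- setdiff(unique(c(connections$source, connections$target)),
                  names(levels))
  if (length(miss))
    stop("no hierarchy level for region(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dh_all <- levels[as.character(connections$target)] -
    levels[as.character(connections$source)]
  types <- sort(unique(connections$cell_type))
  res <- lapply(seq_along(types), function(i) {
    dh <- unname(dh_all[connections$cell_type == types[i]])
    tst <- fffb_test(dh, n_ref = n_ref, seed = seed + i - 1L,
                     method = method)
    data.frame(cell_type = types[i], n = tst$n, mean_dh = tst$mean_dh,
               se_dh = tst$se_dh, p_value = tst$p_value,
               degenerate = tst$degenerate)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$verdict <- ifelse(is.na(out$p_adj) | out$p_adj >= alpha, "none",
                        ifelse(out$mean_dh > 0, "FF", "FB"))
  out[, c("cell_type", "n", "mean_dh", "se_dh", "p_value", "p_adj",
          "verdict", "degenerate")]
}
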