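# in-code fixtures shared across test files

# neuron from a compact edge description: list of (id, type, xyz, parent)
make_neuron <- function(rows, cell_id = "toy", ...) {
  nd <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], type = r[[2]], x = r[[3]][1], y = r[[3]][2],
               z = r[[3]][3], radius = 1, parent = r[[4]])
  }))
  neuron(cell_id, nd, ...)
}

# unbranched neuron along +x: soma at origin then `n` axon nodes `step` apart
path_neuron <- function(n = 5, step = 10, type = 2L) {
  rows <- c(list(list(1L, 1L, c(0, 0, 0), -1L)),
            lapply(seq_len(n), function(i)
              list(i + 1L, type, c(i * step, 0, 0), i)))
  make_neuron(rows)
}

# full binary tree of `depth` bifurcation levels in the axon compartment:
# soma -> single trunk node -> nested bifurcations; 2^depth terminals
binary_tree_neuron <- function(depth = 3) {
  rows <- list(list(1L, 1L, c(0, 0, 0), -1L),
               list(2L, 2L, c(10, 0, 0), 1L))
  nid <- 2L
  grow <- function(parent, pos, d) {
    force(parent)  # guard against lazy promise capturing a mutated nid
    if (d > depth) return(invisible(NULL))
    for (b in c(-1, 1)) {
      nid <<- nid + 1L
      npos <- pos + c(10, b * 10 / d, 0)
      rows[[length(rows) + 1L]] <<- list(nid, 2L, npos, parent)
      grow(nid, npos, d + 1)
    }
  }
  grow(2L, c(10, 0, 0), 1)
  make_neuron(rows)
}

# two-region slab atlas split at x = 100 (region 1: x in [0,100), 2: beyond)
two_region_atlas <- function() {
  lab <- array(0L, dim = c(20, 10, 10))
  lab[1:10, , ] <- 1L
  lab[11:20, , ] <- 2L
  region_atlas(lab, voxel_size = 10, origin = c(0, 0, 0), midline = -1e9,
               regions = data.frame(region_id = 1:2, name = c("R1", "R2"),
                                    layer = NA, group = "test",
                                    hierarchy_level = NA))
}

# brute-force overlap score: direct double-loop scatter-matrix traces
oracle_overlap <- function(a, b) {
  ma <- colMeans(a); mb <- colMeans(b)
  m <- colMeans(rbind(a, b))
  gm <- (nrow(a) * ma + nrow(b) * mb) / (nrow(a) + nrow(b))
  sb <- 0
  for (mi in list(list(ma, nrow(a)), list(mb, nrow(b))))
    sb <- sb + mi[[2]] * sum(diag((mi[[1]] - gm) %o% (mi[[1]] - gm)))
  sw <- 0
  for (i in seq_len(nrow(a)))
    sw <- sw + sum(diag((a[i, ] - ma) %o% (a[i, ] - ma)))
  for (i in seq_len(nrow(b)))
    sw <- sw + sum(diag((b[i, ] - mb) %o% (b[i, ] - mb)))
  S <- sb / sw
  max(0, 1 - S)
}

# supersampled rasterization oracle: dense points along each segment
oracle_raster <- function(p0, p1, spacing, origin = c(0, 0, 0),
                          n_samp = 10000) {
  cells <- list()
  for (s in seq_len(nrow(p0))) {
    tt <- seq(0, 1, length.out = n_samp)
    pts <- outer(tt, p1[s, ] - p0[s, ]) +
      matrix(p0[s, ], n_samp, 3, byrow = TRUE)
    cells[[s]] <- floor(sweep(sweep(pts, 2, origin), 2,
                              rep_len(spacing, 3), "/"))
  }
  unique(as.data.frame(do.call(rbind, cells))) |>
    setNames(c("i", "j", "k"))
}

cellkey <- function(df) paste(df$i, df$j, df$k)
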