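#' Generate a toy layered two-hemisphere atlas
#'
#' Block-partitioned label volume emulating a simplified cortical sheet:
#' cortical areas are blocks along the z (anteroposterior) axis, optionally
#' subdivided into layer slabs along y (depth, 0 = pial surface), mirrored
#' across the x midline into two hemispheres. Below the cortex an unlabeled
#' "white matter" gap separates it from subcortical blocks. Every voxel
#' maps to exactly one region or to background (0).
#'
#' @param n_areas number of cortical areas (named "A1".."An").
#' @param layers character vector of layer labels, or NULL for unlayered
#'   cortical areas.
#' @param layer_thickness layer slab thickness, micrometres.
#' @param area_span cortical area extent along z, micrometres.
#' @param hemi_width hemisphere width along x, micrometres.
#' @param wm_thickness unlabeled white-matter gap below cortex, um.
#' @param n_sub number of subcortical regions ("S1".."Sm").
#' @param sub_depth subcortical block depth, micrometres.
#' @param voxel voxel edge length, micrometres.
#' @param hierarchy_levels numeric hierarchy level per cortical area
#'   (default 1..n_areas).
#' @return a `"region_atlas"`; its regions table carries `hemisphere`,
#'   `area` and y/z block bounds used by the population generator.
#' @export
synth_atlas <- function(n_areas = 3, layers = c("L2/3", "L5", "L6"),
                        layer_thickness = 200, area_span = 400,
                        hemi_width = 800, wm_thickness = 100,
                        n_sub = 2, sub_depth = 600, voxel = 20,
                        hierarchy_levels = seq_len(n_areas)) {
  n_lay <- if (is.null(layers)) 1L else length(layers)
  ctx_depth <- n_lay * layer_thickness
  depth <- ctx_depth + wm_thickness + if (n_sub > 0) sub_depth else 0
  width <- 2 * hemi_width
  zlen <- n_areas * area_span
  dm <- c(width, depth, zlen) / voxel
  stopifnot(all(dm == round(dm)))
  lab <- array(0L, dim = dm)
  regions <- list()
  id <- 0L
  add <- function(name, layer, hemi, group, h, xr, yr, zr) {
    id <<- id + 1L
    i <- (xr[1] / voxel + 1):(xr[2] / voxel)
    j <- (yr[1] / voxel + 1):(yr[2] / voxel)
    k <- (zr[1] / voxel + 1):(zr[2] / voxel)
    if (any(lab[i, j, k] != 0L)) stop("overlapping region specs",
                                      call. = FALSE)
    lab[i, j, k] <<- id
    regions[[id]] <<- data.frame(
      region_id = id, name = name, layer = layer, group = group,
      hierarchy_level = h, hemisphere = hemi, area = name,
      x0 = xr[1], x1 = xr[2], y0 = yr[1], y1 = yr[2],
      z0 = zr[1], z1 = zr[2])
    invisible(id)
  }
  hemis <- list(left = c(0, hemi_width), right = c(hemi_width, width))
  for (a in seq_len(n_areas)) {
    zr <- c(a - 1, a) * area_span
    for (hn in names(hemis)) {
      if (is.null(layers)) {
        add(paste0("A", a), NA_character_, hn, "cortex",
            hierarchy_levels[a], hemis[[hn]], c(0, ctx_depth), zr)
      } else {
        for (l in seq_len(n_lay))
          add(paste0("A", a), layers[l], hn, "cortex", hierarchy_levels[a],
              hemis[[hn]], c(l - 1, l) * layer_thickness, zr)
      }
    }
  }
  if (n_sub > 0) {
    sub_span <- zlen / n_sub
    stopifnot(sub_span %% voxel == 0)
    for (s in seq_len(n_sub)) {
      zr <- c(s - 1, s) * sub_span
      for (hn in names(hemis))
        add(paste0("S", s), NA_character_, hn, "subcortex", NA_real_,
            hemis[[hn]], ctx_depth + wm_thickness + c(0, sub_depth), zr)
    }
  }
  reg <- do.call(rbind, regions)
  atlas <- region_atlas(lab, voxel_size = voxel, origin = c(0, 0, 0),
                        midline = hemi_width, regions = reg)
  atlas$wm_y <- ctx_depth + wm_thickness / 2
  atlas
}

#' Specify a synthetic cell type
#'
#' @param name type label.
#' @param n number of cells.
#' @param source_area cortical area name hosting the somata (right
#'   hemisphere).
#' @param soma_depth soma depth below the pia, micrometres.
#' @param dendrite apical dendrite template: `"tufted"`, `"untufted"`,
#'   `"inverted"`, `"horizontal"` or `"stellate"`.
#' @param dendrite_scale scale factor applied to the dendrite template.
#' @param targets data.frame with columns `area` (region name), `layer`
#'   (layer label or NA), `prob` (targeting probability in [0,1]),
#'   `mean_axl` (mean arbor length, um), and optionally `contra_prob` and
#'   `contra_axl_scale` (contralateral mirror target probability and
#'   strength ratio, defaults 0 and 1).
#' @param topography `"aligned"`, `"reversed"` or `"none"`: how the soma's
#'   z position maps to its arbor anchor position in each target.
#' @param topo_sigma topographic placement noise sd, micrometres.
#' @param arbor_radius arborizations are compact: branch walks stay within
#'   this radius of the arbor anchor (micrometres).
#' @param fiber_through optional cortical area name through which a
#'   terminal-free passing fiber is routed (tests filter specificity).
#' @return a `"cell_type_spec"` list.
#' @export
cell_type_spec <- function(name, n, source_area, soma_depth = 300,
                           dendrite = "tufted", dendrite_scale = 1,
                           targets, topography = "none", topo_sigma = 50,
                           soma_xz_frac = c(1, 1), arbor_radius = 120,
                           fiber_through = NULL) {
  stopifnot(all(c("area", "prob", "mean_axl") %in% names(targets)))
  if (is.null(targets$layer)) targets$layer <- NA_character_
  if (is.null(targets$contra_prob)) targets$contra_prob <- 0
  if (is.null(targets$contra_axl_scale)) targets$contra_axl_scale <- 1
  stopifnot(all(targets$prob >= 0 & targets$prob <= 1), n >= 1)
  structure(list(name = name, n = n, source_area = source_area,
                 soma_depth = soma_depth, dendrite = dendrite,
                 dendrite_scale = dendrite_scale, targets = targets,
                 topography = match.arg(topography,
                                        c("none", "aligned", "reversed")),
                 topo_sigma = topo_sigma,
                 soma_xz_frac = rep_len(soma_xz_frac, 2L),
                 arbor_radius = arbor_radius,
                 fiber_through = fiber_through),
            class = "cell_type_spec")
}

# straight path subdivided into steps of at most `step` um (excludes `from`)
path_nodes <- function(from, to, step = 30) {
  len <- sqrt(sum((to - from)^2))
  if (len == 0) return(matrix(to, ncol = 3L))
  nsub <- max(1L, ceiling(len / step))
  tt <- seq_len(nsub) / nsub
  cbind(from[1] + tt * (to[1] - from[1]), from[2] + tt * (to[2] - from[2]),
        from[3] + tt * (to[3] - from[3]))
}

# bounded persistent random walk of total length `budget` starting at
# `start`; returns node matrix (excluding start)
bounded_walk <- function(start, budget, bounds, step = 20) {
  n_steps <- max(2L, ceiling(budget / step))
  last <- budget - (n_steps - 1L) * step
  if (last <= 0) { n_steps <- n_steps - 1L; last <- budget - (n_steps - 1L) * step }
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  pos <- start
  out <- matrix(0, n_steps, 3L)
  for (s in seq_len(n_steps)) {
    dir <- dir + 0.6 * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    # reflect components that would leave the bounds
    stl <- if (s == n_steps) last else step
    for (ax in 1:3) {
      nxt <- pos[ax] + dir[ax] * stl
      if (nxt < bounds[1, ax] || nxt > bounds[2, ax]) dir[ax] <- -dir[ax]
    }
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + dir * stl
    pos <- pmin(pmax(pos, bounds[1, ]), bounds[2, ])
    out[s, ] <- pos
  }
  out
}

# region table row for (area, layer, hemisphere)
region_row <- function(atlas, area, layer, hemi) {
  reg <- atlas$regions
  sel <- reg$area == area & reg$hemisphere == hemi
  if (!is.na(layer)) sel <- sel & !is.na(reg$layer) & reg$layer == layer
  rows <- reg[sel, , drop = FALSE]
  if (!nrow(rows)) stop("no atlas region for area ", area,
                        if (!is.na(layer)) paste0(" layer ", layer),
                        " (", hemi, ")", call. = FALSE)
  rows[which.max(rows$y1), , drop = FALSE]  # deepest matching slab
}

#' Generate a synthetic neuron population
#'
#' Realizes each cell type specification as SWC-style neuron objects inside
#' the atlas: the soma is placed in the source area (right hemisphere) with
#' a type-template dendrite; for each target drawn from the projection
#' profile, an axon trunk descends to the white-matter gap, travels to the
#' target, and forms a bounded branching arbor (two nested bifurcation
#' levels, four terminals) whose total in-region length matches the planted
#' mean; the trunk's crossings of other regions are terminal-free passing
#' fibers. Topographic modes map the soma's z position (optionally
#' reversed) onto the arbor anchor, with Gaussian noise.
#'
#' @param atlas a `"region_atlas"` from [synth_atlas()].
#' @param types list of [cell_type_spec()] objects.
#' @param seed RNG seed; same seed gives bit-identical populations.
#' @param step axon walk step length, micrometres.
#' @return list: `neurons` (list of `"neuron"`), `cells` (data.frame
#'   cell_id/cell_type/source_area), `truth` (planted per-type target table
#'   and topography modes), `atlas`.
#' @export
generate_population <- function(atlas, types, seed = 1L, step = 20) {
  set.seed(seed)
  reg <- atlas$regions
  neurons <- list()
  cells <- list()
  wm_y <- atlas$wm_y %||% stop("atlas lacks white-matter depth (use synth_atlas)")
  for (tp in types) {
    src <- region_row(atlas, tp$source_area, NA, "right")
    miss <- setdiff(tp$targets$area, reg$area)
    if (length(miss))
      stop("profile targets region(s) absent from atlas: ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (ci in seq_len(tp$n)) {
      cell_id <- sprintf("%s_%04d", tp$name, ci)
      nodes <- list()
      nid <- 0L
      add_node <- function(pos, type, parent) {
        nid <<- nid + 1L
        nodes[[nid]] <<- c(nid, type, pos, if (type == 1) 5 else 1, parent)
        nid
      }
      inset <- 60
      span <- c(src$x1 - src$x0 - 2 * inset, src$z1 - src$z0 - 2 * inset) *
        tp$soma_xz_frac / 2
      ctr_xz <- c((src$x0 + src$x1) / 2, (src$z0 + src$z1) / 2)
      soma <- c(stats::runif(1, ctr_xz[1] - span[1], ctr_xz[1] + span[1]),
                tp$soma_depth + stats::runif(1, -20, 20),
                stats::runif(1, ctr_xz[2] - span[2], ctr_xz[2] + span[2]))
      u <- (soma[3] - src$z0) / (src$z1 - src$z0)  # topographic coordinate
      root <- add_node(soma, 1L, -1L)
      nid_env <- environment()
      grow_dendrites(nid_env, tp, soma)
      # axon hillock
      hil <- add_node(soma + c(0, 15, 0), 2L, root)
      for (ti in seq_len(nrow(tp$targets))) {
        tg <- tp$targets[ti, ]
        for (side in c("ipsi", "contra")) {
          p <- if (side == "ipsi") tg$prob else tg$contra_prob
          if (stats::runif(1) >= p) next
          hemi <- if (side == "ipsi") "right" else "left"
          tr <- region_row(atlas, tg$area, tg$layer, hemi)
          L <- tg$mean_axl * (if (side == "ipsi") 1 else tg$contra_axl_scale)
          L <- max(8 * step, L * stats::rnorm(1, 1, 0.08))
          grow_arbor(nid_env, atlas, soma, hil, tr, L, u, tp, step, wm_y)
        }
      }
      if (!is.null(tp$fiber_through)) {
        fr <- region_row(atlas, tp$fiber_through, NA, "right")
        grow_passing_fiber(nid_env, soma, hil, fr, wm_y, step)
      }
      nd <- as.data.frame(do.call(rbind, nodes))
      names(nd) <- c("id", "type", "x", "y", "z", "radius", "parent")
      neurons[[cell_id]] <- neuron(cell_id, nd, cell_type = tp$name,
                                   source_area = tp$source_area,
                                   hemisphere = "right")
      cells[[cell_id]] <- data.frame(cell_id = cell_id, cell_type = tp$name,
                                     source_area = tp$source_area)
    }
  }
  truth <- do.call(rbind, lapply(types, function(tp) {
    tg <- tp$targets
    data.frame(cell_type = tp$name, source_area = tp$source_area,
               area = tg$area, layer = tg$layer, prob = tg$prob,
               mean_axl = tg$mean_axl, contra_prob = tg$contra_prob,
               contra_axl_scale = tg$contra_axl_scale,
               topography = tp$topography)
  }))
  list(neurons = neurons, cells = do.call(rbind, cells), truth = truth,
       atlas = atlas)
}

# type-template dendrites (apical + basal), drawn in the caller's node env
grow_dendrites <- function(env, tp, soma) {
  sc <- tp$dendrite_scale
  add <- function(pos, type, parent) env$add_node(pos, type, parent)
  seg <- function(from_id, from, to, type, n = 4) {
    pts <- path_nodes(from, to, step = max(10, sqrt(sum((to - from)^2)) / n))
    par <- from_id
    for (r in seq_len(nrow(pts))) par <- add(pts[r, ], type, par)
    list(id = par, pos = pts[nrow(pts), ])
  }
  root <- 1L
  jit <- function(s) stats::rnorm(3, 0, s)
  dir_up <- c(0, -1, 0)
  tpl <- tp$dendrite
  if (tpl == "stellate") {
    for (b in 1:4) {
      to <- soma + 60 * sc * (c(stats::rnorm(1), stats::rnorm(1),
                                stats::rnorm(1)) |> (\(v) v / sqrt(sum(v^2)))())
      seg(root, soma, to, 4L)
    }
  } else {
    dirv <- switch(tpl, tufted = dir_up, untufted = dir_up,
                   inverted = -dir_up, horizontal = c(0, 0, 1))
    trunk_len <- switch(tpl, tufted = 280, untufted = 180, inverted = 160,
                        horizontal = 180) * sc
    tip <- soma + dirv * trunk_len + jit(10)
    tr <- seg(root, soma, tip, 4L, n = 6)
    if (tpl == "tufted") {
      for (b in 1:2) {
        t1 <- tr$pos + (dirv * 60 + c(40 * (b * 2 - 3), 0, 20)) * sc + jit(8)
        s1 <- seg(tr$id, tr$pos, t1, 4L, n = 3)
        for (b2 in 1:2) {
          t2 <- s1$pos + (dirv * 40 + c(20 * (b2 * 2 - 3), 0, -10)) * sc +
            jit(8)
          seg(s1$id, s1$pos, t2, 4L, n = 2)
        }
      }
    }
  }
  for (b in 1:3) {  # basal dendrites
    to <- soma + c(stats::rnorm(1, 0, 50), abs(stats::rnorm(1, 40, 15)),
                   stats::rnorm(1, 0, 50)) * sc
    seg(root, soma, to, 3L)
  }
  invisible(NULL)
}

# trunk to the target + two-level branching arbor of in-region length ~ L
grow_arbor <- function(env, atlas, soma, hil, tr, L, u, tp, step, wm_y) {
  inset <- 50
  bounds <- rbind(c(tr$x0, tr$y0, tr$z0) + inset,
                  c(tr$x1, tr$y1, tr$z1) - inset)
  zspan <- bounds[2, 3] - bounds[1, 3]
  z_anchor <- switch(tp$topography,
    none = stats::runif(1, bounds[1, 3], bounds[2, 3]),
    aligned = bounds[1, 3] + u * zspan + stats::rnorm(1, 0, tp$topo_sigma),
    reversed = bounds[1, 3] + (1 - u) * zspan +
      stats::rnorm(1, 0, tp$topo_sigma))
  z_anchor <- min(max(z_anchor, bounds[1, 3]), bounds[2, 3])
  # topographic projections form a narrow mediolateral band, so the
  # target cloud's dominant axis is the topographic (z) axis; the band
  # width is a fixed geometric property, independent of the mapping noise
  x_anchor <- if (tp$topography == "none") {
    stats::runif(1, bounds[1, 1], bounds[2, 1])
  } else {
    xc <- mean(bounds[, 1]) + stats::rnorm(1, 0, 15)
    min(max(xc, bounds[1, 1]), bounds[2, 1])
  }
  subcortical <- tr$y0 > wm_y
  # anchor near the white-matter-facing edge of the block
  y_edge <- if (subcortical) tr$y0 else tr$y1
  y_anchor <- if (subcortical) min(tr$y0 + 120, bounds[2, 2])
              else max(tr$y1 - 120, bounds[1, 2])
  anchor <- c(x_anchor, y_anchor, z_anchor)
  # trunk: soma -> white matter -> beneath/above anchor -> anchor
  waypts <- rbind(c(soma[1], wm_y, soma[3]),
                  c(x_anchor, wm_y, z_anchor),
                  c(x_anchor, y_edge, z_anchor))
  par <- hil
  from <- soma + c(0, 15, 0)
  for (w in seq_len(nrow(waypts))) {
    pts <- path_nodes(from, waypts[w, ], step = 1.5 * step)
    for (r in seq_len(nrow(pts))) par <- env$add_node(pts[r, ], 2L, par)
    from <- waypts[w, ]
  }
  pts <- path_nodes(from, anchor, step = step)
  for (r in seq_len(nrow(pts))) par <- env$add_node(pts[r, ], 2L, par)
  t_in <- abs(y_anchor - y_edge)          # in-region trunk length
  remaining <- max(8 * step, L - t_in)
  anchor_id <- par
  # compact cluster: walks confined to a radius around the anchor
  bounds <- rbind(pmax(bounds[1, ], anchor - tp$arbor_radius),
                  pmin(bounds[2, ], anchor + tp$arbor_radius))
  for (b in 1:2) {
    w1 <- bounded_walk(anchor, remaining * 0.2, bounds, step)
    p1 <- anchor_id
    for (r in seq_len(nrow(w1))) p1 <- env$add_node(w1[r, ], 2L, p1)
    mid <- w1[nrow(w1), ]
    for (b2 in 1:2) {
      w2 <- bounded_walk(mid, remaining * 0.15, bounds, step)
      p2 <- p1
      for (r in seq_len(nrow(w2))) p2 <- env$add_node(w2[r, ], 2L, p2)
    }
  }
  invisible(NULL)
}

# straight terminal-free fiber through a cortical region, ending above the
# pia (outside the atlas volume, region 0)
grow_passing_fiber <- function(env, soma, hil, fr, wm_y, step) {
  xz <- c(stats::runif(1, fr$x0 + 60, fr$x1 - 60),
          stats::runif(1, fr$z0 + 60, fr$z1 - 60))
  par <- hil
  from <- soma + c(0, 15, 0)
  for (w in list(c(soma[1], wm_y, soma[3]), c(xz[1], wm_y, xz[2]),
                 c(xz[1], -40, xz[2]))) {
    pts <- path_nodes(from, w, step = 1.5 * step)
    for (r in seq_len(nrow(pts))) par <- env$add_node(pts[r, ], 2L, par)
    from <- w
  }
  invisible(NULL)
}

#' Write a generated population to disk
#'
#' One SWC file per cell plus `cells.tsv` (metadata) and `truth.tsv`
#' (planted profiles).
#'
#' @param pop result of [generate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nrn in pop$neurons)
    write_swc(nrn, file.path(dir, paste0(nrn$cell_id, ".swc")))
  utils::write.table(pop$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pop$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
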