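test_that("target filter implements the length/terminal/order criteria", {
  # passing fiber: long but no terminal
  expect_false(call_target(1500, 0, 0))
  # mid-length arbor without a second-order bifurcation
  expect_false(call_target(500, 1, 1))
  # mid-length arbor with nested bifurcations
  expect_true(call_target(500, 2, 2))
  # below the short threshold
  expect_false(call_target(15, 3, 3))
  # boundary handling: 20 and 1000 fall in the banded criterion
  expect_true(call_target(20, 1, 2))
  expect_true(call_target(1000, 1, 2))
  expect_false(call_target(1000, 1, 1))
  expect_true(call_target(1000.01, 1, 0))
})

test_that("raising the long threshold never adds passing arbors", {
  set.seed(31)
  axl <- runif(1000, 0, 3000)
  terms <- rpois(1000, 1.2)
  ords <- rpois(1000, 1.5)
  pass_low <- call_target(axl, terms, ords, long_threshold = 800)
  pass_high <- call_target(axl, terms, ords, long_threshold = 1600)
  # arbors passing at the higher threshold pass at the lower one too
  expect_true(all(pass_low[pass_high]))
})

fake_arbors <- function(df) {
  df$side <- "right"
  if (is.null(df$hemisphere)) df$hemisphere <- "ipsi"
  if (is.null(df$cell_type)) df$cell_type <- "T"
  if (is.null(df$source_area)) df$source_area <- "A"
  df
}

test_that("connectome arithmetic: TargProb percent and mean passing AxL", {
  arb <- fake_arbors(data.frame(
    cell_id = c("c1", "c2", "c3", "c4"),
    region_id = 1L,
    axon_length = c(1000, 3000, 900, 10),
    n_terminals = c(2, 3, 0, 0),
    max_branch_order_within = c(2, 3, 0, 0)))
  cells <- data.frame(cell_id = paste0("c", 1:4), cell_type = "T",
                      source_area = "A")
  cm <- build_connectome(arb, cells = cells)
  expect_equal(cm$table$targ_prob, 50)
  expect_equal(cm$table$targ_stren, 2000)
  expect_equal(cm$rows$target_number, 1)
  expect_equal(cm$rows$n_cells, 4L)

  # permuting arbor rows leaves the matrix unchanged
  set.seed(3)
  cm2 <- build_connectome(arb[sample(nrow(arb)), ], cells = cells)
  expect_equal(cm2$table, cm$table)
})

test_that("cells with passing local arbors give ~100% local TargProb", {
  sc <- scenario_basic(n_per_type = 8)
  pop <- generate_population(sc$atlas, sc$types, seed = 9)
  arb <- decompose_population(pop$neurons, sc$atlas)
  cm <- build_connectome(arb, cells = pop$cells)
  # every type plants a local target with probability 1
  local_r5 <- cm$table[cm$table$cell_type == "IT" &
                         cm$table$hemisphere == "ipsi", ]
  expect_true(any(local_r5$targ_prob == 100))
})

test_that("weak-target fractions count planted weak targets", {
  set.seed(41)
  n_strong <- 45; n_weak <- 5
  arb <- fake_arbors(data.frame(
    cell_id = "c1",
    region_id = seq_len(n_strong + n_weak),
    axon_length = c(runif(n_strong, 1500, 4000), runif(n_weak, 200, 800)),
    n_terminals = 3, max_branch_order_within = 3))
  cm <- build_connectome(arb, cells = data.frame(
    cell_id = "c1", cell_type = "T", source_area = "A"))
  ws <- weak_target_summary(cm, axl_cut = 1000, prob_cut = 2.4)
  expect_equal(ws$n_targets, 50L)
  expect_equal(ws$frac_axl_above, 0.9)
  expect_equal(weak_target_summary(cm, axl_cut = 0)$frac_axl_above, 1)
})

test_that("laminar profiles normalize to the peak layer", {
  atlas <- synth_atlas(n_areas = 1, layers = c("L2/3", "L5", "L6"),
                       n_sub = 0)
  r23 <- atlas$regions$region_id[atlas$regions$layer == "L2/3" &
                                   atlas$regions$hemisphere == "right"]
  r5 <- atlas$regions$region_id[atlas$regions$layer == "L5" &
                                  atlas$regions$hemisphere == "right"]
  arb <- fake_arbors(data.frame(
    cell_id = rep(paste0("c", 1:5), 2),
    region_id = rep(c(r23, r5), each = 5),
    axon_length = 1500,
    n_terminals = c(rep(1, 2), rep(0, 3), rep(1, 1), rep(0, 4)),
    max_branch_order_within = 3))
  cells <- data.frame(cell_id = paste0("c", 1:5), cell_type = "T",
                      source_area = "A")
  cm <- build_connectome(arb, cells = cells)
  prof <- laminar_profile(cm, atlas, "A1", "T", "A", hemisphere = "ipsi")
  # raw probs 40% (L2/3) and 20% (L5) -> normalized 1.0 and 0.5
  expect_equal(prof$norm_prob[prof$layer == "L2/3"], 1)
  expect_equal(prof$norm_prob[prof$layer == "L5"], 0.5)
  expect_equal(prof$norm_prob[prof$layer == "L6"], 0)
  # idempotent: renormalizing the normalized profile changes nothing
  expect_equal(prof$norm_prob / max(prof$norm_prob), prof$norm_prob)
})

test_that("hemispheric symmetry recovers planted mirror correlation", {
  mk_cm <- function(ipsi, contra) {
    k <- length(ipsi)
    tab <- data.frame(cell_type = "T", source_area = "A",
                      region_id = rep(seq_len(k), 2),
                      hemisphere = rep(c("ipsi", "contra"), each = k),
                      n_cells = 100L,
                      n_passing = c(ipsi, contra),
                      targ_prob = c(ipsi, contra),
                      targ_stren = 1000)
    structure(list(table = tab, rows = NULL), class = "connectome")
  }
  ip <- c(80, 60, 40, 20, 10, 5)
  hs <- hemispheric_symmetry(mk_cm(ip, ip), "T", "A", n_perm = 200)
  expect_equal(hs$r, 1)
  hs <- hemispheric_symmetry(mk_cm(ip, max(ip) + min(ip) - ip), "T", "A",
                             n_perm = 200)
  expect_equal(hs$r, -1)
  # planted noisy mirror: r recovered near the planted correlation
  reps <- vapply(1:30, function(k) {
    set.seed(1000 + k)
    ipsi <- runif(30, 0, 100)
    contra <- ipsi + rnorm(30, 0, 15)
    hemispheric_symmetry(mk_cm(ipsi, contra), "T", "A", n_perm = 50,
                         seed = k)$r
  }, numeric(1))
  planted <- sqrt(1 / (1 + 15^2 / (100^2 / 12)))
  expect_lt(abs(mean(reps) - planted), 0.05)
  # zero-variance vector flagged
  expect_true(hemispheric_symmetry(mk_cm(rep(5, 6), ip), "T", "A",
                                   n_perm = 10)$degenerate)
})
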