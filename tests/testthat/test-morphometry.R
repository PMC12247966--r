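test_that("features of canonical trees match hand geometry", {
  # straight 100 um vertical apical: height 100, efficiency 1, one tip
  rows <- c(list(list(1L, 1L, c(0, 0, 0), -1L)),
            lapply(1:10, function(i) list(i + 1L, 4L, c(0, -10 * i, 0), i)))
  f <- extract_features(make_neuron(rows), "apical")
  expect_equal(f$height, 100)
  expect_equal(f$max_dist_soma, 100)
  expect_equal(f$max_path_soma, 100)
  expect_equal(f$path_efficiency, 1)
  expect_equal(f$n_tips, 1)
  expect_equal(f$n_bifurcations, 0)
  expect_true(is.na(f$avg_bif_angle))

  # symmetric Y with a 90 degree opening
  y <- make_neuron(list(list(1L, 1L, c(0, 0, 0), -1L),
                        list(2L, 4L, c(0, -10, 0), 1L),
                        list(3L, 4L, c(10, -20, 0), 2L),
                        list(4L, 4L, c(-10, -20, 0), 2L)))
  fy <- extract_features(y, "apical")
  expect_equal(fy$avg_bif_angle, 90)
  expect_equal(fy$n_bifurcations, 1)
  expect_equal(fy$n_tips, 2)
  expect_equal(fy$n_segments, 3)  # trunk + two daughters

  # tortuous path: efficiency = euclidean / path < 1
  zig <- make_neuron(list(list(1L, 1L, c(0, 0, 0), -1L),
                          list(2L, 4L, c(10, 0, 0), 1L),
                          list(3L, 4L, c(10, 10, 0), 2L),
                          list(4L, 4L, c(20, 10, 0), 3L)))
  fz <- extract_features(zig, "apical")
  expect_equal(fz$path_efficiency, sqrt(500) / 30)
})

test_that("feature counts match construction on random binary trees", {
  set.seed(401)
  for (depth in 2:4) {
    nrn <- binary_tree_neuron(depth)
    nrn$nodes$type[nrn$nodes$type == 2L] <- 4L
    f <- extract_features(nrn, "apical")
    # trunk node plus every internal level bifurcates
    expect_equal(f$n_tips, 2^depth)
    expect_equal(f$n_bifurcations, 2^depth - 1)
    expect_equal(f$n_segments, 2^(depth + 1) - 1)
  }
})

test_that("feature extraction is invariant to node order and translation", {
  sc <- scenario_basic(n_per_type = 2)
  pop <- generate_population(sc$atlas, sc$types, seed = 11)
  nrn <- pop$neurons[[1]]
  f0 <- extract_features(nrn, "apical")
  moved <- nrn
  moved$nodes[, c("x", "y", "z")] <-
    moved$nodes[, c("x", "y", "z")] + rep(c(100, -50, 30), each = nrow(moved$nodes))
  expect_equal(extract_features(moved, "apical"), f0, tolerance = 1e-9)
})

test_that("min-max scaling maps ranges onto [0,1] and preserves order", {
  x <- data.frame(a = c(2, 4, 6), b = c(0, 0.5, 1), id = c("x", "y", "z"))
  nx <- minmax_normalize(x)
  expect_equal(nx$a, c(0, 0.5, 1))
  expect_equal(nx$b, c(0, 0.5, 1))  # idempotent on [0,1] data
  expect_equal(order(nx$a), order(x$a))
  expect_equal(nx$id, x$id)
  expect_warning(minmax_normalize(data.frame(a = 1:3, c = rep(7, 3))),
                 "constant")
})

test_that("well-separated classes cluster and classify perfectly", {
  pf <- planted_feature_table(n_per_class = 25, k = 3, sep = 6, seed = 7)
  cl <- hcluster(minmax_normalize(pf$features), k = 3)
  expect_equal(clustering_accuracy(pf$labels, cl), 1)
  # accuracy invariant under cluster relabeling
  expect_equal(clustering_accuracy(pf$labels, max(cl) + 1 - cl), 1)

  rf <- train_classifier(pf$features, pf$labels, seed = 3)
  expect_equal(rf$accuracy, 1)
  # feature column permutation does not change a forest's separability
  rf2 <- train_classifier(pf$features[, sample(ncol(pf$features))],
                          pf$labels, seed = 3)
  expect_equal(rf2$accuracy, 1)
})

test_that("null labels give chance-level accuracies", {
  set.seed(409)
  pf <- planted_feature_table(n_per_class = 30, k = 3, sep = 5, seed = 9)
  # clustering structure is real but labels are shuffled: accuracy drops
  # toward the best-permutation chance level
  shuffled <- sample(pf$labels)
  cl <- hcluster(minmax_normalize(pf$features), k = 3)
  acc <- clustering_accuracy(shuffled, cl)
  expect_lt(acc, 0.6)
  expect_gte(acc, max(table(shuffled)) / length(shuffled) - 0.1)

  accs <- vapply(1:5, function(k) {
    train_classifier(pf$features, sample(pf$labels), seed = k)$accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.55)
})

test_that("stratified split and class checks guard the classifier", {
  pf <- planted_feature_table(n_per_class = 10, k = 2, sep = 4, seed = 2)
  expect_error(train_classifier(pf$features, rep("one", 20)), "2 classes")
  labs <- as.character(pf$labels)
  labs[1] <- "rare"
  expect_error(train_classifier(pf$features, labs), "2 cells")
})
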