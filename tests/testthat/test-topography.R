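test_that("arbor centroids follow length-weighted geometry", {
  # single straight segment: midpoint
  expect_equal(arbor_centroid(c(0, 0, 0), c(10, 4, 2), step = 0.01),
               c(5, 2, 1), tolerance = 1e-3, ignore_attr = TRUE)
  # symmetric V: centroid on the bisector plane of the apex
  p0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  p1 <- rbind(c(10, 10, 0), c(-10, 10, 0))
  ctr <- arbor_centroid(p0, p1, step = 0.01)
  expect_equal(ctr[1], 0, tolerance = 1e-6)
  expect_equal(ctr[2], 5, tolerance = 1e-2)
  # random tree vs closed-form length-weighted midpoint oracle
  set.seed(211)
  p0 <- matrix(runif(30, 0, 100), ncol = 3)
  p1 <- p0 + matrix(rnorm(30, 0, 20), ncol = 3)
  len <- sqrt(rowSums((p1 - p0)^2))
  oracle <- colSums((p0 + p1) / 2 * len) / sum(len)
  step <- 0.5
  expect_lt(sqrt(sum((arbor_centroid(p0, p1, step) - oracle)^2)), step)
  expect_error(arbor_centroid(matrix(numeric(0), ncol = 3),
                              matrix(numeric(0), ncol = 3)), "empty")
})

test_that("principal axis recovers the dominant direction with fixed sign", {
  pts <- cbind(seq(-5, 5), 0, 0)
  expect_equal(as.vector(principal_axis(pts)), c(1, 0, 0))
  # translation invariance
  expect_equal(as.vector(principal_axis(sweep(pts, 2, c(7, -2, 3), "+"))),
               c(1, 0, 0))
  # anisotropic Gaussian: axis within 5 degrees of x
  set.seed(223)
  g <- cbind(rnorm(500, 0, 10), rnorm(500, 0, 1), rnorm(500, 0, 1))
  ax <- principal_axis(g)
  expect_lt(acos(abs(sum(ax * c(1, 0, 0)))) * 180 / pi, 5)
  # sign convention: largest-magnitude component positive
  expect_gt(max(abs(ax)) * sign(ax[which.max(abs(ax))]), 0)
})

test_that("topography rho hits the rank-correlation limits and formula", {
  n <- 10
  somas <- cbind(seq_len(n) * 10, 0, 0)
  cent_same <- cbind(0, 5, seq_len(n) * 7)       # same order along z
  cent_rev <- cbind(0, 5, rev(seq_len(n)) * 7)   # reversed order
  expect_equal(topography_rho(somas, cent_same)$rho, 1)
  expect_equal(topography_rho(somas, cent_rev)$rho, -1)

  # projected ranks (1,2,3) vs (2,1,3): Spearman 1 - 6*sum(d^2)/(n(n^2-1))
  s3 <- cbind(c(1, 2, 3), 0, 0)
  c3 <- cbind(0, 0, c(2, 1, 3))
  d2 <- sum((c(1, 2, 3) - c(2, 1, 3))^2)
  expect_equal(topography_rho(s3, c3)$rho, 1 - 6 * d2 / (3 * (9 - 1)))
  expect_equal(topography_rho(s3, c3)$rho, 0.5)

  # joint rigid translation leaves rho unchanged; reflecting one set
  # through the plane orthogonal to its axis flips the sign
  set.seed(227)
  S <- matrix(rnorm(60), ncol = 3) %*% diag(c(10, 2, 1))
  C <- S[order(S[, 1]), ][rank(S[, 1]), ] + matrix(rnorm(60, 0, 0.5), 20)
  base <- topography_rho(S, C)
  shifted <- topography_rho(sweep(S, 2, c(5, 5, 5), "+"),
                            sweep(C, 2, c(5, 5, 5), "+"))
  expect_equal(shifted$rho, base$rho)
  ax <- principal_axis(C)
  C_refl <- C - 2 * (C %*% ax) %*% t(ax)
  expect_equal(topography_rho(S, C_refl)$rho, -base$rho)

  # degenerate constant projection flagged
  expect_true(topography_rho(cbind(1:5, 0, 0),
                             matrix(1, 5, 3))$degenerate)
})

test_that("planted topographic gradients are recovered from populations", {
  run_mode <- function(mode, seed, sigma) {
    sc <- scenario_topography(mode, n_cells = 30, sigma = sigma)
    pop <- generate_population(sc$atlas, sc$types, seed = seed)
    tgt <- sc$atlas$regions
    rid <- tgt$region_id[tgt$area == "A3" & tgt$hemisphere == "right"]
    population_topography(pop$neurons, sc$atlas, rid, hemisphere = "right",
                          step = 5)
  }
  # small placement noise: strong rank alignment in the planted direction
  al <- run_mode("aligned", 301, sigma = 10)
  rv <- run_mode("reversed", 302, sigma = 10)
  expect_gt(al$rho, 0.8)
  expect_lt(rv$rho, -0.8)
  expect_gte(al$projecting_fraction, 0.9)
  # moderate noise still fixes the sign
  expect_gt(run_mode("aligned", 303, sigma = 30)$rho, 0.3)
  expect_lt(run_mode("reversed", 304, sigma = 30)$rho, -0.3)
})
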