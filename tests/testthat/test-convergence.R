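test_that("overlap score limits: identical clouds 1, separated clouds 0", {
  set.seed(101)
  cloud <- matrix(rnorm(150), ncol = 3)
  res <- overlap_score(cloud, cloud)
  expect_equal(res$O, 1)
  expect_equal(res$S, 0)

  far <- sweep(cloud, 2, c(100, 0, 0), "+")
  res <- overlap_score(cloud, far)
  expect_equal(res$O, 0)
  expect_gte(res$S, 1)
})

test_that("overlap score matches the hand scatter-matrix example", {
  # 1-D clouds {0,1} vs {0.5,1.5}: m1=0.5, m2=1, mbar=0.75
  # tr(S_B) = 2*(0.25)^2*2 = 0.25; tr(S_W) = 4*(0.5)^2 = 1.0
  a <- cbind(c(0, 1), 0, 0)
  b <- cbind(c(0.5, 1.5), 0, 0)
  res <- overlap_score(a, b)
  expect_equal(res$S, 0.25)
  expect_equal(res$O, 0.75)
})

test_that("overlap equals the brute-force double-loop oracle", {
  set.seed(103)
  for (rep in 1:25) {
    na <- sample(5:200, 1); nb <- sample(5:200, 1)
    sep <- runif(1, 0, 4)
    a <- matrix(rnorm(na * 3), ncol = 3)
    b <- matrix(rnorm(nb * 3, mean = sep), ncol = 3)
    expect_equal(overlap_score(a, b)$O, oracle_overlap(a, b),
                 tolerance = 1e-9)
  }
})

test_that("overlap is symmetric and rigid-motion invariant", {
  set.seed(107)
  a <- matrix(rnorm(90), ncol = 3)
  b <- matrix(rnorm(120, mean = 0.8), ncol = 3)
  expect_equal(overlap_score(a, b)$O, overlap_score(b, a)$O)
  # joint rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -3, 11)
  expect_equal(overlap_score(a %*% R + rep(tr, each = nrow(a)),
                             b %*% R + rep(tr, each = nrow(b)))$O,
               overlap_score(a, b)$O, tolerance = 1e-12)
  # moving one cloud away never increases overlap
  shifts <- seq(0, 6, by = 0.5)
  Os <- vapply(shifts, function(s)
    overlap_score(a, sweep(b, 2, c(s, 0, 0), "+"))$O, numeric(1))
  expect_true(all(diff(Os) <= 1e-12))
})

test_that("degenerate within-class scatter is flagged", {
  pt <- matrix(rep(c(1, 2, 3), 5), ncol = 3, byrow = TRUE)
  same <- overlap_score(pt, pt)
  expect_true(same$degenerate)
  expect_equal(same$O, 1)
  other <- matrix(rep(c(4, 2, 3), 5), ncol = 3, byrow = TRUE)
  expect_equal(overlap_score(pt, other)$O, 0)
})

test_that("overlap matrices are symmetric with planted group structure", {
  set.seed(109)
  base1 <- matrix(rnorm(300), ncol = 3)
  base2 <- sweep(matrix(rnorm(300), ncol = 3), 2, c(200, 0, 0), "+")
  clouds <- list(s1 = base1 + rnorm(300, 0, 0.05),
                 s2 = base1 + rnorm(300, 0, 0.05),
                 s3 = base2 + rnorm(300, 0, 0.05),
                 s4 = base2 + rnorm(300, 0, 0.05))
  om <- overlap_matrix(clouds)
  expect_equal(om$O, t(om$O))
  expect_true(all(diag(om$O) == 1))
  expect_gt(om$O["s1", "s2"], 0.9)
  expect_gt(om$O["s3", "s4"], 0.9)
  expect_equal(om$O["s1", "s3"], 0)
  expect_equal(om$summary$frac_zero, 4 / 6)
  # identical clouds across the board -> all-ones matrix
  om1 <- overlap_matrix(list(a = base1, b = base1, c = base1))
  expect_true(all(om1$O == 1))
  # relabeling sources permutes but does not change values
  om2 <- overlap_matrix(clouds[c(3, 1, 4, 2)])
  expect_equal(om2$O["s3", "s1"], om$O["s1", "s3"])
  # missing source reported as NA, not zero
  om3 <- overlap_matrix(list(a = base1, b = base2,
                             c = matrix(numeric(0), ncol = 3)))
  expect_true(all(is.na(om3$O["c", c("a", "b")])))
})

test_that("KDE density matches a brute-force evaluation oracle", {
  set.seed(113)
  pts <- matrix(rnorm(50 * 3, 50, 10), ncol = 3)
  kde <- kde_cloud(pts, bandwidth = 0.4, voxel_size = 10)
  # direct per-voxel double loop in standardized coordinates
  ctr <- colMeans(pts); scl <- apply(pts, 2, sd)
  oracle <- array(0, dim(kde$density))
  for (i in seq_along(kde$grid[[1]]))
    for (j in seq_along(kde$grid[[2]]))
      for (k in seq_along(kde$grid[[3]])) {
        g <- (c(kde$grid[[1]][i], kde$grid[[2]][j], kde$grid[[3]][k]) -
                ctr) / scl
        z <- sweep(sweep(pts, 2, ctr), 2, scl, "/")
        oracle[i, j, k] <- mean(exp(-rowSums(sweep(z, 2, g)^2) /
                                      (2 * 0.4^2)))
      }
  expect_equal(kde$density / max(kde$density), oracle / max(oracle),
               tolerance = 1e-9)
})

test_that("KDE half-max volume recovers a filled cube geometrically", {
  a <- 100
  g <- seq(0, a, length.out = 21)
  pts <- as.matrix(expand.grid(g, g, g))  # deterministic uniform fill
  kde <- kde_cloud(pts, bandwidth = 4, voxel_size = 5, standardize = FALSE)
  vol_half <- cloud_volume(kde, total_length = 1e5, rel_threshold = 0.5)
  expect_lt(abs(vol_half$volume_um3 - a^3) / a^3, 0.15)
  expect_equal(vol_half$mean_density, 1e5 / vol_half$volume_um3)

  # the 1% default adds the kernel halo: larger, but bounded by ~2.4 sigma
  # beyond each face
  vol_1 <- cloud_volume(kde, rel_threshold = 0.01)
  expect_gte(vol_1$volume_um3, vol_half$volume_um3)
  expect_lte(vol_1$volume_um3, 1.05 * (a + 2 * 2.4 * 4)^3)

  # volume grows monotonically as the relative threshold drops
  vols <- vapply(c(0.9, 0.5, 0.1, 0.01), function(th)
    cloud_volume(kde, rel_threshold = th)$volume_um3, numeric(1))
  expect_true(all(diff(vols) >= 0))

  # doubling the bandwidth never shrinks the thresholded volume of a blob
  set.seed(117)
  blob <- matrix(rnorm(600, 50, 8), ncol = 3)
  v1 <- cloud_volume(kde_cloud(blob, 0.3, voxel_size = 5))$volume_um3
  v2 <- cloud_volume(kde_cloud(blob, 0.6, voxel_size = 5))$volume_um3
  expect_gte(v2, v1)
  expect_error(kde_cloud(blob[1:5, ]), ">= 10 points")
})

test_that("composition clustering groups targets by planted modules", {
  set.seed(127)
  # 3 modules of targets, each drawing from a distinct contributor block
  comp <- matrix(0, 9, 6,
                 dimnames = list(paste0("t", 1:9), paste0("src", 1:6)))
  for (m in 1:3) {
    rows <- (m - 1) * 3 + 1:3
    cols <- (m - 1) * 2 + 1:2
    comp[rows, cols] <- matrix(runif(6, 500, 1500), 3, 2)
  }
  cc <- composition_cluster(comp)
  k3 <- cutree(cc$target_hclust, 3)
  expect_equal(length(unique(k3[1:3])), 1L)
  expect_equal(length(unique(k3[4:6])), 1L)
  expect_equal(length(unique(k3[7:9])), 1L)
  expect_equal(length(unique(tapply(names(k3), k3, length))), 1L)
  expect_equal(cc$target_similarity, t(cc$target_similarity))
  expect_true(all(diag(cc$target_similarity) == 1))

  # identical compositions: similarity 1 and merged first
  comp2 <- rbind(a = c(10, 5, 1), b = c(20, 10, 2), c = c(1, 0, 30))
  cc2 <- composition_cluster(comp2)
  expect_equal(cc2$target_similarity["a", "b"], 1)
  expect_equal(cc2$target_hclust$merge[1, ], c(-1L, -2L))
  # scaling a row is absorbed by the proportion normalization
  comp3 <- comp2; comp3["a", ] <- comp3["a", ] * 7
  expect_equal(composition_cluster(comp3)$target_similarity,
               cc2$target_similarity)
  expect_warning(composition_cluster(rbind(comp2, d = c(0, 0, 0))),
                 "all-zero")
})
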