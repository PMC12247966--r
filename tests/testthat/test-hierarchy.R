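test_that("hierarchy scores follow the probability/length ratio", {
  P <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  P["A", "B"] <- 0.5
  L <- matrix(1000, 2, 2, dimnames = dimnames(P))
  ht <- hierarchy_score(P, L)
  expect_equal(ht$score[ht$region == "B"], 5e-4)
  expect_equal(ht$score[ht$region == "A"], 0)

  # doubling all mean lengths halves all scores
  ht2 <- hierarchy_score(P, 2 * L)
  expect_equal(ht2$score, ht$score / 2)

  # missing length where P > 0 is an error naming the pair
  L_bad <- L; L_bad["A", "B"] <- NA
  expect_error(hierarchy_score(P, L_bad), "A.*B")
})

test_that("hierarchy score equals brute-force summation on random inputs", {
  set.seed(307)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    nm <- paste0("R", seq_len(n))
    P <- matrix(runif(n * n) * rbinom(n * n, 1, 0.6), n, n,
                dimnames = list(nm, nm))
    L <- matrix(runif(n * n, 500, 4000), n, n, dimnames = list(nm, nm))
    ht <- hierarchy_score(P, L)
    oracle <- vapply(seq_len(n), function(j) {
      s <- 0
      for (i in seq_len(n)) if (i != j) s <- s + P[i, j] / L[i, j]
      s
    }, numeric(1))
    expect_equal(ht$score, oracle, tolerance = 1e-12)
  }
})

test_that("score correlates behave on proportional and null inputs", {
  set.seed(311)
  n <- 12
  nm <- paste0("R", seq_len(n))
  # equal lengths: score is proportional to column sums of P, and target
  # number is made proportional to score by a graded targeting pattern
  P <- matrix(0, n, n, dimnames = list(nm, nm))
  for (j in seq_len(n)) P[seq_len(min(j, n - 1)), j] <- 0.5
  diag(P) <- 0
  L <- matrix(1000, n, n, dimnames = list(nm, nm))
  ht <- hierarchy_score(P, L)
  sc <- score_correlates(ht, P, L, n_perm = 500, seed = 2)
  expect_equal(sc$r[sc$measure == "target_number"], 1, tolerance = 1e-9)
  expect_lt(sc$p_value[sc$measure == "target_number"], 0.05)

  # independent random lengths: TargStren correlation is usually null
  pvals <- vapply(1:20, function(k) {
    set.seed(3000 + k)
    P2 <- matrix(runif(n * n) * rbinom(n * n, 1, 0.7), n, n,
                 dimnames = list(nm, nm))
    diag(P2) <- 0
    L2 <- matrix(runif(n * n, 500, 4000), n, n, dimnames = list(nm, nm))
    ht2 <- hierarchy_score(P2, L2)
    # replace lengths by fresh independent values for the correlate
    L3 <- matrix(runif(n * n, 500, 4000), n, n, dimnames = list(nm, nm))
    sc2 <- score_correlates(ht2, P2, L3, n_perm = 300, seed = k)
    sc2$p_value[sc2$measure == "mean_targ_stren"]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("fast rank-sum p-values match wilcox.test", {
  set.seed(313)
  x <- rnorm(40, 0.3)
  ymat <- matrix(rnorm(40 * 50), 40)
  fast <- projectomer:::ranksum_p(x, ymat)
  slow <- apply(ymat, 2, function(y)
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(fast, unname(slow), tolerance = 1e-10)
})

test_that("FF/FB classification detects forced and planted biases", {
  lv <- c(A = 1, B = 2, C = 3, D = 4)
  # strictly ascending projections: every dh = +1 -> FF
  conn <- data.frame(cell_type = "up",
                     source = rep(c("A", "B", "C"), each = 4),
                     target = rep(c("B", "C", "D"), each = 4))
  res <- fffb_classify(conn, lv, seed = 5)
  expect_equal(res$verdict, "FF")
  expect_equal(res$mean_dh, 1)

  # descending projections -> FB
  conn_dn <- data.frame(cell_type = "down", source = conn$target,
                        target = conn$source)
  expect_equal(fffb_classify(conn_dn, lv, seed = 5)$verdict, "FB")

  # missing level is an error; degenerate zero-variance sample flagged
  expect_error(fffb_classify(data.frame(cell_type = "x", source = "A",
                                        target = "Z"), lv), "Z")

  # planted FF bias dh ~ N(0.5, 1) detected with high power at n = 100
  lv2 <- setNames(seq(-10, 10, by = 0.01), paste0("r", 1:2001))
  set.seed(317)
  hits <- vapply(1:20, function(k) {
    dh <- rnorm(100, 0.5, 1)
    src <- sample(names(lv2)[500:1500], 100, replace = TRUE)
    tgt <- names(lv2)[match(src, names(lv2)) + round(dh / 0.01)]
    cc <- data.frame(cell_type = "p", source = src, target = tgt)
    fffb_classify(cc, lv2, seed = k)$verdict == "FF"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment is monotone and alpha-consistent", {
  set.seed(331)
  praw <- runif(12)^2
  adj <- p.adjust(praw, "BH")
  expect_true(all(diff(adj[order(praw)]) >= -1e-12))
  expect_gte(sum(adj < 0.05), sum(adj < 0.01))
})
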