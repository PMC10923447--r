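test_that("standardization centers, scales, round-trips and is idempotent", {
  z <- ts_standardize(cbind(x = c(1, 2, 3)))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  set.seed(1)
  x <- matrix(rnorm(60, 5, 3), 20)
  z <- ts_standardize(x)
  expect_equal(unname(colMeans(z)), rep(0, 3))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3))
  expect_equal(unname(ts_standardize(z)[, ]), unname(z[, ]))  # idempotent
  back <- sweep(sweep(z, 2, attr(z, "scale"), `*`), 2, attr(z, "center"), `+`)
  expect_equal(unname(back[, ]), unname(x))                   # round trip

  expect_error(ts_standardize(cbind(a = c(1, 1, 1))), "zero-variance")
})

test_that("cluster tightness matches the plain-loop oracle", {
  set.seed(2)
  x <- matrix(rnorm(15), 5, 3)
  gv <- biased_var(x)
  # singleton: zero within-variance leaves only the regularizer
  expect_equal(cluster_tightness(x, 1, gv), -sum(0.5 * log(gv)))
  # whole dataset, and arbitrary subsets, against the loop oracle
  expect_equal(cluster_tightness(x, 1:5, gv), xi_oracle(x, 1:5, gv))
  expect_equal(cluster_tightness(x, c(2, 4), gv), xi_oracle(x, c(2, 4), gv))
  # duplicating every point doubles N_v while leaving within-variance as is
  x2 <- rbind(x, x)
  expect_equal(cluster_tightness(x2, 1:10, gv), 2 * cluster_tightness(x, 1:5, gv))
  expect_error(cluster_tightness(x, integer(0)), "nonempty")
})

test_that("log-likelihood distance is symmetric, >= 0, zero for clones", {
  x <- rbind(c(1, 2, 3), c(1, 2, 3), c(4, 0, 1), c(2, 2, 2))
  gv <- biased_var(x)
  expect_equal(loglik_distance(x, 1, 2, gv), 0, tolerance = 1e-12)
  d_ab <- loglik_distance(x, c(1, 2), c(3, 4), gv)
  d_ba <- loglik_distance(x, c(3, 4), c(1, 2), gv)
  expect_equal(d_ab, d_ba)
  # hand evaluation via the oracle pieces
  expect_equal(d_ab, xi_oracle(x, c(1, 2), gv) + xi_oracle(x, c(3, 4), gv) -
                 xi_oracle(x, 1:4, gv))
  expect_gte(d_ab, 0)
  expect_error(loglik_distance(x, c(1, 2), c(2, 3), gv), "disjoint")

  set.seed(3)
  xr <- matrix(rnorm(30), 10, 3)
  gvr <- biased_var(xr)
  for (i in 1:5) {
    a <- sample(10, 3); b <- setdiff(sample(10, 6), a)[1:3]
    expect_equal(loglik_distance(xr, a, b, gvr), loglik_distance(xr, b, a, gvr))
    expect_gte(loglik_distance(xr, a, b, gvr), -1e-10)
  }
})

test_that("agglomeration records merge structure, BIC equals the formula", {
  x <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(5, 5, 5))
  rownames(x) <- c("a", "b", "c")
  agg <- ts_agglomerate(x, J_max = 3)
  expect_equal(length(agg$bic_trace), 3)
  expect_true(all(is.finite(agg$merge_dist[2:3])))   # two merges happened
  # cut at 2 clusters separates the far point
  expect_equal(length(unique(agg$cuts[[2]])), 2)
  expect_true(agg$cuts[[2]][1] == agg$cuts[[2]][2] &&
                agg$cuts[[2]][1] != agg$cuts[[2]][3])

  # BIC(J) = -2 * sum xi_j + 2 p J log n, recomputed from the cuts
  set.seed(4)
  y <- matrix(rnorm(36), 12, 3)
  agg2 <- ts_agglomerate(y, J_max = 5)
  gv <- biased_var(y)
  for (J in 1:5) {
    reps <- agg2$cuts[[J]]
    xi_sum <- sum(vapply(unique(reps), function(r)
      cluster_tightness(y, which(reps == r), gv), numeric(1)))
    expect_equal(agg2$bic_trace[J], -2 * xi_sum + 6 * J * log(12),
                 tolerance = 1e-10)
  }

  # two well-separated blobs: final merge dwarfs all earlier ones
  b <- gen_blobs(80, 2, sep = 10, seed = 5)
  agg3 <- ts_agglomerate(ts_standardize(b$x), J_max = 10)
  expect_gt(agg3$merge_dist[2], 2 * max(agg3$merge_dist[3:80]))
})

test_that("cuts of the merge tree are nested partitions", {
  set.seed(6)
  x <- matrix(rnorm(90), 30, 3)
  agg <- ts_agglomerate(x, J_max = 6)
  for (J in 6:2) {
    fine <- agg$cuts[[J]]; coarse <- agg$cuts[[J - 1]]
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
    expect_equal(length(unique(fine)), J)
  }
})

test_that("choose_k handles trivial and planted traces", {
  # monotone worsening BIC from J = 1
  expect_equal(choose_k(c(10, 20, 30, 40), rep(1, 10)), 1L)
  expect_warning(k <- choose_k(rep(5, 6), rep(1, 10)), "degenerate")
  expect_equal(k, 1L)

  b3 <- gen_blobs(600, 3, sep = 6, seed = 7)
  f3 <- twostep_fit(b3$x)
  expect_equal(f3$k, 3)
  b5 <- gen_blobs(600, 5, sep = 6, seed = 8)
  f5 <- twostep_fit(b5$x)
  expect_equal(f5$k, 5)
})

test_that("planted-model recovery holds across seeded replicates", {
  ok <- 0
  for (s in 1:10) {
    b <- gen_blobs(240, 4, sep = 6, seed = 100 + s)
    f <- twostep_fit(b$x)
    ok <- ok + (f$k == 4 && adjusted_rand_index(b$lab, f$assignments) >= 0.9)
  }
  expect_gte(ok, 9)
})

test_that("fit is invariant to row permutation and to dataset duplication", {
  b <- gen_blobs(150, 3, sep = 6, seed = 9)
  f <- twostep_fit(b$x)
  set.seed(10)
  perm <- sample(nrow(b$x))
  fp <- twostep_fit(b$x[perm, ])
  expect_equal(adjusted_rand_index(f$assignments[perm], fp$assignments), 1)

  # each copy of a duplicated dataset receives the same partition
  x2 <- rbind(b$x, b$x)
  rownames(x2) <- sprintf("r%d", seq_len(nrow(x2)))
  f2 <- twostep_fit(x2)
  first <- f2$assignments[seq_len(nrow(b$x))]
  second <- f2$assignments[nrow(b$x) + seq_len(nrow(b$x))]
  expect_equal(adjusted_rand_index(first, second), 1)
  expect_equal(adjusted_rand_index(first, f$assignments), 1)
})

test_that("fit handles listwise deletion, tiny n, and J_max > n", {
  x <- gen_blobs(30, 2, sep = 8, seed = 11)$x
  x[3, 2] <- NA
  expect_message(f <- twostep_fit(x), "listwise deletion removed 1")
  expect_equal(f$n, 29)
  expect_equal(f$n_dropped, 1)
  expect_warning(f2 <- twostep_fit(gen_blobs(8, 2, sep = 8, seed = 12)$x,
                                   J_max = 15), "J_max lowered")
  expect_lte(f2$k, 8)
  expect_error(twostep_fit(x[1, , drop = FALSE]), "at least 2")
})
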