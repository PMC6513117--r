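test_that("modularity_score reproduces brute-force values on the toy blocks", {
  B <- toy_block_matrix()
  planted <- c(1, 1, 2, 2)

  # frozen oracle values: planted split (8 * 0.5)/4 = 1, merged sums to 0
  expect_equal(modularity_score(B, planted, c_norm = 4), 1)
  expect_equal(modularity_score(B, rep(1, 4), c_norm = 4), 0)
  expect_equal(modularity_score(B, rep(1, 4), c_norm = 4), sum(B) / 4)

  # planted split is the argmax over all 15 set partitions
  best <- brute_force_best(B, c_norm = 4)
  expect_equal(best$q, 1)
  expect_equal(adjusted_rand_index(best$labels, planted), 1)

  # zero matrix scores zero on every partition
  for (p in all_partitions(4)) {
    expect_equal(modularity_score(matrix(0, 4, 4), p, c_norm = 4), 0)
  }
})

test_that("optimizer handles degenerate objectives", {
  # all-positive matrix: any split strictly lowers Q, so one module
  set.seed(1)
  P <- matrix(runif(36, 0.1, 1), 6)
  P <- (P + t(P)) / 2
  p <- optimize_partition(P, seed = 1, n_restarts = 5)
  expect_equal(p$n_modules, 1)

  # zero matrix: single non-significant module
  z <- optimize_partition(matrix(0, 5, 5), seed = 1)
  expect_equal(z$n_modules, 1)
  expect_false(z$significant)
})

test_that("optimizer attains the brute-force optimum on small filtered matrices", {
  for (i in 1:10) {
    n <- sample(4:8, 1)
    B <- random_filtered_matrix(n, rank = sample(1:2, 1), seed = 100 + i)
    p <- optimize_partition(B, seed = i, n_restarts = 20, c_norm = n)
    expect_equal(p$modularity, brute_force_best(B, c_norm = n)$q,
                 tolerance = 1e-10)
  }
})

test_that("returned partitions are permutation-equivariant and dominate trivial ones", {
  gen <- small_benchmark(seed = 11)
  res <- detect_signature(gen$recording, seed = 5, n_restarts = 20)
  mm <- res$modularity
  p <- res$partition

  expect_gte(p$modularity, modularity_score(mm, rep(1, nrow(mm$B))))
  expect_gte(p$modularity, modularity_score(mm, seq_len(nrow(mm$B))))

  set.seed(3)
  perm <- sample(nrow(mm$B))
  Bp <- mm$B[perm, perm]
  pp <- optimize_partition(Bp, seed = 5, n_restarts = 20, c_norm = mm$c_norm)
  expect_equal(adjusted_rand_index(pp$labels, p$labels[perm]), 1)
})

test_that("sign contrast holds: positive within-module, non-positive between-module sums", {
  for (amp in c(0, 15)) {
    gen <- small_benchmark(seed = 13, trend_amplitude = amp)
    res <- detect_signature(gen$recording, seed = 2, n_restarts = 20)
    B <- res$modularity$B
    lab <- res$partition$labels
    for (m in unique(lab)) {
      idx <- lab == m
      if (sum(idx) > 1) expect_gt(sum(B[idx, idx]), 0)
    }
    mods <- unique(lab)
    for (a in mods) for (b in mods) {
      if (a < b) expect_lte(sum(B[lab == a, lab == b]), 0)
    }
  }
})

test_that("co-classification frequencies behave as an ensemble likelihood", {
  gen <- small_benchmark(seed = 17)
  res <- detect_signature(gen$recording, seed = 5, n_restarts = 5)

  one <- co_classification(res$modularity, n_runs = 1, base_seed = 3)
  expect_true(all(one$F %in% c(0, 1)))
  expect_equal(diag(one$F), rep(1, nrow(one$F)), ignore_attr = TRUE)

  cc <- co_classification(res$modularity, n_runs = 20, base_seed = 3)
  expect_true(all(cc$F >= 0 & cc$F <= 1))
  expect_lt(max(abs(cc$F - t(cc$F))), 1e-12)
  same <- outer(gen$truth$labels, gen$truth$labels, "==")
  diag(same) <- NA
  expect_gt(mean(cc$F[which(same)]), 0.95)
  expect_lt(mean(cc$F[which(!same)]), 0.05)
})

test_that("consensus fixes binary block matrices and resolves the benchmark", {
  # binary block co-classification is a fixed point
  F <- matrix(0, 6, 6)
  F[1:3, 1:3] <- 1; F[4:6, 4:6] <- 1
  cp <- consensus_partition(F, seed = 2)
  expect_equal(adjusted_rand_index(cp$labels, c(1, 1, 1, 2, 2, 2)), 1)

  # all-ones matrix collapses to a single module
  expect_equal(consensus_partition(matrix(1, 5, 5), seed = 2)$n_modules, 1)

  # end-to-end: consensus over the benchmark ensemble equals the planted split
  gen <- small_benchmark(seed = 19)
  res <- detect_signature(gen$recording, seed = 5, n_restarts = 5)
  cc <- co_classification(res$modularity, n_runs = 30, base_seed = 7)
  cons <- consensus_partition(cc, seed = 11)
  expect_equal(adjusted_rand_index(cons$labels, gen$truth$labels), 1)
})

test_that("hierarchy recursion resolves nested structure and stops on noise", {
  gen <- nested_benchmark(seed = 23)
  h <- detect_hierarchy(gen$recording, max_depth = 2, seed = 4,
                        n_restarts = 20)
  expect_equal(h$partition$n_modules, 2)
  expect_equal(adjusted_rand_index(h$partition$labels, gen$truth$labels), 1)
  lv <- tidy(h)
  expect_true("level_2" %in% names(lv))
  expect_equal(adjusted_rand_index(lv$level_2, gen$truth$sub_labels), 1)

  # depth 1 is the flat pipeline
  flat <- detect_signature(gen$recording, seed = fan_seed(4, 1),
                           n_restarts = 20)
  h1 <- detect_hierarchy(gen$recording, max_depth = 1, seed = 4,
                         n_restarts = 20)
  expect_identical(h1$partition$labels, flat$partition$labels)
  expect_length(h1$children, 0)

  # pure noise: root not significant, no children
  hn <- detect_hierarchy(generate_pure_noise(40, 400, seed = 1),
                         max_depth = 2, seed = 4, n_restarts = 5)
  expect_false(hn$partition$significant)
  expect_length(hn$children, 0)
})
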