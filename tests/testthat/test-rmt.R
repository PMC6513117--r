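test_that("spectral decomposition matches closed forms and reconstructs", {
  eye <- spectral_decompose(diag(4))
  expect_equal(eye$values, rep(1, 4))

  for (c in c(-0.7, 0.2, 0.9)) {
    two <- spectral_decompose(matrix(c(1, c, c, 1), 2))
    expect_equal(two$values, c(1 + abs(c), 1 - abs(c)), tolerance = 1e-12)
  }

  set.seed(5)
  X <- matrix(rnorm(5 * 60), 5)
  C <- cor(t(X))
  e <- spectral_decompose(C)
  recon <- e$vectors %*% (e$values * t(e$vectors))
  expect_lt(max(abs(recon - C)), 1e-10)
  expect_equal(sum(e$values), 5, tolerance = 1e-8)           # trace
  expect_lt(max(abs(crossprod(e$vectors) - diag(5))), 1e-8)  # orthonormal
  # sign convention: largest-magnitude component of each eigenvector positive
  for (k in 1:5) expect_gt(e$vectors[which.max(abs(e$vectors[, k])), k], 0)

  asym <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(spectral_decompose(asym), "symmetric")
})

test_that("Wishart bounds follow the Marchenko-Pastur closed form", {
  b <- wishart_bounds(100, 400)
  expect_equal(b$lambda_plus, 2.25)
  expect_equal(b$lambda_minus, 0.25)
  expect_equal(b$Q, 4)
  expect_false(b$corrected)

  big <- wishart_bounds(10, 1e8)
  expect_equal(big$lambda_plus, 1, tolerance = 1e-3)
  expect_equal(big$lambda_minus, 1, tolerance = 1e-3)

  expect_warning(sq <- wishart_bounds(50, 50), "rank-deficient")
  expect_equal(sq$lambda_minus, 0)
  expect_equal(sq$lambda_plus, 4)
  expect_error(wishart_bounds(0, 10), "positive")
})

test_that("global-mode correction shifts the bulk as the closed form dictates", {
  expect_equal(corrected_bounds(100, 400, 0)$lambda_plus,
               wishart_bounds(100, 400)$lambda_plus)
  b <- corrected_bounds(100, 400, 50)
  expect_equal(b$lambda_plus, 1.125)
  expect_equal(b$lambda_minus, 0.125)
  expect_true(b$corrected)

  # strictly decreasing and affine in lambda_max with slope -(1+1/sqrt(Q))^2/N
  lp <- vapply(seq(0, 90, by = 10),
               function(l) corrected_bounds(100, 400, l)$lambda_plus, 1)
  expect_true(all(diff(lp) < 0))
  slopes <- diff(lp) / 10
  expect_equal(slopes, rep(-2.25 / 100, length(slopes)), tolerance = 1e-12)

  expect_error(corrected_bounds(100, 400, 100), "lambda_max")
})

test_that("the null density has compact support and unit bulk mass", {
  b <- corrected_bounds(100, 1000, 40)
  expect_equal(null_density(b, c(b$lambda_minus - 1e-6, b$lambda_plus + 1e-6,
                                 -1, 0)),
               rep(0, 4))
  mass <- integrate(function(x) null_density(b, x),
                    b$lambda_minus, b$lambda_plus,
                    subdivisions = 2000, rel.tol = 1e-9)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  # ... consistent (to order 1/N) with a bulk carrying all but the global mode
  expect_lte(abs(mass - (b$N - 1) / b$N), 1 / b$N + 1e-9)
})

test_that("eigenvalue classification follows the bounds variant", {
  # constructed spectrum {4, 1.2, 1, ...} against lambda+ = 2
  C <- diag(6)
  e <- spectral_decompose(C)
  e$values <- c(4, 1.2, rep((6 - 5.2) / 4, 4))

  unc <- new_bounds_for_test(lambda_minus = 0.25, lambda_plus = 2,
                             lambda_max = 0, Q = 4, N = 6, T = 24,
                             corrected = FALSE)
  cls <- classify_eigenvalues(e, unc)
  expect_equal(cls$global, integer(0))
  expect_equal(cls$structural, 1L)  # only lambda = 4 exceeds the edge

  cor <- new_bounds_for_test(lambda_minus = 0.1, lambda_plus = 1.1,
                             lambda_max = 4, Q = 4, N = 6, T = 24,
                             corrected = TRUE)
  cls2 <- classify_eigenvalues(e, cor)
  expect_equal(cls2$global, 1L)
  expect_equal(cls2$structural, 2L)  # 1.2 in (1.1, 4); the rest random
  expect_setequal(c(cls2$global, cls2$structural, cls2$random), 1:6)

  # an eigenvalue exactly at the edge counts as random
  cor2 <- new_bounds_for_test(lambda_minus = 0.1, lambda_plus = 1.2,
                              lambda_max = 4, Q = 4, N = 6, T = 24,
                              corrected = TRUE)
  expect_equal(classify_eigenvalues(e, cor2)$structural, integer(0))
})

test_that("the strong-trend benchmark yields exactly 2 structural eigenvalues and sign blocks", {
  gen <- full_benchmark(seed = 6, trend_amplitude = 15)
  res <- detect_signature(gen$recording, seed = 1, n_restarts = 5)
  expect_true(res$global_mode)
  expect_length(res$classification$structural, 2)

  B <- res$filtered$C_filtered
  same <- outer(gen$truth$labels, gen$truth$labels, "==")
  diag(same) <- NA
  expect_gt(mean(B[which(same)]), 0)
  expect_lt(mean(B[which(!same)]), 0)
})

test_that("filtering reconstructs the matrix and honors degenerate index sets", {
  gen <- small_benchmark(seed = 8, n_per_group = 6, T = 90)
  C <- pearson_correlation(gen$recording)
  e <- spectral_decompose(C)
  b <- wishart_bounds(C$n_units, C$n_timepoints)
  cls <- classify_eigenvalues(e, b)
  f <- filter_matrix(e, cls)
  expect_lt(max(abs(f$C_filtered + f$C_global + f$C_random - C$values)), 1e-8)
  expect_equal(sum(diag(f$C_filtered)), sum(e$values[cls$structural]),
               tolerance = 1e-8)
  expect_equal(qr(f$C_filtered)$rank, length(cls$structural))

  # empty structural set -> zero matrix; all structural -> original matrix
  none <- structure(list(global = integer(0), structural = integer(0),
                         random = seq_len(C$n_units), n = C$n_units),
                    class = "eigen_classification")
  expect_equal(filter_matrix(e, none)$C_filtered,
               matrix(0, C$n_units, C$n_units), ignore_attr = TRUE)
  all_s <- structure(list(global = integer(0), structural = seq_len(C$n_units),
                          random = integer(0), n = C$n_units),
                     class = "eigen_classification")
  expect_lt(max(abs(filter_matrix(e, all_s)$C_filtered - C$values)), 1e-10)
})

test_that("the global-mode detector separates trend from contrast spectra", {
  with_trend <- small_benchmark(seed = 2, trend_amplitude = 15)
  expect_true(detect_global_mode(
    spectral_decompose(pearson_correlation(with_trend$recording))))
  without <- small_benchmark(seed = 2, trend_amplitude = 0)
  expect_false(detect_global_mode(
    spectral_decompose(pearson_correlation(without$recording))))
  noise <- generate_pure_noise(40, 400, seed = 2)
  expect_false(detect_global_mode(
    spectral_decompose(pearson_correlation(noise))))
})
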