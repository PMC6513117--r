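test_that("seeded generation is bit-reproducible and seed-sensitive", {
  cfg <- synth_config(group_sizes = c(5, 5, 5), n_timepoints = 40, seed = 7)
  a <- generate_grouped_oscillators(cfg)
  b <- generate_grouped_oscillators(cfg)
  expect_identical(a$recording$values, b$recording$values)
  cfg2 <- synth_config(group_sizes = c(5, 5, 5), n_timepoints = 40, seed = 8)
  expect_false(identical(a$recording$values,
                         generate_grouped_oscillators(cfg2)$recording$values))

  n1 <- generate_pure_noise(4, 12, seed = 3)
  n2 <- generate_pure_noise(4, 12, seed = 3)
  expect_identical(n1$values, n2$values)
})

test_that("the benchmark config produces 3 groups of 100 units", {
  gen <- full_benchmark(seed = 2)
  expect_equal(dim(gen$recording$values), c(300, 500))
  expect_equal(as.vector(table(gen$truth$labels)), c(100, 100, 100))
})

test_that("degenerate configs behave as closed forms dictate", {
  # identical noise-free oscillators correlate perfectly
  cfg <- synth_config(n_groups = 1, group_sizes = 6, n_timepoints = 50,
                      base_period = 25, phase_spread = 0, noise_sd = 0,
                      seed = 1)
  gen <- generate_grouped_oscillators(cfg)
  C <- pearson_correlation(gen$recording)
  expect_true(all(abs(C$values - 1) < 1e-12))

  # amplitude heterogeneity leaves Pearson correlations untouched
  cfg_amp <- synth_config(n_groups = 1, group_sizes = 6, n_timepoints = 50,
                          base_period = 25, phase_spread = 0, noise_sd = 0,
                          seed = 1, amplitudes = seq(0.5, 3, length.out = 6))
  C_amp <- pearson_correlation(generate_grouped_oscillators(cfg_amp)$recording)
  expect_equal(C_amp$values, C$values, tolerance = 1e-12)
})

test_that("phase opposition gives negative, a strong trend all-positive correlations", {
  anti <- generate_grouped_oscillators(synth_config(
    n_groups = 2, group_sizes = c(10, 10), n_timepoints = 200,
    base_period = 50, group_phase_offsets = c(0, pi), seed = 4))
  C <- pearson_correlation(anti$recording)$values
  between <- C[anti$truth$labels == 1, anti$truth$labels == 2]
  expect_true(all(between < 0))

  trended <- small_benchmark(seed = 4, trend_amplitude = 15)
  Ct <- pearson_correlation(trended$recording)$values
  expect_true(all(Ct[upper.tri(Ct)] > 0))
})

test_that("invalid configurations are rejected and T <= N warns", {
  expect_error(synth_config(n_groups = 2, group_sizes = c(3, 0)), "positive")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(group_phase_offsets = c(0, 1)), "length")
  expect_warning(
    generate_grouped_oscillators(synth_config(group_sizes = c(10, 10, 10),
                                              n_timepoints = 20, seed = 1)),
    "Q <= 1")
})

test_that("pure-noise spectra match the Marchenko-Pastur law (KS < 0.05 at N=200, T=2000)", {
  rec <- generate_pure_noise(200, 2000, seed = 42)
  lam <- spectral_decompose(pearson_correlation(rec))$values
  b <- wishart_bounds(200, 2000)
  grid <- seq(b$lambda_minus, b$lambda_plus, length.out = 2000)
  dens <- null_density(b, grid)
  cdf <- cumsum(dens) * diff(grid[1:2])
  cdf <- cdf / max(cdf)
  emp <- ecdf(lam)
  ks <- max(abs(emp(grid) - cdf))
  expect_lt(ks, 0.05)
})

test_that("nested generation degenerates to the flat generator and validates inputs", {
  cfg <- synth_config(n_groups = 2, group_sizes = c(8, 8), n_timepoints = 60,
                      base_period = 30, group_phase_offsets = c(0, pi), seed = 5)
  flat <- generate_grouped_oscillators(cfg)
  nest0 <- generate_nested_groups(cfg, sub_phase_spread = 0)
  expect_identical(nest0$recording$values, flat$recording$values)

  nest <- generate_nested_groups(cfg, sub_phase_spread = pi / 4)
  expect_equal(sort(unique(nest$truth$sub_labels)), 1:4)
  expect_true(all(tapply(nest$truth$sub_labels, nest$truth$labels,
                         function(x) length(unique(x))) == 2))
  expect_error(generate_nested_groups(cfg, sub_phase_spread = pi),
               "separation")
})

test_that("fixtures round-trip through the text interfaces", {
  gen <- small_benchmark(seed = 9, n_per_group = 4, T = 30)
  dir <- withr::local_tempdir()
  write_recording(gen$recording, file.path(dir, "rec.csv"))
  back <- load_recording(file.path(dir, "rec.csv"))
  expect_equal(back$values, gen$recording$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  write_ground_truth(gen$truth, dir)
  gt <- readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                        show_col_types = FALSE)
  expect_equal(gt$group_id, gen$truth$labels)
})
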