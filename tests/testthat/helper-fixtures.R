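# Shared small fixtures, generated in code at test time.

# Down-scaled planted benchmark: 3 groups, same geometry as the full
# benchmark but fewer units/samples so unit tests stay fast.
small_benchmark <- function(seed = 1, trend_amplitude = 0, n_per_group = 20,
                            T = 200) {
  generate_grouped_oscillators(synth_config(
    group_sizes = rep(n_per_group, 3), n_timepoints = T,
    base_period = 50, trend_period = 120,
    trend_amplitude = trend_amplitude, seed = seed))
}

# Full-size benchmark at the standard study conditions.
full_benchmark <- function(seed = 1, trend_amplitude = 0) {
  generate_grouped_oscillators(synth_config(trend_amplitude = trend_amplitude,
                                            seed = seed))
}

# Nested two-level fixture: 2 antiphase super-groups, each split into two
# sub-groups a quarter-cycle apart.
nested_benchmark <- function(seed = 1) {
  generate_nested_groups(
    synth_config(n_groups = 2, group_sizes = c(100, 100),
                 group_phase_offsets = c(0, pi), phase_spread = pi / 12,
                 seed = seed),
    sub_phase_spread = pi / 4)
}

# Two-block toy modularity matrix: +0.5 within blocks {1,2} and {3,4}
# (diagonal included), -0.5 between.
toy_block_matrix <- function() {
  B <- matrix(-0.5, 4, 4)
  B[1:2, 1:2] <- 0.5
  B[3:4, 3:4] <- 0.5
  B
}

# Hand-built bounds object for classification tests with constructed spectra.
new_bounds_for_test <- function(lambda_minus, lambda_plus, lambda_max,
                                Q, N, T, corrected) {
  structure(list(lambda_minus = lambda_minus, lambda_plus = lambda_plus,
                 lambda_max = lambda_max, Q = Q, N = as.integer(N),
                 T = as.integer(T), corrected = corrected),
            class = "rmt_bounds")
}
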