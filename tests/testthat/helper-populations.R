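# Shared fixtures, built in code.

# moments tibble constructed directly (no sampling) for closed-form checks
make_moments <- function(n = c(100, 100),
                         mean_x = 0, mean_y = 0,
                         sd_x = c(1, 1), sd_y = c(1, 1), r = c(0.3, 0.3)) {
  k <- length(n)
  tibble::tibble(group = as.character(seq_len(k)), n = n,
                 mean_x = rep_len(mean_x, k), mean_y = rep_len(mean_y, k),
                 sd_x = rep_len(sd_x, k), sd_y = rep_len(sd_y, k),
                 r = rep_len(r, k))
}

# two-group dataset from a scenario, as raw data
draw_groups <- function(scenario, seed) {
  sample_scenario(scenario, seed = seed)
}

expect_within <- function(object, target, tol) {
  expect_lt(abs(object - target), tol)
}
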