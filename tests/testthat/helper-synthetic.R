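# shared fixtures, built in code

# small ground truth for fast end-to-end runs
quick_gt <- function(seed = 1, n_trials = 80, ...) {
  ground_truth(n_trials = n_trials, seed = seed, ...)
}

# a flat trace with given events, for preprocessing unit tests
flat_trace <- function(value = 100, dur_s = 60, fs = 50, ...) {
  pupil_trace(rep(value, dur_s * fs), fs, ...)
}

# simulate one subject's trials from two dc conditions (all else shared)
two_bin_trials <- function(dc_low, dc_high, n_per_bin, seed,
                           base = ddm_params(a = 1.4, z = 0.5, v = 0.9,
                                             dc = 0, t0 = 0.3, sv = 0),
                           dt = 1e-3) {
  stim <- c(rep(1, n_per_bin / 2), rep(-1, n_per_bin / 2))
  p_lo <- base; p_lo$dc <- dc_low
  p_hi <- base; p_hi$dc <- dc_high
  lo <- simulate_ddm(p_lo, stim, n = n_per_bin, dt = dt, seed = seed)
  hi <- simulate_ddm(p_hi, stim, n = n_per_bin, dt = dt, seed = seed + 50000)
  list(trials = rbind(lo, hi),
       bins = rep(c("low", "high"), each = n_per_bin))
}

# pure-noise pattern set with random labels
noise_patterns <- function(n = 100, nv = 100, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * nv), n, nv)
  half <- nv / 2
  vm <- data.frame(x = c(-(1:half), 1:half) * 3, y = 0, z = 0,
                   hemisphere = rep(c("L", "R"), each = half),
                   partner = c(seq_len(half) + half, seq_len(half)))
  labels <- data.frame(stimulus = sample(c(1, -1), n, replace = TRUE),
                       choice = sample(c(1, 0), n, replace = TRUE),
                       block_orientation = sample(c("CW", "CCW"), n,
                                                  replace = TRUE))
  pattern_set(X, vm, labels)
}
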