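test_that("SDT metrics match the inverse-normal oracle", {
  # H = F = 0.5: no sensitivity, no bias
  s0 <- sdt_metrics(5, 5, 5, 5)
  expect_equal(s0$dprime, 0)
  expect_equal(s0$criterion, 0)

  # H = 0.8, F = 0.3: z(0.8) = 0.8416, z(0.3) = -0.5244
  s <- sdt_metrics(8, 2, 3, 7)
  expect_equal(s$dprime, qnorm(0.8) - qnorm(0.3), tolerance = 1e-12)
  expect_equal(s$dprime, 1.366, tolerance = 1e-3)
  expect_equal(s$criterion, -(qnorm(0.8) + qnorm(0.3)) / 2, tolerance = 1e-12)
  expect_equal(s$criterion, -0.1586, tolerance = 1e-3)

  # swapping hits<->misses and fas<->crs negates d'
  s_sw <- sdt_metrics(2, 8, 7, 3)
  expect_equal(s_sw$dprime, -s$dprime)

  # edge rates are corrected, not infinite
  se <- sdt_metrics(10, 0, 0, 10)
  expect_true(is.finite(se$dprime) && se$dprime > 0)

  expect_error(sdt_metrics(0, 0, 3, 7), "signal")
  expect_error(sdt_metrics(5, 5, 0, 0), "noise")
})

test_that("SDT metrics recover a simulated equal-variance Gaussian observer", {
  set.seed(3)
  n <- 4e4
  dp_true <- 1.2; c_true <- 0.4
  # evidence ~ N(+-dp/2, 1), respond yes above criterion c
  stim <- sample(c(1, -1), n, replace = TRUE)
  ev <- rnorm(n, mean = stim * dp_true / 2)
  yes <- ev > c_true
  s <- sdt_metrics(sum(stim == 1 & yes), sum(stim == 1 & !yes),
                   sum(stim == -1 & yes), sum(stim == -1 & !yes))
  expect_lt(abs(s$dprime - dp_true), 0.05)
  expect_lt(abs(s$criterion - c_true), 0.05)
})

test_that("balanced fraction of yes is unbiased and seed-stable", {
  set.seed(4)
  n <- 800
  trials <- data.frame(stimulus = sample(c(1, -1), n, replace = TRUE),
                       choice = rbinom(n, 1, 0.7))
  bins <- factor(sample(c("low", "high"), n, replace = TRUE))
  f <- balanced_fraction_yes(trials, bins, n_resamples = 300, seed = 9)
  expect_lt(max(abs(f - 0.7)), 0.05)
  expect_identical(f, balanced_fraction_yes(trials, bins,
                                            n_resamples = 300, seed = 9))

  # already balanced cells: equals the plain fraction per bin
  tb <- data.frame(stimulus = rep(c(1, -1), each = 100),
                   choice = rep(c(1, 0, 1, 1), 50))
  bb <- factor(rep(c("a", "b"), 100))
  fb <- balanced_fraction_yes(tb, bb, n_resamples = 10, seed = 1)
  plain <- tapply(tb$choice, bb, mean)
  expect_equal(as.numeric(fb), as.numeric(plain[names(fb)]))
})

test_that("balancing makes the index invariant to duplicating the majority stimulus class", {
  set.seed(5)
  n <- 400
  trials <- data.frame(stimulus = sample(c(1, -1), n, replace = TRUE),
                       choice = rbinom(n, 1, 0.6))
  bins <- factor(sample(c("low", "high"), n, replace = TRUE))
  f1 <- balanced_fraction_yes(trials, bins, n_resamples = 400, seed = 2)
  dup <- which(trials$stimulus == 1)
  trials2 <- rbind(trials, trials[dup, ])
  bins2 <- factor(c(as.character(bins), as.character(bins[dup])))
  f2 <- balanced_fraction_yes(trials2, bins2, n_resamples = 400, seed = 2)
  expect_lt(max(abs(f1 - f2)), 0.04)   # Monte-Carlo tolerance
})

test_that("non-preferred fraction uses the overall bias with a documented tie-break", {
  trials <- data.frame(stimulus = rep(c(1, -1), 50),
                       choice = rep(c(1, 1, 1, 0, 0), 20))  # 60% 'yes'
  bins <- factor(rep(c("low", "high"), each = 50))
  f <- nonpreferred_fraction(trials, bins, n_resamples = 50, seed = 1)
  expect_equal(attr(f, "preferred"), 1)
  expect_true(all(f < 0.5))

  # exact 50/50: tie resolved toward 'yes'
  t2 <- data.frame(stimulus = rep(c(1, -1), 10), choice = rep(c(1, 0), 10))
  f2 <- nonpreferred_fraction(t2, factor(rep("a", 20)),
                              n_resamples = 10, seed = 1)
  expect_equal(attr(f2, "preferred"), 1)
})

test_that("absolute criterion is invariant to relabeling the choice options", {
  set.seed(6)
  n <- 400
  trials <- data.frame(stimulus = sample(c(1, -1), n, replace = TRUE),
                       choice = rbinom(n, 1, 0.4))
  bins <- factor(sample(c("low", "mid", "high"), n, replace = TRUE),
                 levels = c("low", "mid", "high"))
  a1 <- abs_criterion(trials, bins)
  flipped <- data.frame(stimulus = -trials$stimulus,
                        choice = 1 - trials$choice)
  a2 <- abs_criterion(flipped, bins)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("sequential polynomial regression selects the generating order", {
  y_const <- matrix(2, nrow = 6, ncol = 5)
  expect_equal(sequential_poly_regression(y_const)$selected_order, 0)

  set.seed(7)
  lin <- t(replicate(8, 2 * (1:5) + rnorm(5, sd = 1e-8)))
  r1 <- sequential_poly_regression(lin)
  expect_equal(r1$selected_order, 1)
  expect_true(all(r1$subject_coefs[, "linear"] > 0))

  # inverted-U: order 2 selected in the vast majority of simulated cohorts
  hits <- mean(replicate(50, {
    yq <- t(replicate(10, -((1:5) - 3)^2 + rnorm(5, sd = 0.8)))
    sequential_poly_regression(yq)$selected_order == 2
  }))
  expect_gt(hits, 0.9)
})

test_that("sliding-window pupil-criterion correlation finds the coupling before choice", {
  # pronounced arousal-bias coupling so the 5-point bin correlation is stable
  gt <- quick_gt(seed = 12, n_trials = 400, noise_sd = 0.5,
                 ddm_low = ddm_params(a = 1.4, z = 0.5, v = 0.9, dc = -0.5,
                                      t0 = 0.3, sv = 0.3),
                 ddm_high = ddm_params(a = 1.4, z = 0.5, v = 0.9, dc = 0.1,
                                       t0 = 0.3, sv = 0.3),
                 pupil_betas = c(cue = 1, choice = 1, sustained_low = 1,
                                 sustained_high = 6))
  tt <- generate_trial_table(gt)
  pp <- preprocess_pupil(generate_pupil_trace(tt, gt))
  sw <- sliding_window_criterion(pp$trace, tt, t_start = -2, t_end = 2)
  expect_equal(nrow(sw), floor((2 - (-2) - 0.25) / 0.025) + 1)
  # arousal lowers criterion: negative correlation around the button press
  around <- sw$r[sw$time > -0.5 & sw$time < 1]
  expect_lt(mean(around, na.rm = TRUE), -0.3)

  # pupil unrelated to behavior: correlations hover near zero
  perm <- pp$trace
  set.seed(1)
  perm$samples <- sample(perm$samples)
  sw0 <- sliding_window_criterion(perm, tt, t_start = -1, t_end = 1)
  expect_lt(abs(mean(sw0$r, na.rm = TRUE)), 0.35)
})

test_that("paired permutation test matches exact enumeration and handles ties", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(paired_permutation_test(a, a), 1)

  set.seed(8)
  x <- rnorm(10) + 1.5
  p_exact <- paired_permutation_test(x, exact = TRUE)
  p_mc <- paired_permutation_test(x, n_perm = 20000, seed = 3)
  expect_lt(abs(p_exact - p_mc), 0.01)
  # large constant shift, tiny noise: p at the enumeration floor region
  d <- 5 + rnorm(12, sd = 1e-3)
  expect_lte(paired_permutation_test(d, exact = TRUE), 2 / 2^11)
  # seeded reproducibility
  expect_identical(paired_permutation_test(x, n_perm = 500, seed = 4),
                   paired_permutation_test(x, n_perm = 500, seed = 4))
})
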