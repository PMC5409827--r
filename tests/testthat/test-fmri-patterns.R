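test_that("scalar trial responses follow the window definition", {
  times <- seq(-2, 14, by = 2)
  flat <- matrix(0, 1, length(times))
  expect_equal(trial_scalar_response(flat, times), 0)

  box <- ifelse(times >= 2 & times <= 12, 3, 0)
  expect_equal(trial_scalar_response(box, times), 3)

  # injected response scaled by amplitude: scalar is monotone in amplitude
  hrf <- dgamma(times + 2, shape = 6, scale = 1)
  scal <- sapply(c(0.5, 1, 2), function(a)
    trial_scalar_response(a * hrf, times))
  expect_true(all(diff(scal) > 0))
})

test_that("voxel t-statistics match a hand-computed oracle on a toy set", {
  X <- matrix(c(1.2, 0.8, 1.0, -0.9, -1.1, -1.0,
                0.1, -0.2, 0.1, 0.2, -0.1, 0.0), nrow = 6)
  in_a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  t_oracle <- apply(X, 2, function(v) {
    a <- v[1:3]; b <- v[4:6]
    (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  })
  expect_equal(voxel_tstat(X, in_a), t_oracle, tolerance = 1e-12)
  # a voxel with a huge contrast ranks first
  expect_equal(which.max(abs(voxel_tstat(X, in_a))), 1L)
  # literal reading differs but is finite
  expect_true(all(is.finite(voxel_tstat(X, in_a, literal = TRUE))))
})

test_that("voxel selection takes the 50+50 rule with deterministic ties", {
  tv <- c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5)
  expect_equal(select_voxels(tv, 2, 2), c(1, 2, 9, 10))
  tied <- rep(0, 10)
  expect_identical(select_voxels(tied, 2, 2), select_voxels(tied, 2, 2))
})

test_that("template scores are +-1 for noiseless template patterns and chance for noise", {
  set.seed(21)
  nv <- 40
  templ <- rnorm(nv)
  n <- 40
  ch <- rep(c(1, 0), n / 2)
  X <- outer(ifelse(ch == 1, 1, -1), templ)
  ps <- pattern_set(X, data.frame(x = seq_len(nv), y = 0, z = 0,
                                  hemisphere = "L"),
                    labels = data.frame(stimulus = 1, choice = ch,
                                        block_orientation = "CW"))
  sc <- template_response(ps, mode = "choice")
  expect_equal(sc[ch == 1], rep(1, n / 2), tolerance = 1e-10)
  expect_equal(sc[ch == 0], rep(-1, n / 2), tolerance = 1e-10)

  # pure noise: symmetric about zero, stimulus-predictive index ~ 0.5
  np <- noise_patterns(n = 120, nv = 60, seed = 22)
  s_or <- template_response(np, mode = "orientation")
  idx <- roc_predictive_index(s_or, np$labels$stimulus == 1,
                              balance_by = np$labels$choice)
  expect_lt(abs(idx - 0.5), 0.15)
  expect_lt(abs(mean(s_or)), 0.1)
})

test_that("orientation scores grow with the generating pattern amplitude", {
  sep <- sapply(c(0.05, 0.15, 0.4), function(a) {
    gt <- quick_gt(seed = 23, n_trials = 160, orientation_amp = a,
                   choice_amp = 0)
    tt <- generate_trial_table(gt)
    pats <- generate_patterns(tt, gt)
    ok <- which(!is.na(tt$choice))
    sub <- pattern_set(pats$responses[ok, ], pats$voxel_meta,
                       pats$labels[ok, ])
    sc <- template_response(sub, mode = "orientation")
    mean(sc[sub$labels$stimulus == 1]) - mean(sc[sub$labels$stimulus == -1])
  })
  expect_true(all(diff(sep) > 0))
})

test_that("choice logistic regression has the right sign, scale equivariance and separation flag", {
  set.seed(24)
  n <- 200
  ch <- rep(c(1, 0), n / 2)
  a <- ifelse(ch == 1, 1, -1) + rnorm(n)
  f <- choice_logistic(a, ch)
  expect_gt(f$beta1, 0)
  expect_false(f$separation)

  # doubling the response scale halves the slope
  f2 <- choice_logistic(2 * a, ch)
  expect_equal(f2$beta1, f$beta1 / 2, tolerance = 1e-6)

  # response independent of choice: slope near zero
  f0 <- choice_logistic(rnorm(n), ch)
  expect_lt(abs(f0$beta1), 0.3)

  # perfectly separated responses are flagged
  fs <- choice_logistic(ifelse(ch == 1, 1, -1), ch)
  expect_true(fs$separation)

  # condition-wise averaging removes a stimulus confound
  stim <- rep(c(1, -1), each = n / 2)
  a_conf <- a + 2 * stim
  fc <- choice_logistic(a_conf, ch, stimulus = stim)
  expect_gt(fc$beta1, 0)
})

test_that("lateralization is an involution and cancels symmetric patterns", {
  np <- noise_patterns(n = 30, nv = 20, seed = 25)
  X <- np$responses
  p <- np$voxel_meta$partner
  # symmetric bilateral pattern: lateralization 0
  sym <- np
  sym$responses <- (X + X[, p]) / 2
  expect_equal(max(abs(lateralize(sym))), 0)
  # flip twice = identity
  flipped_once <- np
  flipped_once$responses <- X[, p]
  expect_equal(lateralize(flipped_once, flip = TRUE), lateralize(np))
  # mirror subjects with opposite mappings give identical lateralization
  mirror <- np
  mirror$responses <- X[, p]
  expect_equal(lateralize(mirror, flip = TRUE), lateralize(np))
})

test_that("searchlight finds an informative cluster and is chance for shuffled labels", {
  set.seed(26)
  n <- 80; nv <- 30
  vm <- data.frame(x = seq(0, by = 3, length.out = nv), y = 0, z = 0,
                   hemisphere = "L")
  ch <- rep(c(1, 0), n / 2)
  X <- matrix(rnorm(n * nv), n, nv)
  X[, 10:12] <- X[, 10:12] + outer(ifelse(ch == 1, 1.5, -1.5), rep(1, 3))
  ps <- pattern_set(X, vm, data.frame(stimulus = 1, choice = ch,
                                      block_orientation = "CW"))
  sl <- searchlight_choice(ps, radius_mm = 7)
  expect_true(which.max(sl) %in% 8:14)
  expect_gt(max(sl, na.rm = TRUE), 0.85)

  shuf <- ps
  shuf$labels$choice <- sample(ch)
  sl0 <- searchlight_choice(shuf, choices = shuf$labels$choice, radius_mm = 7)
  expect_lt(abs(mean(sl0, na.rm = TRUE) - 0.5), 0.12)
  # no randomness in the LOO scheme: identical re-runs
  expect_identical(sl, searchlight_choice(ps, radius_mm = 7))
})

test_that("ROC predictive index matches the rank-statistic oracle and balances conditions", {
  expect_equal(roc_predictive_index(c(1, 2, 3, 4, 5, 6),
                                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)), 1)
  expect_equal(roc_predictive_index(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  set.seed(27)
  sc <- rnorm(10); lb <- c(rep(TRUE, 4), rep(FALSE, 6))
  u <- wilcox.test(sc[lb], sc[!lb], exact = TRUE)$statistic
  expect_equal(roc_predictive_index(sc, lb), unname(u) / (4 * 6))

  # choice-driven scores with balanced computation: stimulus index at chance
  n <- 2000
  ch <- sample(c(1, 0), n, replace = TRUE)
  stim <- ifelse(runif(n) < 0.7, ch, 1 - ch)  # stimulus correlates with choice
  scores <- ifelse(ch == 1, 1, -1) + rnorm(n, sd = 0.1)
  raw <- roc_predictive_index(scores, stim == 1)
  bal <- roc_predictive_index(scores, stim == 1, balance_by = ch)
  expect_gt(raw, 0.6)            # confounded without balancing
  expect_lt(abs(bal - 0.5), 0.05)
})

test_that("combined signals behave like least-squares projections", {
  set.seed(28)
  n <- 500
  target <- rnorm(n)
  r1 <- target * 0.5 + rnorm(n)
  r_noise <- rnorm(n)
  R <- cbind(roi1 = r1, roi2 = r_noise)
  cs <- combine_signals(R, target, "linear")
  expect_equal(sd(cs$signal), 1, tolerance = 1e-9)
  # combination correlates at least as well as the best single ROI
  expect_gte(cor(cs$signal, target) + 1e-12,
             max(abs(cor(r1, target)), abs(cor(r_noise, target))))
  # single ROI: combined signal is that ROI z-scored (up to sign of weight)
  c1 <- combine_signals(R[, 1, drop = FALSE], target, "linear")
  expect_equal(c1$signal, as.numeric(scale(r1)), tolerance = 1e-9)
  # logistic variant runs and weights the informative ROI
  ch <- rbinom(n, 1, plogis(r1))
  cl <- combine_signals(R, ch, "logistic")
  expect_gt(abs(cl$weights[1]), abs(cl$weights[2]))
})

test_that("partial correlation isolates the uniquely coupled ROI", {
  gt <- quick_gt(seed = 29, n_trials = 400,
                 roi_tpr_couplings = c(LC = 0.5, SN = 0, VTA = 0, SC = 0))
  tt <- generate_trial_table(gt)
  set.seed(30)
  tpr <- rnorm(nrow(tt))
  roi <- generate_roi_responses(tt, tpr, gt)
  bs <- tpr_brainstem_correlation(roi, stimulus = tt$stimulus)
  expect_gt(bs$partial_r[bs$roi == "LC"], 0.2)
  # uncoupled ROIs: no positive partials (conditioning on the coupled ROI
  # induces a small negative partial in shared-factor ROIs)
  expect_lt(max(bs$partial_r[bs$roi != "LC"]), 0.1)
  expect_gt(bs$partial_r[bs$roi == "LC"],
            3 * max(abs(bs$partial_r[bs$roi != "LC"])))

  # zero coupling everywhere: raw correlations near zero
  gt0 <- quick_gt(seed = 31, n_trials = 320,
                  roi_tpr_couplings = c(LC = 0, SN = 0, SC = 0))
  tt0 <- generate_trial_table(gt0)
  roi0 <- generate_roi_responses(tt0, rnorm(nrow(tt0)), gt0)
  bs0 <- tpr_brainstem_correlation(roi0, stimulus = tt0$stimulus)
  expect_lt(max(abs(bs0$r)), 0.15)

  # shared factor only: raw r positive for all, pairwise structure constant
  gt1 <- quick_gt(seed = 32, n_trials = 400,
                  roi_tpr_couplings = c(LC = 0.4, SN = 0.4, SC = 0.4))
  tt1 <- generate_trial_table(gt1)
  roi1 <- generate_roi_responses(tt1, rnorm(nrow(tt1)), gt1)
  cm <- cor(roi1$responses)
  off <- cm[upper.tri(cm)]
  expect_lt(max(off) - min(off), 0.25)
  expect_true(all(off > 0.2))
})

test_that("partial correlations agree with the inverse-covariance identity", {
  gt <- quick_gt(seed = 33, n_trials = 320)
  tt <- generate_trial_table(gt)
  set.seed(34)
  tpr <- rnorm(nrow(tt))
  roi <- generate_roi_responses(tt, tpr, gt)
  roi$nuisance <- NULL
  bs <- tpr_brainstem_correlation(roi, stimulus = tt$stimulus)
  R <- apply(roi$responses, 2, residualize, covariate = tt$stimulus)
  tp <- residualize(tpr, tt$stimulus)
  for (i in seq_len(ncol(R))) {
    V <- cbind(tp, R[, i], R[, -i])
    P <- solve(cov(V))
    pr <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(bs$partial_r[i], pr, tolerance = 1e-10)
  }
})

test_that("binned linear fit recovers an arousal modulation and ignores stimulus leakage", {
  set.seed(35)
  n <- 2000
  tpr <- rnorm(n)
  stim <- sample(c(1, -1), n, replace = TRUE)
  ctx <- 0.5 * tpr + rnorm(n)
  b <- bin_linear_fit(ctx, tpr, stim)
  expect_lt(abs(b["beta1"] - 0.5), 0.1)
  # slope invariant to adding any multiple of the stimulus vector
  b2 <- bin_linear_fit(ctx + 3 * stim, tpr, stim)
  expect_equal(unname(b["beta1"]), unname(b2["beta1"]), tolerance = 1e-10)
  # unrelated signal: slope near zero
  b0 <- bin_linear_fit(rnorm(n), tpr, stim)
  expect_lt(abs(b0["beta1"]), 0.1)
})

test_that("brainstem ROI masks retain the highest-probability voxels with their weights", {
  set.seed(36)
  prob <- c(rep(0, 50), runif(50))
  m <- brainstem_roi_mask(prob, n_voxels = 12)
  expect_length(m$voxels, 12)
  expect_true(all(prob[m$voxels] >= sort(prob, decreasing = TRUE)[12]))
  expect_equal(m$weights, prob[m$voxels])
  # weighted ROI time series
  X <- matrix(rnorm(20 * 100), 20, 100)
  ts <- roi_weighted_mean(X, m)
  expect_equal(ts, as.numeric(X[, m$voxels] %*% (m$weights / sum(m$weights))))
  expect_error(brainstem_roi_mask(c(0.1, 0.2), 12), "fewer than")
})
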