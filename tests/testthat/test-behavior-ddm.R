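test_that("hitting probabilities match the closed form", {
  # symmetric diffusion: exactly 1/2
  p0 <- ddm_params(a = 1, z = 0.5, v = 0, dc = 0, t0 = 0.2)
  expect_equal(ddm_prob_yes(p0, 1), 0.5)

  # unit drift on [0, 1] from the middle: 0.731
  p1 <- ddm_params(a = 1, z = 0.5, v = 1, dc = 0, t0 = 0)
  expect_equal(ddm_prob_yes(p1, 1),
               (exp(-2 * 1 * 0.5) - 1) / (exp(-2 * 1) - 1), tolerance = 1e-12)
  expect_equal(ddm_prob_yes(p1, 1), 0.731, tolerance = 1e-3)

  # simulated choice fractions agree within binomial error
  s <- simulate_ddm(p1, 1, n = 4e4, dt = 1e-3, seed = 2)
  expect_lt(abs(mean(s$choice == 1, na.rm = TRUE) - 0.7310586), 0.01)
  s0 <- simulate_ddm(p0, 1, n = 4e4, dt = 1e-3, seed = 3)
  expect_lt(abs(mean(s0$choice == 1, na.rm = TRUE) - 0.5), 0.01)
})

test_that("first-passage density integrates to the choice probabilities and vanishes at infinity", {
  tg <- seq(0, 30, by = 2e-4)
  for (p in list(ddm_params(a = 1, z = 0.5, v = 1, dc = 0, t0 = 0),
                 ddm_params(a = 1.6, z = 0.35, v = 0.4, dc = -0.3, t0 = 0.3),
                 ddm_params(a = 1.2, z = 0.5, v = 0.8, dc = 0.2, t0 = 0.2,
                            sv = 0.6))) {
    dy <- ddm_fpt_density(tg, p, 1, 1)
    dn <- ddm_fpt_density(tg, p, 1, 0)
    total <- sum(dy + dn) * 2e-4
    expect_equal(total, 1, tolerance = 1e-5)
    expect_equal(sum(dy) * 2e-4, ddm_prob_yes(p, 1), tolerance = 1e-4)
    expect_lt(dy[length(tg)], 1e-10)
    # density is zero at and before the non-decision time
    expect_equal(ddm_fpt_density(c(0, p$t0 * 0.5, p$t0), p, 1, 1),
                 rep(0, 3))
  }
})

test_that("likelihood prefers the generating parameters on large samples", {
  p <- ddm_params(a = 1.4, z = 0.5, v = 0.9, dc = -0.2, t0 = 0.3, sv = 0)
  s <- simulate_ddm(p, rep(c(1, -1), each = 5000), dt = 1e-3, seed = 4)
  ll <- function(pp) {
    tot <- 0
    for (ch in c(0, 1)) for (st in c(-1, 1)) {
      idx <- which(s$choice == ch & s$stimulus == st)
      tot <- tot + sum(log(pmax(
        ddm_fpt_density(s$rt[idx], pp, st, ch), 1e-12)))
    }
    tot
  }
  ll_true <- ll(p)
  for (perturb in list(c("v", 1.15), c("dc", 0.05), c("a", 1.6),
                       c("z", 0.42))) {
    pp <- p
    pp[[perturb[1]]] <- as.numeric(perturb[2])
    expect_gt(ll_true, ll(pp))
  }
})

test_that("fitting identical data in both conditions yields matched parameters", {
  set.seed(5)
  sim <- simulate_ddm(ddm_params(a = 1.3, z = 0.5, v = 0.8, dc = -0.15,
                                 t0 = 0.3, sv = 0),
                      rep(c(1, -1), 600), dt = 1e-3, seed = 6)
  trials <- rbind(sim, sim)
  bins <- rep(c("low", "high"), each = nrow(sim))
  fit <- fit_ddm(trials, bins, free = c("v", "dc"),
                 shared = c("a", "z", "t0"), fixed = list(sv = 0, c = 1),
                 n_starts = 2, seed = 1)
  d <- fit$params
  expect_lt(abs(diff(d$dc)), 0.02)
  expect_lt(abs(diff(d$v)), 0.02)
})

test_that("drift-criterion differences are recovered with the default free set", {
  tb <- two_bin_trials(-0.3, -0.05, n_per_bin = 1500, seed = 101)
  fit <- fit_ddm(tb$trials, tb$bins, n_starts = 3, seed = 2)
  d <- fit$params
  ddc <- d$dc[d$bin == "high"] - d$dc[d$bin == "low"]
  expect_gt(ddc, 0.05)
  expect_lt(abs(d$v[1] - 0.9), 0.25)
  expect_lt(abs(d$a[1] - 1.4), 0.25)
  expect_true(fit$converged)
})

test_that("information criteria identify a drift-criterion bias over a starting-point account", {
  wins <- sapply(1:5, function(r) {
    tb <- two_bin_trials(-0.35, 0, n_per_bin = 900, seed = 200 + r)
    f_dc <- fit_ddm(tb$trials, tb$bins, free = "dc",
                    shared = c("a", "v", "z", "t0"),
                    fixed = list(sv = 0, c = 1), n_starts = 2, seed = r)
    f_z <- fit_ddm(tb$trials, tb$bins, free = "z",
                   shared = c("a", "v", "t0"),
                   fixed = list(dc = 0, sv = 0, c = 1), n_starts = 2, seed = r)
    f_dc$bic < f_z$bic
  })
  expect_gte(sum(wins), 4)
})

test_that("matched-bias mode-shift diagnostic separates the two bias mechanisms", {
  base <- ddm_params(a = 1.4, z = 0.5, v = 0.9, dc = 0, t0 = 0.3, sv = 0)
  target <- 0.62
  p_dc <- match_bias(base, target, "dc")
  p_z <- match_bias(base, target, "z")
  expect_equal(mean(c(ddm_prob_yes(p_dc, 1), ddm_prob_yes(p_dc, -1))),
               target, tolerance = 1e-3)
  expect_equal(mean(c(ddm_prob_yes(p_z, 1), ddm_prob_yes(p_z, -1))),
               target, tolerance = 1e-3)
  ms <- mode_shift_diagnostic(p_z, p_dc, base)
  # starting-point bias moves the RT modes far more than drift-criterion bias
  expect_gt(ms$shift_z, 3 * ms$shift_dc)
  # drift-criterion bias: negligible effect on the mode (< 5% of the mode)
  base_modes <- ms$modes$mode[ms$modes$model == "base"]
  expect_lt(ms$shift_dc, 0.05 * mean(base_modes))
})

test_that("regression DDM reduces to the stimulus-coded model for null covariates", {
  set.seed(9)
  n <- 1200
  S <- sample(c(1, -1), n, replace = TRUE)
  p <- ddm_params(a = 1.4, z = 0.5, v = 0.9, dc = 0.1, t0 = 0.3, sv = 0)
  s <- simulate_ddm(p, S, dt = 1e-3, seed = 10)
  f0 <- fit_regression_ddm(s, M = rep(0, n), C = rep(0, n),
                           n_starts = 2, seed = 1)
  fit_plain <- fit_ddm(s, free = c("v", "dc"), shared = c("a", "z", "t0"),
                       fixed = list(sv = 0, c = 1), n_starts = 2, seed = 1)
  expect_equal(unname(f0$betas["beta0"]), fit_plain$params$dc,
               tolerance = 0.05)
  expect_equal(unname(f0$betas["beta1"]), fit_plain$params$v,
               tolerance = 0.05)
})

test_that("regression DDM recovers a trial-wise drift modulation and nulls a permuted one", {
  set.seed(11)
  n <- 1500
  S <- sample(c(1, -1), n, replace = TRUE)
  M <- rnorm(n)
  v <- 0.1 + 0.9 * S + 0.25 * M
  s <- arousalbias:::.ddm_simulate_cpp(n, v, 1.4, 0.5, 0.3, 1, 0, 1e-3, 10)
  trials <- data.frame(rt = s$rt, choice = s$choice, stimulus = S)
  f <- fit_regression_ddm(trials, M, C = rnorm(n), n_starts = 2, seed = 2)
  expect_lt(abs(f$betas["beta2"] - 0.25), 0.12)
  expect_lt(abs(f$betas["beta3"]), 0.12)
  # permuted covariate: modulation estimate collapses toward zero
  set.seed(12)
  f_perm <- fit_regression_ddm(trials, sample(M), C = rep(0, n),
                               n_starts = 2, seed = 3)
  expect_lt(abs(f_perm$betas["beta2"]), 0.12)
})

test_that("simulator census: unabsorbed trials are flagged, bad steps rejected", {
  p <- ddm_params(a = 8, z = 0.5, v = 0, dc = 0, t0 = 0.3)
  s <- simulate_ddm(p, 1, n = 200, dt = 1e-3, t_max = 0.5, seed = 13)
  expect_gt(attr(s, "n_unabsorbed"), 0)
  expect_true(all(is.na(s$rt[is.na(s$choice)])))
  expect_error(simulate_ddm(p, 1, n = 10, dt = 0), "dt")
})
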