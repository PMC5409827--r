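#' Drift-diffusion model parameters
#'
#' Container for the parameters of a stimulus-coded drift-diffusion model
#' (DDM). The decision variable starts at `z * a` on the interval `[0, a]`
#' and evolves as `dy = (v * stimulus + dc) dt + c dW`; hitting `a` is a
#' 'yes', hitting 0 a 'no'. The response time is the hitting time plus the
#' non-decision time `t0`.
#'
#' @param a boundary separation (> 0).
#' @param z starting point as a fraction of `a` (in (0, 1)).
#' @param v mean drift rate; multiplied by the stimulus code (+1 signal,
#'   -1 noise).
#' @param dc drift criterion: an evidence-independent constant added to the
#'   drift, biasing accumulation toward one bound. Negative values bias
#'   toward 'no'.
#' @param t0 non-decision time in seconds (>= 0).
#' @param sv across-trial standard deviation of the drift (>= 0).
#' @param c diffusion noise scale. Fixed at 1 by convention; only ratios of
#'   the other parameters to `c` are identifiable.
#' @return An object of class `ddm_params` (a named list).
#' @export
ddm_params <- function(a = 1, z = 0.5, v = 1, dc = 0, t0 = 0.3, sv = 0, c = 1) {
  stopifnot(a > 0, z > 0, z < 1, t0 >= 0, sv >= 0, c > 0)
  structure(list(a = a, z = z, v = v, dc = dc, t0 = t0, sv = sv, c = c),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters: a =", format(x$a, digits = 3),
      " z =", format(x$z, digits = 3),
      " v =", format(x$v, digits = 3),
      " dc =", format(x$dc, digits = 3),
      " t0 =", format(x$t0, digits = 3),
      " sv =", format(x$sv, digits = 3),
      " c =", format(x$c, digits = 3), "\n")
  invisible(x)
}

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

.pkg_cache <- new.env(parent = emptyenv())
gh_cache <- function(n = 20) {
  key <- paste0("gh", n)
  gh <- get0(key, envir = .pkg_cache)
  if (is.null(gh)) {
    gh <- gauss_hermite(n)
    assign(key, gh, envir = .pkg_cache)
  }
  gh
}

#' Probability of a 'yes' choice under the DDM
#'
#' Closed-form probability that the diffusion hits the upper ('yes')
#' boundary: `P(yes) = (1 - exp(-2 mu z a / c^2)) / (1 - exp(-2 mu a / c^2))`
#' with effective drift `mu = v * stimulus + dc`, and `z` when `mu = 0`.
#' Across-trial drift variability (`sv > 0`) is handled by Gauss-Hermite
#' quadrature over the drift distribution.
#'
#' @param params a [ddm_params()] object.
#' @param stimulus stimulus code, +1 (signal) or -1 (noise); may be a vector.
#' @param gh_n number of Gauss-Hermite nodes used when `sv > 0`.
#' @return Numeric vector of hitting probabilities.
#' @export
ddm_prob_yes <- function(params, stimulus = 1, gh_n = 20) {
  p_up <- function(mu) {
    with(params, {
      x <- 2 * mu * a / c^2
      ifelse(abs(x) < 1e-10, z, (1 - exp(-x * z)) / (1 - exp(-x)))
    })
  }
  mu <- params$v * stimulus + params$dc
  if (params$sv <= 0) return(p_up(mu))
  gh <- gh_cache(gh_n)
  vapply(mu, function(m) {
    sum(gh$weights * p_up(m + sqrt(2) * params$sv * gh$nodes)) / sqrt(pi)
  }, numeric(1))
}

#' Simulate choices and response times from the DDM
#'
#' Euler-Maruyama simulation of the stimulus-coded diffusion. Per-trial drift
#' is drawn from `N(v * stimulus + dc, sv)`. Trials not absorbed within
#' `t_max` seconds are returned with `NA` choice/rt and counted.
#'
#' @param params a [ddm_params()] object.
#' @param stimulus stimulus code per trial (+1/-1); recycled to length `n`.
#' @param n number of trials.
#' @param dt Euler time step in seconds (> 0).
#' @param t_max absorption deadline in seconds.
#' @param seed optional integer seed.
#' @return A data.frame with columns `stimulus`, `choice` (1 'yes', 0 'no'),
#'   `rt` (seconds, includes `t0`). Attribute `n_unabsorbed` counts censored
#'   trials.
#' @export
simulate_ddm <- function(params, stimulus = 1, n = length(stimulus),
                         dt = 1e-4, t_max = 10, seed = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  stimulus <- rep_len(stimulus, n)
  mu <- params$v * stimulus + params$dc
  sim <- .ddm_simulate_cpp(n, mu, params$a, params$z, params$t0,
                           params$c, params$sv, dt, t_max)
  out <- data.frame(stimulus = stimulus, choice = sim$choice, rt = sim$rt)
  attr(out, "n_unabsorbed") <- sum(is.na(sim$choice))
  out
}

#' Analytic first-passage-time density of the DDM
#'
#' Exact density of the two-boundary constant-drift diffusion hitting the
#' boundary associated with `choice` at time `t` (measured from trial onset,
#' i.e. including `t0`), via the standard series expansion with the
#' small-time/large-time form chosen by a truncation-error bound. Drift
#' variability is integrated out by Gauss-Hermite quadrature.
#'
#' @param t time(s) in seconds; density is 0 for `t <= t0`.
#' @param params a [ddm_params()] object.
#' @param stimulus stimulus code (+1/-1), scalar.
#' @param choice 1 for 'yes' (upper boundary), 0 for 'no'.
#' @param err absolute truncation tolerance of the series.
#' @param gh_n Gauss-Hermite nodes for `sv > 0`.
#' @return Numeric vector of density values (per second).
#' @export
ddm_fpt_density <- function(t, params, stimulus = 1, choice = 1,
                            err = 1e-8, gh_n = 20) {
  stopifnot(length(stimulus) == 1, choice %in% c(0, 1))
  gh <- gh_cache(gh_n)
  mu <- params$v * stimulus + params$dc
  td <- t - params$t0
  out <- numeric(length(t))
  pos <- which(td > 0)
  if (length(pos)) {
    out[pos] <- .fpt_density_cpp(td[pos], mu, params$a, params$z, params$c,
                                 as.integer(choice), gh$nodes, gh$weights,
                                 params$sv, err)
  }
  out
}

# ---- fitting ---------------------------------------------------------------

.ddm_par_names <- c("a", "z", "v", "dc", "t0", "sv", "c")

# forward/backward transforms to an unconstrained scale
.ddm_tf <- list(
  a  = list(to = log,    from = exp),
  z  = list(to = stats::qlogis, from = stats::plogis),
  v  = list(to = identity, from = identity),
  dc = list(to = identity, from = identity),
  t0 = list(to = log,    from = exp),
  sv = list(to = function(x) log(pmax(x, 1e-4)), from = exp),
  c  = list(to = log,    from = exp)
)

.ddm_negll <- function(theta, layout, data, gh, err = 1e-6, floor_dens = 1e-12) {
  pars <- .ddm_unpack(theta, layout)
  ll <- 0
  for (b in seq_along(layout$bins)) {
    d <- data[[b]]
    p <- pars[[b]]
    if (p$t0 >= min(d$rt)) {
      # keep finite but strongly penalized so optimizers back off
      ll <- ll - 1e4 * (1 + p$t0 - min(d$rt)) * nrow(d)
      next
    }
    mu <- p$v * d$stimulus + p$dc
    ll <- ll + .ddm_loglik_cpp(d$rt, as.integer(d$choice), mu, p$a, p$z,
                               p$t0, p$c, gh$nodes, gh$weights, p$sv,
                               err, floor_dens)
  }
  if (!is.finite(ll)) ll <- -1e10
  -ll
}

.ddm_layout <- function(bins, free, shared, fixed) {
  stopifnot(all(free %in% .ddm_par_names), all(shared %in% .ddm_par_names))
  both <- intersect(free, shared)
  if (length(both)) stop("parameters cannot be both free and shared: ",
                         paste(both, collapse = ", "))
  covered <- c(free, shared, names(fixed))
  miss <- setdiff(.ddm_par_names, covered)
  if (length(miss)) stop("parameters neither free, shared, nor fixed: ",
                         paste(miss, collapse = ", "))
  list(bins = bins, free = free, shared = shared, fixed = fixed)
}

.ddm_pack <- function(start, layout) {
  th <- c()
  for (p in layout$free) for (b in layout$bins)
    th <- c(th, .ddm_tf[[p]]$to(start[[p]]))
  for (p in layout$shared) th <- c(th, .ddm_tf[[p]]$to(start[[p]]))
  th
}

.ddm_unpack <- function(theta, layout) {
  nb <- length(layout$bins)
  pars <- rep(list(layout$fixed), nb)
  i <- 0
  for (p in layout$free) for (b in seq_len(nb)) {
    i <- i + 1
    pars[[b]][[p]] <- .ddm_tf[[p]]$from(theta[i])
  }
  for (p in layout$shared) {
    i <- i + 1
    val <- .ddm_tf[[p]]$from(theta[i])
    for (b in seq_len(nb)) pars[[b]][[p]] <- val
  }
  pars
}

#' Fit the stimulus-coded DDM by maximum likelihood
#'
#' Fits the DDM to choices and response times using the full analytic
#' first-passage-time likelihood (not quantile summaries), with multi-start
#' optimization on transformed parameters. Trials may be partitioned into
#' conditions (e.g. low/high TPR bins); each parameter is either free per
#' condition, shared across conditions, or fixed. The default mirrors the
#' condition design used for phasic-arousal analyses: boundary separation,
#' non-decision time, drift rate, starting point and drift criterion free per
#' condition, drift-rate variability shared, noise fixed at 1.
#'
#' @param trials data.frame with columns `rt` (s), `choice` (1/0) and
#'   `stimulus` (+1/-1). Rows with `NA` choice are dropped.
#' @param bin_labels optional factor/vector of condition labels (one per
#'   trial); `NULL` fits a single condition.
#' @param free character vector of per-condition parameters.
#' @param shared character vector of parameters shared across conditions.
#' @param fixed named list of fixed parameter values.
#' @param n_starts number of optimization starts (>= 1; first start is a
#'   heuristic, the rest are jittered).
#' @param start optional [ddm_params()]-like list of starting values.
#' @param seed integer seed controlling start jitter.
#' @param gh_n Gauss-Hermite nodes for `sv`.
#' @return A `ddm_fit` object: per-condition parameter table, log-likelihood,
#'   AIC/BIC, convergence info.
#' @export
fit_ddm <- function(trials, bin_labels = NULL,
                    free = c("a", "t0", "v", "z", "dc"),
                    shared = "sv", fixed = list(c = 1),
                    n_starts = 5, start = NULL, seed = 1, gh_n = 20) {
  keep <- !is.na(trials$choice) & !is.na(trials$rt)
  trials <- trials[keep, , drop = FALSE]
  if (is.null(bin_labels)) bin_labels <- rep("all", nrow(trials))
  else bin_labels <- bin_labels[keep]
  bins <- sort(unique(as.character(bin_labels)))
  data <- lapply(bins, function(b) trials[bin_labels == b, , drop = FALSE])
  for (d in data) {
    if (length(unique(d$choice)) < 2)
      stop("both choice types must be present in every condition")
  }
  layout <- .ddm_layout(bins, free, shared, fixed)
  gh <- gh_cache(gh_n)

  min_rt <- min(trials$rt)
  if (is.null(start)) {
    p_yes <- mean(trials$choice == 1)
    start <- list(a = 1.2, z = 0.5, v = 1, dc = stats::qlogis(min(max(p_yes, .05), .95)) / 4,
                  t0 = 0.7 * min_rt, sv = 0.3, c = 1)
  }
  th0 <- .ddm_pack(start, layout)

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) th0 else th0 + stats::rnorm(length(th0), sd = 0.4)
    opt <- try(stats::optim(th, .ddm_negll, layout = layout, data = data,
                            gh = gh, method = "BFGS",
                            control = list(maxit = 400, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed")

  pars <- .ddm_unpack(best$par, layout)
  tab <- do.call(rbind, lapply(seq_along(bins), function(b)
    data.frame(bin = bins[b], as.data.frame(pars[[b]][.ddm_par_names]))))
  k <- length(best$par)
  n <- nrow(trials)
  structure(list(
    params = tab, bins = bins, loglik = -best$value,
    aic = 2 * best$value + 2 * k, bic = 2 * best$value + log(n) * k,
    k = k, n = n, convergence = best$convergence, n_starts = n_starts,
    converged = best$convergence == 0, layout = layout
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("DDM maximum-likelihood fit:", x$n, "trials,",
      length(x$bins), "condition(s)\n")
  cat("  logLik =", format(x$loglik, digits = 6),
      " AIC =", format(x$aic, digits = 6),
      " BIC =", format(x$bic, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(x$params, digits = 4)
  invisible(x)
}

#' Match a bias mechanism to a target 'yes' fraction
#'
#' Given base parameters, finds the drift criterion (`mechanism = "dc"`) or
#' starting point (`mechanism = "z"`) that yields a target overall
#' probability of 'yes' (averaged over signal and noise trials in equal
#' proportion), by numeric root-finding on the closed-form hitting
#' probability.
#'
#' @param params base [ddm_params()].
#' @param target_p_yes desired overall P(yes).
#' @param mechanism `"dc"` or `"z"`.
#' @param tol root-finding tolerance on P(yes).
#' @return A [ddm_params()] object with the adjusted parameter.
#' @export
match_bias <- function(params, target_p_yes, mechanism = c("dc", "z"),
                       tol = 1e-6) {
  mechanism <- match.arg(mechanism)
  f <- function(x) {
    p <- params
    p[[mechanism]] <- x
    mean(c(ddm_prob_yes(p, 1), ddm_prob_yes(p, -1))) - target_p_yes
  }
  interval <- if (mechanism == "dc") c(-10, 10) else c(1e-4, 1 - 1e-4)
  root <- stats::uniroot(f, interval, tol = tol)$root
  out <- params
  out[[mechanism]] <- root
  out
}

# Mode of the analytic RT density for one stimulus/choice cell.
.ddm_rt_mode <- function(params, stimulus, choice, t_max = 6, dt = 1e-3) {
  t <- seq(params$t0 + dt, params$t0 + t_max, by = dt)
  d <- ddm_fpt_density(t, params, stimulus, choice)
  t[which.max(d)]
}

#' Dissociate drift-criterion from starting-point bias via RT modes
#'
#' A drift-criterion bias accumulates over time and barely moves the mode of
#' the RT distributions, whereas a starting-point bias shifts the modes
#' substantially. Given two parameterizations matched on overall P(yes) (one
#' biased via `z`, one via `dc`) and an unbiased reference, returns the
#' analytic RT-distribution modes per stimulus x choice cell and the mean
#' absolute mode shift of each biased model relative to the reference.
#'
#' @param params_z starting-point-biased [ddm_params()].
#' @param params_dc drift-criterion-biased [ddm_params()].
#' @param params_base unbiased reference; defaults to `params_dc` with
#'   `dc = 0`, `z = 0.5`.
#' @return List with `modes` (data.frame of modes per model/stimulus/choice),
#'   `shift_z`, `shift_dc` (mean absolute mode shifts, s) and `p_yes` per
#'   model.
#' @export
mode_shift_diagnostic <- function(params_z, params_dc, params_base = NULL) {
  if (is.null(params_base)) {
    params_base <- params_dc
    params_base$dc <- 0
    params_base$z <- 0.5
  }
  models <- list(base = params_base, z_bias = params_z, dc_bias = params_dc)
  cells <- expand.grid(stimulus = c(1, -1), choice = c(1, 0))
  modes <- do.call(rbind, lapply(names(models), function(m) {
    p <- models[[m]]
    data.frame(model = m, cells,
               mode = mapply(function(s, ch) .ddm_rt_mode(p, s, ch),
                             cells$stimulus, cells$choice))
  }))
  base_modes <- modes$mode[modes$model == "base"]
  shift <- function(m) mean(abs(modes$mode[modes$model == m] - base_modes))
  p_yes <- vapply(models, function(p)
    mean(c(ddm_prob_yes(p, 1), ddm_prob_yes(p, -1))), numeric(1))
  list(modes = modes, shift_z = shift("z_bias"), shift_dc = shift("dc_bias"),
       p_yes = p_yes)
}

#' Fit the trial-level regression DDM
#'
#' Fits a DDM in which the single-trial drift is a linear function of the
#' stimulus and two trial-wise neural covariates:
#' `v_i = beta0 + beta1 * S_i + beta2 * M_i + beta3 * C_i`,
#' where `S` is the stimulus code (+1/-1), `M` the combined neuromodulatory
#' brainstem response and `C` the combined colliculi response (both z-scored
#' before entering the likelihood). Boundary separation, starting point and
#' non-decision time are fitted but do not depend on the covariates.
#'
#' @param trials data.frame with `rt`, `choice`, `stimulus`.
#' @param M,C numeric covariates, one value per trial. Z-scored internally
#'   (constant vectors are left untouched).
#' @param n_starts,seed,gh_n,fixed as in [fit_ddm()].
#' @return A `ddm_regression_fit` object with `betas` (beta0..beta3), the
#'   shared `a`, `z`, `t0`, log-likelihood and AIC/BIC.
#' @export
fit_regression_ddm <- function(trials, M, C, n_starts = 5, seed = 1,
                               gh_n = 20, fixed = list(sv = 0, c = 1)) {
  keep <- !is.na(trials$choice) & !is.na(trials$rt)
  trials <- trials[keep, , drop = FALSE]
  M <- M[keep]; C <- C[keep]
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
  M <- zs(M); C <- zs(C)
  gh <- gh_cache(gh_n)
  min_rt <- min(trials$rt)

  # theta: beta0..beta3, log a, qlogis z, log t0 (+ log sv if not fixed)
  fit_sv <- !("sv" %in% names(fixed))
  negll <- function(th) {
    betas <- th[1:4]
    a <- exp(th[5]); z <- stats::plogis(th[6]); t0 <- exp(th[7])
    sv <- if (fit_sv) exp(th[8]) else fixed$sv
    if (t0 >= min_rt) return(1e4 * (1 + t0 - min_rt) * nrow(trials))
    mu <- betas[1] + betas[2] * trials$stimulus + betas[3] * M + betas[4] * C
    ll <- .ddm_loglik_cpp(trials$rt, as.integer(trials$choice), mu, a, z,
                          t0, fixed$c, gh$nodes, gh$weights, sv, 1e-6, 1e-12)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  th0 <- c(0, 1, 0, 0, log(1.2), 0, log(0.7 * min_rt))
  if (fit_sv) th0 <- c(th0, log(0.3))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) th0 else th0 + stats::rnorm(length(th0), sd = 0.3)
    opt <- try(stats::optim(th, negll, method = "BFGS",
                            control = list(maxit = 400, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed")
  k <- length(best$par); n <- nrow(trials)
  structure(list(
    betas = stats::setNames(best$par[1:4], c("beta0", "beta1", "beta2", "beta3")),
    a = exp(best$par[5]), z = stats::plogis(best$par[6]),
    t0 = exp(best$par[7]),
    sv = if (fit_sv) exp(best$par[8]) else fixed$sv,
    loglik = -best$value, aic = 2 * best$value + 2 * k,
    bic = 2 * best$value + log(n) * k, n = n,
    converged = best$convergence == 0
  ), class = "ddm_regression_fit")
}

#' @export
print.ddm_regression_fit <- function(x, ...) {
  cat("Regression DDM fit (", x$n, " trials)\n", sep = "")
  cat("  drift: v_i = beta0 + beta1*S + beta2*M + beta3*C\n")
  print(round(x$betas, 4))
  cat("  a =", format(x$a, digits = 3), " z =", format(x$z, digits = 3),
      " t0 =", format(x$t0, digits = 3), " logLik =",
      format(x$loglik, digits = 6), "\n")
  invisible(x)
}
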