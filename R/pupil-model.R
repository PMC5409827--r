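#' Canonical pupil impulse response function
#'
#' `h(t) = (t / t_max)^w * exp(-w * (t / t_max - 1))` for `t >= 0`, 0
#' otherwise: an Erlang-like kernel normalized to peak 1 at `t = t_max`.
#' Default parameters (shape `w = 10.1`, time-to-peak `t_max = 0.93` s) are
#' the canonical values from the pupillometry literature; the kernel links
#' putative neural input to measured pupil diameter.
#'
#' @param t time in seconds (vector).
#' @param w dimensionless shape exponent (> 0).
#' @param t_max time-to-peak in seconds (> 0).
#' @return `h(t)` values.
#' @export
pupil_irf <- function(t, w = 10.1, t_max = 0.93) {
  stopifnot(w > 0, t_max > 0)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / t_max)^w * exp(-w * (t[pos] / t_max - 1))
  out
}

#' Residualize values on a covariate, preserving the mean
#'
#' Ordinary least-squares regression of `values` on `covariate` (plus
#' intercept); returns the residuals shifted back to the original mean
#' level, so downstream binned metrics stay on the original scale. Used to
#' remove reaction-time-driven variance from task-evoked pupil and fMRI
#' response amplitudes (slow peripheral/hemodynamic filtering makes longer
#' trials produce larger responses without larger neural input).
#'
#' @param values numeric vector.
#' @param covariate numeric vector (same length). Pairs with `NA` in either
#'   are passed through as `NA`.
#' @return Residualized values, `cor(out, covariate) = 0` (up to machine
#'   precision) and `mean(out) = mean(values)` on complete pairs.
#' @export
residualize <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  ok <- is.finite(values) & is.finite(covariate)
  out <- rep(NA_real_, length(values))
  if (sum(ok) < 3 || stats::sd(covariate[ok]) == 0) {
    out[ok] <- values[ok]
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, covariate[ok]), values[ok])
  out[ok] <- fit$residuals + mean(values[ok])
  out
}

#' Assign trials to pupil-response bins
#'
#' Sorts trials by amplitude and partitions them according to the scheme:
#' `"three_40_20_40"` assigns the lowest 40% to `"low"`, the middle 20% to
#' `"mid"` and the highest 40% to `"high"`; `"quantile"` forms `k` equally
#' populated ordered bins (`"bin1"` lowest). Ties are broken by the stable
#' order of the trial index, so assignments are deterministic.
#'
#' @param amplitudes numeric vector (e.g. RT-residualized TPR amplitudes).
#' @param scheme `"three_40_20_40"` or `"quantile"`.
#' @param k number of quantile bins (4 or 5 are the usual choices).
#' @return Factor of bin labels, ordered from low to high.
#' @export
bin_trials <- function(amplitudes, scheme = c("three_40_20_40", "quantile"),
                       k = 5) {
  scheme <- match.arg(scheme)
  n <- length(amplitudes)
  ord <- order(amplitudes, seq_len(n))   # stable tie-break by trial index
  if (scheme == "three_40_20_40") {
    n_low <- round(0.4 * n)
    n_high <- round(0.4 * n)
    labs <- c("low", "mid", "high")
    lab <- rep(labs[2], n)
    lab[ord[seq_len(n_low)]] <- "low"
    lab[ord[(n - n_high + 1):n]] <- "high"
    factor(lab, levels = labs)
  } else {
    stopifnot(k >= 2)
    sizes <- diff(floor(n * (0:k) / k))
    labs <- paste0("bin", seq_len(k))
    lab <- rep(labs[1], n)
    lab[ord] <- rep(labs, sizes)
    factor(lab, levels = labs)
  }
}

#' Single-trial task-evoked pupil response (TPR)
#'
#' For each trial with a recorded choice: `baseline` is the mean percent
#' modulation in the 0.5 s before the cue (decision-interval onset);
#' `amplitude_raw` is the mean in the window -1 s to +1.5 s around the
#' choice (button press), minus the baseline. `amplitude` is
#' `amplitude_raw` with reaction-time-driven variance removed via
#' [residualize()] (set `rt_residualize = FALSE` for the control variant).
#' Trials without a response, or whose windows fall outside the trace, are
#' excluded (flagged in the `included` column of the result).
#'
#' @param trace a preprocessed [pupil_trace()] (percent modulation).
#' @param trial_table data.frame with `trial`, `cue_s`, `choice_s`, `rt`.
#' @param baseline_window window relative to cue (s).
#' @param response_window window relative to choice (s).
#' @param rt_residualize remove RT-driven variance from the amplitude.
#' @return data.frame with `trial`, `baseline`, `amplitude_raw`,
#'   `amplitude`, `rt`, `included`.
#' @export
compute_tpr <- function(trace, trial_table,
                        baseline_window = c(-0.5, 0),
                        response_window = c(-1, 1.5),
                        rt_residualize = TRUE) {
  fs <- trace$sample_rate
  n <- length(trace$samples)
  win_mean <- function(t0, t1) {
    i0 <- floor(t0 * fs) + 1
    i1 <- ceiling(t1 * fs)
    if (i0 < 1 || i1 > n || i1 < i0) return(NA_real_)
    mean(trace$samples[i0:i1])
  }
  res <- lapply(seq_len(nrow(trial_table)), function(i) {
    tr <- trial_table[i, ]
    if (is.na(tr$choice_s))
      return(data.frame(trial = tr$trial, baseline = NA_real_,
                        amplitude_raw = NA_real_, rt = tr$rt,
                        included = FALSE))
    b <- win_mean(tr$cue_s + baseline_window[1], tr$cue_s + baseline_window[2])
    a <- win_mean(tr$choice_s + response_window[1],
                  tr$choice_s + response_window[2])
    data.frame(trial = tr$trial, baseline = b, amplitude_raw = a - b,
               rt = tr$rt, included = is.finite(a - b))
  })
  out <- do.call(rbind, res)
  out$amplitude <- if (rt_residualize) {
    residualize(out$amplitude_raw, out$rt)
  } else out$amplitude_raw
  out
}

#' Build the pupil GLM design on concatenated trial epochs
#'
#' Epochs run from 1 s before cue to 5 s after cue. Three input components
#' are modeled per trial: a transient at the cue, a transient 0.24 s before
#' the button press (the latency between phasic brainstem activity and the
#' overt response), and a sustained boxcar spanning cue to choice whose
#' height is divided by the number of samples in the interval, so that every
#' pre-convolution column sums to 1 per trial and the beta weights of
#' transient and sustained inputs are comparable. Each component is
#' convolved with the canonical pupil impulse response within its epoch.
#'
#' @param trial_table data.frame with `cue_s`, `choice_s`, `rt`.
#' @param sample_rate Hz.
#' @param epoch epoch window relative to cue (s).
#' @param choice_offset_s transient placed this long before the button press.
#' @param w,t_max impulse-response parameters, see [pupil_irf()].
#' @return List: `design` (samples x 3 matrix: cue, choice, sustained),
#'   `sticks` (pre-convolution channels), `trials` (row indices of trials
#'   used), `n_epoch` (samples per epoch), `sample_rate`, `epoch`.
#' @export
build_pupil_design <- function(trial_table, sample_rate, epoch = c(-1, 5),
                               choice_offset_s = 0.24, w = 10.1,
                               t_max = 0.93) {
  fs <- sample_rate
  n_ep <- round((epoch[2] - epoch[1]) * fs)
  used <- which(!is.na(trial_table$choice_s))
  kern <- pupil_irf(seq(0, epoch[2] - epoch[1], by = 1 / fs), w, t_max)
  clamped <- 0
  blocks <- lapply(used, function(i) {
    rt <- trial_table$rt[i]
    sticks <- matrix(0, n_ep, 3,
                     dimnames = list(NULL, c("cue", "choice", "sustained")))
    i_cue <- round(-epoch[1] * fs) + 1
    t_choice <- rt - choice_offset_s
    if (t_choice < 0) { t_choice <- 0; clamped <<- clamped + 1 }
    i_choice <- min(i_cue + round(t_choice * fs), n_ep)
    sticks[i_cue, "cue"] <- 1
    sticks[i_choice, "choice"] <- 1
    i_end <- min(i_cue + round(rt * fs), n_ep)
    box <- i_cue:i_end
    sticks[box, "sustained"] <- 1 / length(box)
    des <- apply(sticks, 2, function(s)
      stats::convolve(s, rev(kern), type = "open")[seq_len(n_ep)])
    list(sticks = sticks, design = des)
  })
  if (clamped > 0)
    warning(clamped, " trial(s) with choice transient before cue; clamped")
  list(design = do.call(rbind, lapply(blocks, `[[`, "design")),
       sticks = do.call(rbind, lapply(blocks, `[[`, "sticks")),
       trials = used, n_epoch = n_ep, sample_rate = fs, epoch = epoch)
}

# Cut baseline-corrected epochs from a trace and concatenate them.
.concat_epochs <- function(trace, trial_table, epoch = c(-1, 5),
                           baseline_s = 0.5, trials = NULL) {
  fs <- trace$sample_rate
  n <- length(trace$samples)
  n_ep <- round((epoch[2] - epoch[1]) * fs)
  if (is.null(trials)) trials <- which(!is.na(trial_table$choice_s))
  segs <- lapply(trials, function(i) {
    cue <- trial_table$cue_s[i]
    i0 <- round((cue + epoch[1]) * fs) + 1
    idx <- i0:(i0 + n_ep - 1)
    if (idx[1] < 1 || idx[n_ep] > n) return(NULL)
    seg <- trace$samples[idx]
    b0 <- round((cue - baseline_s) * fs) + 1
    seg - mean(trace$samples[b0:(round(cue * fs))])
  })
  if (any(vapply(segs, is.null, logical(1))))
    stop("trial epochs extend beyond the trace")
  unlist(segs)
}

#' Fit the pupil GLM with transient and sustained inputs
#'
#' Fits, by ordinary least squares, the three-component general linear model
#' of the task-evoked pupil response on concatenated baseline-corrected
#' trial epochs: transient inputs at cue and just before choice, plus a
#' sustained input spanning the decision interval, all convolved with the
#' canonical pupil impulse response (see [build_pupil_design()]). Can be fit
#' separately per condition (e.g. per TPR bin) via `bin_labels`.
#'
#' @param trace a preprocessed [pupil_trace()].
#' @param trial_table data.frame with `cue_s`, `choice_s`, `rt`.
#' @param bin_labels optional per-trial condition labels; one fit per level.
#' @param ... passed to [build_pupil_design()].
#' @return For a single fit: list with `betas` (`beta_cue`, `beta_choice`,
#'   `beta_sustained`), `r_squared`, `predicted`, `design`. With
#'   `bin_labels`: data.frame of betas and R-squared per bin.
#' @export
fit_pupil_glm <- function(trace, trial_table, bin_labels = NULL, ...) {
  if (!is.null(bin_labels)) {
    levs <- levels(factor(bin_labels))
    out <- do.call(rbind, lapply(levs, function(l) {
      idx <- which(bin_labels == l)
      f <- fit_pupil_glm(trace, trial_table[idx, , drop = FALSE], NULL, ...)
      data.frame(bin = l, beta_cue = f$betas[["beta_cue"]],
                 beta_choice = f$betas[["beta_choice"]],
                 beta_sustained = f$betas[["beta_sustained"]],
                 r_squared = f$r_squared)
    }))
    return(out)
  }
  dsn <- build_pupil_design(trial_table, trace$sample_rate, ...)
  y <- .concat_epochs(trace, trial_table,
                      epoch = dsn$epoch, trials = dsn$trials)
  fit <- stats::lm.fit(cbind(1, dsn$design), y)
  betas <- fit$coefficients[-1]
  names(betas) <- c("beta_cue", "beta_choice", "beta_sustained")
  pred <- y - fit$residuals
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(betas = betas, r_squared = r2, predicted = pred, design = dsn)
}
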