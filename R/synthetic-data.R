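#' Ground truth for synthetic data generation
#'
#' Bundles every parameter from which the generator builds trial tables,
#' pupil traces, voxel patterns and brainstem ROI responses. Defaults
#' emulate the study conditions of a near-threshold yes-no contrast
#' detection experiment: blocks of 40 trials with signal on exactly half of
#' the trials per block, a 2 s pre-decision baseline, a response deadline
#' of 3.5 s and inter-trial intervals uniform on 4-12 s. A latent per-trial
#' arousal state ("low"/"high" TPR condition) drives both the sustained
#' pupil input and the drift criterion, creating the pupil-bias coupling
#' the pipeline must detect: the drift criterion is markedly negative
#' (conservative) on low-arousal trials and near zero on high-arousal
#' trials.
#'
#' @param n_trials number of trials (> 0).
#' @param block_size trials per block.
#' @param ddm_low,ddm_high [ddm_params()] for the low/high TPR condition.
#' @param baseline_s pre-decision baseline duration (s).
#' @param iti_range inter-trial interval range (s).
#' @param deadline_s response deadline (s); slower trials are non-responses.
#' @param pupil_betas named vector: `cue`, `choice` transient weights and
#'   `sustained_low`, `sustained_high` sustained weights (percent
#'   modulation per unit input).
#' @param irf_w,irf_t_max canonical pupil impulse response parameters.
#' @param noise_sd total pupil trace noise sd (percent modulation).
#' @param blink_rate blink events per minute.
#' @param blink_response_amp,saccade_response_amp amplitude of stereotyped
#'   pupil responses following blink/saccade events (0 disables).
#' @param sample_rate pupil sampling rate (Hz); 50 keeps simulation light,
#'   up to 1000 Hz as acquired is supported.
#' @param signal_fraction proportion of signal+noise trials (in [0, 1]).
#' @param n_voxels number of voxels for pattern generation (even).
#' @param orientation_amp,choice_amp voxel pattern effect amplitudes.
#' @param pattern_noise_sd i.i.d. voxel noise sd.
#' @param roi_tpr_couplings named per-ROI coupling of responses to TPR.
#' @param roi_shared_sd sd of the latent factor shared by all ROIs.
#' @param sim_dt Euler step for the choice/RT simulation (s).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_trials = 400, block_size = 40,
                         ddm_low = ddm_params(a = 1.4, z = 0.5, v = 0.9,
                                              dc = -0.3, t0 = 0.3, sv = 0.3),
                         ddm_high = ddm_params(a = 1.4, z = 0.5, v = 0.9,
                                               dc = -0.05, t0 = 0.3, sv = 0.3),
                         baseline_s = 2, iti_range = c(4, 12),
                         deadline_s = 3.5,
                         pupil_betas = c(cue = 1, choice = 1,
                                         sustained_low = 1.5,
                                         sustained_high = 4.5),
                         irf_w = 10.1, irf_t_max = 0.93,
                         noise_sd = 1, blink_rate = 6,
                         blink_response_amp = 0, saccade_response_amp = 0,
                         sample_rate = 50, signal_fraction = 0.5,
                         n_voxels = 100, orientation_amp = 0.08,
                         choice_amp = 0.08, pattern_noise_sd = 1,
                         roi_tpr_couplings = c(LC = 0.35, SN = 0.2,
                                               VTA = 0.2, BF_sept = 0.15,
                                               BF_subl = 0.15, SC = 0.1,
                                               IC = 0.1),
                         roi_shared_sd = 1, sim_dt = 1e-3, seed = 1) {
  stopifnot(n_trials > 0, signal_fraction >= 0, signal_fraction <= 1,
            n_voxels %% 2 == 0)
  structure(as.list(environment()), class = "ground_truth")
}

#' Generate a trial table with DDM-simulated behavior
#'
#' Lays out trials in blocks of `block_size` with signal present on exactly
#' `signal_fraction` of the trials within each block (random order), draws
#' a latent low/high arousal condition per trial, and simulates the choice
#' and reaction time of every trial from the stimulus-coded diffusion
#' process of the trial's condition. Cue times are spaced by the baseline
#' interval, the decision interval and an inter-trial interval drawn
#' uniformly from `iti_range`. Trials slower than the deadline are flagged
#' as non-responses. If `n_trials` is not a multiple of the block size the
#' final block is partial, with a warning.
#'
#' @param gt a [ground_truth()].
#' @return A data.frame (class `trial_table`) with columns `trial`,
#'   `block`, `block_orientation`, `stimulus` (+1/-1), `tpr_condition`,
#'   `cue_s`, `rt`, `choice` (1/0/NA), `choice_s`, `responded`.
#' @export
generate_trial_table <- function(gt) {
  set.seed(gt$seed)
  n <- gt$n_trials
  bs <- gt$block_size
  n_blocks <- ceiling(n / bs)
  if (n %% bs != 0)
    warning("n_trials is not a multiple of the block size; final block is partial")
  stimulus <- unlist(lapply(seq_len(n_blocks), function(b) {
    size <- min(bs, n - (b - 1) * bs)
    n_sig <- round(gt$signal_fraction * size)
    sample(c(rep(1, n_sig), rep(-1, size - n_sig)))
  }))
  block <- rep(seq_len(n_blocks), each = bs)[seq_len(n)]
  block_orientation <- c("CW", "CCW")[(block - 1) %% 2 + 1]
  tpr_condition <- sample(c("low", "high"), n, replace = TRUE)

  rt <- numeric(n); choice <- integer(n)
  for (cond in c("low", "high")) {
    idx <- which(tpr_condition == cond)
    p <- if (cond == "low") gt$ddm_low else gt$ddm_high
    sim <- simulate_ddm(p, stimulus[idx], n = length(idx), dt = gt$sim_dt,
                        t_max = 2 * gt$deadline_s)
    rt[idx] <- sim$rt
    choice[idx] <- sim$choice
  }
  responded <- !is.na(rt) & rt <= gt$deadline_s
  dur <- ifelse(responded, rt, gt$deadline_s)
  iti <- stats::runif(n, gt$iti_range[1], gt$iti_range[2])
  # successive cues are separated by decision interval + ITI + next baseline
  cue_s <- gt$baseline_s + cumsum(c(0, (dur + iti + gt$baseline_s)[-n]))
  out <- data.frame(trial = seq_len(n), block = block,
                    block_orientation = block_orientation,
                    stimulus = stimulus, tpr_condition = tpr_condition,
                    cue_s = cue_s,
                    rt = ifelse(responded, rt, NA_real_),
                    choice = ifelse(responded, choice, NA_integer_),
                    choice_s = ifelse(responded, cue_s + rt, NA_real_),
                    responded = responded)
  class(out) <- c("trial_table", "data.frame")
  out
}

# AR(1) low-frequency drift + white noise, scaled to total sd
.trace_noise <- function(n, sd_total, rho = 0.99) {
  if (sd_total <= 0) return(numeric(n))
  drift <- as.numeric(stats::filter(stats::rnorm(n), rho, method = "recursive"))
  drift <- drift / stats::sd(drift)
  white <- stats::rnorm(n)
  x <- drift + white
  x / stats::sd(x) * sd_total
}

#' Generate a raw pupil trace for a trial table
#'
#' Builds the neural-input model of the pupil: transient sticks at cue and
#' 0.24 s before each button press, and a sustained boxcar spanning cue to
#' choice (height 1/n samples), weighted by the ground-truth betas (the
#' sustained weight depends on the trial's latent arousal condition) and
#' convolved with the canonical impulse response. Noise is white plus a
#' low-frequency AR(1) (rho = 0.99) drift; blinks are injected as 100-300
#' ms sharp dropouts with logged event times, and optional stereotyped
#' post-event pupil responses can be added for artifact-removal testing.
#' The percent-modulation signal is mounted on a raw diameter baseline so
#' the trace enters preprocessing in arbitrary units.
#'
#' @param trial_table output of [generate_trial_table()].
#' @param gt the [ground_truth()].
#' @param baseline_level raw diameter units the modulation rides on.
#' @return A raw [pupil_trace()] (single block spanning the run).
#' @export
generate_pupil_trace <- function(trial_table, gt, baseline_level = 1000) {
  set.seed(gt$seed + 1L)
  fs <- gt$sample_rate
  if (is.unsorted(trial_table$cue_s, strictly = TRUE) ||
      any(diff(trial_table$cue_s) <
            c(ifelse(trial_table$responded, trial_table$rt,
                     gt$deadline_s))[-nrow(trial_table)]))
    stop("overlapping trials")
  dur <- max(trial_table$cue_s) + gt$deadline_s + 10
  n <- round(dur * fs)
  sig <- numeric(n)
  kern <- pupil_irf(seq(0, 6, by = 1 / fs), gt$irf_w, gt$irf_t_max)
  add_conv <- function(sig, stick) {
    sig + stats::convolve(stick, rev(kern), type = "open")[seq_len(n)]
  }
  cue_stick <- numeric(n); choice_stick <- numeric(n)
  sus <- numeric(n)
  for (i in seq_len(nrow(trial_table))) {
    tr <- trial_table[i, ]
    ci <- round(tr$cue_s * fs) + 1
    cue_stick[ci] <- cue_stick[ci] + gt$pupil_betas[["cue"]]
    if (!tr$responded) next
    chi <- ci + round((tr$rt - 0.24) * fs)
    choice_stick[chi] <- choice_stick[chi] + gt$pupil_betas[["choice"]]
    b_sus <- gt$pupil_betas[[paste0("sustained_", tr$tpr_condition)]]
    box <- ci:(ci + round(tr$rt * fs))
    sus[box] <- sus[box] + b_sus / length(box)
  }
  sig <- add_conv(sig, cue_stick)
  sig <- add_conv(sig, choice_stick)
  sig <- add_conv(sig, sus)
  sig <- sig + .trace_noise(n, gt$noise_sd)

  # blink events (Poisson in time, 100-300 ms) as sharp dropouts
  n_blinks <- stats::rpois(1, gt$blink_rate * dur / 60)
  blink_events <- data.frame(start_s = numeric(), end_s = numeric())
  if (n_blinks > 0) {
    starts <- sort(stats::runif(n_blinks, 1, dur - 2))
    lens <- stats::runif(n_blinks, 0.1, 0.3)
    blink_events <- .merge_windows(data.frame(start_s = starts,
                                              end_s = starts + lens))
  }
  # saccade events: times only (no pupil consequence unless amp > 0)
  n_sacc <- stats::rpois(1, gt$blink_rate * dur / 60)
  saccade_events <- data.frame(start_s = numeric(), end_s = numeric())
  if (n_sacc > 0) {
    s0 <- sort(stats::runif(n_sacc, 1, dur - 2))
    saccade_events <- data.frame(start_s = s0, end_s = s0 + 0.05)
  }
  add_artifact <- function(sig, events, amp) {
    if (amp == 0 || nrow(events) == 0) return(sig)
    # transient constriction-then-redilation following the event
    tk <- seq(0, 4, by = 1 / fs)
    ak <- -amp * pupil_irf(tk, w = 2, t_max = 0.5) +
      0.5 * amp * pupil_irf(tk, w = 3, t_max = 2)
    stick <- numeric(n)
    onsets <- pmin(round(events$end_s * fs) + 1, n)
    stick[onsets] <- 1
    sig + stats::convolve(stick, rev(ak), type = "open")[seq_len(n)]
  }
  sig <- add_artifact(sig, blink_events, gt$blink_response_amp)
  sig <- add_artifact(sig, saccade_events, gt$saccade_response_amp)

  raw <- baseline_level * (1 + sig / 100)
  for (i in seq_len(nrow(blink_events))) {
    i0 <- max(round(blink_events$start_s[i] * fs) + 1, 1)
    i1 <- min(round(blink_events$end_s[i] * fs) + 1, n)
    raw[i0:i1] <- 0.02 * baseline_level
  }
  pupil_trace(raw, fs, blink_events = blink_events,
              saccade_events = saccade_events)
}

#' Generate trial-by-voxel response patterns
#'
#' trials x voxels matrix composed of a common task-evoked response, an
#' orientation-specific pattern (a fixed random voxel pattern whose sign
#' follows the block's orientation, present only on signal trials), a
#' choice-specific pattern (sign follows the trial's choice) and i.i.d.
#' Gaussian noise. Voxels are split into two hemispheres on a 3-D grid with
#' mirrored homotopic partners.
#'
#' @param trial_table output of [generate_trial_table()].
#' @param gt the [ground_truth()].
#' @return A [pattern_set()]. Trials without a response carry a 0 choice
#'   pattern.
#' @export
generate_patterns <- function(trial_table, gt) {
  set.seed(gt$seed + 2L)
  n <- nrow(trial_table); nv <- gt$n_voxels
  half <- nv / 2
  p_or <- stats::rnorm(nv); p_or <- p_or / sqrt(sum(p_or^2) / nv)
  p_ch <- stats::rnorm(nv); p_ch <- p_ch / sqrt(sum(p_ch^2) / nv)
  task <- rep(1, n)
  or_sign <- ifelse(trial_table$stimulus == 1,
                    ifelse(trial_table$block_orientation == "CW", 1, -1), 0)
  ch_sign <- ifelse(is.na(trial_table$choice), 0,
                    ifelse(trial_table$choice == 1, 1, -1))
  X <- outer(task, rep(1, nv)) +
    gt$orientation_amp * outer(or_sign, p_or) +
    gt$choice_amp * outer(ch_sign, p_ch) +
    matrix(stats::rnorm(n * nv, sd = gt$pattern_noise_sd), n, nv)
  side <- ceiling(sqrt(half))
  gx <- ((seq_len(half) - 1) %% side) + 1
  gy <- ((seq_len(half) - 1) %/% side) + 1
  voxel_meta <- data.frame(
    x = c(-gx * 3, gx * 3), y = rep(gy * 3, 2), z = 0,
    hemisphere = rep(c("L", "R"), each = half),
    partner = c(seq_len(half) + half, seq_len(half)))
  pattern_set(X, voxel_meta,
              labels = data.frame(stimulus = trial_table$stimulus,
                                  choice = trial_table$choice,
                                  block_orientation = trial_table$block_orientation))
}

#' Generate trial-wise brainstem ROI responses
#'
#' Each ROI's trial response is a shared latent factor (loading 1 on every
#' ROI) plus an ROI-specific component coupled to the z-scored TPR with the
#' ground-truth coupling, plus unit Gaussian noise; a fourth-ventricle
#' nuisance series uncorrelated with TPR is included.
#'
#' @param trial_table output of [generate_trial_table()].
#' @param tpr per-trial TPR values (length = number of trials).
#' @param gt the [ground_truth()].
#' @return An [roi_response_set()].
#' @export
generate_roi_responses <- function(trial_table, tpr, gt) {
  set.seed(gt$seed + 3L)
  n <- nrow(trial_table)
  stopifnot(length(tpr) == n)
  z <- (tpr - mean(tpr, na.rm = TRUE)) / stats::sd(tpr, na.rm = TRUE)
  z[!is.finite(z)] <- 0
  shared <- stats::rnorm(n, sd = gt$roi_shared_sd)
  cps <- gt$roi_tpr_couplings
  R <- sapply(names(cps), function(roi)
    shared + cps[[roi]] * z + stats::rnorm(n))
  roi_response_set(R, roi_names = names(cps),
                   nuisance = stats::rnorm(n), tpr = tpr)
}

#' Weibull psychometric observer for two-interval forced choice
#'
#' `p(correct | x) = gamma + (1 - gamma - lapse) * (1 - exp(-(x/alpha)^beta))`
#' with guess rate `gamma = 0.5` for 2IFC.
#'
#' @param alpha threshold parameter (contrast units, > 0).
#' @param beta slope (> 0).
#' @param gamma guess rate.
#' @param lapse lapse rate (in [0, 0.5)).
#' @return An object of class `weibull_observer` (callable parameters).
#' @export
weibull_observer <- function(alpha, beta = 3.5, gamma = 0.5, lapse = 0) {
  if (!(alpha > 0) || !(beta > 0))
    stop("psychometric function must be monotone increasing (alpha, beta > 0)")
  stopifnot(gamma >= 0, gamma < 1, lapse >= 0, lapse < 1 - gamma)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lapse = lapse),
            class = "weibull_observer")
}

#' Probability correct of a Weibull observer at a contrast
#' @param observer a [weibull_observer()].
#' @param x stimulus contrast (vector).
#' @return Probability of a correct 2IFC response.
#' @export
observer_p_correct <- function(observer, x) {
  with(observer, gamma + (1 - gamma - lapse) * (1 - exp(-(x / alpha)^beta)))
}

# contrast at which an assumed Weibull (alpha, beta, gamma, lapse) predicts p
.weibull_inverse <- function(p, alpha, beta, gamma, lapse) {
  q <- (p - gamma) / (1 - gamma - lapse)
  stopifnot(q > 0, q < 1)
  alpha * (-log(1 - q))^(1 / beta)
}

#' Adaptive staircase titration of threshold contrast
#'
#' Bayesian adaptive staircase (Quest-style) for a two-interval
#' forced-choice detection task: a posterior over the log10 threshold of an
#' assumed Weibull psychometric is updated after every trial, each trial is
#' placed at the contrast where the current posterior-mean threshold
#' predicts `target_p` correct, and the returned contrast is the
#' `target_p` point of the posterior-mean threshold after `n_trials`
#' trials. Evaluating the observer at the returned contrast should yield
#' accuracy near `target_p` (75% by default).
#'
#' @param observer a [weibull_observer()] (the simulated subject).
#' @param n_trials number of staircase trials.
#' @param seed integer seed for the simulated responses.
#' @param target_p targeted proportion correct.
#' @param guess initial threshold guess (contrast units).
#' @param prior_sd prior sd on log10 threshold.
#' @param assumed_beta,assumed_lapse psychometric shape assumed by the
#'   staircase.
#' @return A list of class `staircase_result`: `threshold_contrast` (the
#'   converged contrast), `alpha_estimate` (posterior-mean threshold),
#'   `trials` (data.frame of tested contrasts and responses).
#' @export
simulate_staircase <- function(observer, n_trials = 200, seed = 1,
                               target_p = 0.75, guess = 0.1,
                               prior_sd = 0.5, assumed_beta = 3.5,
                               assumed_lapse = 0.01) {
  stopifnot(inherits(observer, "weibull_observer"), n_trials > 0)
  set.seed(seed)
  grid <- seq(log10(guess) - 3, log10(guess) + 3, length.out = 601)
  post <- stats::dnorm(grid, mean = log10(guess), sd = prior_sd)
  post <- post / sum(post)
  xs <- numeric(n_trials); resp <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    alpha_hat <- 10^sum(grid * post)
    x <- .weibull_inverse(target_p, alpha_hat, assumed_beta, observer$gamma,
                          assumed_lapse)
    p_true <- observer_p_correct(observer, x)
    correct <- stats::runif(1) < p_true
    p_model <- observer$gamma + (1 - observer$gamma - assumed_lapse) *
      (1 - exp(-(x / 10^grid)^assumed_beta))
    post <- post * if (correct) p_model else (1 - p_model)
    post <- post / sum(post)
    xs[t] <- x; resp[t] <- correct
  }
  alpha_hat <- 10^sum(grid * post)
  structure(list(
    threshold_contrast = .weibull_inverse(target_p, alpha_hat, assumed_beta,
                                          observer$gamma, assumed_lapse),
    alpha_estimate = alpha_hat,
    trials = data.frame(contrast = xs, correct = resp)
  ), class = "staircase_result")
}

#' @export
print.staircase_result <- function(x, ...) {
  cat("Staircase:", nrow(x$trials), "trials; threshold contrast =",
      format(x$threshold_contrast, digits = 4),
      "(alpha estimate", format(x$alpha_estimate, digits = 4), ")\n")
  invisible(x)
}

# ---- plain-text I/O --------------------------------------------------------

#' Write / read a trial table as CSV
#' @param trial_table a trial table.
#' @param path file path.
#' @return `read_trial_table` returns the trial table.
#' @export
write_trial_table <- function(trial_table, path) {
  utils::write.csv(trial_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write / read a pupil trace (samples CSV + JSON sidecar)
#'
#' Samples go to `<path>.csv` (columns `time_s`, `pupil`); the sample rate,
#' block boundaries and blink/saccade event lists go to `<path>.json`.
#'
#' @param trace a [pupil_trace()].
#' @param path base path (without extension).
#' @return `read_pupil_trace` returns the `pupil_trace`.
#' @export
write_pupil_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace_time(trace),
                              pupil = trace$samples),
                   paste0(path, ".csv"), row.names = FALSE)
  side <- list(sample_rate = trace$sample_rate, blocks = trace$blocks,
               blink_events = trace$blink_events,
               saccade_events = trace$saccade_events)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pupil_trace
#' @export
read_pupil_trace <- function(path) {
  samp <- utils::read.csv(paste0(path, ".csv"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- function(e) if (is.null(e) || length(e) == 0)
    data.frame(start_s = numeric(), end_s = numeric()) else as.data.frame(e)
  pupil_trace(samp$pupil, side$sample_rate,
              blocks = as.data.frame(side$blocks),
              blink_events = ev(side$blink_events),
              saccade_events = ev(side$saccade_events))
}
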