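#' Signal-detection metrics from a 2x2 count table
#'
#' Sensitivity `d' = z(H) - z(F)` and criterion `c = -(z(H) + z(F)) / 2`
#' from hit, miss, false-alarm and correct-rejection counts. Negative
#' criterion means a liberal bias (toward 'yes'). Rates of exactly 0 or 1
#' would give infinite z-scores; such cells are corrected with the
#' log-linear rule (0.5 added to each count of the affected signal or noise
#' pair, 1 to the denominator).
#'
#' @param hits,misses,fas,crs non-negative counts.
#' @param correction `"edge"` corrects only signal/noise pairs with a 0 or 1
#'   rate (default); `"loglinear"` corrects all cells; `"none"` applies no
#'   correction.
#' @return An `sdt_result` list: `hit_rate`, `fa_rate`, `dprime`,
#'   `criterion`, `n` (named counts).
#' @export
sdt_metrics <- function(hits, misses, fas, crs,
                        correction = c("edge", "loglinear", "none")) {
  correction <- match.arg(correction)
  stopifnot(hits >= 0, misses >= 0, fas >= 0, crs >= 0)
  if (hits + misses == 0) stop("empty cell: no signal trials (hits + misses = 0)")
  if (fas + crs == 0) stop("empty cell: no noise trials (fas + crs = 0)")
  rate <- function(k, n) {
    r <- k / n
    if (correction == "loglinear" ||
        (correction == "edge" && (r == 0 || r == 1))) (k + 0.5) / (n + 1)
    else r
  }
  h <- rate(hits, hits + misses)
  f <- rate(fas, fas + crs)
  zh <- stats::qnorm(h); zf <- stats::qnorm(f)
  structure(list(hit_rate = h, fa_rate = f, dprime = zh - zf,
                 criterion = -(zh + zf) / 2,
                 n = c(hits = hits, misses = misses, fas = fas, crs = crs)),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat("SDT: H =", format(x$hit_rate, digits = 3),
      " F =", format(x$fa_rate, digits = 3),
      " d' =", format(x$dprime, digits = 4),
      " criterion =", format(x$criterion, digits = 4), "\n")
  invisible(x)
}

# SDT metrics from a trial table subset (stimulus +1/-1, choice 1/0)
.sdt_from_trials <- function(trials, ...) {
  sdt_metrics(hits = sum(trials$stimulus == 1 & trials$choice == 1),
              misses = sum(trials$stimulus == 1 & trials$choice == 0),
              fas = sum(trials$stimulus == -1 & trials$choice == 1),
              crs = sum(trials$stimulus == -1 & trials$choice == 0), ...)
}

#' Stimulus-balanced fraction of 'yes' choices per bin
#'
#' The raw fraction of 'yes' choices per pupil bin confounds bias with any
#' accidental imbalance of signal and noise trials across bins. Balancing:
#' trials are sorted into bin x stimulus cells, the minimum cell count is
#' determined, that number of trials is sampled without replacement from
#' every cell, and the fraction of 'yes' choices is computed per bin; the
#' procedure is repeated `n_resamples` times and averaged.
#'
#' @param trials data.frame with `stimulus` (+1/-1) and `choice` (1/0).
#' @param bin_labels factor of bin labels, one per trial.
#' @param n_resamples number of resampling repetitions.
#' @param seed integer seed (fixed seed gives bit-identical output).
#' @return Named numeric vector: mean fraction of 'yes' per bin.
#' @export
balanced_fraction_yes <- function(trials, bin_labels, n_resamples = 1000,
                                  seed = 1) {
  bin_labels <- factor(bin_labels)
  cells <- split(seq_len(nrow(trials)),
                 interaction(bin_labels, trials$stimulus, drop = FALSE))
  counts <- vapply(cells, length, integer(1))
  if (any(counts == 0)) stop("empty bin x stimulus cell: ",
                             names(counts)[which(counts == 0)[1]])
  m <- min(counts)
  set.seed(seed)
  levs <- levels(bin_labels)
  acc <- matrix(0, n_resamples, length(levs), dimnames = list(NULL, levs))
  for (r in seq_len(n_resamples)) {
    take <- unlist(lapply(cells, function(ix)
      if (length(ix) == m) ix else sample(ix, m)))
    sub <- trials[take, ]
    subbin <- bin_labels[take]
    acc[r, ] <- vapply(levs, function(l)
      mean(sub$choice[subbin == l] == 1), numeric(1))
  }
  colMeans(acc)
}

#' Fraction of non-preferred choices per bin
#'
#' The preferred choice is the option the subject picks most often across
#' all trials irrespective of bin (ties are resolved toward 'yes'/up, and
#' noted). Returns the stimulus-balanced fraction of the opposite
#' (non-preferred) choice per bin, using the same balanced resampling as
#' [balanced_fraction_yes()].
#'
#' @inheritParams balanced_fraction_yes
#' @return Named numeric vector of non-preferred-choice fractions per bin,
#'   with attribute `preferred` (1 or 0).
#' @export
nonpreferred_fraction <- function(trials, bin_labels, n_resamples = 1000,
                                  seed = 1) {
  preferred <- if (mean(trials$choice == 1) >= 0.5) 1 else 0
  flipped <- trials
  flipped$choice <- ifelse(trials$choice == preferred, 0, 1)
  out <- balanced_fraction_yes(flipped, bin_labels, n_resamples, seed)
  attr(out, "preferred") <- preferred
  out
}

#' Absolute criterion per bin
#'
#' `|criterion|` per bin: overall bias magnitude regardless of sign, the
#' bias measure of choice when the sign of individual biases varies across
#' subjects (e.g. symmetric two-alternative tasks). Invariant to relabeling
#' the two choice options.
#'
#' @inheritParams balanced_fraction_yes
#' @param ... passed to [sdt_metrics()].
#' @return Named numeric vector of absolute criterion values per bin.
#' @export
abs_criterion <- function(trials, bin_labels, ...) {
  bin_labels <- factor(bin_labels)
  vapply(levels(bin_labels), function(l) {
    abs(.sdt_from_trials(trials[bin_labels == l, , drop = FALSE], ...)$criterion)
  }, numeric(1))
}

#' Sequential polynomial regression of a metric on pupil bins
#'
#' Tests, in a serial hierarchical fashion, whether a behavioral metric
#' depends on the task-evoked pupil response: a zero-order (constant),
#' first-order (monotonic) and second-order (non-monotonic) polynomial of
#' the bin-level predictor are compared by nested-model F-tests on the
#' group data (subject intercepts included). The selected order is the
#' highest order whose step improves significantly on the next lower model
#' at `alpha`; a purely non-monotonic dependence has no linear component,
#' so the quadratic step is evaluated regardless of the linear step's
#' outcome. If order >= 1 is selected, per-subject first- (and second-)
#' order coefficients are returned for group-level testing.
#'
#' @param y subjects x bins matrix of the metric (one row per subject).
#' @param x bin-level predictor (e.g. bin-mean TPR); defaults to the bin
#'   index.
#' @param alpha step-wise significance threshold.
#' @return A `poly_regression` list: `selected_order`, `F_stats`, `p_values`
#'   (per step), `subject_coefs` (per-subject linear/quadratic
#'   coefficients on the orthogonal basis), `basis`.
#' @export
sequential_poly_regression <- function(y, x = NULL, alpha = 0.05) {
  y <- as.matrix(y)
  n_sub <- nrow(y); n_bin <- ncol(y)
  stopifnot(n_bin >= 3, n_sub >= 2)
  if (is.null(x)) x <- seq_len(n_bin)
  basis <- stats::poly(x, degree = 2)      # orthogonal columns
  dat <- data.frame(y = as.vector(t(y)),
                    subject = factor(rep(seq_len(n_sub), each = n_bin)),
                    p1 = rep(basis[, 1], n_sub), p2 = rep(basis[, 2], n_sub))
  m0 <- stats::lm(y ~ subject, dat)
  m1 <- stats::lm(y ~ subject + p1, dat)
  m2 <- stats::lm(y ~ subject + p1 + p2, dat)
  a1 <- stats::anova(m0, m1); a2 <- stats::anova(m1, m2)
  Fs <- c(order1 = a1$F[2], order2 = a2$F[2])
  ps <- c(order1 = a1$`Pr(>F)`[2], order2 = a2$`Pr(>F)`[2])
  selected <- 0L
  if (is.finite(ps[1]) && ps[1] < alpha) selected <- 1L
  if (is.finite(ps[2]) && ps[2] < alpha) selected <- 2L
  subject_coefs <- t(apply(y, 1, function(yy)
    stats::lm.fit(cbind(1, basis), yy)$coefficients[2:3]))
  colnames(subject_coefs) <- c("linear", "quadratic")
  structure(list(selected_order = selected, F_stats = Fs, p_values = ps,
                 subject_coefs = subject_coefs, basis = basis, x = x),
            class = "poly_regression")
}

#' @export
print.poly_regression <- function(x, ...) {
  cat("Sequential polynomial regression: selected order", x$selected_order, "\n")
  cat("  step F:", format(x$F_stats, digits = 4),
      " p:", format(x$p_values, digits = 4), "\n")
  invisible(x)
}

#' Sliding-window correlation between pupil and criterion
#'
#' Characterizes the timing of the pupil-criterion link. For each window
#' position aligned to the button press, a baseline-corrected windowed
#' pupil value is computed per trial, trials are sorted into `n_bins`
#' equally populated bins of that value, criterion is computed per bin, and
#' the Pearson correlation between bin-mean pupil value and criterion is
#' recorded. The number of window positions is
#' `floor((t_end - t_start - window) / step) + 1`.
#'
#' @param trace a preprocessed [pupil_trace()].
#' @param trial_table data.frame with `cue_s`, `choice_s`, `stimulus`,
#'   `choice`.
#' @param window,step window length and step in seconds.
#' @param n_bins number of pupil bins.
#' @param t_start,t_end window-onset range relative to the button press (s);
#'   the default reaches from before the cue (for typical reaction times)
#'   to 3 s after the response.
#' @param baseline_window pre-cue baseline window (s, relative to cue).
#' @return data.frame with `time` (window center relative to button press)
#'   and `r`.
#' @export
sliding_window_criterion <- function(trace, trial_table, window = 0.25,
                                     step = 0.025, n_bins = 5,
                                     t_start = -3.5, t_end = 3,
                                     baseline_window = c(-0.5, 0)) {
  fs <- trace$sample_rate
  n <- length(trace$samples)
  tt <- trial_table[!is.na(trial_table$choice_s), , drop = FALSE]
  base <- vapply(seq_len(nrow(tt)), function(i) {
    i0 <- floor((tt$cue_s[i] + baseline_window[1]) * fs) + 1
    i1 <- ceiling((tt$cue_s[i] + baseline_window[2]) * fs)
    mean(trace$samples[max(i0, 1):min(i1, n)])
  }, numeric(1))
  offsets <- seq(t_start, t_end - window, by = step)
  r <- vapply(offsets, function(off) {
    vals <- vapply(seq_len(nrow(tt)), function(i) {
      i0 <- floor((tt$choice_s[i] + off) * fs) + 1
      i1 <- ceiling((tt$choice_s[i] + off + window) * fs)
      if (i0 < 1 || i1 > n) return(NA_real_)
      mean(trace$samples[i0:i1]) - base[i]
    }, numeric(1))
    ok <- is.finite(vals)
    if (sum(ok) < n_bins * 4) return(NA_real_)
    bins <- bin_trials(vals[ok], "quantile", k = n_bins)
    sub <- tt[ok, , drop = FALSE]
    crit <- vapply(levels(bins), function(l)
      tryCatch(.sdt_from_trials(sub[bins == l, , drop = FALSE])$criterion,
               error = function(e) NA_real_), numeric(1))
    mp <- vapply(levels(bins), function(l) mean(vals[ok][bins == l]),
                 numeric(1))
    if (anyNA(crit)) return(NA_real_)
    stats::cor(mp, crit)
  }, numeric(1))
  data.frame(time = offsets + window / 2, r = r)
}

#' Paired permutation test
#'
#' Nonparametric test for a difference between paired observations (or of
#' one sample against zero): the labels of each pair are randomly permuted
#' (sign flips of the paired differences), the group mean difference is
#' recomputed, and the p-value is the fraction of permutations whose mean
#' difference is at least as extreme as the observed one (absolute value for
#' the two-sided default). For small samples the full set of `2^n` sign
#' patterns can be enumerated exactly.
#'
#' @param a,b paired numeric vectors (`b` defaults to zeros).
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param two_sided compare `|mean|`; otherwise tests `mean(a) > mean(b)`.
#' @param exact enumerate all sign patterns (requires `length(a) <= 20`).
#' @return The permutation p-value.
#' @export
paired_permutation_test <- function(a, b = NULL, n_perm = 10000, seed = 1,
                                    two_sided = TRUE, exact = FALSE) {
  if (is.null(b)) b <- numeric(length(a))
  stopifnot(length(a) == length(b))
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  stat <- if (two_sided) abs else identity
  if (exact) {
    stopifnot(n <= 20)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.numeric(signs %*% d) / n
    return(mean(stat(perm) >= stat(obs)))
  }
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  perm <- as.numeric(flips %*% d) / n
  mean(stat(perm) >= stat(obs))
}
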