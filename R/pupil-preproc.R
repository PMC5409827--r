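#' Pupil trace container
#'
#' A uniformly sampled pupil diameter time series, possibly spanning several
#' task blocks, together with blink and saccade event lists (detection itself
#' is an input: events come from the eye-tracker's own algorithms).
#'
#' @param samples numeric vector of pupil diameter (arbitrary units, or
#'   percent modulation after [to_percent_signal()]).
#' @param sample_rate sampling rate in Hz.
#' @param blocks data.frame with columns `block`, `start_s`, `end_s` giving
#'   block boundaries; defaults to one block covering the whole trace.
#' @param blink_events,saccade_events data.frames with `start_s`, `end_s`.
#' @param raw_block_means per-block means of the raw (pre-filtering) trace;
#'   filled in by [interpolate_blinks()] and used by [to_percent_signal()].
#' @return An object of class `pupil_trace`.
#' @export
pupil_trace <- function(samples, sample_rate,
                        blocks = NULL,
                        blink_events = data.frame(start_s = numeric(),
                                                  end_s = numeric()),
                        saccade_events = data.frame(start_s = numeric(),
                                                    end_s = numeric()),
                        raw_block_means = NULL) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  dur <- length(samples) / sample_rate
  if (is.null(blocks))
    blocks <- data.frame(block = 1L, start_s = 0, end_s = dur)
  ev_ok <- function(ev) nrow(ev) == 0 ||
    (all(ev$start_s <= ev$end_s) && all(ev$end_s <= dur + 1 / sample_rate) &&
       all(ev$start_s >= 0))
  if (!ev_ok(blink_events) || !ev_ok(saccade_events))
    stop("events must lie within the trace duration")
  structure(list(samples = samples, sample_rate = sample_rate,
                 blocks = blocks, blink_events = blink_events,
                 saccade_events = saccade_events,
                 raw_block_means = raw_block_means),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat("Pupil trace:", length(x$samples), "samples @", x$sample_rate, "Hz (",
      format(length(x$samples) / x$sample_rate, digits = 4), "s ),",
      nrow(x$blocks), "block(s),", nrow(x$blink_events), "blinks,",
      nrow(x$saccade_events), "saccades\n")
  invisible(x)
}

#' Sample times of a pupil trace
#' @param trace a [pupil_trace()].
#' @return Numeric vector of sample times in seconds (first sample at 0).
#' @export
trace_time <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sample_rate
}

# indices of blocks for each sample
.block_index <- function(trace) {
  t <- trace_time(trace)
  idx <- rep(NA_integer_, length(t))
  for (b in seq_len(nrow(trace$blocks)))
    idx[t >= trace$blocks$start_s[b] &
          t < trace$blocks$end_s[b] + 1e-9] <- b
  if (anyNA(idx)) idx[is.na(idx)] <- 1L
  idx
}

# merge overlapping [start, end] windows (rows sorted by start)
.merge_windows <- function(w) {
  if (nrow(w) <= 1) return(w)
  w <- w[order(w$start_s), , drop = FALSE]
  out <- w[1, , drop = FALSE]
  for (i in 2:nrow(w)) {
    j <- nrow(out)
    if (w$start_s[i] <= out$end_s[j]) {
      out$end_s[j] <- max(out$end_s[j], w$end_s[i])
    } else out <- rbind(out, w[i, , drop = FALSE])
  }
  out
}

#' Linearly interpolate pupil samples across blinks
#'
#' Replaces samples within a margin-expanded window around each blink
#' (default: 150 ms before blink onset to 150 ms after blink offset) by
#' linear interpolation between the boundary samples. Overlapping expanded
#' windows are merged; windows spanning a trace edge are clamped and filled
#' flat from the nearest valid sample (with a warning). Also records the
#' per-block raw means used later for percent-signal conversion.
#'
#' @param trace a [pupil_trace()].
#' @param margin_s margin in seconds added on both sides of each blink.
#' @return The interpolated `pupil_trace`.
#' @export
interpolate_blinks <- function(trace, margin_s = 0.15) {
  x <- trace$samples
  fs <- trace$sample_rate
  n <- length(x)
  ev <- trace$blink_events
  if (nrow(ev) > 0) {
    w <- data.frame(start_s = ev$start_s - margin_s,
                    end_s = ev$end_s + margin_s)
    w <- .merge_windows(w)
    for (i in seq_len(nrow(w))) {
      i0 <- floor(w$start_s[i] * fs) + 1     # last sample before window
      i1 <- ceiling(w$end_s[i] * fs) + 1     # first sample after window
      lo <- max(i0, 1); hi <- min(i1, n)
      if (i0 < 1 && i1 > n) {
        warning("blink window spans entire trace; leaving unchanged")
        next
      }
      if (i0 < 1) {
        warning("blink window clipped at trace start; flat extrapolation")
        x[1:hi] <- x[hi]
      } else if (i1 > n) {
        warning("blink window clipped at trace end; flat extrapolation")
        x[lo:n] <- x[lo]
      } else {
        idx <- i0:i1
        x[idx] <- x[i0] + (x[i1] - x[i0]) * (idx - i0) / (i1 - i0)
      }
    }
  }
  out <- trace
  out$samples <- x
  bi <- .block_index(out)
  out$raw_block_means <- tapply(x, bi, mean)[as.character(seq_len(nrow(trace$blocks)))]
  out
}

#' Band-pass filter a pupil trace
#'
#' Third-order Butterworth band-pass (default passband 0.01-6 Hz), applied
#' zero-phase (forward-backward) by default so no lag is introduced into the
#' timing of task-evoked responses. The DC component lies outside the
#' passband and is removed.
#'
#' @param trace a [pupil_trace()].
#' @param low,high passband edges in Hz.
#' @param order filter order.
#' @param zero_phase apply forward-backward (`signal::filtfilt`); `FALSE`
#'   gives a single causal pass.
#' @return The filtered `pupil_trace`.
#' @export
bandpass_filter <- function(trace, low = 0.01, high = 6, order = 3,
                            zero_phase = TRUE) {
  fs <- trace$sample_rate
  if (fs <= 2 * high)
    stop("sample rate must exceed twice the upper passband edge")
  dur <- length(trace$samples) / fs
  tc <- 1 / (2 * pi * low)
  if (dur < 3 * tc)
    stop("trace shorter than ~3 time constants of the high-pass edge (",
         format(3 * tc, digits = 3), " s needed)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- trace$samples - mean(trace$samples)
  y <- if (zero_phase) signal::filtfilt(bf, x)
       else as.numeric(signal::filter(bf, x))
  out <- trace
  out$samples <- y
  out
}

#' Estimate and remove pupil responses to blinks and saccades
#'
#' The pupil responds to blinks and saccades themselves; these stereotyped
#' responses are first estimated by finite-impulse-response deconvolution
#' (a least-squares estimate of the mean post-event response over a fixed
#' window, all event types estimated jointly) and then removed from the
#' trace by multiple linear regression of the trace on the event series
#' convolved with the estimated responses.
#'
#' @param trace a [pupil_trace()], already interpolated and filtered.
#' @param window_s post-event estimation window in seconds.
#' @param min_events event types with fewer events than this are skipped
#'   with a warning.
#' @return A list with `trace` (the residual `pupil_trace`) and `irfs`, a
#'   list with `blink_irf`, `saccade_irf` (numeric vectors at the trace
#'   sample rate) and `estimation_window_s`.
#' @export
remove_artifact_responses <- function(trace, window_s = 6, min_events = 5) {
  fs <- trace$sample_rate
  n <- length(trace$samples)
  m <- round(window_s * fs)
  types <- list(blink = trace$blink_events, saccade = trace$saccade_events)
  use <- vapply(types, function(ev) {
    nrow(ev) >= min_events
  }, logical(1))
  for (ty in names(types)[!use]) {
    if (nrow(types[[ty]]) > 0)
      warning("fewer than ", min_events, " ", ty,
              " events; skipping removal for that type")
  }
  irfs <- list(blink_irf = rep(0, m), saccade_irf = rep(0, m),
               estimation_window_s = window_s)
  if (!any(use)) return(list(trace = trace, irfs = irfs))

  # FIR deconvolution design, sparse (one column per lag per used type)
  used <- names(types)[use]
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(used)) {
    ev <- types[[used[k]]]
    onsets <- pmin(pmax(round(ev$end_s * fs) + 1, 1), n)  # response follows event offset
    for (o in onsets) {
      lags <- o:min(o + m - 1, n)
      ii <- c(ii, lags)
      jj <- c(jj, (k - 1) * m + seq_along(lags))
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n, m * length(used)))
  X <- cbind(Matrix::sparseMatrix(i = seq_len(n), j = rep(1, n), x = 1), X)
  XtX <- as.matrix(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, trace$samples))
  beta <- tryCatch(solve(XtX, Xty),
                   error = function(e) qr.coef(qr(XtX), Xty))[-1]
  beta[is.na(beta)] <- 0
  for (k in seq_along(used)) {
    irfs[[paste0(used[k], "_irf")]] <- beta[(k - 1) * m + seq_len(m)]
  }

  # regress out the event series convolved with the estimated responses
  regs <- sapply(seq_along(used), function(k) {
    stick <- numeric(n)
    ev <- types[[used[k]]]
    onsets <- pmin(pmax(round(ev$end_s * fs) + 1, 1), n)
    stick[onsets] <- stick[onsets] + 1
    conv <- stats::convolve(stick, rev(beta[(k - 1) * m + seq_len(m)]),
                            type = "open")[seq_len(n)]
    conv
  })
  fit <- stats::lm.fit(cbind(1, regs), trace$samples)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  out <- trace
  out$samples <- trace$samples - as.numeric(regs %*% coefs[-1])
  list(trace = out, irfs = irfs)
}

#' Convert a pupil trace to percent signal change
#'
#' Converts the trace, per block, to units of modulation around the block
#' mean: the current per-block mean of the samples is subtracted and the
#' result expressed as a percentage of the reference block mean `m`. The
#' reference is the mean of the interpolated, pre-band-pass trace
#' (band-passed traces have ~zero mean), as recorded by
#' [interpolate_blinks()]; it can also be supplied directly. By
#' construction the output has zero mean within every block.
#'
#' @param trace a [pupil_trace()].
#' @param block_means optional reference per-block means; defaults to the
#'   stored raw block means, falling back to the current per-block means.
#' @return The converted `pupil_trace` (in percent modulation).
#' @export
to_percent_signal <- function(trace, block_means = NULL) {
  bi <- .block_index(trace)
  cur <- as.numeric(tapply(trace$samples, bi, mean)[as.character(seq_len(nrow(trace$blocks)))])
  if (is.null(block_means)) block_means <- trace$raw_block_means
  if (is.null(block_means)) block_means <- cur
  block_means <- as.numeric(block_means)
  if (any(!is.finite(block_means)) || any(block_means <= 0))
    stop("block mean must be positive for percent-signal conversion")
  out <- trace
  out$samples <- 100 * (trace$samples - cur[bi]) / block_means[bi]
  out
}

#' Full pupil preprocessing pipeline
#'
#' Applies, in order: (i) linear blink interpolation, (ii) Butterworth
#' band-pass, (iii) deconvolution-based removal of blink/saccade responses,
#' (iv) conversion to percent signal change around the per-block mean of the
#' pre-filtering trace.
#'
#' @param trace a raw [pupil_trace()].
#' @param margin_s blink interpolation margin (s).
#' @param low,high,order band-pass settings.
#' @param zero_phase forward-backward filtering flag.
#' @param artifact_window_s deconvolution window (s); `NULL` skips step iii.
#' @return A list with `trace` (preprocessed, percent modulation) and
#'   `irfs` (estimated artifact responses, or `NULL`).
#' @export
preprocess_pupil <- function(trace, margin_s = 0.15, low = 0.01, high = 6,
                             order = 3, zero_phase = TRUE,
                             artifact_window_s = 6) {
  t1 <- interpolate_blinks(trace, margin_s = margin_s)
  t2 <- bandpass_filter(t1, low = low, high = high, order = order,
                        zero_phase = zero_phase)
  irfs <- NULL
  if (!is.null(artifact_window_s)) {
    ar <- remove_artifact_responses(t2, window_s = artifact_window_s)
    t2 <- ar$trace
    irfs <- ar$irfs
  }
  t3 <- to_percent_signal(t2, block_means = t1$raw_block_means)
  list(trace = t3, irfs = irfs)
}
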