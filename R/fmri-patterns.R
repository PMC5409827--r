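#' Trial-by-voxel pattern set
#'
#' Container for single-trial multi-voxel fMRI response patterns with voxel
#' metadata and trial labels.
#'
#' @param responses trials x voxels numeric matrix (scalar response
#'   amplitudes, percent signal change).
#' @param voxel_meta data.frame with one row per voxel: coordinates (`x`,
#'   `y`, `z`, mm), `hemisphere` (`"L"`/`"R"`) and `partner` (index of the
#'   homotopic voxel in the other hemisphere; must be an involution).
#' @param labels data.frame with one row per trial: `stimulus` (+1/-1),
#'   `choice` (1/0), `block_orientation` (`"CW"`/`"CCW"`), optionally
#'   `session`.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(responses, voxel_meta, labels) {
  responses <- as.matrix(responses)
  stopifnot(nrow(voxel_meta) == ncol(responses),
            nrow(labels) == nrow(responses))
  if (!is.null(voxel_meta$partner)) {
    p <- voxel_meta$partner
    if (!all(p[p] == seq_along(p)))
      stop("homotopic partner mapping must be an involution")
  }
  structure(list(responses = responses, voxel_meta = voxel_meta,
                 labels = labels), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("Pattern set:", nrow(x$responses), "trials x", ncol(x$responses),
      "voxels\n")
  invisible(x)
}

#' Trial-by-ROI response set
#'
#' @param responses trials x ROI numeric matrix of scalar responses.
#' @param roi_names ROI names (columns of `responses`).
#' @param nuisance optional per-trial nuisance series (e.g. fourth-ventricle
#'   signal).
#' @param tpr optional per-trial task-evoked pupil response.
#' @return An object of class `roi_response_set`.
#' @export
roi_response_set <- function(responses, roi_names = colnames(responses),
                             nuisance = NULL, tpr = NULL) {
  responses <- as.matrix(responses)
  colnames(responses) <- roi_names
  stopifnot(all(is.finite(responses)))
  structure(list(responses = responses, roi_names = roi_names,
                 nuisance = nuisance, tpr = tpr),
            class = "roi_response_set")
}

#' Scalar task-evoked fMRI response from a trial epoch
#'
#' Mean response over the decision/post-decision interval (2 to 12 s from
#' cue) minus the mean over the pre-decision baseline (-2 s up to, but not
#' including, 2 s from cue; the half-open baseline keeps the two windows
#' disjoint). RT-driven variance should be removed afterwards via
#' [residualize()].
#'
#' @param epochs trials x timepoints matrix (or a single epoch vector).
#' @param times timepoint latencies relative to cue (s).
#' @param response_window,baseline_window intervals relative to cue (s).
#' @return Numeric vector of scalar amplitudes, one per trial.
#' @export
trial_scalar_response <- function(epochs, times,
                                  response_window = c(2, 12),
                                  baseline_window = c(-2, 2)) {
  if (is.null(dim(epochs))) epochs <- matrix(epochs, nrow = 1)
  stopifnot(ncol(epochs) == length(times))
  ri <- times >= response_window[1] & times <= response_window[2]
  bi <- times >= baseline_window[1] & times < baseline_window[2]
  rowMeans(epochs[, ri, drop = FALSE]) - rowMeans(epochs[, bi, drop = FALSE])
}

#' Per-voxel t-statistic contrasting two conditions
#'
#' Welch-type two-sample statistic per voxel:
#' `t = (mean_a - mean_b) / sqrt(sem_a^2 + sem_b^2)`. The printed form of
#' the selection statistic in the source methods is typographically
#' ambiguous; `literal = TRUE` gives the alternative reading
#' `mean_a / sem_a - mean_b / sem_b`.
#'
#' @param X trials x voxels matrix.
#' @param in_a logical vector marking condition-A trials (the rest are B).
#' @param literal use the per-condition normalized-mean difference instead
#'   of the Welch form.
#' @return Numeric vector of t-values per voxel.
#' @export
voxel_tstat <- function(X, in_a, literal = FALSE) {
  A <- X[in_a, , drop = FALSE]; B <- X[!in_a, , drop = FALSE]
  ma <- colMeans(A); mb <- colMeans(B)
  sema <- apply(A, 2, stats::sd) / sqrt(nrow(A))
  semb <- apply(B, 2, stats::sd) / sqrt(nrow(B))
  if (literal) ma / sema - mb / semb
  else (ma - mb) / sqrt(sema^2 + semb^2)
}

#' Select the most condition-preferring voxels
#'
#' Returns the `n_pos` voxels with the most positive and `n_neg` with the
#' most negative t-values; ties are broken by voxel index (deterministic).
#'
#' @param tvals per-voxel t-values.
#' @param n_pos,n_neg counts of positive- and negative-preferring voxels.
#' @return Integer vector of selected voxel indices.
#' @export
select_voxels <- function(tvals, n_pos = 50, n_neg = 50) {
  nv <- length(tvals)
  stopifnot(n_pos + n_neg <= nv)
  ord <- order(-tvals, seq_len(nv))
  sort(c(ord[seq_len(n_pos)], rev(ord)[seq_len(n_neg)]))
}

#' Leave-one-out template-correlation pattern response
#'
#' Quantifies the orientation- or choice-specific component of single-trial
#' response patterns as the Pearson correlation with a condition-difference
#' 'template', built with the held-out trial excluded on every iteration.
#' Orientation mode: the template is the difference between the mean
#' patterns of the block's own signal orientation and the other orientation
#' (built from signal trials), so a genuine stimulus response scores
#' positive on both CW and CCW blocks. Choice mode: the template is the
#' mean 'yes' pattern minus the mean 'no' pattern.
#'
#' @param patterns a [pattern_set()].
#' @param selection voxel indices to use (e.g. from [select_voxels()] on
#'   independent data); `NULL` uses all voxels.
#' @param mode `"orientation"` or `"choice"`.
#' @return Numeric vector: one correlation score per trial.
#' @export
template_response <- function(patterns, selection = NULL,
                              mode = c("orientation", "choice")) {
  mode <- match.arg(mode)
  X <- patterns$responses
  if (!is.null(selection)) X <- X[, selection, drop = FALSE]
  lab <- patterns$labels
  n <- nrow(X)
  if (mode == "orientation") {
    grp <- ifelse(lab$stimulus == 1, as.character(lab$block_orientation), NA)
    g_cw <- which(!is.na(grp) & grp == "CW")
    g_ccw <- which(!is.na(grp) & grp == "CCW")
    if (length(g_cw) < 2 || length(g_ccw) < 2)
      stop("need at least 2 signal trials per orientation to build templates")
    s_cw <- colSums(X[g_cw, , drop = FALSE])
    s_ccw <- colSums(X[g_ccw, , drop = FALSE])
    vapply(seq_len(n), function(i) {
      scw <- s_cw; sccw <- s_ccw
      ncw <- length(g_cw); nccw <- length(g_ccw)
      if (i %in% g_cw) { scw <- scw - X[i, ]; ncw <- ncw - 1 }
      if (i %in% g_ccw) { sccw <- sccw - X[i, ]; nccw <- nccw - 1 }
      own_cw <- lab$block_orientation[i] == "CW"
      templ <- if (own_cw) scw / ncw - sccw / nccw else sccw / nccw - scw / ncw
      stats::cor(X[i, ], templ)
    }, numeric(1))
  } else {
    g_yes <- which(lab$choice == 1)
    g_no <- which(lab$choice == 0)
    if (length(g_yes) < 2 || length(g_no) < 2)
      stop("need at least 2 trials per choice to build templates")
    s_yes <- colSums(X[g_yes, , drop = FALSE])
    s_no <- colSums(X[g_no, , drop = FALSE])
    vapply(seq_len(n), function(i) {
      sy <- s_yes; sn <- s_no
      ny <- length(g_yes); nn <- length(g_no)
      if (i %in% g_yes) { sy <- sy - X[i, ]; ny <- ny - 1 }
      if (i %in% g_no) { sn <- sn - X[i, ]; nn <- nn - 1 }
      stats::cor(X[i, ], sy / ny - sn / nn)
    }, numeric(1))
  }
}

#' Per-voxel logistic regression of choice on response amplitude
#'
#' Fits `P(yes) = plogis(beta0 + beta1 * A)` per voxel by maximum
#' likelihood. When `stimulus` is supplied the fit is performed separately
#' for signal+noise and noise trials and the coefficient maps averaged,
#' isolating the effect of choice from that of the stimulus. Perfect
#' separation is flagged (capped-iteration fit) rather than returned as a
#' silently huge coefficient.
#'
#' @param X trials x voxels matrix (a single voxel may be given as a
#'   vector).
#' @param choices 1/0 per trial.
#' @param stimulus optional +1/-1 per trial for condition-wise averaging.
#' @return List with `beta0`, `beta1` (per voxel) and `separation` (logical
#'   per voxel).
#' @export
choice_logistic <- function(X, choices, stimulus = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  fit_one <- function(a, y) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, a), y,
                                           family = stats::binomial(),
                                           control = list(maxit = 50)))
    sep <- !fit$converged || any(abs(fit$coefficients) > 20 / max(stats::sd(a), 1e-12))
    c(fit$coefficients, sep)
  }
  run <- function(rows) {
    t(apply(X[rows, , drop = FALSE], 2, fit_one, y = choices[rows]))
  }
  if (is.null(stimulus)) {
    res <- run(seq_len(nrow(X)))
    list(beta0 = res[, 1], beta1 = res[, 2], separation = res[, 3] > 0)
  } else {
    r1 <- run(which(stimulus == 1))
    r0 <- run(which(stimulus == -1))
    list(beta0 = (r1[, 1] + r0[, 1]) / 2, beta1 = (r1[, 2] + r0[, 2]) / 2,
         separation = (r1[, 3] + r0[, 3]) > 0)
  }
}

#' Hemispheric lateralization of voxel responses
#'
#' Expresses each voxel's response relative to its homotopic counterpart in
#' the contralateral hemisphere: `response - partner response`. For
#' subjects whose response mapping is 'yes' to the right hand
#' (`flip = TRUE`), voxels are first swapped with their partners so that
#' lateralization is expressed with respect to the hand used for 'yes' in
#' all subjects and values pool across subjects without cancellation.
#' Applying the flip twice is the identity.
#'
#' @param patterns a [pattern_set()] with a `partner` column in
#'   `voxel_meta`.
#' @param flip swap each voxel with its homotopic partner first.
#' @return trials x voxels matrix of lateralization values.
#' @export
lateralize <- function(patterns, flip = FALSE) {
  X <- patterns$responses
  p <- patterns$voxel_meta$partner
  if (is.null(p)) stop("voxel_meta must contain a 'partner' column")
  if (flip) X <- X[, p, drop = FALSE]
  X - X[, p, drop = FALSE]
}

#' Searchlight choice classification map
#'
#' For every center voxel, selects the sphere of voxels whose centers lie
#' strictly within `radius_mm`, trains a linear maximum-margin classifier
#' (LIBSVM, cost `cost`) on all trials but one, predicts the held-out
#' trial's choice, and assigns the mean leave-one-trial-out classification
#' score to the center. When `stimulus` is supplied the score is computed
#' separately per stimulus condition and averaged, removing stimulus
#' information from the map. Spheres with fewer than `min_voxels` voxels
#' are masked (`NA`). The scheme contains no randomness, so re-runs are
#' identical.
#'
#' @param patterns a [pattern_set()] with voxel coordinates in
#'   `voxel_meta` (`x`, `y`, `z`, mm).
#' @param choices 1/0 per trial (defaults to the pattern labels).
#' @param stimulus optional +1/-1 per trial.
#' @param radius_mm searchlight radius.
#' @param cost SVM cost parameter.
#' @param min_voxels minimum sphere size.
#' @return Numeric vector: mean cross-validated classification score per
#'   center voxel.
#' @export
searchlight_choice <- function(patterns, choices = patterns$labels$choice,
                               stimulus = NULL, radius_mm = 10, cost = 1,
                               min_voxels = 3) {
  X <- patterns$responses
  vm <- patterns$voxel_meta
  coords <- as.matrix(vm[, c("x", "y", "z")])
  nv <- ncol(X)
  loo_acc <- function(rows, cols) {
    y <- factor(choices[rows])
    if (nlevels(y) < 2) return(NA_real_)
    hits <- vapply(seq_along(rows), function(i) {
      ytr <- y[-i]
      if (nlevels(droplevels(ytr)) < 2) return(NA)
      m <- e1071::svm(X[rows[-i], cols, drop = FALSE], ytr,
                      kernel = "linear", cost = cost, scale = FALSE)
      pred <- predict(m, X[rows[i], cols, drop = FALSE])
      as.character(pred) == as.character(y[i])
    }, logical(1))
    mean(hits, na.rm = TRUE)
  }
  vapply(seq_len(nv), function(v) {
    d2 <- colSums((t(coords) - coords[v, ])^2)
    sphere <- which(d2 < radius_mm^2)
    if (length(sphere) < min_voxels) return(NA_real_)
    if (is.null(stimulus)) {
      loo_acc(seq_len(nrow(X)), sphere)
    } else {
      mean(c(loo_acc(which(stimulus == 1), sphere),
             loo_acc(which(stimulus == -1), sphere)))
    }
  }, numeric(1))
}

# area under the ROC curve via the rank statistic (equals the criterion-sweep
# construction and Mann-Whitney U / (n1*n0))
.auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC predictive index with condition balancing
#'
#' Area under the ROC curve for predicting a binary trial variable (signal
#' presence or choice) from single-trial scores; 0.5 is chance. To remove
#' the influence of a correlated second factor, the index is computed
#' separately within each level of `balance_by` and averaged (e.g. the
#' stimulus-predictive index is averaged over 'yes' and 'no' trials; the
#' choice-predictive index over signal+noise and noise trials).
#'
#' @param scores numeric per-trial scores.
#' @param labels logical (or 1/0) per trial: the class to predict.
#' @param balance_by optional per-trial factor to balance over.
#' @return The predictive index in `[0, 1]`.
#' @export
roc_predictive_index <- function(scores, labels, balance_by = NULL) {
  labels <- as.logical(labels)
  if (is.null(balance_by)) return(.auc(scores, labels))
  levs <- unique(balance_by)
  mean(vapply(levs, function(l) {
    sel <- balance_by == l
    .auc(scores[sel], labels[sel])
  }, numeric(1)), na.rm = TRUE)
}

#' Combine ROI responses into a single trial-wise signal
#'
#' Computes regression weights of a target variable on trial-wise ROI
#' responses (multiple linear regression against a continuous target such
#' as TPR, or multiple logistic regression against a binary target such as
#' choice) and returns the weighted sum of the ROI responses, z-scored.
#'
#' @param R trials x ROI matrix.
#' @param target per-trial target.
#' @param mode `"linear"` or `"logistic"`.
#' @return List with `weights` (per ROI, no intercept) and `signal`
#'   (z-scored combined per-trial signal).
#' @export
combine_signals <- function(R, target, mode = c("linear", "logistic")) {
  mode <- match.arg(mode)
  R <- as.matrix(R)
  w <- if (mode == "linear") {
    stats::lm.fit(cbind(1, R), target)$coefficients[-1]
  } else {
    suppressWarnings(stats::glm.fit(cbind(1, R), target,
                                    family = stats::binomial()))$coefficients[-1]
  }
  w[is.na(w)] <- 0
  s <- as.numeric(R %*% w)
  if (stats::sd(s) > 0) s <- (s - mean(s)) / stats::sd(s)
  list(weights = w, signal = s)
}

#' Trial-wise correlation between TPR and brainstem ROI responses
#'
#' Pearson correlation between the task-evoked pupil response and each
#' ROI's task-evoked fMRI response, after removing (via linear regression)
#' the effect of signal presence from both, and fourth-ventricle signal
#' fluctuations from the ROI responses. The partial correlation
#' additionally removes the responses of all other ROIs from both the ROI
#' and the TPR, isolating each ROI's unique coupling.
#'
#' @param roi a [roi_response_set()] (its `nuisance` series, if present, is
#'   regressed out of the ROI responses).
#' @param tpr per-trial TPR values (defaults to `roi$tpr`).
#' @param stimulus per-trial +1/-1 stimulus codes.
#' @return data.frame with `roi`, `r`, `partial_r`.
#' @export
tpr_brainstem_correlation <- function(roi, tpr = roi$tpr, stimulus) {
  R <- roi$responses
  if (!is.null(roi$nuisance))
    R <- apply(R, 2, residualize, covariate = roi$nuisance)
  R <- apply(R, 2, residualize, covariate = stimulus)
  tpr <- residualize(tpr, stimulus)
  k <- ncol(R)
  r <- vapply(seq_len(k), function(i) stats::cor(tpr, R[, i]), numeric(1))
  pr <- vapply(seq_len(k), function(i) {
    others <- R[, -i, drop = FALSE]
    res_roi <- stats::lm.fit(cbind(1, others), R[, i])$residuals
    res_tpr <- stats::lm.fit(cbind(1, others), tpr)$residuals
    stats::cor(res_tpr, res_roi)
  }, numeric(1))
  data.frame(roi = colnames(R), r = r, partial_r = pr,
             row.names = NULL)
}

#' Binned linear fit of residual choice-specific responses on TPR
#'
#' Removes the physical stimulus from the trial-wise choice-specific
#' (cortical) signal via linear regression, averages the residual signal
#' and the TPR within `n_bins` equally populated TPR bins, and fits
#' `Ctx = beta0 + beta1 * TPR` across bin means. A non-zero slope indicates
#' a stimulus-independent arousal modulation of the choice signal.
#'
#' @param ctx per-trial choice-specific signal.
#' @param tpr per-trial TPR.
#' @param stimulus per-trial +1/-1 codes to residualize out.
#' @param n_bins number of TPR bins.
#' @return Named numeric vector `c(beta0, beta1)` with attribute
#'   `bin_means` (data.frame of bin-mean TPR and Ctx).
#' @export
bin_linear_fit <- function(ctx, tpr, stimulus, n_bins = 5) {
  ctx_res <- residualize(ctx, stimulus)
  bins <- bin_trials(tpr, "quantile", k = n_bins)
  mtpr <- tapply(tpr, bins, mean)
  mctx <- tapply(ctx_res, bins, mean)
  co <- stats::coef(stats::lm(mctx ~ mtpr))
  out <- c(beta0 = unname(co[1]), beta1 = unname(co[2]))
  attr(out, "bin_means") <- data.frame(tpr = as.numeric(mtpr),
                                       ctx = as.numeric(mctx))
  out
}

#' Probability-ranked brainstem ROI mask
#'
#' Brainstem nuclei are small relative to functional voxels; ROI masks are
#' therefore thresholded to retain, per ROI, exactly the `n_voxels` voxels
#' with the largest probability of containing the structure (only voxels
#' with non-zero probability are eligible; ties broken by voxel index).
#' ROI time series are then computed as the probability-weighted average of
#' the retained voxels.
#'
#' @param prob numeric vector of per-voxel probabilities for one ROI.
#' @param n_voxels number of voxels to retain.
#' @return List with `voxels` (indices) and `weights` (their
#'   probabilities).
#' @export
brainstem_roi_mask <- function(prob, n_voxels = 12) {
  eligible <- which(prob > 0)
  if (length(eligible) < n_voxels)
    stop("fewer than ", n_voxels, " voxels with non-zero probability")
  ord <- eligible[order(-prob[eligible], eligible)]
  vox <- sort(ord[seq_len(n_voxels)])
  list(voxels = vox, weights = prob[vox])
}

#' Probability-weighted ROI time series
#'
#' @param X samples (or trials) x voxels matrix.
#' @param mask a mask from [brainstem_roi_mask()].
#' @return Numeric vector: weighted average across the mask's voxels.
#' @export
roi_weighted_mean <- function(X, mask) {
  w <- mask$weights / sum(mask$weights)
  as.numeric(X[, mask$voxels, drop = FALSE] %*% w)
}
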