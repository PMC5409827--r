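#' Pipeline configuration
#'
#' A serializable configuration that fully determines an end-to-end run on
#' synthetic data: ground-truth parameters, stage toggles and the
#' control-analysis variants (running without RT residualization, or
#' splitting trials by pre-cue baseline pupil size instead of TPR).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param stages character subset of `c("pupil", "sdt", "ddm", "patterns")`.
#' @param rt_residualization remove RT-driven variance from TPR (and fMRI)
#'   amplitudes; `FALSE` reproduces the no-residualization control.
#' @param baseline_split key analyses on the pre-cue baseline pupil size
#'   instead of the task-evoked response.
#' @param binning_scheme,binning_k trial binning, see [bin_trials()].
#' @param ddm_free,ddm_shared,ddm_fixed,ddm_n_starts DDM fit layout (the
#'   default frees drift rate and drift criterion per bin and shares the
#'   structural parameters, keeping runs light).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param ... overrides passed to [ground_truth()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("pupil", "sdt", "ddm", "patterns"),
                            rt_residualization = TRUE,
                            baseline_split = FALSE,
                            binning_scheme = "three_40_20_40",
                            binning_k = 5,
                            ddm_free = c("v", "dc"),
                            ddm_shared = c("a", "z", "t0"),
                            ddm_fixed = list(sv = 0, c = 1),
                            ddm_n_starts = 2,
                            out_dir = NULL, ...) {
  stopifnot(all(stages %in% c("pupil", "sdt", "ddm", "patterns")))
  gt_args <- list(...)
  gt_args$seed <- seed
  structure(list(seed = seed, stages = stages,
                 rt_residualization = rt_residualization,
                 baseline_split = baseline_split,
                 binning_scheme = binning_scheme, binning_k = binning_k,
                 ddm_free = ddm_free, ddm_shared = ddm_shared,
                 ddm_fixed = ddm_fixed, ddm_n_starts = ddm_n_starts,
                 out_dir = out_dir, gt_args = gt_args),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in order: synthetic generation, pupil
#' preprocessing and TPR quantification, TPR-binned signal-detection
#' analysis, drift-diffusion fitting (low vs high bin), and fMRI pattern
#' analyses (stimulus-/choice-predictive indices, brainstem TPR
#' correlations, combined signals). Stage outputs are pure functions of
#' the configuration, so the same configuration yields an identical report.
#'
#' @param config a [pipeline_config()].
#' @return A report list (class `pipeline_report`) with elements
#'   `provenance`, `trial_table`, `tpr`, `bins`, `sdt`, `ddm`, `patterns`
#'   (stages not run are `NULL`). If `config$out_dir` is set, CSV/JSON
#'   artifacts are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gt <- do.call(ground_truth, config$gt_args)
  trial_table <- generate_trial_table(gt)
  report <- list(provenance = list(
    config_hash = .config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("arousalbias")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")))
  report$trial_table <- trial_table

  tpr <- NULL; bins <- NULL
  if (any(c("pupil", "sdt", "ddm") %in% config$stages)) {
    raw <- generate_pupil_trace(trial_table, gt)
    prep <- preprocess_pupil(raw)
    tpr <- compute_tpr(prep$trace, trial_table,
                       rt_residualize = config$rt_residualization)
    report$tpr <- tpr
    split_values <- if (config$baseline_split) tpr$baseline else tpr$amplitude
    ok <- which(tpr$included & is.finite(split_values))
    bins <- rep(NA_character_, nrow(trial_table))
    bins[ok] <- as.character(bin_trials(split_values[ok],
                                        scheme = config$binning_scheme,
                                        k = config$binning_k))
    report$bins <- bins
  }

  if ("sdt" %in% config$stages) {
    ok <- which(!is.na(bins))
    trials <- trial_table[ok, ]
    bl <- factor(bins[ok])
    sdt_tab <- do.call(rbind, lapply(levels(bl), function(l) {
      s <- .sdt_from_trials(trials[bl == l, , drop = FALSE])
      data.frame(bin = l, hit_rate = s$hit_rate, fa_rate = s$fa_rate,
                 dprime = s$dprime, criterion = s$criterion)
    }))
    frac_yes <- balanced_fraction_yes(trials, bl, n_resamples = 200,
                                      seed = config$seed)
    report$sdt <- list(per_bin = sdt_tab, balanced_fraction_yes = frac_yes)
  }

  if ("ddm" %in% config$stages) {
    extreme <- !is.na(bins) & bins %in% c("low", "high", "bin1",
                                          paste0("bin", config$binning_k))
    fit <- fit_ddm(trial_table[extreme, ], bins[extreme],
                   free = config$ddm_free, shared = config$ddm_shared,
                   fixed = config$ddm_fixed, n_starts = config$ddm_n_starts,
                   seed = config$seed)
    report$ddm <- fit
  }

  if ("patterns" %in% config$stages) {
    pats <- generate_patterns(trial_table, gt)
    ok <- which(!is.na(trial_table$choice))
    sub <- pattern_set(pats$responses[ok, , drop = FALSE], pats$voxel_meta,
                       pats$labels[ok, , drop = FALSE])
    or_scores <- template_response(sub, mode = "orientation")
    ch_scores <- template_response(sub, mode = "choice")
    stim_idx <- roc_predictive_index(or_scores, sub$labels$stimulus == 1,
                                     balance_by = sub$labels$choice)
    choice_idx <- roc_predictive_index(ch_scores, sub$labels$choice == 1,
                                       balance_by = sub$labels$stimulus)
    amp <- if (is.null(tpr)) stats::rnorm(nrow(trial_table)) else tpr$amplitude
    roi <- generate_roi_responses(trial_table, ifelse(is.finite(amp), amp, 0), gt)
    bs <- tpr_brainstem_correlation(roi, stimulus = trial_table$stimulus)
    neuromod <- intersect(c("LC", "SN", "VTA", "BF_sept", "BF_subl"),
                          colnames(roi$responses))
    comb <- combine_signals(roi$responses[, neuromod, drop = FALSE],
                            roi$tpr, mode = "linear")
    report$patterns <- list(stimulus_predictive_index = stim_idx,
                            choice_predictive_index = choice_idx,
                            brainstem = bs,
                            combined_neuromod_weights = comb$weights)
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(report$trial_table, file.path(out_dir, "trial_table.csv"))
  if (!is.null(report$tpr))
    utils::write.csv(report$tpr, file.path(out_dir, "tpr.csv"),
                     row.names = FALSE)
  summary <- list(provenance = report$provenance)
  if (!is.null(report$sdt)) {
    utils::write.csv(report$sdt$per_bin, file.path(out_dir, "sdt_per_bin.csv"),
                     row.names = FALSE)
    summary$balanced_fraction_yes <- as.list(report$sdt$balanced_fraction_yes)
  }
  if (!is.null(report$ddm)) {
    utils::write.csv(report$ddm$params, file.path(out_dir, "ddm_params.csv"),
                     row.names = FALSE)
    summary$ddm <- list(loglik = report$ddm$loglik, aic = report$ddm$aic,
                        bic = report$ddm$bic)
  }
  if (!is.null(report$patterns)) {
    summary$patterns <- report$patterns[c("stimulus_predictive_index",
                                          "choice_predictive_index")]
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$provenance$seed, ", config",
      substr(x$provenance$config_hash, 1, 8), ")\n")
  cat("  trials:", nrow(x$trial_table), "\n")
  if (!is.null(x$sdt)) {
    cat("  SDT per bin:\n")
    print(x$sdt$per_bin, digits = 3)
  }
  if (!is.null(x$ddm)) print(x$ddm)
  if (!is.null(x$patterns))
    cat("  stimulus-predictive index:",
        format(x$patterns$stimulus_predictive_index, digits = 3),
        " choice-predictive index:",
        format(x$patterns$choice_predictive_index, digits = 3), "\n")
  invisible(x)
}
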