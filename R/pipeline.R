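# End-to-end orchestration: synthetic or file-based cohort -> clean
# HRV -> feature tables -> FCBF selection -> kappa-optimized MLPs ->
# evaluation reports.

#' Pipeline configuration
#'
#' Collects every stage default in one validated object. Defaults are
#' the analysis-protocol constants: 15 min edge trimming, NN bounds
#' `[0.33, 1.5]` s with a 0.66 s successive-difference limit, 3 h
#' minimum duration, 3.41 Hz resampling, 1024-sample Hamming windows
#' with 50% overlap and a 2048-point FFT, 64 phase-histogram bins,
#' FCBF over 1000 bootstrap replicates with a strict more-than-500
#' vote rule, the 680-point MLP grid, and severity cutoffs 1, 5 and
#' 10 e/h.
#'
#' @param trim Minutes trimmed at each recording end.
#' @param min_hours Minimum retained recording duration, hours.
#' @param fs Resampling rate, Hz.
#' @param window_len,overlap,nfft Segmentation parameters.
#' @param n_phase_bins Phase-entropy histogram bins.
#' @param fcbf_B,fcbf_threshold Bootstrap replicates and vote
#'   threshold for feature selection.
#' @param mlp_B Bootstrap replicates per MLP grid point.
#' @param mlp_grid Hyperparameter grid (default the full 680-point
#'   grid; reduce for exploratory runs).
#' @param cutoffs AHI severity cutoffs for the binary classifiers.
#' @param seed Base RNG seed for selection and training.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(trim = 15, min_hours = 3, fs = 3.41,
                            window_len = 1024L, overlap = 0.5, nfft = 2048L,
                            n_phase_bins = 64L, fcbf_B = 1000L,
                            fcbf_threshold = 500L, mlp_B = 50L,
                            mlp_grid = bisphrv::mlp_grid(),
                            cutoffs = c(1, 5, 10), seed = 1L) {
  cfg <- list(trim = trim, min_hours = min_hours, fs = fs,
              plan = segment_plan(window_len, overlap, nfft),
              n_phase_bins = as.integer(n_phase_bins),
              fcbf_B = as.integer(fcbf_B),
              fcbf_threshold = as.integer(fcbf_threshold),
              mlp_B = as.integer(mlp_B), mlp_grid = mlp_grid,
              cutoffs = cutoffs, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a cohort
#'
#' Pre-processes every subject (trim, artifact rejection,
#' minimum-duration check, uniform resampling), extracts both feature
#' catalogs, performs bootstrap FCBF selection per catalog, trains one
#' kappa-optimized MLP per catalog and severity cutoff, and evaluates
#' each model on the training subjects (or a held-out set when
#' `holdout` indices are given). Subjects failing any stage are
#' reported and dropped.
#'
#' @param cohort Output of [simulate_cohort()], or a list with
#'   `manifest` (data frame with `subject_id`, `ahi`, `age`, and
#'   optionally `path`) and `rr` (named list of `rr_series`; read from
#'   `manifest$path` when absent).
#' @param config A [pipeline_config()].
#' @param holdout Optional integer indices of subjects reserved for
#'   evaluation.
#' @param out_dir Optional directory for stage artifacts (feature CSV,
#'   selection JSON, evaluation JSON).
#' @return A list with `features` (data frame), `selection`,
#'   `models`, `reports`, `dropped`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), holdout = NULL,
                         out_dir = NULL) {
  manifest <- cohort$manifest
  req <- c("subject_id", "ahi", "age")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stop("manifest is missing column(s): ",
                         paste(miss, collapse = ", "))
  rr <- cohort$rr
  if (is.null(rr)) {
    if (is.null(manifest$path)) stop("cohort has neither rr series nor paths")
    rr <- lapply(manifest$path, read_rr)
    names(rr) <- manifest$subject_id
  }

  signals <- list()
  dropped <- character(0)
  for (sid in manifest$subject_id) {
    res <- tryCatch(
      preprocess_subject(rr[[sid]], trim = config$trim,
                         min_hours = config$min_hours, fs = config$fs),
      error = function(e) {
        warning("subject ", sid, " dropped in preprocessing: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(res)) dropped <- c(dropped, sid) else signals[[sid]] <- res$hrv
  }

  features <- extract_feature_table(signals, manifest, catalog = "both",
                                    plan = config$plan,
                                    n_phase_bins = config$n_phase_bins)
  catalogs <- list(classic = catalog_columns("classic"),
                   specific = catalog_columns("specific"))

  sel_y <- factor(features$severity,
                  levels = c("none", "mild", "moderate", "severe"))
  selection <- lapply(names(catalogs), function(cat) {
    bootstrap_select(features[catalogs[[cat]]], droplevels(sel_y),
                     B = config$fcbf_B, threshold = config$fcbf_threshold,
                     seed = config$seed)
  })
  names(selection) <- names(catalogs)

  train_idx <- seq_len(nrow(features))
  if (!is.null(holdout)) train_idx <- setdiff(train_idx, holdout)

  models <- list()
  reports <- list()
  for (cat in names(catalogs)) {
    sel <- selection[[cat]]$selected
    if (length(sel) == 0) {
      # fall back to the top-voted features so the stage stays exercisable
      sel <- names(sort(selection[[cat]]$votes, decreasing = TRUE))[1:3]
    }
    for (cut in config$cutoffs) {
      y <- as.integer(features$ahi >= cut)
      key <- sprintf("%s_cutoff%g", cat, cut)
      if (length(unique(y[train_idx])) < 2) {
        warning("cutoff ", cut, ": single-class training labels; model skipped",
                call. = FALSE)
        next
      }
      xm <- as.matrix(features[sel])
      opt <- optimize_hyperparams(xm[train_idx, , drop = FALSE], y[train_idx],
                                  grid = config$mlp_grid, B = config$mlp_B,
                                  seed = config$seed)
      fit <- train_mlp(xm[train_idx, , drop = FALSE], y[train_idx],
                       n_hidden = opt$best$n_hidden, lambda = opt$best$lambda,
                       seed = config$seed)
      eval_idx <- if (is.null(holdout)) train_idx else holdout
      post <- predict_posterior(fit, xm[eval_idx, , drop = FALSE])
      models[[key]] <- list(fit = fit, best = opt$best, selected = sel)
      reports[[key]] <- if (length(unique(y[eval_idx])) == 2) {
        diagnostic_metrics(y[eval_idx], post)
      } else NULL
    }
  }

  out <- list(features = features, selection = selection, models = models,
              reports = reports, dropped = dropped, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  sel <- lapply(result$selection, function(s)
    list(votes = as.list(s$votes), selected = s$selected, B = s$B,
         threshold = s$threshold))
  jsonlite::write_json(sel, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rep <- lapply(result$reports, function(r) {
    if (is.null(r)) return(NULL)
    list(se = r$se, sp = r$sp, acc = r$acc, auc = r$auc,
         threshold = r$threshold)
  })
  jsonlite::write_json(rep, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
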