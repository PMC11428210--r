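# End-to-end orchestration of the two experiments: k-fold cross-validated
# segmentation (tolerance-window metrics per fold plus a pooled confusion
# matrix) and the cycle-count classification sweep.

#' Validated run configuration
#'
#' Collects every tunable of the pipeline in one validated list; unknown
#' names are rejected.
#'
#' @param ... Name-value overrides of the defaults (see
#'   [pcg_run_defaults()]).
#' @return A `pcg_run_config` list.
#' @export
pcg_run_config <- function(...) {
  cfg <- pcg_run_defaults()
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pcg_run_config")
}

#' Default run configuration values
#' @return Named list of defaults.
#' @export
pcg_run_defaults <- function() {
  list(
    seed = 1L,
    # simulated data
    n_per_class = 20L, duration_s = 5, snr_db = 15,
    # segmentation experiment
    seg_folds = 6L, frame_rate = 50, tol_s1 = 100, tol_s2 = 80,
    model = tblstm_config(),
    # classification experiment
    cycle_range = 1:6, class_folds = 6L, n_trees = 100L,
    retained_variance = 0.95, class_duration_s = 12,
    use_true_labels = TRUE
  )
}

dataset_features <- function(dataset, frame_rate = 50) {
  feats <- lapply(dataset$records, function(r) build_feature_matrix(r$signal,
                                                                    frame_rate))
  labs <- mapply(function(r, f) {
    labels_to_frames(r$labels, nrow(f$values), frame_rate)
  }, dataset$records, feats, SIMPLIFY = FALSE)
  list(features = feats, labels = labs)
}

#' Cross-validated segmentation experiment
#'
#' Trains the TBLSTM segmenter on `folds - 1` folds of a labelled dataset
#' and scores the held-out fold with tolerance-window metrics; reports one
#' row per fold plus the mean row, and the pooled row-normalized confusion
#' matrix.
#'
#' @param dataset A `pcg_dataset` (simulated or user-supplied records with
#'   `signal` and `labels` fields).
#' @param config A [pcg_run_config] (or list of overrides).
#' @param verbose Print progress.
#' @return List with `report` (data frame of per-fold and mean macro
#'   metrics), `per_state` (pooled per-state metrics), `confusion`,
#'   `models` (one per fold).
#' @export
run_segmentation_experiment <- function(dataset, config = pcg_run_config(),
                                        verbose = FALSE) {
  config <- pcg_run_config(config)
  classes <- dataset$manifest$class
  prep <- dataset_features(dataset, config$frame_rate)
  set.seed(config$seed)
  fold <- assign_folds(classes, config$seg_folds)

  rows <- list(); models <- list(); pooled <- NULL
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    mcfg <- config$model
    mcfg$seed <- config$model$seed + f
    model <- train_segmenter(prep$features[tr], prep$labels[tr], mcfg)
    counts <- lapply(te, function(i) {
      post <- predict_states(model, prep$features[[i]])
      pred <- decode_states(post)
      tolerance_match(pred, prep$labels[[i]], config$tol_s1, config$tol_s2)
    })
    fold_counts <- pool_counts(counts)
    pooled <- if (is.null(pooled)) fold_counts else pool_counts(pooled, fold_counts)
    m <- compute_metrics(fold_counts)
    rows[[f]] <- data.frame(fold = f, t(m$macro), row.names = NULL)
    models[[f]] <- model
    if (verbose) message(sprintf("fold %d: macro F1 %.4f", f, m$macro["F1"]))
  }
  report <- do.call(rbind, rows)
  report <- rbind(report,
                  data.frame(fold = NA, t(colMeans(report[-1])),
                             row.names = NULL))
  pm <- compute_metrics(pooled)
  conf <- pooled$confusion
  rs <- rowSums(conf)
  conf[rs > 0, ] <- conf[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(report = report, per_state = pm$per_state, macro = pm$macro,
       confusion = conf, models = models)
}

#' Cycle-count classification experiment
#'
#' Simulates (or reuses) a balanced dataset and runs the cross-validated
#' cycle sweep; optionally writes the per-cycle-count summary CSV and an F1-vs-cycles
#' plot (overall, ASD, VSD).
#'
#' @param config A [pcg_run_config] (or list of overrides).
#' @param dataset Optional existing `pcg_dataset` (default: simulate one
#'   from the config).
#' @param out_dir Optional output directory for `sweep.csv` and
#'   `f1_curves.pdf`.
#' @return The `cycle_sweep` object (invisibly carries `records`).
#' @export
run_classification_experiment <- function(config = pcg_run_config(),
                                          dataset = NULL, out_dir = NULL) {
  config <- pcg_run_config(config)
  if (is.null(dataset)) {
    dataset <- simulate_dataset(config$n_per_class,
                                duration_s = config$class_duration_s,
                                seed = config$seed)
  }
  sweep <- cross_validate_cycles(dataset, cycle_range = config$cycle_range,
                                 k = config$class_folds, seed = config$seed,
                                 n_trees = config$n_trees,
                                 retained_variance = config$retained_variance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sweep$summary, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(out_dir, "f1_curves.pdf"), width = 6, height = 4)
    on.exit(grDevices::dev.off())
    s <- sweep$summary
    graphics::matplot(s$cycle, cbind(s$F1, s$F1_ASD, s$F1_VSD), type = "b",
                      pch = 16, lty = 1, xlab = "cardiac cycles per fragment",
                      ylab = "F1", ylim = c(0, 1))
    graphics::legend("bottomright", c("overall", "ASD", "VSD"), col = 1:3,
                     lty = 1, pch = 16, bty = "n")
  }
  sweep
}
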