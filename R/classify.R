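# Random-forest multi-classification of N-cycle fragments (normal/ASD/VSD)
# and the six-fold cross-validated sweep over the number of cardiac cycles
# per fragment.

#' Train a random forest classifier
#'
#' Thin, seeded wrapper around `randomForest` with a 100-tree
#' default. Deterministic given the seed.
#'
#' @param X Feature matrix (rows = fragments).
#' @param y Class labels (coerced to factor); at least two classes required.
#' @param n_trees Number of trees (default 100).
#' @param seed RNG seed.
#' @return A `randomForest` model.
#' @export
train_rf <- function(X, y, n_trees = 100L, seed = 1L) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (n_trees < 10L) {
    message("random forest with only ", n_trees, " tree(s)")
  }
  set.seed(seed)
  randomForest::randomForest(x = as.matrix(X), y = y, ntree = n_trees)
}

#' Multi-class metrics from classified records
#'
#' One-vs-rest sensitivity, precision and F1 per class, macro averages, the
#' overall accuracy, and the macro-average accuracy (mean per-class recall,
#' i.e. balanced accuracy) — which equals overall accuracy exactly when the
#' class counts are balanced.
#'
#' @param records Data frame with columns `true_class` and `pred_class`.
#' @return List with `per_class` data frame, `macro` named vector (`Se`,
#'   `P`, `F1`), `overall_accuracy`, `macro_accuracy`.
#' @export
evaluate_multiclass <- function(records) {
  stopifnot(all(c("true_class", "pred_class") %in% names(records)))
  y <- as.character(records$true_class)
  p <- as.character(records$pred_class)
  classes <- sort(unique(y))
  per <- lapply(classes, function(cl) {
    tp <- sum(y == cl & p == cl)
    fp <- sum(y != cl & p == cl)
    fn <- sum(y == cl & p != cl)
    se <- if (tp + fn > 0) tp / (tp + fn) else 0
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (se + pr > 0) 2 * se * pr / (se + pr) else 0
    data.frame(class = cl, n = tp + fn, Se = se, P = pr, F1 = f1)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       macro = c(Se = mean(per$Se), P = mean(per$P), F1 = mean(per$F1)),
       overall_accuracy = mean(y == p),
       macro_accuracy = mean(per$Se))
}

# stratified record-level fold assignment: shuffled records are dealt
# round-robin, continuing the rotation across classes, so fold sizes differ
# by at most one both within every class and overall
assign_folds <- function(classes, k) {
  fold <- integer(length(classes))
  pos <- 0L
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  fold
}

#' Fragment feature table for a dataset at a given cycle count
#'
#' Cuts every record into overlapping `n_cycles`-cycle fragments (stride one
#' cycle) using ground-truth cycle boundaries and extracts the 78-dimension
#' aggregated MFCC+delta features per fragment.
#'
#' @param dataset A `pcg_dataset` from [simulate_dataset()].
#' @param n_cycles Cycles per fragment.
#' @return Data frame: `record`, `class`, feature columns; zero rows if no
#'   record has enough cycles.
#' @export
fragment_feature_table <- function(dataset, n_cycles) {
  feats <- list(); rec_idx <- integer(0); rec_cls <- character(0)
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    cyc <- true_cycles(rec)
    if (nrow(cyc) < n_cycles) next
    frags <- suppressWarnings(fragment_by_cycles(rec$signal, cyc, n_cycles))
    for (fr in frags) {
      feats[[length(feats) + 1L]] <- fragment_features(fr)
      rec_idx <- c(rec_idx, i); rec_cls <- c(rec_cls, rec$class)
    }
  }
  if (!length(feats)) return(data.frame())
  cbind(data.frame(record = rec_idx, class = rec_cls,
                   stringsAsFactors = FALSE),
        as.data.frame(do.call(rbind, feats)))
}

#' Cross-validated sweep over the number of cycles per fragment
#'
#' For each cycle count, fragments are rebuilt, features re-extracted, and a
#' PCA + random-forest pipeline is fitted per fold. Folds are split at the
#' RECORDING level (stratified by class) so overlapping fragments of one
#' recording never straddle a train/test split.
#'
#' @param dataset A `pcg_dataset`.
#' @param cycle_range Integer vector of cycle counts (default 1:9).
#' @param k Number of folds (default 6).
#' @param seed Seed driving fold assignment and forest training.
#' @param n_trees Trees per forest.
#' @param retained_variance PCA retained-variance fraction.
#' @return A `cycle_sweep`: list with `summary` (data frame `cycle`, `Acc`,
#'   `Se`, `P`, `F1`, `F1_ASD`, `F1_VSD`, `F1_normal`) and `records`
#'   (per-fragment predictions with fold and cycle-count metadata).
#' @export
cross_validate_cycles <- function(dataset, cycle_range = 1:9, k = 6L,
                                  seed = 1L, n_trees = 100L,
                                  retained_variance = 0.95) {
  classes <- dataset$manifest$class
  if (length(unique(classes)) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (length(classes) < k) stop("fewer recordings than folds", call. = FALSE)
  set.seed(seed)
  fold <- assign_folds(classes, k)

  per_cls_f1 <- function(ev, cl) {
    i <- match(cl, ev$per_class$class)
    if (is.na(i)) NA_real_ else ev$per_class$F1[i]
  }
  summary_rows <- list()
  all_records <- list()
  for (nc in cycle_range) {
    tab <- fragment_feature_table(dataset, nc)
    if (!nrow(tab)) {
      warning("no fragments at n_cycles = ", nc, call. = FALSE)
      next
    }
    feat_cols <- setdiff(names(tab), c("record", "class"))
    X <- as.matrix(tab[feat_cols])
    frag_fold <- fold[tab$record]
    preds <- character(nrow(tab))
    for (f in sort(unique(frag_fold))) {
      tr <- frag_fold != f; te <- frag_fold == f
      if (!any(te)) next
      pca <- pca_fit_transform(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                               retained_variance = retained_variance)
      rf <- train_rf(pca$train, tab$class[tr], n_trees = n_trees,
                     seed = (seed %% 1000000L) * 1000L + f * 16L + nc)
      preds[te] <- as.character(stats::predict(rf, pca$test))
    }
    rec <- data.frame(record = tab$record, fold = frag_fold, n_cycles = nc,
                      true_class = tab$class, pred_class = preds,
                      stringsAsFactors = FALSE)
    ev <- evaluate_multiclass(rec)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      cycle = nc, n_fragments = nrow(rec),
      Acc = ev$overall_accuracy, Se = ev$macro["Se"], P = ev$macro["P"],
      F1 = ev$macro["F1"],
      F1_ASD = per_cls_f1(ev, "asd"), F1_VSD = per_cls_f1(ev, "vsd"),
      F1_normal = per_cls_f1(ev, "normal"), row.names = NULL)
    all_records[[length(all_records) + 1L]] <- rec
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 records = do.call(rbind, all_records),
                 k = k, seed = seed),
            class = "cycle_sweep")
}

#' @export
print.cycle_sweep <- function(x, ...) {
  cat(sprintf("<cycle_sweep> %d-fold CV, seed %d\n", x$k, x$seed))
  s <- x$summary
  s[-1] <- round(s[-1], 4)
  print(s)
  invisible(x)
}
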