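# Pairwise cluster-comparison learning: comparison matrix construction,
# extremely randomized trees training, leave-complex-out cross-validation
# and win-count ranking.

#' Extremely randomized trees configuration
#'
#' Defaults follow the protocol: 3000 trees, bootstrapped samples, Gini
#' impurity splits, `floor(sqrt(p))` candidate features per split (33 for
#' the 1092-feature comparison records), maximum depth 100, minimum one
#' sample per leaf, out-of-bag generalization estimate.
#'
#' @param n_trees Number of trees.
#' @param bootstrap Bootstrap samples (with replacement)?
#' @param max_depth Maximum tree depth.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param max_features Candidate features per split; `NULL` means
#'   `floor(sqrt(p))`.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @param orientation Prediction-time pair orientation: `"canonical"`
#'   evaluates each unordered pair once (lower cluster id in slot C1),
#'   `"both"` averages the two orderings.
#' @return List of class `ert_config`.
#' @export
ert_config <- function(n_trees = 3000, bootstrap = TRUE, max_depth = 100,
                       min_samples_leaf = 1, max_features = NULL,
                       seed = 1, orientation = c("canonical", "both")) {
  stopifnot(n_trees >= 1)
  structure(
    list(n_trees = n_trees, bootstrap = bootstrap, max_depth = max_depth,
         min_samples_leaf = min_samples_leaf, max_features = max_features,
         seed = as.integer(seed),
         orientation = match.arg(orientation)),
    class = "ert_config")
}

#' Default number of candidate split features
#'
#' `floor(sqrt(n_features))`: 33 for 1092-dimensional comparison records.
#'
#' @param n_features Total feature count.
#' @return Integer.
#' @export
ert_max_features <- function(n_features) max(1L, floor(sqrt(n_features)))

#' Build the pairwise cluster-comparison matrix
#'
#' For every target, every unordered pair of clusters becomes one record:
#' the feature vectors of the two clusters are concatenated (slot C1 then
#' slot C2, names prefixed accordingly; the lower cluster id takes slot
#' C1), and the label is 1 if the C1 cluster's minimum member LRMSD is
#' strictly lower than the C2 cluster's, else 0. With 546 features per
#' cluster each record has 1092 features. Pairs with exactly equal minimum
#' LRMSD are excluded with a warning; cross-target pairs are never formed;
#' targets with fewer than two clusters are skipped with a warning.
#'
#' @param targets Named list (by target id); each element is a list with
#'   `features` (list of `cluster_features`) and `min_lrmsd` (numeric named
#'   by cluster id, `NULL` in label-free mode).
#' @return Object of class `comparison_set`: `features` (record x feature
#'   matrix), `meta` (target_id, cluster_n, cluster_m, label),
#'   `feature_names`.
#' @export
build_comparison_matrix <- function(targets) {
  rows <- list()
  meta <- list()
  fnames <- NULL
  for (tid in names(targets)) {
    tgt <- targets[[tid]]
    fl <- tgt$features
    if (length(fl) < 2) {
      warning("target ", tid, " has < 2 clusters; skipped", call. = FALSE)
      next
    }
    cids <- vapply(fl, `[[`, integer(1), "cluster_id")
    names(fl) <- as.character(cids)
    ml <- tgt$min_lrmsd
    if (!is.null(ml)) ml <- ml[as.character(cids)]
    base_names <- fl[[1]]$feature_names
    if (is.null(fnames))
      fnames <- c(paste0("C1_", base_names), paste0("C2_", base_names))
    pairs <- utils::combn(sort(cids), 2)
    for (p in seq_len(ncol(pairs))) {
      n_id <- pairs[1, p]; m_id <- pairs[2, p]
      if (!is.null(ml)) {
        if (ml[as.character(n_id)] == ml[as.character(m_id)]) {
          warning("target ", tid, ": clusters ", n_id, "/", m_id,
                  " have equal min LRMSD; pair excluded", call. = FALSE)
          next
        }
        lab <- as.integer(ml[as.character(n_id)] < ml[as.character(m_id)])
      } else lab <- NA_integer_
      rows[[length(rows) + 1]] <-
        c(fl[[as.character(n_id)]]$values, fl[[as.character(m_id)]]$values)
      meta[[length(meta) + 1]] <-
        data.frame(target_id = tid, cluster_n = n_id, cluster_m = m_id,
                   label = lab, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no comparison records could be built")
  features <- do.call(rbind, rows)
  colnames(features) <- fnames
  structure(
    list(features = features, meta = do.call(rbind, meta),
         feature_names = fnames),
    class = "comparison_set")
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set: %d records x %d features, %d target(s)>\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$meta$target_id))))
  invisible(x)
}

subset_comparisons <- function(cs, idx) {
  structure(
    list(features = cs$features[idx, , drop = FALSE],
         meta = cs$meta[idx, , drop = FALSE],
         feature_names = cs$feature_names),
    class = "comparison_set")
}

select_features <- function(cs, keep) {
  structure(
    list(features = cs$features[, keep, drop = FALSE],
         meta = cs$meta, feature_names = keep),
    class = "comparison_set")
}

#' Train the extremely randomized trees pair classifier
#'
#' Fits a probability forest with `ranger` (extra-trees splitting, Gini
#' impurity, bootstrapped samples) on the comparison records and reports
#' the out-of-bag accuracy as generalization estimate.
#'
#' @param cs A labelled `comparison_set`.
#' @param config An `ert_config`.
#' @return Object of class `ranker_model`: `forest`, `config`,
#'   `feature_names`, `oob_accuracy`, `n_records`.
#' @export
train_ert <- function(cs, config = ert_config()) {
  labs <- cs$meta$label
  if (anyNA(labs)) stop("comparison set is unlabelled")
  if (length(labs) < 2 || length(unique(labs)) < 2)
    stop("training needs records of both classes")
  p <- ncol(cs$features)
  mtry <- config$max_features %||% ert_max_features(p)
  forest <- ranger::ranger(
    x = cs$features, y = factor(labs, levels = c(0, 1)),
    num.trees = config$n_trees,
    mtry = min(mtry, p),
    min.node.size = config$min_samples_leaf,
    max.depth = config$max_depth,
    splitrule = "extratrees", num.random.splits = 1,
    replace = config$bootstrap, sample.fraction = 1,
    probability = TRUE, importance = "impurity",
    oob.error = TRUE, seed = config$seed, num.threads = 1,
    verbose = FALSE)
  oob_p1 <- forest$predictions[, "1"]
  ok <- !is.na(oob_p1)
  oob_acc <- mean((oob_p1[ok] > 0.5) == (labs[ok] == 1))
  structure(
    list(forest = forest, config = config,
         feature_names = cs$feature_names,
         oob_accuracy = oob_acc, n_records = length(labs)),
    class = "ranker_model")
}

#' @export
print.ranker_model <- function(x, ...) {
  cat(sprintf(
    "<ranker_model: %d trees on %d records x %d features, OOB accuracy %.3f>\n",
    x$config$n_trees, x$n_records, length(x$feature_names), x$oob_accuracy))
  invisible(x)
}

# class-1 probability for a feature matrix
predict_prob1 <- function(model, features) {
  if (ncol(features) != length(model$feature_names))
    stop("feature dimension mismatch: model expects ",
         length(model$feature_names), ", got ", ncol(features))
  pr <- stats::predict(model$forest, data = features,
                       num.threads = 1, verbose = FALSE)$predictions
  pr[, "1"]
}

#' Confusion counts of binary predictions
#'
#' @param truth,pred Vectors of 0/1 labels.
#' @return List with tp, fp, fn, tn.
#' @export
confusion_counts <- function(truth, pred) {
  list(tp = sum(truth == 1 & pred == 1),
       fp = sum(truth == 0 & pred == 1),
       fn = sum(truth == 1 & pred == 0),
       tn = sum(truth == 0 & pred == 0))
}

#' Classification metrics from confusion counts
#'
#' Recall TP/(TP+FN), precision TP/(TP+FP), F1 (harmonic mean of the two)
#' and accuracy (TP+TN)/total. Ratios with a zero denominator are 0 by
#' convention.
#'
#' @param counts List with tp, fp, fn, tn (see [confusion_counts()]).
#' @return Named numeric: recall, precision, f1, accuracy.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    total <- tp + fp + fn + tn
    if (total == 0) stop("all-zero confusion counts")
    safe <- function(num, den) if (den == 0) 0 else num / den
    recall <- safe(tp, tp + fn)
    precision <- safe(tp, tp + fp)
    f1 <- safe(2 * precision * recall, precision + recall)
    c(recall = recall, precision = precision, f1 = f1,
      accuracy = (tp + tn) / total)
  })
}

#' Leave-complex-out cross-validation
#'
#' One fold per target: the fold's test set holds exactly that target's
#' comparison records, the training set all others. Returns per-fold and
#' mean +/- sd recall, precision, F1 and accuracy, plus per-fold feature
#' importances (used by recursive feature elimination) and optionally the
#' per-fold fitted models.
#'
#' @param cs A labelled `comparison_set` with >= 2 targets.
#' @param config An `ert_config`.
#' @param keep_models Keep the per-fold `ranker_model`s?
#' @return List of class `lco_cv`: `folds` (data.frame of per-target
#'   metrics), `mean`, `sd`, `importance` (feature x fold matrix),
#'   `models` (if kept), `train_targets` (per fold).
#' @export
leave_complex_out_cv <- function(cs, config = ert_config(),
                                 keep_models = FALSE) {
  tids <- unique(cs$meta$target_id)
  if (length(tids) < 2) stop("need >= 2 targets for leave-complex-out CV")
  fold_rows <- list()
  importances <- list()
  models <- list()
  train_targets <- list()
  for (tid in tids) {
    test_idx <- cs$meta$target_id == tid
    train <- subset_comparisons(cs, !test_idx)
    test <- subset_comparisons(cs, test_idx)
    m <- train_ert(train, config)
    p1 <- predict_prob1(m, test$features)
    pred <- as.integer(p1 > 0.5)
    truth <- test$meta$label
    flagged <- length(unique(truth)) < 2
    met <- classification_metrics(confusion_counts(truth, pred))
    fold_rows[[tid]] <- data.frame(
      target_id = tid, n_test = length(truth),
      single_class_test = flagged, t(met), stringsAsFactors = FALSE)
    importances[[tid]] <- m$forest$variable.importance
    train_targets[[tid]] <- setdiff(tids, tid)
    if (keep_models) models[[tid]] <- m
  }
  folds <- do.call(rbind, fold_rows)
  rownames(folds) <- NULL
  metr <- folds[, c("recall", "precision", "f1", "accuracy")]
  structure(
    list(folds = folds,
         mean = colMeans(metr), sd = apply(metr, 2, stats::sd),
         importance = do.call(cbind, importances),
         models = if (keep_models) models,
         train_targets = train_targets),
    class = "lco_cv")
}

#' @export
print.lco_cv <- function(x, ...) {
  cat(sprintf("<lco_cv: %d folds>\n", nrow(x$folds)))
  print(round(rbind(mean = x$mean, sd = x$sd), 3))
  invisible(x)
}

#' Rank clusters by predicted win counts
#'
#' Every unordered cluster pair is evaluated once in canonical slot order
#' (lower cluster id in C1; with `orientation = "both"` in the model
#' config, both orderings are averaged). A predicted label 1 is a win for
#' the C1 cluster, else the C2 cluster wins. Clusters are ranked by
#' descending win count; ties are broken by descending summed class-1
#' probability margin, then ascending cluster id.
#'
#' @param model A `ranker_model`.
#' @param feature_list List of `cluster_features` for one target
#'   (>= 2 clusters).
#' @return data.frame of class `rank_result`: cluster_id, wins, rank,
#'   tie_break_key. Win counts over k clusters sum to k(k-1)/2.
#' @export
rank_clusters <- function(model, feature_list) {
  if (length(feature_list) < 2) stop("need >= 2 clusters to rank")
  if (2 * length(feature_list[[1]]$values) != length(model$feature_names))
    stop("feature dimension mismatch: model expects ",
         length(model$feature_names), " per record, clusters provide ",
         length(feature_list[[1]]$values), " each")
  cids <- vapply(feature_list, `[[`, integer(1), "cluster_id")
  names(feature_list) <- as.character(cids)
  cids <- sort(cids)
  pairs <- utils::combn(cids, 2)
  fwd <- t(apply(pairs, 2, function(p)
    c(feature_list[[as.character(p[1])]]$values,
      feature_list[[as.character(p[2])]]$values)))
  colnames(fwd) <- model$feature_names
  p1 <- predict_prob1(model, fwd)
  if (model$config$orientation == "both") {
    rev <- t(apply(pairs, 2, function(p)
      c(feature_list[[as.character(p[2])]]$values,
        feature_list[[as.character(p[1])]]$values)))
    colnames(rev) <- model$feature_names
    p1 <- (p1 + (1 - predict_prob1(model, rev))) / 2
  }
  wins <- stats::setNames(integer(length(cids)), cids)
  margin <- stats::setNames(numeric(length(cids)), cids)
  for (k in seq_len(ncol(pairs))) {
    a <- as.character(pairs[1, k]); b <- as.character(pairs[2, k])
    if (p1[k] > 0.5) wins[a] <- wins[a] + 1L else wins[b] <- wins[b] + 1L
    margin[a] <- margin[a] + (2 * p1[k] - 1)
    margin[b] <- margin[b] - (2 * p1[k] - 1)
  }
  ord <- order(-wins, -margin, cids)
  out <- data.frame(cluster_id = cids, wins = as.integer(wins),
                    tie_break_key = margin)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_along(ord)
  out <- out[order(out$rank), c("cluster_id", "wins", "rank",
                                "tie_break_key")]
  rownames(out) <- NULL
  class(out) <- c("rank_result", "data.frame")
  out
}
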