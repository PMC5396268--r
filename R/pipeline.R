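# End-to-end orchestration: clash filter -> truncation -> clustering ->
# (enrichment) -> standardisation -> features -> comparisons -> CV /
# training -> ranking, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Protocol constants: 10 A clustering cutoff, 3 A enrichment
#' sub-clustering cutoff, strict "> 5 models" cluster-size cutoff (with a
#' per-target exemption list for small near-native clusters), the ERT
#' configuration, and the pruning/sweep step sizes.
#'
#' @param cluster_cutoff GROMOS clustering cutoff, Angstrom.
#' @param sub_cutoff Enrichment sub-clustering cutoff, Angstrom.
#' @param size_cutoff Strict lower bound on cluster size.
#' @param always_include Named list: target id -> cluster ids exempt from
#'   the size cutoff.
#' @param ert An [ert_config()].
#' @param rfe_step Features removed per RFE round.
#' @param transform_step Dimension grid step for transform sweeps.
#' @param count_enrichment_in_size Count enrichment poses in the SIZE
#'   feature? Default `FALSE`: enrichment poses only densify descriptor
#'   distributions.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cluster_cutoff = 10, sub_cutoff = 3,
                            size_cutoff = 5, always_include = list(),
                            ert = ert_config(), rfe_step = 10,
                            transform_step = 10,
                            count_enrichment_in_size = FALSE) {
  stopifnot(cluster_cutoff > 0, sub_cutoff > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Prepare one target: filter, cluster, featurise, label
#'
#' Runs the per-target stages: clash filtering, truncation to the shared
#' residue set (jointly with the reference when labels are wanted),
#' pairwise-LRMSD GROMOS clustering, size cutoff, optional enrichment
#' attachment, per-target standardisation, cluster feature construction
#' and (when a reference is available) per-cluster minimum-LRMSD labels
#' computed over original members only.
#'
#' @param target List with `target_id`, `models`, `descriptors` (raw
#'   `descriptor_table`), optional `reference` and optional `enrichment`
#'   (named list: cluster id -> enrichment `complex_model`s).
#' @param pcfg A `pipeline_config`.
#' @param with_labels Compute per-cluster minimum LRMSD? Requires
#'   `target$reference`.
#' @return List of class `prepared_target`: `target_id`, `clusters`,
#'   `features`, `min_lrmsd`, `model_lrmsd`, `counts`.
#' @export
prepare_target <- function(target, pcfg = pipeline_config(),
                           with_labels = !is.null(target$reference)) {
  tid <- target$target_id
  fc <- filter_clashed(target$models)
  kept <- fc$kept
  if (length(kept) == 0) stop("target ", tid, ": all models clashed")
  reference <- target$reference
  if (with_labels) {
    if (is.null(reference)) stop("labels requested but no reference")
    tm <- truncate_to_shared_residues(c(kept, list(reference)))
    kept <- tm[-length(tm)]
    reference <- tm[[length(tm)]]
  } else {
    kept <- truncate_to_shared_residues(kept)
  }
  dm <- pairwise_lrmsd_matrix(kept)
  clusters <- gromos_cluster(dm, pcfg$cluster_cutoff)
  n_before <- length(clusters)
  clusters <- apply_size_cutoff(clusters, pcfg$size_cutoff,
                                pcfg$always_include[[tid]] %||% integer(0))
  enrich_models <- list()
  if (!is.null(target$enrichment)) {
    clusters <- lapply(clusters, function(cl) {
      pool <- target$enrichment[[as.character(cl$cluster_id)]]
      if (is.null(pool)) return(cl)
      pool <- filter_clashed(pool)$kept
      reps <- select_enrichment_representatives(pool, pcfg$sub_cutoff)
      if (length(reps) == 0) return(cl)
      enrich_models <<- c(enrich_models, reps)
      attach_enrichment(cl, reps)
    })
  }
  used_ids <- unlist(lapply(clusters, function(cl)
    c(cl$member_ids, cl$enrichment_ids)))
  desc <- target$descriptors
  if (length(enrich_models) > 0) {
    # enrichment poses are part of the standardisation population
    extra <- setdiff(used_ids, rownames(desc$values))
    if (length(extra) > 0)
      stop("no descriptor rows for enrichment model(s): ",
           paste(utils::head(extra, 3), collapse = ", "))
  }
  missing <- setdiff(used_ids, rownames(desc$values))
  if (length(missing) > 0)
    stop("target ", tid, ": no descriptor rows for ",
         paste(utils::head(missing, 3), collapse = ", "))
  sub <- new_descriptor_table(
    tid, desc$values[intersect(rownames(desc$values), used_ids), ,
                     drop = FALSE])
  std <- standardize_per_target(sub)
  features <- lapply(clusters, build_cluster_features, table = std)
  min_lrmsd <- NULL
  model_lrmsd <- NULL
  if (with_labels) {
    kept_ids <- vapply(kept, `[[`, character(1), "model_id")
    model_lrmsd <- stats::setNames(
      vapply(kept, lrmsd, numeric(1), reference = reference), kept_ids)
    min_lrmsd <- stats::setNames(
      vapply(clusters, function(cl) min(model_lrmsd[cl$member_ids]),
             numeric(1)),
      vapply(clusters, `[[`, integer(1), "cluster_id"))
  }
  structure(
    list(target_id = tid, clusters = clusters, features = features,
         min_lrmsd = min_lrmsd, model_lrmsd = model_lrmsd,
         counts = list(models_in = length(target$models),
                       removed_clash = length(fc$removed),
                       kept = length(kept),
                       clusters_total = n_before,
                       clusters_kept = length(clusters),
                       enrichment_attached = length(enrich_models))),
    class = "prepared_target")
}

comparison_input <- function(prepared) {
  out <- lapply(prepared, function(p)
    list(features = p$features, min_lrmsd = p$min_lrmsd))
  names(out) <- vapply(prepared, `[[`, character(1), "target_id")
  out
}

#' Train the full pipeline on a benchmark
#'
#' Prepares every training target, builds the pairwise comparison matrix,
#' runs leave-complex-out cross-validation, fits the final model on all
#' training records and assembles a reproducibility manifest of per-stage
#' counts.
#'
#' @param benchmark A `synth_benchmark` (in memory, see
#'   [generate_benchmark()]) or a benchmark directory path.
#' @param pcfg A `pipeline_config`.
#' @return List of class `pipeline_fit`: `model`, `cv`, `comparisons`,
#'   `prepared`, `manifest`.
#' @export
run_train <- function(benchmark, pcfg = pipeline_config()) {
  if (is.character(benchmark)) benchmark <- read_benchmark(benchmark)
  training <- benchmark$manifest$training %||%
    names(benchmark$targets)
  if (length(training) < 2)
    stop("need >= 2 training targets to cross-validate")
  prepared <- lapply(benchmark$targets[training], prepare_target,
                     pcfg = pcfg)
  cs <- build_comparison_matrix(comparison_input(prepared))
  cv <- leave_complex_out_cv(cs, pcfg$ert)
  model <- train_ert(cs, pcfg$ert)
  manifest <- list(
    training_targets = training,
    holdout_targets = benchmark$manifest$holdout %||% character(0),
    n_records = nrow(cs$features),
    n_features = ncol(cs$features),
    seed = pcfg$ert$seed,
    stages = lapply(prepared, `[[`, "counts"))
  structure(list(model = model, cv = cv, comparisons = cs,
                 prepared = prepared, manifest = manifest),
            class = "pipeline_fit")
}

#' @export
print.pipeline_fit <- function(x, ...) {
  cat(sprintf("<pipeline_fit: %d targets, %d records, OOB accuracy %.3f>\n",
              length(x$manifest$training_targets), x$manifest$n_records,
              x$model$oob_accuracy))
  invisible(x)
}

#' Rank the clusters of a target
#'
#' Reference-free: the target is prepared without labels and its surviving
#' clusters are ranked by predicted win counts.
#'
#' @param model A `ranker_model`.
#' @param target Target list (see [prepare_target()]) or a target
#'   subdirectory of a benchmark.
#' @param pcfg A `pipeline_config`.
#' @param file Optional output CSV path.
#' @return A `rank_result` data.frame (cluster_id, wins, rank,
#'   tie_break_key).
#' @export
run_rank <- function(model, target, pcfg = pipeline_config(), file = NULL) {
  if (is.character(target)) {
    td <- target
    models <- read_models(file.path(td, "models.pdb"), "A", "B",
                          basename(td))
    desc <- read_descriptor_table(
      file.path(td, "descriptors.csv"), basename(td),
      known_model_ids = vapply(models, `[[`, character(1), "model_id"))
    target <- list(target_id = basename(td), models = models,
                   descriptors = desc)
  }
  prep <- prepare_target(target, pcfg, with_labels = FALSE)
  if (length(prep$clusters) < 2)
    stop("target has < 2 clusters after the size cutoff (> ",
         pcfg$size_cutoff, " models); cannot rank")
  out <- rank_clusters(model, prep$features)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Leave-complex-out ranking evaluation
#'
#' For every training target: train the pair classifier on all other
#' targets' comparison records, rank the held-out target's clusters, and
#' report the predicted rank of its best (lowest minimum-LRMSD) cluster
#' alongside the fold's pairwise classification metrics.
#'
#' @param fit A `pipeline_fit` from [run_train()] (its prepared targets
#'   and comparison records are reused).
#' @param pcfg A `pipeline_config`.
#' @return data.frame: target_id, best_cluster, rank, n_clusters, recall,
#'   precision, f1, accuracy.
#' @export
cv_rank_eval <- function(fit, pcfg = pipeline_config()) {
  cs <- fit$comparisons
  rows <- lapply(fit$prepared, function(p) {
    tid <- p$target_id
    test_idx <- cs$meta$target_id == tid
    m <- train_ert(subset_comparisons(cs, !test_idx), pcfg$ert)
    rk <- rank_clusters(m, p$features)
    best <- as.integer(names(p$min_lrmsd)[which.min(p$min_lrmsd)])
    pred <- as.integer(
      predict_prob1(m, cs$features[test_idx, , drop = FALSE]) > 0.5)
    met <- classification_metrics(
      confusion_counts(cs$meta$label[test_idx], pred))
    data.frame(target_id = tid, best_cluster = best,
               rank = rk$rank[rk$cluster_id == best],
               n_clusters = nrow(rk), t(met), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
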