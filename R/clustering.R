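# GROMOS-style neighbour-count clustering of docked poses by pairwise
# LRMSD, size filtering, and enrichment sub-clustering.

new_cluster <- function(cluster_id, member_ids, centroid_id,
                        enrichment_ids = character(0)) {
  stopifnot(centroid_id %in% member_ids)
  structure(
    list(cluster_id = as.integer(cluster_id), member_ids = member_ids,
         centroid_id = centroid_id, size = length(member_ids),
         enrichment_ids = enrichment_ids),
    class = "decoy_cluster")
}

#' @export
print.decoy_cluster <- function(x, ...) {
  cat(sprintf("<cluster %s: %d members (centroid %s)%s>\n",
              x$cluster_id, x$size, x$centroid_id,
              if (length(x$enrichment_ids))
                sprintf(" + %d enrichment", length(x$enrichment_ids)) else ""))
  invisible(x)
}

#' Pairwise LRMSD matrix
#'
#' Symmetric matrix of receptor-superposed ligand C-alpha RMSD between all
#' model pairs (zero diagonal). Models must share residue sets
#' ([truncate_to_shared_residues()]).
#'
#' @param models List of `complex_model`.
#' @return List of class `distance_matrix`: `model_ids`, `d` (symmetric
#'   matrix, Angstrom).
#' @export
pairwise_lrmsd_matrix <- function(models) {
  stopifnot(length(models) >= 1)
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) stop("duplicate model ids")
  # fixed atom order from the first model
  ref <- models[[1]]
  rec <- lapply(models, function(m)
    matched_coords(m, ref, "receptor", "CA")$model)
  lig <- lapply(models, function(m)
    matched_coords(m, ref, "ligand", "CA")$model)
  n <- length(models)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sp <- kabsch_superpose(rec[[j]], rec[[i]])
      v <- rmsd_of(apply_superposition(sp, lig[[i]]), lig[[j]])
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  structure(list(model_ids = ids, d = d), class = "distance_matrix")
}

#' GROMOS neighbour-count clustering
#'
#' Iteratively counts, for every unassigned model, its neighbours within
#' `cutoff` (inclusive). The model with the most neighbours becomes the
#' centroid of a new cluster containing it and its neighbours; all are
#' removed and the procedure repeats. The result is a partition in which
#' every member is within `cutoff` of its centroid. Ties in neighbour
#' count are broken by the lexicographically smallest model id, which makes
#' the partition invariant to the input order.
#'
#' @param dm A `distance_matrix`.
#' @param cutoff Neighbour cutoff in the same units as `dm` (Angstrom).
#' @return List of `decoy_cluster`, in formation order.
#' @export
gromos_cluster <- function(dm, cutoff) {
  stopifnot(cutoff > 0)
  ids <- dm$model_ids
  adj <- dm$d <= cutoff       # includes self on the diagonal
  remaining <- seq_along(ids)
  clusters <- list()
  k <- 0
  while (length(remaining) > 0) {
    sub <- adj[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub)
    best <- max(counts)
    cand <- remaining[counts == best]
    centroid <- cand[order(ids[cand])][1]
    members <- remaining[adj[centroid, remaining]]
    k <- k + 1
    clusters[[k]] <- new_cluster(k, ids[members], ids[centroid])
    remaining <- setdiff(remaining, members)
  }
  clusters
}

#' Filter clusters by size
#'
#' Keeps clusters with strictly more than `min_size_exclusive` members,
#' plus any cluster listed in `always_include` (e.g. small near-native
#' clusters kept by hand). Order is preserved.
#'
#' @param clusters List of `decoy_cluster`.
#' @param min_size_exclusive Strict lower bound on cluster size (default 5,
#'   i.e. clusters must contain > 5 models).
#' @param always_include Cluster ids exempt from the cutoff.
#' @return Filtered list of clusters.
#' @export
apply_size_cutoff <- function(clusters, min_size_exclusive = 5,
                              always_include = integer(0)) {
  keep <- vapply(clusters, function(cl) {
    cl$size > min_size_exclusive || cl$cluster_id %in% always_include
  }, logical(1))
  clusters[keep]
}

#' Select representative models from enrichment poses
#'
#' Sub-clusters locally resampled (enrichment) poses with the GROMOS
#' algorithm at `sub_cutoff` (default 3 A), ranks sub-clusters by size and,
#' for each of the top `top_n`, returns the member closest to the
#' sub-cluster centroid (the centroid itself). Returns fewer than `top_n`
#' models when fewer sub-clusters form.
#'
#' @param enrichment_models List of `complex_model` restricted to one
#'   parent cluster's neighbourhood.
#' @param sub_cutoff Sub-clustering cutoff, Angstrom.
#' @param top_n Maximum number of representatives.
#' @return List of representative `complex_model` (source flagged
#'   `"enrichment"`).
#' @export
select_enrichment_representatives <- function(enrichment_models,
                                              sub_cutoff = 3.0,
                                              top_n = 10) {
  if (length(enrichment_models) == 0) return(list())
  if (length(enrichment_models) == 1) {
    m <- enrichment_models[[1]]
    m$source <- "enrichment"
    return(list(m))
  }
  dm <- pairwise_lrmsd_matrix(enrichment_models)
  sub <- gromos_cluster(dm, sub_cutoff)
  sizes <- vapply(sub, `[[`, integer(1), "size")
  sub <- sub[order(-sizes)]           # stable: formation order breaks ties
  sub <- sub[seq_len(min(top_n, length(sub)))]
  ids <- dm$model_ids
  vapply_ids <- stats::setNames(seq_along(ids), ids)
  lapply(sub, function(cl) {
    di <- dm$d[vapply_ids[cl$centroid_id], vapply_ids[cl$member_ids]]
    rep_id <- cl$member_ids[which.min(di)]   # the centroid, distance 0
    m <- enrichment_models[[vapply_ids[rep_id]]]
    m$source <- "enrichment"
    m
  })
}

#' Attach enrichment representatives to a cluster
#'
#' Enrichment poses densify the cluster's descriptor distributions but are
#' not counted as model poses: the cluster-size feature and the minimum
#' LRMSD label are computed over the original members only.
#'
#' @param cluster A `decoy_cluster`.
#' @param representatives List of clash-filtered enrichment
#'   `complex_model`.
#' @return The cluster with `enrichment_ids` set.
#' @export
attach_enrichment <- function(cluster, representatives) {
  if (length(representatives) == 0) return(cluster)
  ids <- vapply(representatives, `[[`, character(1), "model_id")
  if (anyDuplicated(ids) ||
      any(ids %in% c(cluster$member_ids, cluster$enrichment_ids)))
    stop("duplicate model id among enrichment representatives")
  cluster$enrichment_ids <- c(cluster$enrichment_ids, ids)
  cluster
}

#' Write a cluster assignment table
#'
#' @param clusters List of `decoy_cluster`.
#' @param file Optional CSV path.
#' @return data.frame: model_id, cluster_id, is_centroid, source.
#' @export
cluster_assignment_table <- function(clusters, file = NULL) {
  rows <- lapply(clusters, function(cl) {
    rbind(
      data.frame(model_id = cl$member_ids, cluster_id = cl$cluster_id,
                 is_centroid = cl$member_ids == cl$centroid_id,
                 source = "scoreset_like", stringsAsFactors = FALSE),
      if (length(cl$enrichment_ids))
        data.frame(model_id = cl$enrichment_ids, cluster_id = cl$cluster_id,
                   is_centroid = FALSE, source = "enrichment",
                   stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
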