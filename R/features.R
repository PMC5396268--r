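# Cluster feature construction: five-point summaries of descriptor
# distributions plus cluster size, with the STAT_N_DESC naming scheme.

.stat_order <- c("MIN", "Q1", "AVG", "Q3", "MAX")

#' Five-point summary of a distribution
#'
#' Minimum, first quartile, median, third quartile and maximum. Quartiles
#' use linear interpolation of order statistics at positions `(n - 1) * p`
#' (quantile type 7). The median is reported under the name `AVG` to match
#' the feature naming convention.
#'
#' @param values Non-empty numeric vector, all finite.
#' @return Named numeric vector (MIN, Q1, AVG, Q3, MAX), non-decreasing.
#' @export
five_point_summary <- function(values) {
  if (length(values) == 0) stop("empty value vector")
  if (!all(is.finite(values))) stop("non-finite values")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1),
                       type = 7, names = FALSE)
  stats::setNames(q, .stat_order)
}

#' Compose a feature name
#'
#' Features are named `{slot}_{stat}_{descriptor}` where slot is the
#' position of the cluster in a pairwise comparison (`C1` or `C2`), stat is
#' one of MIN, Q1, AVG, Q3, MAX and the descriptor keeps its `N_` prefix
#' marking the per-target normalised distribution - e.g. `C2_Q1_N_CP_TB`.
#' The size feature is `{slot}_SIZE`.
#'
#' @param slot `"C1"` or `"C2"`.
#' @param stat One of MIN, Q1, AVG, Q3, MAX, SIZE.
#' @param descriptor Descriptor name (ignored for SIZE).
#' @return Feature name string.
#' @export
feature_name <- function(slot, stat, descriptor = NULL) {
  slot <- match.arg(slot, c("C1", "C2"))
  stat <- match.arg(stat, c(.stat_order, "SIZE"))
  if (stat == "SIZE") return(paste(slot, "SIZE", sep = "_"))
  paste(slot, stat, descriptor, sep = "_")
}

#' Build the feature vector of one cluster
#'
#' For every descriptor (in table column order) the five-point summary of
#' the values over the cluster's aggregated members (original decoys plus
#' enrichment representatives) is computed; the count of original members
#' is appended as the SIZE feature. With D descriptors the vector has
#' 5 D + 1 entries (546 for D = 109). Feature order is descriptor-major,
#' stat-minor (MIN, Q1, AVG, Q3, MAX), SIZE last.
#'
#' @param cluster A `decoy_cluster`.
#' @param table A standardized `descriptor_table` covering all members.
#' @return Object of class `cluster_features`: `cluster_id`,
#'   `feature_names`, `values`.
#' @export
build_cluster_features <- function(cluster, table) {
  stopifnot(inherits(cluster, "decoy_cluster"),
            inherits(table, "descriptor_table"))
  if (!table$standardized) stop("descriptor table must be standardized")
  ids <- c(cluster$member_ids, cluster$enrichment_ids)
  missing <- setdiff(ids, table$model_ids)
  if (length(missing) > 0)
    stop("cluster member(s) missing from descriptor table: ",
         paste(utils::head(missing, 3), collapse = ", "))
  m <- table$values[ids, , drop = FALSE]
  summ <- apply(m, 2, five_point_summary)      # 5 x D
  vals <- c(as.vector(summ), cluster$size)
  nms <- c(as.vector(outer(.stat_order, colnames(m), paste, sep = "_")),
           "SIZE")
  structure(
    list(cluster_id = cluster$cluster_id,
         feature_names = nms,
         values = stats::setNames(vals, nms)),
    class = "cluster_features")
}

#' @export
print.cluster_features <- function(x, ...) {
  cat(sprintf("<cluster_features %s: %d features>\n",
              x$cluster_id, length(x$values)))
  invisible(x)
}

#' Per-target cluster feature table
#'
#' @param feature_list List of `cluster_features`.
#' @param file Optional CSV path.
#' @return data.frame with cluster_id and one column per feature.
#' @export
cluster_feature_table <- function(feature_list, file = NULL) {
  out <- cbind(
    data.frame(cluster_id = vapply(feature_list, `[[`, integer(1),
                                   "cluster_id")),
    as.data.frame(do.call(rbind, lapply(feature_list, `[[`, "values"))))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
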