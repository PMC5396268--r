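# Per-model molecular descriptor tables: CSV ingestion, two built-in
# exemplar descriptors computable from coordinates alone, and per-target
# standardisation.

new_descriptor_table <- function(target_id, values, standardized = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) stop("duplicate descriptor names")
  structure(
    list(target_id = target_id, model_ids = rownames(values),
         descriptor_names = colnames(values), values = values,
         standardized = standardized),
    class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table %s: %d models x %d descriptors%s>\n",
              x$target_id, nrow(x$values), ncol(x$values),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Read a per-model descriptor table from CSV
#'
#' The CSV must have a `model_id` first column and one numeric column per
#' descriptor (conventionally named with an `N_` prefix, e.g. `N_CP_TB`).
#' Rows for models not in `known_model_ids` are dropped with a warning;
#' models missing from the CSV are handled by `missing_policy`: `"drop"`
#' leaves them without descriptor rows (they are excluded downstream) or
#' `"impute"` fills a row with per-column medians.
#'
#' @param csv_path Path to the CSV file.
#' @param target_id Target the table belongs to.
#' @param known_model_ids Optional character vector of expected model ids.
#' @param missing_policy `"drop"` or `"impute"`.
#' @return A `descriptor_table` (unstandardized).
#' @export
read_descriptor_table <- function(csv_path, target_id,
                                  known_model_ids = NULL,
                                  missing_policy = c("drop", "impute")) {
  missing_policy <- match.arg(missing_policy)
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (ncol(raw) < 2) stop("descriptor CSV needs model_id + >= 1 descriptor")
  if (names(raw)[1] != "model_id")
    stop("first column of ", csv_path, " must be model_id")
  ids <- as.character(raw$model_id)
  if (anyDuplicated(ids))
    stop("duplicate model_id in ", csv_path, ": ",
         ids[duplicated(ids)][1])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in ", csv_path, " row ", bad,
           " column ", names(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!is.null(known_model_ids)) {
    unknown <- setdiff(ids, known_model_ids)
    if (length(unknown) > 0) {
      warning(length(unknown), " descriptor row(s) for unknown models ",
              "dropped (e.g. ", unknown[1], ")", call. = FALSE)
      m <- m[!rownames(m) %in% unknown, , drop = FALSE]
    }
    missing <- setdiff(known_model_ids, rownames(m))
    if (length(missing) > 0) {
      warning(length(missing), " model(s) missing from descriptor table (",
              missing_policy, " policy), e.g. ", missing[1], call. = FALSE)
      if (missing_policy == "impute") {
        med <- apply(m, 2, stats::median)
        add <- matrix(rep(med, each = length(missing)),
                      nrow = length(missing),
                      dimnames = list(missing, colnames(m)))
        m <- rbind(m, add)
        m <- m[intersect(known_model_ids, rownames(m)), , drop = FALSE]
      }
    }
  }
  if (anyNA(m)) stop("missing values in descriptor table ", csv_path)
  new_descriptor_table(target_id, m)
}

#' Coarse-grained residue contact potential (exemplar descriptor)
#'
#' Sums `pair_scores[type_i, type_j]` over all receptor-ligand residue
#' pairs with any heavy-atom pair within `contact_cutoff`; each residue
#' pair is counted once. With a uniform unit score matrix this is the
#' inter-chain residue contact count.
#'
#' @param model A `complex_model`.
#' @param pair_scores Symmetric matrix indexed by 3-letter residue codes
#'   in both dimnames.
#' @param contact_cutoff Heavy-atom cutoff, Angstrom.
#' @param unknown `"skip"` unknown residue types with a warning, or
#'   `"error"`.
#' @return Scalar energy (arbitrary units).
#' @export
residue_contact_potential <- function(model, pair_scores,
                                      contact_cutoff = 5.0,
                                      unknown = c("skip", "error")) {
  unknown <- match.arg(unknown)
  stopifnot(contact_cutoff > 0)
  rec <- heavy_atoms(model$receptor)
  lig <- heavy_atoms(model$ligand)
  d <- cross_dist(atom_xyz(rec), atom_xyz(lig))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0.0)
  pair_key <- paste(residue_keys(rec)[hit[, 1]],
                    residue_keys(lig)[hit[, 2]], sep = " :: ")
  first <- !duplicated(pair_key)
  ri <- rec$resid[hit[first, 1]]
  rj <- lig$resid[hit[first, 2]]
  known <- ri %in% rownames(pair_scores) & rj %in% colnames(pair_scores)
  if (any(!known)) {
    msg <- paste(unique(c(ri[!known], rj[!known])), collapse = ", ")
    if (unknown == "error") stop("unknown residue type(s): ", msg)
    warning("skipping contacts with unknown residue type(s): ", msg,
            call. = FALSE)
  }
  sum(pair_scores[cbind(ri[known], rj[known])])
}

#' Inter-chain atomic contact count (exemplar descriptor)
#'
#' Number of receptor-ligand heavy-atom pairs within `cutoff`.
#'
#' @param model A `complex_model`.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Integer count.
#' @export
atomic_contact_count <- function(model, cutoff) {
  stopifnot(cutoff >= 0)
  if (cutoff == 0) return(0L)
  rec <- heavy_atoms(model$receptor)
  lig <- heavy_atoms(model$ligand)
  d <- cross_dist(atom_xyz(rec), atom_xyz(lig))
  sum(d <= cutoff)
}

#' Standardize descriptors per target
#'
#' Scales each descriptor column to zero mean and unit variance using the
#' population standard deviation over all models of the target (original
#' decoys and enrichment poses together). Zero-variance columns become all
#' zeros and are flagged in the `zero_variance` attribute.
#'
#' @param table An unstandardized `descriptor_table` with >= 2 models.
#' @return The standardized `descriptor_table`.
#' @export
standardize_per_target <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  if (table$standardized) stop("table is already standardized")
  if (nrow(table$values) < 2)
    stop("cannot standardize a single-model table")
  m <- table$values
  mu <- colMeans(m)
  sd <- apply(m, 2, sd_pop)
  zero <- sd < 1e-12
  sd[zero] <- 1
  out <- sweep(sweep(m, 2, mu), 2, sd, "/")
  out[, zero] <- 0
  res <- new_descriptor_table(table$target_id, out, standardized = TRUE)
  attr(res, "zero_variance") <- stats::setNames(zero, colnames(m))
  res
}

#' Descriptor category metadata
#'
#' The eight descriptor categories: residue contact/distance potentials
#' (rc), atomic contact/distance potentials (ac), statistical potential
#' terms (sp), composite scoring functions (cs), solvation energy (se),
#' hydrogen bonding (hb), van der Waals/electrostatics (ve) and
#' miscellaneous (mi).
#'
#' @param names Descriptor names.
#' @param categories Matching category codes.
#' @return data.frame(name, category).
#' @export
descriptor_meta <- function(names, categories) {
  allowed <- c("rc", "ac", "sp", "cs", "se", "hb", "ve", "mi")
  if (!all(categories %in% allowed))
    stop("categories must be one of: ", paste(allowed, collapse = ", "))
  data.frame(name = names, category = categories, stringsAsFactors = FALSE)
}
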