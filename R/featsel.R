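# Descriptor screening (Mann-Whitney U), collinearity (Pearson
# correlation), recursive feature elimination and dimensionality-reduction
# sweeps (PCA, maximum-likelihood factor analysis, RBF kernel PCA).

#' Mann-Whitney U screen of descriptor discrimination
#'
#' For each descriptor, compares its values between near-native and
#' incorrect clusters with a two-sided Mann-Whitney U test. The screening
#' unit is the cluster: each cluster contributes one aggregated value per
#' descriptor (`aggregate = "median"` over its member models by default;
#' `"model"` pools the raw per-model values instead). Significance tiers:
#' `***` p < 1e-4, `**` p < 1e-3, `*` p < 1e-2, else `ns`. The exact null
#' distribution is used for small tie-free samples, the tie-corrected
#' normal approximation otherwise (the `wilcox.test` default).
#'
#' @param tables List of standardized `descriptor_table`s, one per target.
#' @param clusterings List (parallel to `tables`) of cluster lists.
#' @param near_native List (parallel) of near-native cluster ids per
#'   target (clusters containing at least one acceptable-or-better model).
#' @param aggregate `"median"` (per-cluster) or `"model"` (pooled).
#' @return data.frame of class `screen_result`: name, u_statistic,
#'   p_value, tier.
#' @export
mannwhitney_screen <- function(tables, clusterings, near_native,
                               aggregate = c("median", "model")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(tables) == length(clusterings),
            length(tables) == length(near_native))
  dnames <- tables[[1]]$descriptor_names
  grp_pos <- list(); grp_neg <- list()
  for (t in seq_along(tables)) {
    tab <- tables[[t]]
    for (cl in clusterings[[t]]) {
      ids <- c(cl$member_ids, cl$enrichment_ids)
      m <- tab$values[ids, , drop = FALSE]
      v <- if (aggregate == "median")
        matrix(apply(m, 2, stats::median), nrow = 1) else m
      if (cl$cluster_id %in% near_native[[t]])
        grp_pos[[length(grp_pos) + 1]] <- v
      else
        grp_neg[[length(grp_neg) + 1]] <- v
    }
  }
  if (length(grp_pos) == 0) stop("no near-native clusters in the input")
  if (length(grp_neg) == 0) stop("no incorrect clusters in the input")
  pos <- do.call(rbind, grp_pos)
  neg <- do.call(rbind, grp_neg)
  res <- lapply(seq_along(dnames), function(j) {
    wt <- suppressWarnings(
      stats::wilcox.test(pos[, j], neg[, j], alternative = "two.sided"))
    data.frame(name = dnames[j], u_statistic = unname(wt$statistic),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$tier <- cut(out$p_value, c(-Inf, 1e-4, 1e-3, 1e-2, Inf),
                  labels = c("***", "**", "*", "ns"))
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Pairwise Pearson correlation of descriptors
#'
#' Pools per-model standardized descriptor values over all targets and
#' computes the D x D Pearson product-moment correlation matrix, plus the
#' per-descriptor count of partners with |r| above `high_cutoff` (0.6
#' marks strong correlation). Zero-variance descriptors get correlation 0
#' and are flagged.
#'
#' @param tables List of standardized `descriptor_table`s.
#' @param high_cutoff Absolute-correlation threshold for "highly
#'   correlated".
#' @return List of class `correlation_summary`: `ppmcc` (matrix),
#'   `partner_counts`, `zero_variance`.
#' @export
ppmcc_analysis <- function(tables, high_cutoff = 0.6) {
  if (inherits(tables, "descriptor_table")) tables <- list(tables)
  m <- do.call(rbind, lapply(tables, `[[`, "values"))
  if (nrow(m) < 3) stop("need >= 3 observations per descriptor")
  sds <- apply(m, 2, sd_pop)
  zero <- sds < 1e-12
  r <- matrix(0, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
  if (any(!zero))
    r[!zero, !zero] <- stats::cor(m[, !zero, drop = FALSE])
  diag(r) <- 1
  counts <- rowSums(abs(r) > high_cutoff) - 1L
  counts[zero] <- 0L
  structure(
    list(ppmcc = r, partner_counts = counts,
         zero_variance = stats::setNames(zero, colnames(m))),
    class = "correlation_summary")
}

#' Recursive feature elimination over leave-complex-out folds
#'
#' Starting from the full feature set, repeatedly: run leave-complex-out
#' CV, average the per-fold impurity importances, record the mean metrics,
#' and drop the `step` least-important features. Pruning continues down to
#' `<= 2 * step` features. The selected size maximises mean F1 (ties go to
#' the smaller set). Importances are always averaged over training folds
#' only, so no held-out target influences the pruning of the round it is
#' tested in.
#'
#' @param cs A labelled `comparison_set`.
#' @param config An `ert_config`.
#' @param step Features removed per round.
#' @return List of class `rfe_path`: `path` (data.frame size + mean
#'   metrics), `retained` (feature sets per visited size),
#'   `selected_size`, `selected_features`, `audit` (per-round fold
#'   train-target lists).
#' @export
recursive_feature_elimination <- function(cs, config = ert_config(),
                                          step = 10) {
  stopifnot(ncol(cs$features) > step)
  current <- cs$feature_names
  path <- list(); retained <- list(); audit <- list()
  repeat {
    sub <- select_features(cs, current)
    cv <- leave_complex_out_cv(sub, config)
    path[[length(path) + 1]] <- data.frame(
      size = length(current), t(cv$mean))
    retained[[as.character(length(current))]] <- current
    audit[[length(audit) + 1]] <- list(size = length(current),
                                       train_targets = cv$train_targets)
    if (length(current) <= 2 * step) break
    imp <- rowMeans(cv$importance)
    drop <- names(sort(imp))[seq_len(step)]
    current <- setdiff(current, drop)
  }
  path <- do.call(rbind, path)
  best <- which(path$f1 == max(path$f1))
  sel <- best[which.min(path$size[best])]
  structure(
    list(path = path, retained = retained,
         selected_size = path$size[sel],
         selected_features = retained[[as.character(path$size[sel])]],
         audit = audit),
    class = "rfe_path")
}

#' @export
print.rfe_path <- function(x, ...) {
  cat(sprintf("<rfe_path: %d rounds, selected %d features (mean F1 %.3f)>\n",
              nrow(x$path), x$selected_size,
              max(x$path$f1)))
  invisible(x)
}

# ---- feature-space transformers -------------------------------------------

# Maximum-likelihood factor analysis via EM (isotropic-free diagonal
# noise), as used for high-dimensional sweeps where the classical
# degrees-of-freedom constraint of factanal() would forbid large factor
# counts. Transform = posterior mean of the factors.
fa_fit <- function(x, k, max_iter = 100, tol = 1e-3) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  svd0 <- svd(xc, nu = 0, nv = k)
  d <- svd0$d
  w <- svd0$v %*% diag(d[seq_len(k)] / sqrt(n), k, k)
  v <- colMeans(xc^2)
  psi <- pmax(v - rowSums(w^2), 1e-6)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    wp <- w / psi
    g <- solve(diag(k) + crossprod(w, wp))       # k x k
    ez <- xc %*% wp %*% g                        # n x k
    szz <- n * g + crossprod(ez)
    xez <- crossprod(xc, ez)                     # p x k
    w <- xez %*% solve(szz)
    psi <- pmax(v - rowSums(w * xez) / n, 1e-6)
    # observed-data log-likelihood via Woodbury determinant lemma
    wp <- w / psi
    gg <- diag(k) + crossprod(w, wp)
    logdet <- determinant(gg, logarithm = TRUE)$modulus + sum(log(psi))
    quad <- sum(xc^2 / rep(psi, each = n)) -
      sum((xc %*% wp) * (xc %*% wp %*% solve(gg)))
    ll <- -0.5 * (n * (p * log(2 * pi) + logdet / 1) + quad) / n
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(w = w, psi = psi, mu = mu, k = k)
}

fa_transform <- function(fit, x) {
  xc <- sweep(as.matrix(x), 2, fit$mu)
  wp <- fit$w / fit$psi
  g <- solve(diag(fit$k) + crossprod(fit$w, wp))
  xc %*% wp %*% g
}

#' Fit a feature-space transformer on training data
#'
#' Supported methods: `"PCA"` (principal components of the centred
#' training matrix), `"FA"` (maximum-likelihood factor analysis, EM with a
#' fixed iteration cap) and `"KPCA_rbf"` (kernel PCA with a radial basis
#' function kernel; default gamma 1 / n_features). The fitted object
#' transforms unseen data with statistics from the training split only;
#' the row names of the training matrix are recorded in `fit_ids` for
#' leakage auditing.
#'
#' @param x Training feature matrix.
#' @param method `"PCA"`, `"FA"` or `"KPCA_rbf"`.
#' @param ndim Output dimensionality (<= ncol(x)).
#' @param kpca_gamma RBF bandwidth; `NULL` means `1 / ncol(x)`.
#' @param fa_max_iter EM iteration cap for FA.
#' @return Object of class `feature_transformer`.
#' @export
fit_transformer <- function(x, method = c("PCA", "FA", "KPCA_rbf"),
                            ndim, kpca_gamma = NULL, fa_max_iter = 100) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (ndim > ncol(x)) stop("requested dimension exceeds feature count")
  fit <- switch(method,
    PCA = {
      pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      nd <- min(ndim, ncol(pr$rotation))
      list(center = pr$center, rotation = pr$rotation[, seq_len(nd),
                                                      drop = FALSE])
    },
    FA = fa_fit(x, ndim, max_iter = fa_max_iter),
    KPCA_rbf = {
      sigma <- kpca_gamma %||% (1 / ncol(x))
      nd <- min(ndim, nrow(x) - 1L)
      kernlab::kpca(x, kernel = "rbfdot", kpar = list(sigma = sigma),
                    features = nd)
    })
  structure(list(method = method, ndim = ndim, fit = fit,
                 fit_ids = rownames(x) %||% as.character(seq_len(nrow(x)))),
            class = "feature_transformer")
}

#' Apply a fitted transformer to new data
#'
#' @param tr A `feature_transformer`.
#' @param x Feature matrix to project.
#' @return Transformed matrix with `tr$ndim` (or fewer, if rank-limited)
#'   columns.
#' @export
apply_transformer <- function(tr, x) {
  x <- as.matrix(x)
  out <- switch(tr$method,
    PCA = sweep(x, 2, tr$fit$center) %*% tr$fit$rotation,
    FA = fa_transform(tr$fit, x),
    KPCA_rbf = kernlab::predict(tr$fit, x))
  colnames(out) <- paste0("T", seq_len(ncol(out)))
  out
}

#' Dimensionality-reduction sweep under leave-complex-out CV
#'
#' For every dimension on the grid (from the full feature count down to 2
#' in steps of `step` by default; `anchoring = "bottom_up"` starts the
#' grid at 2 instead), each leave-complex-out fold fits the transformer on
#' the training records only, transforms both splits, trains the ERT
#' classifier on the transformed training records and evaluates on the
#' held-out target. Mean metrics per dimension are reported; the returned
#' best model maximises mean F1 (ties to the smaller dimension) and is
#' refitted on all records.
#'
#' @param cs A labelled `comparison_set`.
#' @param method `"PCA"`, `"FA"` or `"KPCA_rbf"`.
#' @param config An `ert_config`.
#' @param step Grid step in dimensions.
#' @param anchoring `"top_down"` (default) or `"bottom_up"` grid anchoring.
#' @param kpca_gamma,fa_max_iter Passed to [fit_transformer()].
#' @return List of class `transform_sweep`: `path` (dimension + mean
#'   metrics), `best_dim`, `best_transformer`, `best_model`, `audit`
#'   (per dimension/fold: the record ids the transformer was fitted on).
#' @export
transform_sweep <- function(cs, method = c("PCA", "FA", "KPCA_rbf"),
                            config = ert_config(), step = 10,
                            anchoring = c("top_down", "bottom_up"),
                            kpca_gamma = NULL, fa_max_iter = 100) {
  method <- match.arg(method)
  anchoring <- match.arg(anchoring)
  p <- ncol(cs$features)
  stopifnot(p >= 2)
  dims <- if (anchoring == "top_down") seq(p, 2, by = -step)
          else seq(2, p, by = step)
  tids <- unique(cs$meta$target_id)
  if (length(tids) < 2) stop("need >= 2 targets")
  rownames(cs$features) <- sprintf("r%05d", seq_len(nrow(cs$features)))
  path <- list(); audit <- list()
  for (nd in dims) {
    fold_metrics <- list()
    for (tid in tids) {
      test_idx <- cs$meta$target_id == tid
      xtr <- cs$features[!test_idx, , drop = FALSE]
      xte <- cs$features[test_idx, , drop = FALSE]
      tr <- fit_transformer(xtr, method, nd, kpca_gamma = kpca_gamma,
                            fa_max_iter = fa_max_iter)
      audit[[length(audit) + 1]] <-
        list(dim = nd, fold = tid, fit_ids = tr$fit_ids,
             test_ids = rownames(xte))
      ztr <- apply_transformer(tr, xtr)
      zte <- apply_transformer(tr, xte)
      sub <- structure(
        list(features = ztr, meta = cs$meta[!test_idx, , drop = FALSE],
             feature_names = colnames(ztr)),
        class = "comparison_set")
      m <- train_ert(sub, config)
      pred <- as.integer(predict_prob1(m, zte) > 0.5)
      fold_metrics[[tid]] <- classification_metrics(
        confusion_counts(cs$meta$label[test_idx], pred))
    }
    path[[length(path) + 1]] <- data.frame(
      dim = nd, t(colMeans(do.call(rbind, fold_metrics))))
  }
  path <- do.call(rbind, path)
  best <- which(path$f1 == max(path$f1))
  best_dim <- min(path$dim[best])
  tr <- fit_transformer(cs$features, method, best_dim,
                        kpca_gamma = kpca_gamma, fa_max_iter = fa_max_iter)
  z <- apply_transformer(tr, cs$features)
  full <- structure(
    list(features = z, meta = cs$meta, feature_names = colnames(z)),
    class = "comparison_set")
  structure(
    list(path = path, best_dim = best_dim, best_transformer = tr,
         best_model = train_ert(full, config), audit = audit),
    class = "transform_sweep")
}

#' Feature importance report
#'
#' Features sorted by descending impurity importance, normalised to sum
#' one, annotated with slot, stat, descriptor and category, plus the
#' cumulative fraction of each category's features used as a function of
#' rank (a category curve reaching f at rank r means a fraction f of that
#' category's features appear among the top r).
#'
#' @param model A `ranker_model`.
#' @param meta Optional `data.frame(name, category)` mapping descriptor
#'   names to the eight category codes (see [descriptor_meta()]).
#' @return List of class `importance_report`: `table` (feature,
#'   importance, rank, slot, stat, descriptor, category),
#'   `category_curves` (long data.frame rank/category/fraction).
#' @export
feature_importance_report <- function(model, meta = NULL) {
  imp <- model$forest$variable.importance
  s <- sum(imp)
  imp <- if (s > 0) imp / s else imp
  parse1 <- function(nm) {
    p <- regmatches(nm, regexec("^(C[12])_(MIN|Q1|AVG|Q3|MAX|SIZE)_?(.*)$",
                                nm))[[1]]
    if (length(p) == 4)
      return(c(p[2], p[3], if (nzchar(p[4])) p[4] else NA))
    # fall back for features without a distribution statistic in the name
    p <- regmatches(nm, regexec("^(C[12])_(.*)$", nm))[[1]]
    if (length(p) == 3) return(c(p[2], NA, p[3]))
    c(NA, NA, nm)
  }
  parts <- t(vapply(names(imp), parse1, character(3)))
  tab <- data.frame(
    feature = names(imp), importance = unname(imp),
    slot = parts[, 1], stat = parts[, 2], descriptor = parts[, 3],
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$feature), ]
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(meta)) {
    tab$category <- meta$category[match(tab$descriptor, meta$name)]
    tab$category[is.na(tab$category) & tab$stat == "SIZE"] <- "size"
  } else tab$category <- NA_character_
  curves <- NULL
  if (!all(is.na(tab$category))) {
    cats <- unique(stats::na.omit(tab$category))
    totals <- table(factor(tab$category, levels = cats))
    curves <- do.call(rbind, lapply(cats, function(cc) {
      data.frame(rank = tab$rank, category = cc,
                 fraction = cumsum(tab$category == cc) / totals[[cc]])
    }))
  }
  rownames(tab) <- NULL
  structure(list(table = tab, category_curves = curves),
            class = "importance_report")
}
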