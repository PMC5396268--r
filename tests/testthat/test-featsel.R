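# fixtures for screening: two targets, clusters with known group labels
mk_screen_input <- function(shift = 0, n_clusters = 8, seed = 60) {
  set.seed(seed)
  ids <- sprintf("m%03d", 1:(n_clusters * 4))
  groups <- rep(seq_len(n_clusters), each = 4)
  near <- seq_len(n_clusters / 2)
  vals <- matrix(rnorm(length(ids) * 2), length(ids),
                 dimnames = list(ids, c("N_A", "N_B")))
  vals[groups %in% near, 1] <- vals[groups %in% near, 1] - shift
  tab <- clusterrank:::new_descriptor_table("T01", vals, standardized = TRUE)
  clusters <- lapply(seq_len(n_clusters), function(g)
    clusterrank:::new_cluster(g, ids[groups == g], ids[groups == g][1]))
  list(tables = list(tab), clusterings = list(clusters),
       near_native = list(near))
}

test_that("Mann-Whitney U matches exhaustive enumeration for small groups", {
  set.seed(61)
  for (rep in 1:4) {
    x <- rnorm(sample(4:8, 1))
    y <- rnorm(sample(4:8, 1))
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    oracle <- exact_mannwhitney(x, y)
    expect_equal(unname(wt$statistic), oracle$u)
    expect_equal(wt$p.value, oracle$p, tolerance = 1e-10)
  }
})

test_that("descriptor screening separates planted from null descriptors", {
  inp <- mk_screen_input(shift = 6, n_clusters = 20)
  res <- mannwhitney_screen(inp$tables, inp$clusterings, inp$near_native)
  expect_s3_class(res, "screen_result")
  expect_equal(as.character(res$tier[res$name == "N_A"]), "***")
  expect_equal(as.character(res$tier[res$name == "N_B"]), "ns")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # identical group distributions -> not significant
  same <- mk_screen_input(shift = 0, seed = 62)
  res2 <- mannwhitney_screen(same$tables, same$clusterings, same$near_native)
  expect_equal(as.character(res2$tier), c("ns", "ns"))

  none <- mk_screen_input(shift = 1, seed = 63)
  none$near_native <- list(integer(0))
  expect_error(mannwhitney_screen(none$tables, none$clusterings,
                                  none$near_native), "no near-native")
})

test_that("fully separated groups of 20 clusters reach the *** tier", {
  inp <- mk_screen_input(shift = 50, n_clusters = 40, seed = 64)
  res <- mannwhitney_screen(inp$tables, inp$clusterings, inp$near_native)
  expect_equal(as.character(res$tier[res$name == "N_A"]), "***")
  # exact U null at full separation: U = n1 * n2 extreme tail
  expect_equal(unname(res$u_statistic[res$name == "N_A"]), 0)
})

test_that("correlation analysis flags planted collinear blocks", {
  set.seed(65)
  n <- 60
  x <- rnorm(n)
  m <- cbind(N_A = x, N_B = 2 * x, N_C = -x + rnorm(n, 0, 0.1),
             N_D = rnorm(n), N_E = rep(1, n))
  rownames(m) <- sprintf("m%03d", 1:n)
  tab <- clusterrank:::new_descriptor_table("T01", m, standardized = TRUE)
  cs <- ppmcc_analysis(tab)
  expect_equal(cs$ppmcc, t(cs$ppmcc))
  expect_equal(unname(diag(cs$ppmcc)), rep(1, 5))
  expect_equal(cs$ppmcc["N_A", "N_B"], 1, tolerance = 1e-12)
  expect_lt(cs$ppmcc["N_A", "N_C"], -0.9)
  # partner counts at |r| > 0.6: A-B, A-C, B-C correlated; D, E not
  expect_equal(unname(cs$partner_counts[c("N_A", "N_B", "N_C", "N_D")]),
               c(2L, 2L, 2L, 0L))
  expect_true(cs$zero_variance[["N_E"]])
  expect_equal(unname(cs$ppmcc["N_E", "N_A"]), 0)
})

# small separable comparison set with named informative features
mk_rfe_set <- function(n_targets = 4, k = 6, n_noise = 20, n_const = 5,
                       seed = 66, inf_scale = 1) {
  set.seed(seed)
  targets <- list()
  for (t in seq_len(n_targets)) {
    ml <- runif(k, 1, 40) + seq_len(k) * 1e-3
    feats <- lapply(seq_len(k), function(i) {
      v <- c(inf_scale * (ml[i] / 40 + rnorm(1, 0, 0.03)),
             inf_scale * (ml[i] / 40 + rnorm(1, 0, 0.03)),
             rnorm(n_noise), rep(1, n_const))
      mk_cf(i, v, c("INF1", "INF2", sprintf("NOISE%02d", seq_len(n_noise)),
                    sprintf("CONST%02d", seq_len(n_const))))
    })
    targets[[sprintf("S%02d", t)]] <-
      list(features = feats, min_lrmsd = stats::setNames(ml, seq_len(k)))
  }
  build_comparison_matrix(targets)
}

test_that("RFE prunes by step with nested retained sets, constants first", {
  cs <- mk_rfe_set()
  cfg <- ert_config(n_trees = 80, seed = 4)
  rfe <- recursive_feature_elimination(cs, cfg, step = 10)
  p <- ncol(cs$features)     # 54
  expect_equal(rfe$path$size, seq(p, by = -10,
                                  length.out = nrow(rfe$path)))
  expect_lte(min(rfe$path$size), 2 * 10 + 9)
  # retained sets are nested round over round
  sizes <- as.character(rfe$path$size)
  for (i in seq_len(length(sizes) - 1))
    expect_true(all(rfe$retained[[sizes[i + 1]]] %in%
                      rfe$retained[[sizes[i]]]))
  # constant features never split -> gone after the first pruning round
  second <- rfe$retained[[sizes[2]]]
  expect_false(any(grepl("^CONST", second)))
  # informative features survive to the selected set
  expect_true(all(c("C1_INF1", "C2_INF1") %in% rfe$selected_features))
  expect_equal(rfe$selected_size, length(rfe$selected_features))
})

test_that("planted informative features survive RFE across seeds", {
  for (s in 1:3) {
    cs <- mk_rfe_set(seed = 70 + s)
    rfe <- recursive_feature_elimination(cs, ert_config(n_trees = 80,
                                                        seed = s), step = 10)
    final <- rfe$retained[[as.character(min(rfe$path$size))]]
    expect_true(all(c("C1_INF1", "C1_INF2", "C2_INF1", "C2_INF2") %in% final))
  }
})

test_that("transform sweep walks the dimension grid and finds signal", {
  cs <- mk_rfe_set(n_noise = 8, n_const = 2, seed = 74)   # 24 features
  cfg <- ert_config(n_trees = 80, seed = 5)
  sw <- transform_sweep(cs, "PCA", cfg, step = 10)
  expect_equal(sw$path$dim, c(24, 14, 4))
  expect_true(sw$best_dim %in% sw$path$dim)
  expect_equal(ncol(apply_transformer(sw$best_transformer,
                                      cs$features)), sw$best_dim)
  # bottom-up anchoring starts at 2
  sw2 <- transform_sweep(cs, "PCA", cfg, step = 10, anchoring = "bottom_up")
  expect_equal(sw2$path$dim, c(2, 12, 22))
})

test_that("full-rank PCA preserves ERT performance within noise", {
  f1s <- sapply(1:5, function(s) {
    cs <- mk_rfe_set(n_targets = 4, n_noise = 6, n_const = 0,
                     seed = 80 + s, inf_scale = 4)
    cfg <- ert_config(n_trees = 100, seed = s)
    base <- leave_complex_out_cv(cs, cfg)$mean["f1"]
    sw <- transform_sweep(cs, "PCA", cfg, step = ncol(cs$features) + 1)
    c(base = unname(base), pca = sw$path$f1[sw$path$dim == ncol(cs$features)])
  })
  d <- f1s["base", ] - f1s["pca", ]
  # the rotation does not destroy information: any mean gap stays within
  # the seed-to-seed spread of the estimate
  expect_lt(abs(mean(d)), 2 * stats::sd(d) + 0.05)
})

test_that("FA and kernel PCA transformers fit on train and project test", {
  set.seed(75)
  x <- matrix(rnorm(60 * 10), 60,
              dimnames = list(sprintf("r%02d", 1:60), sprintf("F%02d", 1:10)))
  for (method in c("FA", "KPCA_rbf")) {
    tr <- fit_transformer(x[1:40, ], method, 3)
    expect_setequal(tr$fit_ids, sprintf("r%02d", 1:40))
    z1 <- apply_transformer(tr, x[41:60, ])
    z2 <- apply_transformer(tr, x[41:60, ])
    expect_identical(z1, z2)          # deterministic projection
    expect_equal(nrow(z1), 20)
    expect_lte(ncol(z1), 3)
  }
  expect_error(fit_transformer(x, "PCA", 11), "exceeds")
})

test_that("no transformer or pruning statistic sees held-out fold data", {
  cs <- mk_rfe_set(n_noise = 8, n_const = 2, seed = 76)
  cfg <- ert_config(n_trees = 60, seed = 6)
  sw <- transform_sweep(cs, "PCA", cfg, step = 12)
  for (a in sw$audit)
    expect_length(intersect(a$fit_ids, a$test_ids), 0)
  rfe <- recursive_feature_elimination(cs, cfg, step = 10)
  for (round in rfe$audit)
    for (tid in names(round$train_targets))
      expect_false(tid %in% round$train_targets[[tid]])
})

test_that("feature importances normalise, zero out constants, find signal", {
  cs <- mk_rfe_set(seed = 77)
  model <- train_ert(cs, ert_config(n_trees = 150, seed = 7))
  rep <- feature_importance_report(model)
  expect_equal(sum(rep$table$importance), 1, tolerance = 1e-8)
  const_imp <- rep$table$importance[grepl("CONST", rep$table$feature)]
  expect_true(all(const_imp == 0))
  expect_true(grepl("INF", rep$table$feature[1]))

  # category curves with metadata
  meta <- data.frame(name = c("INF1", "INF2", sprintf("NOISE%02d", 1:20),
                              sprintf("CONST%02d", 1:5)),
                     category = c("rc", "rc", rep("ve", 20), rep("hb", 5)))
  rep2 <- feature_importance_report(model, meta)
  expect_true(!is.null(rep2$category_curves))
  last <- subset(rep2$category_curves, rank == max(rank))
  expect_true(all(abs(last$fraction - 1) < 1e-12))
})
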