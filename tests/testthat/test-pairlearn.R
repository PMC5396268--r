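test_that("comparison matrix enumerates unordered pairs with the label rule", {
  tg <- mk_monotone_targets(1, 5, seed = 50)
  cs <- build_comparison_matrix(tg)
  expect_equal(nrow(cs$features), choose(5, 2))
  expect_equal(ncol(cs$features), 2 * 4)     # two slots of 4 features each
  expect_true(all(startsWith(cs$feature_names[1:4], "C1_")))
  expect_true(all(startsWith(utils::tail(cs$feature_names, 4), "C2_")))
  # canonical order: lower cluster id in slot C1, labels follow min LRMSD
  ml <- tg[[1]]$min_lrmsd
  for (r in seq_len(nrow(cs$meta))) {
    n <- cs$meta$cluster_n[r]; m <- cs$meta$cluster_m[r]
    expect_lt(n, m)
    expect_equal(cs$meta$label[r],
                 as.integer(ml[as.character(n)] < ml[as.character(m)]))
  }
})

test_that("the label rule is antisymmetric in the slot assignment", {
  feats <- list(mk_cf(1, c(0.1, 0.2)), mk_cf(2, c(0.8, 0.9)))
  fwd <- build_comparison_matrix(list(
    A = list(features = feats, min_lrmsd = c(`1` = 3.0, `2` = 5.0))))
  expect_equal(fwd$meta$label, 1L)
  rev <- build_comparison_matrix(list(
    A = list(features = feats, min_lrmsd = c(`1` = 5.0, `2` = 3.0))))
  expect_equal(rev$meta$label, 0L)
})

test_that("equal-minimum pairs are excluded and small targets skipped", {
  tg <- mk_monotone_targets(1, 3, seed = 52)
  tg[[1]]$min_lrmsd[1:2] <- 4.4
  expect_warning(cs <- build_comparison_matrix(tg), "equal min LRMSD")
  expect_equal(nrow(cs$features), 2)

  tiny <- mk_monotone_targets(2, 3, seed = 53)
  tiny[[2]]$features <- tiny[[2]]$features[1]
  tiny[[2]]$min_lrmsd <- tiny[[2]]$min_lrmsd[1]
  expect_warning(cs2 <- build_comparison_matrix(tiny), "< 2 clusters")
  expect_equal(unique(cs2$meta$target_id), names(tiny)[1])
})

test_that("cluster counts from an 11-target benchmark yield 7248 records", {
  counts <- c(49, 24, 12, 12, 44, 57, 25, 35, 20, 42, 49)
  set.seed(54)
  targets <- list()
  for (i in seq_along(counts)) {
    k <- counts[i]
    ml <- sample(seq(0.5, 60, length.out = k))
    targets[[sprintf("T%02d", i)]] <- list(
      features = lapply(seq_len(k), function(j) mk_cf(j, rnorm(2))),
      min_lrmsd = stats::setNames(ml, seq_len(k)))
  }
  cs <- build_comparison_matrix(targets)
  expect_equal(nrow(cs$features), 7248)
  expect_equal(sum(choose(counts, 2)), 7248)
})

test_that("classification metrics follow the standard definitions", {
  m <- classification_metrics(list(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(unname(m), c(0.75, 0.75, 0.75, 0.8))
  perfect <- classification_metrics(list(tp = 4, fp = 0, fn = 0, tn = 6))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  degenerate <- classification_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(unname(degenerate[c("recall", "f1")]), c(0, 0))
  expect_error(classification_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "all-zero")
})

test_that("the ERT learns a separable rule and is seed-reproducible", {
  set.seed(55)
  x <- matrix(rnorm(200 * 6), 200,
              dimnames = list(NULL, sprintf("F%02d", 1:6)))
  meta <- data.frame(target_id = rep(c("A", "B"), each = 100),
                     cluster_n = 1L, cluster_m = 2L,
                     label = as.integer(x[, 1] > 0))
  cs <- structure(list(features = x, meta = meta,
                       feature_names = colnames(x)),
                  class = "comparison_set")
  cfg <- ert_config(n_trees = 300, seed = 9)
  m <- train_ert(cs, cfg)
  expect_gt(m$oob_accuracy, 0.95)

  p <- clusterrank:::predict_prob1(m, x)
  expect_true(all(p >= 0 & p <= 1))
  m2 <- train_ert(cs, cfg)
  expect_identical(clusterrank:::predict_prob1(m2, x), p)

  cs_one <- cs
  cs_one$meta$label <- 1L
  expect_error(train_ert(cs_one, cfg), "both classes")
})

test_that("leave-complex-out folds partition the targets", {
  tg <- mk_monotone_targets(11, 4, seed = 56)
  cs <- build_comparison_matrix(tg)
  cfg <- ert_config(n_trees = 50, seed = 2)
  cv <- leave_complex_out_cv(cs, cfg)
  expect_equal(nrow(cv$folds), 11)
  expect_setequal(cv$folds$target_id, names(tg))
  for (tid in names(tg))
    expect_false(tid %in% cv$train_targets[[tid]])
  expect_equal(dim(cv$importance), c(ncol(cs$features), 11))
})

test_that("LCO-CV accuracy is consistent with the OOB estimate", {
  # identical generative process in every target: the held-out target is
  # exchangeable with the bootstrap out-of-bag samples
  accs <- sapply(1:5, function(s) {
    tg <- mk_monotone_targets(4, 8, noise = 0.3, seed = 100 + s)
    cs <- build_comparison_matrix(tg)
    cfg <- ert_config(n_trees = 200, seed = s)
    cv <- leave_complex_out_cv(cs, cfg)
    m <- train_ert(cs, cfg)
    c(cv = unname(cv$mean["accuracy"]), oob = m$oob_accuracy)
  })
  d <- accs["cv", ] - accs["oob", ]
  # mean disagreement bounded by the seed-to-seed sampling spread
  expect_lt(abs(mean(d)), 2 * stats::sd(d) + 0.05)
})

test_that("win-count ranking matches a brute-force tournament oracle", {
  set.seed(57)
  tg <- mk_monotone_targets(6, 6, noise = 0.02, seed = 58)
  cs <- build_comparison_matrix(tg)
  model <- train_ert(cs, ert_config(n_trees = 300, seed = 3))

  new_t <- mk_monotone_targets(1, 4, noise = 0.0, seed = 59)[[1]]
  rk <- rank_clusters(model, new_t$features)
  # transitive near-oracle classifier: wins 3,2,1,0 in min-LRMSD order
  expect_equal(sort(rk$wins, decreasing = TRUE), c(3, 2, 1, 0))
  expect_equal(rk$cluster_id[rk$rank == 1],
               as.integer(names(which.min(new_t$min_lrmsd))))
  expect_equal(sum(rk$wins), choose(4, 2))
  expect_setequal(rk$rank, 1:4)

  # brute-force loop over ordered pairs reproduces the win counts
  cids <- vapply(new_t$features, `[[`, integer(1), "cluster_id")
  names(new_t$features) <- as.character(cids)
  wins <- stats::setNames(integer(4), sort(cids))
  for (a in sort(cids)) for (b in sort(cids)) {
    if (a >= b) next
    row <- matrix(c(new_t$features[[as.character(a)]]$values,
                    new_t$features[[as.character(b)]]$values), 1)
    colnames(row) <- model$feature_names
    p <- clusterrank:::predict_prob1(model, row)
    if (p > 0.5) wins[as.character(a)] <- wins[as.character(a)] + 1L
    else wins[as.character(b)] <- wins[as.character(b)] + 1L
  }
  expect_equal(rk$wins[order(rk$cluster_id)], unname(wins))

  # k = 2 degenerate tournament
  rk2 <- rank_clusters(model, new_t$features[1:2])
  expect_equal(rk2$rank, 1:2)
  expect_equal(sum(rk2$wins), 1)

  bad <- mk_cf(9, rnorm(3))
  expect_error(rank_clusters(model, list(bad, bad)), "dimension mismatch")
})

test_that("ranking quality degrades monotonically with descriptor noise", {
  ranks_at <- function(noise, seed) {
    tg <- mk_monotone_targets(5, 5, noise = noise, seed = seed)
    cs <- build_comparison_matrix(tg)
    cfg <- ert_config(n_trees = 150, seed = seed)
    mean(sapply(names(tg), function(tid) {
      m <- train_ert(clusterrank:::subset_comparisons(
        cs, cs$meta$target_id != tid), cfg)
      rk <- rank_clusters(m, tg[[tid]]$features)
      best <- as.integer(names(which.min(tg[[tid]]$min_lrmsd)))
      rk$rank[rk$cluster_id == best]
    }))
  }
  lo <- mean(sapply(1:3, function(s) ranks_at(0.01, 200 + s)))
  hi <- mean(sapply(1:3, function(s) ranks_at(3.0, 200 + s)))
  expect_lte(lo, hi)
  expect_lt(lo, 1.5)   # near-noiseless: best cluster found at the top
})
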