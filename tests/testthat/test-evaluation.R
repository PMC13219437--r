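test_that("fold assignment partitions instances into near-equal folds", {
  ids <- sprintf("i%03d", 1:136)
  fold <- make_folds(ids, n_folds = 10, seed = 1)
  sizes <- as.integer(table(fold))
  expect_equal(sort(sizes), sort(c(rep(14L, 6), rep(13L, 4))))
  expect_equal(sum(sizes), 136)
  expect_setequal(names(fold), ids)
  # determinism and seed sensitivity
  expect_identical(fold, make_folds(ids, 10, seed = 1))
  expect_false(identical(fold, make_folds(ids, 10, seed = 2)))
  # leave-one-out structure
  loo <- make_folds(1:12, n_folds = 12, seed = 3)
  expect_equal(sort(as.integer(table(loo))), rep(1L, 12))
  expect_error(make_folds(1:5, n_folds = 10), "at least as many")
})

test_that("stratified folds balance classes and keep sizes within one", {
  y <- rep(c("a", "b"), c(40, 96))
  fold <- make_folds(seq_along(y), n_folds = 10, seed = 4, stratified = TRUE, labels = y)
  sizes <- as.integer(table(fold))
  expect_lte(diff(range(sizes)), 1)
  per_fold_a <- table(fold[y == "a"])
  expect_lte(diff(range(as.integer(per_fold_a))), 1)
})

test_that("confusion-matrix metrics reproduce the reference arithmetic", {
  cm <- matrix(c(55, 6, 6, 69), 2, 2,
    byrow = TRUE,
    dimnames = list(
      actual = c("stressed", "non_stressed"),
      predicted = c("stressed", "non_stressed")
    )
  )
  expect_equal(sum(diag(cm)), 124)
  expect_equal(sum(cm), 136)
  m <- metrics_from_confusion(cm)
  expect_equal(round(m$accuracy, 2), 91.18)

  perfect <- matrix(c(10, 0, 0, 20), 2, 2)
  mp <- metrics_from_confusion(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$kappa, 1)
  expect_equal(mp$f_measure, 1)

  # all predictions in one class on a 50/50 truth: chance-level kappa
  onecol <- matrix(c(25, 0, 25, 0), 2, 2)
  mo <- metrics_from_confusion(onecol)
  expect_equal(mo$kappa, 0)
  expect_true(length(mo$flagged) > 0)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(5)
  for (i in 1:50) {
    cm <- matrix(rpois(4, 20), 2, 2)
    if (sum(cm) == 0) next
    m <- metrics_from_confusion(cm)
    expect_equal(m$accuracy, 100 * sum(diag(cm)) / sum(cm), tolerance = 1e-12)
    if (sum(cm) - sum(diag(cm)) == 0) {
      expect_equal(m$kappa, 1)
    } else {
      expect_lt(m$kappa, 1)
    }
    expect_gte(m$recall, 0)
    expect_lte(m$recall, 1)
  }
})

test_that("golden distance is zero at the ideal point and monotone", {
  expect_equal(golden_distance(1, 0), 0)
  expect_equal(round(golden_distance(0.9226, 0.0125), 4), 0.0784)
  expect_equal(round(golden_distance(0.5728, 0.0617), 4), 0.4316)
  expect_lte(golden_distance(0, 1), sqrt(2))
  # monotone: better av_nav or worse av_dco moves gd the right way
  g <- golden_distance(c(0.7, 0.8, 0.8), c(0.1, 0.1, 0.2))
  expect_gt(g[1], g[2])
  expect_lt(g[2], g[3])
  expect_error(golden_distance(NA, 0.1), "finite")
})

test_that("classifier specs carry the per-scheme reference hyperparameters", {
  rf <- classifier_spec("RF")
  expect_equal(rf$hyperparameters$iterations, 100L)
  expect_equal(rf$hyperparameters$max_depth, 10L)
  expect_equal(rf$hyperparameters$seed, 1L)
  expect_equal(classifier_spec("ABM", "non_overlapping")$hyperparameters$iterations, 100L)
  expect_equal(classifier_spec("ABM", "overlapping")$hyperparameters$iterations, 200L)
  expect_equal(classifier_spec("J48", "non_overlapping")$hyperparameters$folds, 3L)
  expect_equal(classifier_spec("J48", "overlapping")$hyperparameters$folds, 5L)
  expect_equal(classifier_spec("KNN")$hyperparameters$k, 5L)
  expect_error(classifier_spec("KNN", k_neighbors = 3), "unknown hyperparameter")
})

test_that("cross-validation is perfect on separable blobs and reproducible", {
  tab <- make_blob_table(n = 100, p = 4, sep = 5, seed = 6)
  knn <- cross_validate(tab, classifier_spec("KNN"), seed = 1)
  expect_equal(knn$accuracy, 100)
  expect_equal(knn$kappa, 1)
  # axis-aligned learners may drop a boundary point; still near-perfect
  for (cl in c("RF", "ABM", "J48")) {
    rep1 <- suppressMessages(cross_validate(tab, classifier_spec(cl), seed = 1))
    expect_gte(rep1$accuracy, 95)
    expect_gte(rep1$kappa, 0.9)
    rep2 <- suppressMessages(cross_validate(tab, classifier_spec(cl), seed = 1))
    expect_identical(rep1$confusion, rep2$confusion, info = cl)
  }
  mlp1 <- cross_validate(tab, classifier_spec("MLP"), seed = 1)
  mlp2 <- cross_validate(tab, classifier_spec("MLP"), seed = 1)
  expect_identical(mlp1$confusion, mlp2$confusion)
  expect_gte(mlp1$accuracy, 95)
})

test_that("cross-validation sits at chance under permuted labels", {
  set.seed(7)
  tab <- make_blob_table(n = 200, p = 5, sep = 0, seed = 8)
  tab$label <- sample(tab$label)
  rep <- cross_validate(tab, classifier_spec("KNN"), seed = 9)
  expect_lt(abs(rep$accuracy - 50), 10)
  expect_lt(abs(rep$kappa), 0.2)
  expect_equal(sum(rep$confusion), 200)
})

test_that("pooled confusion matrix accounts for every instance", {
  tab <- make_blob_table(n = 60, p = 3, sep = 2, seed = 10)
  rep <- cross_validate(tab, classifier_spec("RF"), n_folds = 5, seed = 11)
  expect_equal(sum(rep$confusion), nrow(tab))
  expect_equal(rep$accuracy, 100 * sum(diag(rep$confusion)) / sum(rep$confusion),
    tolerance = 1e-12
  )
  expect_gte(rep$roc_auc, 0.5)
})

test_that("degenerate CV inputs raise informative errors", {
  tab <- make_blob_table(n = 30, p = 2, sep = 1, seed = 12)
  tab$label[] <- "stressed"
  expect_error(cross_validate(tab, classifier_spec("KNN")), "both classes")
  tab2 <- make_blob_table(n = 30, p = 2, sep = 1, seed = 13)
  tab2$label[1:29] <- "stressed"
  tab2$label[30] <- "non_stressed"
  expect_error(
    cross_validate(tab2, classifier_spec("KNN"), n_folds = 10, seed = 1),
    "single-class training set"
  )
})

test_that("comparison table ranks by golden distance with deterministic ties", {
  tab <- make_blob_table(n = 80, p = 3, sep = 4, seed = 14)
  r1 <- cross_validate(tab, classifier_spec("KNN"), seed = 1)
  r2 <- cross_validate(tab, classifier_spec("RF"), seed = 1)
  single <- compare_report(r1)
  expect_equal(nrow(single), 1)

  av <- tibble::tibble(
    classifier = c("KNN", "RF"),
    scheme = "non_overlapping",
    av_nav = c(0.9, 0.8),
    av_dco = c(0.01, 0.02)
  )
  out <- compare_report(list(r1, r2), av = av)
  expect_equal(out$classifier[1], "KNN")
  expect_true(all(diff(out$golden_distance) >= 0))

  # equal gd: accuracy then name decides
  av2 <- av
  av2$av_nav <- 0.9
  av2$av_dco <- 0.01
  out2 <- compare_report(list(r1, r2), av = av2)
  expect_equal(
    out2$classifier[1],
    if (r1$accuracy >= r2$accuracy) "KNN" else "RF"
  )
})
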