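test_that("stratified folds are disjoint, exhaustive and label-balanced", {
  labels49 <- c(rep(1, 18), rep(0, 31))
  ks <- stratified_kfold(labels49, k = 5, seed = 3)
  sizes <- sort(vapply(ks$folds, length, integer(1)), decreasing = TRUE)
  expect_equal(sizes, c(10L, 10L, 10L, 10L, 9L))
  all_idx <- sort(unlist(ks$folds))
  expect_equal(all_idx, seq_along(labels49)) # exhaustive and disjoint
  pos <- vapply(ks$folds, function(f) sum(labels49[f]), numeric(1))
  expect_lte(max(pos) - min(pos), 1L)

  # property over random label vectors
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(25:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) < 5 || sum(1 - y) < 5) next
    ks_r <- stratified_kfold(y, 5, seed = rep)
    expect_equal(sort(unlist(ks_r$folds)), seq_len(n))
    for (cl in 0:1) {
      per <- vapply(ks_r$folds, function(f) sum(y[f] == cl), integer(1))
      expect_lte(max(per) - min(per), 1L)
    }
  }

  expect_error(stratified_kfold(c(rep(1, 3), rep(0, 20)), 5),
               "at least k")
  expect_identical(stratified_kfold(labels49, 5, seed = 3)$folds, ks$folds)
})

test_that("confusion metrics reproduce hand-computed confusion matrices", {
  # TP=3 FP=1 FN=1 TN=5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(.9, .8, .7, .2, .6, .1, .2, .3, .1, .2)
  m <- confusion_metrics(y, p)
  expect_equal(m$counts, c(tp = 3L, fp = 1L, fn = 1L, tn = 5L))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_false(m$degenerate)

  perfect <- confusion_metrics(c(1, 0, 1), c(.9, .1, .8))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, precision = 1, f1 = 1))

  none <- confusion_metrics(c(1, 1, 0), c(.1, .2, .3))
  expect_true(none$degenerate)
  expect_equal(none$precision, 0)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$f1, 0)

  # the positive call is strictly greater than the threshold
  at <- confusion_metrics(c(1, 0), c(0.5, 0.5))
  expect_equal(unname(at$counts["tp"]), 0L)
  expect_error(confusion_metrics(integer(0), numeric(0)))

  # enumerated small confusion matrices against direct formulas
  for (tp in 0:3) for (fp in 0:2) for (fn in 0:2) for (tn in 0:2) {
    n <- tp + fp + fn + tn
    if (n == 0) next
    y <- rep(c(1, 0, 1, 0), c(tp, fp, fn, tn))
    p <- rep(c(0.9, 0.9, 0.1, 0.1), c(tp, fp, fn, tn))
    m <- confusion_metrics(y, p)
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
  }
})

test_that("roc_auc equals the exhaustive pairwise statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.9, .5, .5, .1)), 0.875)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.9, .8, .2, .1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(.2, .3)), "single-class")

  set.seed(13)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2)) # rounded scores force ties
    expect_equal(roc_auc(y, s), brute_force_auc(y, s), tolerance = 1e-12)
    if (!any(duplicated(s))) {
      expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1, tolerance = 1e-12)
    }
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(40, 1, 0.5); s <- rnorm(40)
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("the AUC Z test matches an independently coded Hanley-McNeil oracle", {
  same <- auc_z_test(0.7, 10, 12, 0.7, 10, 12)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  zt <- auc_z_test(0.62, 18, 31, 0.69, 18, 31)
  expect_equal(zt$z, hm_z_oracle(0.62, 18, 31, 0.69, 18, 31),
               tolerance = 1e-6)
  expect_equal(zt$p, 2 * pnorm(-abs(zt$z)))

  # |Z| strictly increases with the AUC gap near 0.5
  gaps <- seq(0.01, 0.2, by = 0.01)
  zs <- vapply(gaps, function(g) {
    abs(auc_z_test(0.5, 20, 20, 0.5 + g, 20, 20)$z)
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(auc_z_test(0, 5, 5, 0.5, 5, 5))
})

test_that("embedding projection is deterministic and separates built clusters", {
  set.seed(15)
  base <- matrix(rnorm(40 * 8, sd = 0.1), 40)
  base[21:40, 1] <- base[21:40, 1] + 10 # inter/intra distance ratio ~ 10
  lab <- rep(0:1, each = 20)
  pr1 <- project_embeddings(base, lab)
  pr2 <- project_embeddings(base, lab)
  expect_identical(pr1, pr2)
  expect_equal(nrow(pr1), 40)
  expect_gt(silhouette_score(cbind(pr1$dim1, pr1$dim2), lab), 0.5)
  expect_error(project_embeddings(base[1:2, ], lab[1:2]), "nrow")
})

test_that("the CV harness emits per-fold rows plus coherent aggregates", {
  co <- tiny_cohort(n_ct = 14, n_mri = 0, n_mixed = 0, side = 32, d = 3,
                    seed = 41)
  grid <- data.frame(branch = "ct", network = "mcat", mode = "two_stage")
  opts <- cv_options(policy = augmentation_policy(multiplicity = 1),
                     pretrain_epochs = 2, finetune_epochs = 2,
                     batch_size = 8)
  rep1 <- run_cv_experiment(co, grid, seed = 2, k = 3, opts = opts)
  expect_s3_class(rep1, "metrics_report")
  expect_equal(nrow(rep1), 5) # 3 folds + mean + sd
  expect_equal(rep1$fold, c("1", "2", "3", "mean", "sd"))
  mcols <- c("accuracy", "sensitivity", "precision", "f1", "auc")
  folds <- rep1[rep1$fold %in% c("1", "2", "3"), mcols]
  expect_true(all(folds >= 0 & folds <= 1))
  # aggregates recomputed independently
  expect_equal(unlist(rep1[rep1$fold == "mean", mcols]), colMeans(folds),
               ignore_attr = TRUE)
  expect_equal(unlist(rep1[rep1$fold == "sd", mcols]), apply(folds, 2, sd),
               ignore_attr = TRUE)
  # identical seed and grid reproduce the report exactly
  rep2 <- run_cv_experiment(co, grid, seed = 2, k = 3, opts = opts)
  expect_identical(rep1, rep2)
  # baselines refuse two-stage training
  bad <- data.frame(branch = "ct", network = "2dcnn", mode = "two_stage")
  expect_error(run_cv_experiment(co, bad, seed = 2, k = 3, opts = opts),
               "end-to-end only")
})
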