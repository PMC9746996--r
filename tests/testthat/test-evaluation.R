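test_that("kfold_split partitions exactly, evenly and deterministically", {
  folds <- kfold_split(1000, k = 5, seed = 3)
  expect_length(folds, 5L)
  expect_equal(vapply(folds, length, 1L), rep(200L, 5))
  expect_identical(sort(unlist(folds)), 1:1000)         # disjoint cover
  expect_identical(folds, kfold_split(1000, k = 5, seed = 3))
  expect_false(identical(folds, kfold_split(1000, k = 5, seed = 4)))
  expect_error(kfold_split(10, k = 1), "k")
  expect_error(kfold_split(3, k = 5), "fewer")
})

test_that("cell-grouped folds never split a cell across folds", {
  ids <- rep(sprintf("c%02d", 1:20), each = 16)
  folds <- kfold_split(length(ids), k = 5, seed = 7, group = ids)
  expect_identical(sort(unlist(folds)), seq_along(ids))
  for (f in folds) {
    cells_in <- unique(ids[f])
    expect_true(all(table(ids[f]) == 16))               # whole cells only
    for (g in setdiff(seq_along(folds), which(vapply(folds, identical, TRUE, f))))
      expect_length(intersect(cells_in, unique(ids[folds[[g]]])), 0)
  }
})

test_that("score_metrics implements the three percentage formulas", {
  m <- score_metrics(list(TP = 9, FN = 1, FP = 0, TN = 10))
  expect_equal(unname(m), c(90, 100, 95))
  # perfect classifier
  expect_equal(unname(score_metrics(list(TP = 5, FN = 0, FP = 0, TN = 5))),
               c(100, 100, 100))
  # sensitivity not computable when no positives exist
  m0 <- score_metrics(list(TP = 0, FN = 0, FP = 2, TN = 8))
  expect_true(is.na(m0[["sensitivity"]]))
  expect_false(is.na(m0[["accuracy"]]))
  expect_error(score_metrics(list(TP = 0, FN = 0, FP = 0, TN = 0)), "samples")
  # accuracy invariant to which class is positive
  pred <- c("dying", "healthy", "dying", "dying")
  tru <- c("dying", "healthy", "healthy", "dying")
  a1 <- score_metrics(confusion_counts(pred, tru, "dying"))[["accuracy"]]
  a2 <- score_metrics(confusion_counts(pred, tru, "healthy"))[["accuracy"]]
  expect_equal(a1, a2)
})

test_that("roc_auc matches the Mann-Whitney oracle and its fixed points", {
  set.seed(19)
  labels <- sample(c("healthy", "dying"), 200, replace = TRUE)
  scores <- cbind(healthy = runif(200), dying = runif(200))
  # make scores informative for one class, leave ties in
  scores[, "dying"] <- round(scores[, "dying"] + (labels == "dying"), 1)
  r <- roc_auc(scores, labels)
  for (cls in c("healthy", "dying"))
    expect_equal(r[[cls]]$auc,
                 oracle_auc(scores[, cls], labels == cls), tolerance = 1e-12)

  # perfect separation: AUC = 1 for both classes
  y <- rep(c("healthy", "dying"), each = 10)
  perfect <- cbind(healthy = as.numeric(y == "healthy"),
                   dying = as.numeric(y == "dying"))
  rp <- roc_auc(perfect, y)
  expect_equal(rp$healthy$auc, 1); expect_equal(rp$dying$auc, 1)

  # constant scores: chance line, AUC = 0.5
  rc <- roc_auc(matrix(0.5, 20, 2), y)
  expect_equal(rc$healthy$auc, 0.5); expect_equal(rc$dying$auc, 0.5)

  expect_error(roc_auc(perfect, rep("dying", 20)), "both classes")
})

test_that("ROC curves are valid staircases from (0,0) to (1,1)", {
  set.seed(23)
  labels <- rep(c("healthy", "dying"), 30)
  scores <- cbind(runif(60), runif(60))
  r <- roc_auc(scores, labels)
  for (cls in names(r)) {
    expect_equal(r[[cls]]$tpr[1], 0); expect_equal(r[[cls]]$fpr[1], 0)
    expect_equal(tail(r[[cls]]$tpr, 1), 1); expect_equal(tail(r[[cls]]$fpr, 1), 1)
    expect_true(all(diff(r[[cls]]$tpr) >= 0))
    expect_true(all(diff(r[[cls]]$fpr) >= 0))
  }
})

test_that("evaluate_config wires the pipeline end to end", {
  cells <- small_cells(10, seed = 41)          # 20 cells, 320 samples
  rep1 <- evaluate_config(cells, "gd", N = 8, group = 1, arch = "mlp1",
                          seed = 11,
                          train_cfg = train_config(max_epochs = 60, seed = 11))
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$per_fold), 5L)
  expect_true(all(rep1$per_fold$accuracy >= 0 & rep1$per_fold$accuracy <= 100))
  expect_true(all(rep1$per_fold$auc_dying >= 0 & rep1$per_fold$auc_dying <= 1))
  # determinism under a fixed seed
  rep2 <- evaluate_config(cells, "gd", N = 8, group = 1, arch = "mlp1",
                          seed = 11,
                          train_cfg = train_config(max_epochs = 60, seed = 11))
  expect_identical(rep1$per_fold, rep2$per_fold)
})

test_that("run_experiment sweeps a grid and tolerates failures", {
  cells <- small_cells(6, seed = 43)
  res <- run_experiment(cells, methods = c("gd", "standard"),
                        levels = 8L, groups = 1L, archs = c("slp", "mlp1"),
                        seed = 5,
                        train_cfg = train_config(max_epochs = 40, seed = 5))
  expect_equal(nrow(res$summary), 4L)
  expect_setequal(res$summary$method, c("gd", "standard"))
  expect_true(all(is.finite(res$summary$accuracy)))
})
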