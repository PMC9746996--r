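#' Seeded k-fold partition
#'
#' Randomised partition of the sample indices into `k` near-equal parts;
#' each part serves as the validation fold exactly once. With `group`
#' supplied (e.g. cell ids), whole groups are assigned to folds so that no
#' group spans train and validation -- the guard against
#' within-cell feature leakage.
#'
#' @param n sample count, or a vector of sample ids whose length is used.
#' @param k number of folds (default 5); must satisfy `2 <= k <= n`.
#' @param seed RNG seed.
#' @param group optional vector of length `n` of group ids.
#' @return list of `k` integer vectors of validation indices (disjoint,
#'   covering `1..n`).
#' @export
kfold_split <- function(n, k = 5L, seed = 1L, group = NULL) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (k < 2) stop("kfold_split: k must be >= 2", call. = FALSE)
  if (n < k) stop("kfold_split: fewer samples than folds", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.null(group)) {
    fold_of <- integer(n)
    fold_of[sample.int(n)] <- rep(seq_len(k), length.out = n)
    lapply(seq_len(k), function(f) which(fold_of == f))
  } else {
    if (length(group) != n)
      stop("kfold_split: 'group' length must equal n", call. = FALSE)
    g <- unique(group)
    if (length(g) < k) stop("kfold_split: fewer groups than folds", call. = FALSE)
    gf <- rep(seq_len(k), length.out = length(g))[sample.int(length(g))]
    lapply(seq_len(k), function(f) which(group %in% g[gf == f]))
  }
}

#' Confusion counts for a two-class decision
#'
#' @param predicted character vector of predicted labels.
#' @param truth character vector of true labels.
#' @param positive the label counted as positive (default `"dying"`).
#' @return object of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth, positive = "dying") {
  structure(list(TP = sum(predicted == positive & truth == positive),
                 TN = sum(predicted != positive & truth != positive),
                 FP = sum(predicted == positive & truth != positive),
                 FN = sum(predicted != positive & truth == positive),
                 positive = positive),
            class = "confusion_counts")
}

#' Sensitivity, selectivity and accuracy from confusion counts
#'
#' Sensitivity (recall) `TP / (TP + FN) * 100`; selectivity (precision)
#' `TP / (TP + FP) * 100`; accuracy `(TP + TN) / total * 100`. When a
#' denominator is zero -- e.g. a classifier that never emits the positive
#' class -- the corresponding metric is `NA` ("could not be calculated"),
#' not an error: classification failure is a recordable outcome.
#'
#' @param counts a [confusion_counts()] or a list with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `c(sensitivity, selectivity, accuracy)` in
#'   percent; undefined entries `NA`.
#' @export
score_metrics <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("score_metrics: no samples counted", call. = FALSE)
  sens <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) * 100 else NA_real_
  sel  <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP) * 100 else NA_real_
  acc  <- (counts$TP + counts$TN) / tot * 100
  c(sensitivity = sens, selectivity = sel, accuracy = acc)
}

# ROC for one class: TPR/FPR swept over score thresholds, ties grouped
.roc_one <- function(score, pos) {
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop("roc_auc: both classes must be present", call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))              # tie groups share a threshold
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(tpr = tpr, fpr = fpr, auc = auc)
}

#' Per-class ROC curves and AUC
#'
#' One ROC curve per class, as is standard for a multi-class multi-label
#' head: for class `c`, samples of class `c` are positives and the class-`c`
#' score column is the discriminant. AUC by trapezoidal integration (with
#' tie-grouped thresholds this equals the Mann-Whitney U statistic).
#'
#' @param scores samples x classes matrix (columns ordered as `classes`).
#' @param labels character vector of true labels.
#' @param classes class order matching the score columns (default
#'   `c("healthy", "dying")`).
#' @return named list per class: `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels, classes = c("healthy", "dying")) {
  scores <- as.matrix(scores)
  out <- lapply(seq_along(classes), function(ci)
    .roc_one(scores[, ci], labels == classes[ci]))
  names(out) <- classes
  out
}

# one cross-validated evaluation of one dataset/classifier configuration
.cv_one <- function(ds, arch_name, k = 5L, seed = 1L, group_by_cell = FALSE,
                    tc = NULL, positive = "dying",
                    classes = c("healthy", "dying")) {
  X <- ds$X
  Y <- cbind(healthy = as.numeric(ds$label == "healthy"),
             dying = as.numeric(ds$label == "dying"))
  folds <- kfold_split(nrow(X), k = k, seed = seed,
                       group = if (group_by_cell) ds$cell_id)
  if (is.null(tc)) tc <- train_config(seed = seed)
  zscore <- !is.null(ds$features) && ds$features == "haralick"
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    vi <- folds[[f]]; ti <- setdiff(seq_len(nrow(X)), vi)
    Xt <- X[ti, , drop = FALSE]; Xv <- X[vi, , drop = FALSE]
    if (zscore) {       # training-fold statistics only, never the val fold
      mu <- colMeans(Xt); sd <- apply(Xt, 2, stats::sd); sd[sd == 0] <- 1
      Xt <- sweep(sweep(Xt, 2, mu), 2, sd, "/")
      Xv <- sweep(sweep(Xv, 2, mu), 2, sd, "/")
    }
    fold_seed <- (seed * 131L + f) %% .Machine$integer.max
    if (arch_name == "slp") {
      model <- slp_fit(Xt, Y[ti, ], mu = 0.1, epochs = 10L, seed = fold_seed)
    } else {
      nh <- if (arch_name == "mlp1") 1L else 2L
      fc <- tc; fc$seed <- as.integer(fold_seed)
      model <- mlp_fit(Xt, Y[ti, ], config = fc,
                       arch = mlp_architecture(ncol(Xt), nh, allow_odd = TRUE))
    }
    sc <- predict(model, Xv)
    pred <- classes[max.col(sc, ties.method = "first")]
    truth <- ds$label[vi]
    m <- score_metrics(confusion_counts(pred, truth, positive))
    roc <- tryCatch(roc_auc(sc, truth, classes), error = function(e) NULL)
    # per-cell granularity: mean score over each cell's GLCM samples
    ag <- aggregate_by_cell(sc, ds$cell_id[vi])
    truth_cell <- ds$label[vi][match(ag$cell_id, ds$cell_id[vi])]
    pred_cell <- classes[max.col(ag$scores, ties.method = "first")]
    mc <- score_metrics(confusion_counts(pred_cell, truth_cell, positive))
    roc_c <- tryCatch(roc_auc(ag$scores, truth_cell, classes),
                      error = function(e) NULL)
    per_fold[[f]] <- data.frame(
      fold = f, sensitivity = m[["sensitivity"]],
      selectivity = m[["selectivity"]], accuracy = m[["accuracy"]],
      auc_healthy = if (is.null(roc)) NA_real_ else roc$healthy$auc,
      auc_dying = if (is.null(roc)) NA_real_ else roc$dying$auc,
      cell_sensitivity = mc[["sensitivity"]],
      cell_selectivity = mc[["selectivity"]],
      cell_accuracy = mc[["accuracy"]],
      cell_auc_healthy = if (is.null(roc_c)) NA_real_ else roc_c$healthy$auc,
      cell_auc_dying = if (is.null(roc_c)) NA_real_ else roc_c$dying$auc)
  }
  per_fold <- do.call(rbind, per_fold)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, -1], na.rm = TRUE),
       sd = apply(per_fold[, -1], 2, stats::sd, na.rm = TRUE))
}

#' Cross-validated evaluation of one configuration
#'
#' Featurizes `cells` for one (method, N, group) combination, trains the
#' requested classifier with 5-fold cross-validation and reports the three
#' headline metrics plus per-class AUC, per fold and aggregated.
#'
#' @param cells list of [cell_image()].
#' @param method `"gd"`, `"gm"` (vectorised gradient-map GLCMs) or
#'   `"standard"` (ten Haralick features of intensity GLCMs).
#' @param N GLCM size (8, 16, 32, 64).
#' @param group offset group (1, 2, 3).
#' @param arch `"slp"`, `"mlp1"` or `"mlp2"`.
#' @param k folds (default 5).
#' @param seed RNG seed driving the fold split and training.
#' @param group_by_cell keep all GLCM samples of a cell in one fold.
#' @param train_cfg optional [train_config()] override.
#' @return object of class `eval_report`: `config`, `per_fold` (data.frame),
#'   `mean`, `sd`.
#' @export
evaluate_config <- function(cells, method = c("gd", "gm", "standard"),
                            N = 8L, group = 1L,
                            arch = c("mlp1", "mlp2", "slp"),
                            k = 5L, seed = 1L, group_by_cell = FALSE,
                            train_cfg = NULL) {
  method <- match.arg(method)
  arch <- match.arg(arch)
  ds <- switch(method,
               gd = build_dataset(cells, "GD", N = N, group = group),
               gm = build_dataset(cells, "GM", N = N, group = group),
               standard = build_standard_dataset(cells, N = N, group = group))
  res <- .cv_one(ds, arch, k = k, seed = seed, group_by_cell = group_by_cell,
                 tc = train_cfg)
  structure(list(config = list(method = method, N = as.integer(N),
                               group = as.integer(group), arch = arch,
                               k = as.integer(k), seed = as.integer(seed),
                               group_by_cell = group_by_cell),
                 per_fold = res$per_fold, mean = res$mean, sd = res$sd),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<eval_report %s N=%d group=%d %s, %d-fold seed=%d>\n",
              cfg$method, cfg$N, cfg$group, cfg$arch, cfg$k, cfg$seed))
  cat(sprintf("  accuracy    %.2f%% +/- %.2f\n", x$mean[["accuracy"]],
              x$sd[["accuracy"]]))
  cat(sprintf("  sensitivity %.2f%%  selectivity %.2f%%\n",
              x$mean[["sensitivity"]], x$mean[["selectivity"]]))
  cat(sprintf("  AUC healthy %.4f  dying %.4f\n",
              x$mean[["auc_healthy"]], x$mean[["auc_dying"]]))
  cat(sprintf("  per-cell: accuracy %.2f%%  AUC healthy %.4f  dying %.4f\n",
              x$mean[["cell_accuracy"]], x$mean[["cell_auc_healthy"]],
              x$mean[["cell_auc_dying"]]))
  invisible(x)
}

#' Run a grid of method/size/group/architecture configurations
#'
#' The comparative experiment: every requested combination is evaluated by
#' [evaluate_config()]; a failing configuration is recorded (message and NA
#' metrics) rather than aborting the sweep, since classification failure is
#' itself a result.
#'
#' @param cells list of [cell_image()].
#' @param methods subset of `c("gd", "gm", "standard")`.
#' @param levels GLCM sizes to sweep.
#' @param groups offset groups to sweep.
#' @param archs classifier architectures to sweep.
#' @inheritParams evaluate_config
#' @return list with `summary` (tidy data.frame, one row per configuration)
#'   and `reports` (list of `eval_report`).
#' @export
run_experiment <- function(cells, methods = c("gd", "gm", "standard"),
                           levels = c(8L, 16L, 32L, 64L), groups = 1:3,
                           archs = c("slp", "mlp1", "mlp2"),
                           k = 5L, seed = 1L, group_by_cell = FALSE,
                           train_cfg = NULL) {
  grid <- expand.grid(method = methods, N = levels, group = groups,
                      arch = archs, stringsAsFactors = FALSE)
  reports <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rep_i <- tryCatch(
      evaluate_config(cells, g$method, g$N, g$group, g$arch,
                      k = k, seed = seed, group_by_cell = group_by_cell,
                      train_cfg = train_cfg),
      error = function(e) {
        message(sprintf("config %s/N=%d/g%d/%s failed: %s",
                        g$method, g$N, g$group, g$arch, conditionMessage(e)))
        NULL
      })
    reports[[i]] <- rep_i
    rows[[i]] <- data.frame(
      method = g$method, N = g$N, group = g$group, arch = g$arch,
      accuracy = if (is.null(rep_i)) NA_real_ else rep_i$mean[["accuracy"]],
      accuracy_sd = if (is.null(rep_i)) NA_real_ else rep_i$sd[["accuracy"]],
      sensitivity = if (is.null(rep_i)) NA_real_ else rep_i$mean[["sensitivity"]],
      selectivity = if (is.null(rep_i)) NA_real_ else rep_i$mean[["selectivity"]],
      auc_healthy = if (is.null(rep_i)) NA_real_ else rep_i$mean[["auc_healthy"]],
      auc_dying = if (is.null(rep_i)) NA_real_ else rep_i$mean[["auc_dying"]])
  }
  list(summary = do.call(rbind, rows), reports = reports)
}
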