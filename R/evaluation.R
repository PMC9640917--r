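# Evaluation protocol: stratified 5-fold cross-validation with 4:1 splits,
# thresholded confusion metrics, Mann-Whitney AUC, Hanley-McNeil Z test for
# AUC comparison, the cross-validated experiment grid, and 2D embedding
# projections.

#' Stratified k-fold split
#'
#' Partitions record indices into k folds preserving class balance: each
#' class is dealt evenly, with remainders assigned to the currently smallest
#' folds, so per-fold positive counts deviate from perfect stratification by
#' at most one.  With `k = 5` each validation fold holds ~1/5 of the records
#' (the 4:1 train:validation convention).
#'
#' @param records List of [lesion_record()]s, or a vector of binary labels.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffles.
#' @return A `fold_split`: list with `folds` (list of validation index
#'   vectors), `k`, `labels` and `seed`.
#' @export
stratified_kfold <- function(records, k = 5L, seed = 1L) {
  labels <- if (is.list(records)) record_labels(records) else as.integer(records)
  k <- as.integer(k)
  stopifnot(k >= 2)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " members (got ",
         min(counts), ")")
  }
  folds <- rep(list(integer(0)), k)
  with_seed(derive_seed(seed, "kfold"), {
    for (cl in names(sort(counts, decreasing = TRUE))) {
      idx <- sample(which(labels == as.integer(cl)))
      q <- length(idx) %/% k
      r <- length(idx) %% k
      sizes <- vapply(folds, length, integer(1))
      extra <- order(sizes, seq_len(k))[seq_len(r)] # smallest folds first
      take <- rep(q, k)
      take[extra] <- q + 1L
      pos <- 1L
      for (f in seq_len(k)) {
        if (take[f] == 0) next
        folds[[f]] <- c(folds[[f]], idx[pos:(pos + take[f] - 1L)])
        pos <- pos + take[f]
      }
    }
  })
  folds <- lapply(folds, sort)
  structure(list(folds = folds, k = k, labels = labels, seed = seed),
            class = "fold_split")
}

#' Thresholded confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall on the MVI-positive class), precision and
#' F1 at a positive-call threshold (strictly greater than).  When no positive
#' calls are made, precision and F1 are defined as 0 and flagged.
#'
#' @param labels Binary labels.
#' @param probabilities Predicted probabilities, same length.
#' @param threshold Positive-call threshold (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `precision`, `f1`, the
#'   confusion counts, and `degenerate` (TRUE when no positive predictions).
#' @export
confusion_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities), length(labels) > 0,
            all(labels %in% c(0, 1)))
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  degenerate <- (tp + fp) == 0
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  prec <- if (degenerate) 0 else tp / (tp + fp)
  f1 <- if (degenerate || is.na(sens) || (prec + sens) == 0) 0 else {
    2 * prec * sens / (prec + sens)
  }
  list(accuracy = (tp + tn) / length(labels), sensitivity = sens,
       precision = prec, f1 = f1,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       degenerate = degenerate)
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The fraction of (positive, negative) pairs ordered correctly by the
#' score, with ties counted 1/2 — computed via midranks.
#'
#' @param labels Binary labels (both classes must be present).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: single-class labels")
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Unpaired Z test between two AUCs (Hanley-McNeil standard errors)
#'
#' `Z = (auc2 - auc1) / sqrt(SE1^2 + SE2^2)` with each standard error from
#' the Hanley-McNeil closed form, and a two-sided normal p value.
#'
#' @param auc1,auc2 The two AUC values (in (0, 1)).
#' @param n_pos1,n_neg1,n_pos2,n_neg2 Class sizes behind each AUC.
#' @return List with `z`, `p`, `se1`, `se2`.
#' @export
auc_z_test <- function(auc1, n_pos1, n_neg1, auc2, n_pos2, n_neg2) {
  stopifnot(auc1 > 0, auc1 < 1, auc2 > 0, auc2 < 1,
            n_pos1 >= 1, n_neg1 >= 1, n_pos2 >= 1, n_neg2 >= 1)
  se1 <- hanley_mcneil_se(auc1, n_pos1, n_neg1)
  se2 <- hanley_mcneil_se(auc2, n_pos2, n_neg2)
  z <- (auc2 - auc1) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(-abs(z)), se1 = se1, se2 = se2)
}

#' Mean silhouette width of a binary labelling in embedding space
#'
#' @param embeddings `N x E` matrix.
#' @param labels Binary labels.
#' @return Mean silhouette width (Euclidean distances).
#' @export
silhouette_score <- function(embeddings, labels) {
  stopifnot(nrow(embeddings) == length(labels), length(unique(labels)) == 2)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(as.integer(factor(labels)),
                               stats::dist(embeddings))
    return(mean(sil[, "sil_width"]))
  }
  d <- as.matrix(stats::dist(embeddings))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Deterministic 2D projection of an embedding space
#'
#' Principal-component projection onto the first two components with a fixed
#' sign convention (the largest-magnitude loading of each component is made
#' positive), so identical inputs yield identical coordinates.
#'
#' @param embeddings `N x E` matrix (`N >= 3`).
#' @param labels Class labels for colouring.
#' @param method Projection method (principal components).
#' @return Data frame with `dim1`, `dim2`, `label`.
#' @export
project_embeddings <- function(embeddings, labels, method = "pca") {
  stopifnot(nrow(embeddings) >= 3, nrow(embeddings) == length(labels))
  method <- match.arg(method, "pca")
  pc <- prcomp(embeddings, center = TRUE, scale. = FALSE, rank. = 2)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
    }
  }
  xy <- scale(embeddings, center = pc$center, scale = FALSE) %*% rot
  data.frame(dim1 = xy[, 1], dim2 = if (ncol(xy) > 1) xy[, 2] else 0,
             label = labels)
}

# Cross-validated experiment grid ----------------------------------------------

# Train a baseline classifier (BCE, single stage) on one modality.
train_classifier <- function(model, records, modality, policy, epochs,
                             epochs_aug = epochs, batch_size = 16L, lr = 0.05,
                             momentum = 0.9, weight_decay = 1e-3, seed = 1L) {
  check_trainable(records, modality)
  if (epochs > 0) {
    model$norm <- fit_input_norm(stack_array(records, modality))
  }
  state <- sgd_state(net_params(model$layers))
  with_seed(derive_seed(seed, paste0("classifier/", model$kind)), {
    for (ep in seq_len(epochs)) {
      use_policy <- if (ep <= epochs_aug) policy else NULL
      dat <- epoch_arrays(records, modality, use_policy)
      ord <- sample(length(dat$y))
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        xb <- apply_input_norm(dat$x[, , , idx, drop = FALSE], model$norm)
        yb <- dat$y[idx]
        fw <- net_forward(model$layers, xb, train = TRUE)
        model$layers <- net_commit_bn(model$layers, fw$bn)
        prob <- sigmoid(as.numeric(fw$out))
        dlogit <- matrix((prob - yb) / length(yb), ncol = 1)
        bw <- net_backward(model$layers, fw$caches, dlogit)
        upd <- net_update(model$layers, bw$grads, state, lr, momentum,
                          weight_decay)
        model$layers <- upd$layers
        state <- upd$state
      }
    }
  })
  model
}

classifier_probs <- function(model, records, modality) {
  classifier_forward(model, stack_array(records, modality))$prob
}

branch_probs <- function(branch, records) {
  branch_forward(branch, stack_array(records, branch$cfg$modality))$prob
}

fold_metric_row <- function(labels, probs) {
  cm <- confusion_metrics(labels, probs)
  data.frame(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             precision = cm$precision, f1 = cm$f1,
             auc = roc_auc(labels, probs))
}

#' Experiment options for the cross-validation harness
#'
#' Problem-size knobs of [run_cv_experiment()]: augmentation policy, stage
#' epochs, joint-update epochs and batch size.
#'
#' @param policy Augmentation policy applied to training folds only.
#' @param pretrain_epochs,finetune_epochs Two-stage epoch budget (end-to-end
#'   runs use their sum under budget parity).
#' @param joint_epochs Joint-update epochs for the double branch.
#' @param batch_size Minibatch size.
#' @param mining Triplet mining strategy used in pretraining.
#' @return A list of options.
#' @export
cv_options <- function(policy = augmentation_policy(multiplicity = 1L),
                       pretrain_epochs = 12L, finetune_epochs = 12L,
                       joint_epochs = 5L, batch_size = 32L,
                       mining = "batch_all") {
  list(policy = policy, pretrain_epochs = pretrain_epochs,
       finetune_epochs = finetune_epochs, joint_epochs = joint_epochs,
       batch_size = batch_size, mining = mining)
}

#' Records eligible for a branch
#'
#' CT branch: CT-only plus mixed lesions; MRI branch: MRI-only plus mixed;
#' double branch: the mixed group only.
#'
#' @param cohort List of [lesion_record()]s.
#' @param branch `"ct"`, `"mri"` or `"double"`.
#' @return The eligible subset of `cohort`.
#' @export
eligible_records <- function(cohort, branch) {
  av <- vapply(cohort, function(r) r$availability, character(1))
  switch(branch,
    ct = cohort[av %in% c("ct", "both")],
    mri = cohort[av %in% c("mri", "both")],
    double = cohort[av == "both"],
    stop("unknown branch: ", branch)
  )
}

train_single_for_modality <- function(network, mode, modality, records,
                                      side, opts, seed) {
  if (network == "mcat") {
    branch <- build_single_branch(branch_config(modality), seed = seed)
    train_branch(branch, records, mode = mode, policy = opts$policy,
                 pretrain_epochs = opts$pretrain_epochs,
                 finetune_epochs = opts$finetune_epochs, seed = seed,
                 batch_size = opts$batch_size, mining = opts$mining)
  } else {
    if (mode != "end_to_end") {
      stop("baseline networks train end-to-end only")
    }
    n_ch <- length(modality_channels(modality))
    model <- build_baseline(network, n_ch, seed = seed)
    train_classifier(model, records, modality, opts$policy,
                     epochs = opts$pretrain_epochs + opts$finetune_epochs,
                     epochs_aug = opts$pretrain_epochs,
                     batch_size = opts$batch_size, seed = seed)
  }
}

#' Run a grid of cross-validated experiments
#'
#' For every requested (branch, network, mode) combination: stratified
#' 5-fold cross-validation within the branch's eligible records (CT branch:
#' CT-only plus mixed lesions; MRI branch: MRI-only plus mixed; double
#' branch: folds over the mixed group, with single-modality lesions always
#' available for branch training).  Augmentation touches training folds
#' only; validation folds are evaluated on the raw records.  The double
#' branch fuses the two trained branches with equal weights and, for the
#' MCAT network, jointly updates both branches on the mixed training
#' records.
#'
#' @param cohort List of [lesion_record()]s.
#' @param grid Data frame with columns `branch` (`ct`/`mri`/`double`),
#'   `network` (`2dcnn`/`resnet18`/`senet18`/`ecanet18`/`mcat`) and `mode`
#'   (`two_stage`/`end_to_end`; baselines support `end_to_end` only).
#' @param seed Integer seed controlling folds, initialisation and training.
#' @param k Number of folds.
#' @param opts Options from [cv_options()].
#' @return A `metrics_report` data frame with one row per fold plus `mean`
#'   and `sd` aggregate rows per experiment.
#' @export
run_cv_experiment <- function(cohort, grid, seed = 1L, k = 5L,
                              opts = cv_options()) {
  stopifnot(all(c("branch", "network", "mode") %in% names(grid)))
  side <- dim(stack_array(cohort[1], ifelse(is.null(cohort[[1]]$ct), "mri", "ct")))[1]
  out <- list()
  for (g in seq_len(nrow(grid))) {
    branch_kind <- as.character(grid$branch[g])
    network <- as.character(grid$network[g])
    mode <- as.character(grid$mode[g])
    elig <- eligible_records(cohort, branch_kind)
    split <- stratified_kfold(elig, k = k,
                              seed = derive_seed(seed, paste(branch_kind, network, mode)))
    fold_rows <- list()
    for (f in seq_len(k)) {
      va_idx <- split$folds[[f]]
      va <- elig[va_idx]
      tr <- elig[setdiff(seq_along(elig), va_idx)]
      fseed <- derive_seed(seed, paste(branch_kind, network, mode, "fold", f))
      if (branch_kind %in% c("ct", "mri")) {
        model <- train_single_for_modality(network, mode, branch_kind, tr,
                                           side, opts, fseed)
        probs <- if (network == "mcat") branch_probs(model, va)
                 else classifier_probs(model, va, branch_kind)
      } else {
        av <- vapply(cohort, function(r) r$availability, character(1))
        va_ids <- vapply(va, function(r) r$lesion_id, character(1))
        pool <- cohort[!vapply(cohort, function(r) r$lesion_id, character(1)) %in% va_ids]
        pav <- vapply(pool, function(r) r$availability, character(1))
        ct_tr <- pool[pav %in% c("ct", "both")]
        mr_tr <- pool[pav %in% c("mri", "both")]
        mixed_tr <- pool[pav == "both"]
        if (network == "mcat") {
          ct_b <- train_single_for_modality("mcat", mode, "ct", ct_tr, side, opts, fseed)
          mr_b <- train_single_for_modality("mcat", mode, "mri", mr_tr, side, opts, fseed)
          model <- fuse_branches(ct_b, mr_b,
                                 fusion_config(epochs = opts$joint_epochs,
                                               batch_size = opts$batch_size,
                                               seed = fseed))
          if (opts$joint_epochs > 0 && length(mixed_tr) > 0) {
            model <- joint_update(model, mixed_tr)
          }
          probs <- predict_cohort(model, va)$prob
        } else {
          ct_m <- train_single_for_modality(network, mode, "ct", ct_tr, side, opts, fseed)
          mr_m <- train_single_for_modality(network, mode, "mri", mr_tr, side, opts, fseed)
          probs <- 0.5 * classifier_probs(ct_m, va, "ct") +
            0.5 * classifier_probs(mr_m, va, "mri")
        }
      }
      labels <- record_labels(va)
      fold_rows[[f]] <- cbind(
        data.frame(branch = branch_kind, network = network, mode = mode,
                   fold = as.character(f), n = length(va)),
        fold_metric_row(labels, probs)
      )
    }
    folds_df <- do.call(rbind, fold_rows)
    mcols <- c("accuracy", "sensitivity", "precision", "f1", "auc")
    agg <- folds_df[1:2, ]
    agg$fold <- c("mean", "sd")
    agg$n <- sum(folds_df$n)
    agg[1, mcols] <- colMeans(folds_df[, mcols])
    agg[2, mcols] <- apply(folds_df[, mcols], 2, sd)
    out[[g]] <- rbind(folds_df, agg)
  }
  structure(do.call(rbind, out), class = c("metrics_report", "data.frame"))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Cross-validated metrics (per fold and aggregate):\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
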