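# Small-sample training: geometric/intensity augmentation, triplet
# metric-learning pretraining of the feature-embedding module, fine-tuning
# of the evaluation head, and the end-to-end comparator trained under the
# same step budget.

#' Data augmentation policy
#'
#' One policy describes the random transform family applied to training
#' stacks: flips, rotation, isotropic scale jitter and a per-channel additive
#' intensity jitter.  The same geometric transform is applied to every
#' channel of a stack so channels stay registered.
#'
#' @param hflip,vflip Enable horizontal / vertical flips (each with
#'   probability 0.5 when enabled).
#' @param rotate Maximum rotation in degrees (drawn uniformly in ±`rotate`).
#' @param scale Scale jitter half-range (factor drawn in `1 ± scale`).
#' @param intensity_sd SD of the per-channel additive intensity offset.
#' @param multiplicity Augmented copies per original per epoch, `M >= 1`.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(hflip = TRUE, vflip = TRUE, rotate = 15,
                                scale = 0.1, intensity_sd = 0.02,
                                multiplicity = 8L) {
  stopifnot(rotate >= 0, scale >= 0, intensity_sd >= 0, multiplicity >= 1)
  structure(list(hflip = hflip, vflip = vflip, rotate = rotate, scale = scale,
                 intensity_sd = intensity_sd,
                 multiplicity = as.integer(multiplicity)),
            class = "augmentation_policy")
}

# Affine (rotation + scale + flips) bilinear warp about the patch centre;
# the sampling loop is compiled.
affine_warp <- function(img, theta, scale, fh, fv) {
  .warp_affine(img, theta, scale, fh, fv)
}

#' Augment one modality stack
#'
#' Draws one random transform from the policy (using the current RNG stream)
#' and applies it identically to every channel; values are re-clipped to
#' `[0, 1]`.  A policy with all ranges zero and flips disabled returns the
#' stack unchanged.
#'
#' @param stack A `modality_stack`.
#' @param policy An [augmentation_policy()].
#' @return The augmented `modality_stack`.
#' @export
augment <- function(stack, policy) {
  stopifnot(inherits(stack, "modality_stack"),
            inherits(policy, "augmentation_policy"))
  fh <- policy$hflip && runif(1) < 0.5
  fv <- policy$vflip && runif(1) < 0.5
  theta <- if (policy$rotate > 0) runif(1, -policy$rotate, policy$rotate) * pi / 180 else 0
  sc <- if (policy$scale > 0) runif(1, 1 - policy$scale, 1 + policy$scale) else 1
  px <- stack$pixels
  identity_geom <- !fh && !fv && theta == 0 && sc == 1
  for (i in seq_len(dim(px)[3])) {
    ch <- px[, , i]
    if (!identity_geom) ch <- affine_warp(ch, theta, sc, fh, fv)
    if (policy$intensity_sd > 0) ch <- ch + rnorm(1, sd = policy$intensity_sd)
    px[, , i] <- if (identity_geom && policy$intensity_sd == 0) ch else pmin(pmax(ch, 0), 1)
  }
  stack$pixels <- px
  stack
}

#' Triplet margin loss on (anchor, positive, negative) embeddings
#'
#' `max(0, ||e_a - e_p||^2 - ||e_a - e_n||^2 + m)` with squared Euclidean
#' distances; rows are triplets when matrices are given.
#'
#' @param e_a,e_p,e_n Embedding vectors, or matrices with one triplet per row.
#' @param margin Margin `m > 0`.
#' @return Nonnegative loss per triplet.
#' @export
triplet_loss <- function(e_a, e_p, e_n, margin = 0.3) {
  if (is.null(dim(e_a))) e_a <- matrix(e_a, 1)
  if (is.null(dim(e_p))) e_p <- matrix(e_p, 1)
  if (is.null(dim(e_n))) e_n <- matrix(e_n, 1)
  if (!all(dim(e_a) == dim(e_p)) || !all(dim(e_a) == dim(e_n))) {
    stop("embedding dimensions differ")
  }
  stopifnot(margin > 0)
  dp <- rowSums((e_a - e_p)^2)
  dn <- rowSums((e_a - e_n)^2)
  pmax(0, dp - dn + margin)
}

#' Mine triplets within a batch
#'
#' `batch_all` enumerates every valid (anchor, positive, negative) index
#' triple; `batch_hard` keeps, per anchor, its farthest positive and nearest
#' negative in embedding space.
#'
#' @param embeddings `N x E` matrix of embeddings.
#' @param labels Binary labels of the batch rows.
#' @param strategy `"batch_hard"` (default) or `"batch_all"`.
#' @return A `triplet_batch`: data frame of index columns
#'   `anchor`, `positive`, `negative` plus the strategy tag.
#' @export
mine_triplets <- function(embeddings, labels,
                          strategy = c("batch_hard", "batch_all")) {
  strategy <- match.arg(strategy)
  n <- length(labels)
  stopifnot(nrow(embeddings) == n)
  has_pos <- vapply(seq_len(n), function(i) sum(labels == labels[i]) > 1, logical(1))
  has_neg <- vapply(seq_len(n), function(i) any(labels != labels[i]), logical(1))
  anchors <- which(has_pos & has_neg)
  if (length(anchors) == 0) stop("no valid triplets: batch is single-class")
  rows <- list()
  if (strategy == "batch_all") {
    for (a in anchors) {
      ps <- setdiff(which(labels == labels[a]), a)
      ns <- which(labels != labels[a])
      grid <- expand.grid(positive = ps, negative = ns)
      rows[[length(rows) + 1L]] <- data.frame(anchor = a, grid)
    }
  } else {
    d2 <- as.matrix(stats::dist(embeddings))^2
    for (a in anchors) {
      ps <- setdiff(which(labels == labels[a]), a)
      ns <- which(labels != labels[a])
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = a,
        positive = ps[which.max(d2[a, ps])],
        negative = ns[which.min(d2[a, ns])]
      )
    }
  }
  out <- do.call(rbind, rows)[, c("anchor", "positive", "negative")]
  structure(out, strategy = strategy, class = c("triplet_batch", "data.frame"))
}

#' Training-stage configuration
#'
#' @param stage `"pretrain"`, `"finetune"` or `"end_to_end"`.
#' @param epochs Number of passes over the (augmented) training set.
#' @param batch_size Minibatch size.
#' @param lr Learning rate (SGD with momentum); stage defaults: 0.05 for
#'   pretraining / end-to-end, 0.01 for fine-tuning.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient applied through the optimizer.
#' @param margin Triplet margin (pretraining).
#' @param mining Triplet mining strategy.
#' @param embed_lr_factor Learning-rate multiplier on the embedding module
#'   during fine-tuning (0.1; the embedding is kept plastic but slow).
#' @param freeze_embedding Freeze the embedding entirely during fine-tuning.
#' @param seed Integer seed controlling shuffling and augmentation draws.
#' @return A `training_config` list.
#' @export
training_config <- function(stage = c("pretrain", "finetune", "end_to_end"),
                            epochs = 30L, batch_size = 16L, lr = NULL,
                            momentum = 0.9, weight_decay = 1e-3, margin = 0.3,
                            mining = "batch_hard", embed_lr_factor = 0.1,
                            freeze_embedding = FALSE, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(lr)) lr <- if (stage == "finetune") 0.01 else 0.05
  stopifnot(epochs >= 0, batch_size >= 2, lr > 0, margin > 0)
  structure(list(stage = stage, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 margin = margin, mining = mining,
                 embed_lr_factor = embed_lr_factor,
                 freeze_embedding = freeze_embedding, seed = as.integer(seed)),
            class = "training_config")
}

# One epoch's worth of training arrays: M augmented copies per original (or
# the originals themselves when policy is NULL).
epoch_arrays <- function(records, modality, policy) {
  if (is.null(policy)) {
    return(list(x = stack_array(records, modality), y = record_labels(records)))
  }
  M <- policy$multiplicity
  stacks <- lapply(records, function(r) r[[modality]])
  y <- rep(record_labels(records), each = M)
  d <- dim(stacks[[1]]$pixels)
  x <- array(0, c(d, length(stacks) * M))
  k <- 0L
  for (s in stacks) {
    for (m in seq_len(M)) {
      k <- k + 1L
      x[, , , k] <- augment(s, policy)$pixels
    }
  }
  list(x = x, y = y)
}

check_trainable <- function(records, modality, need_both_classes = TRUE) {
  if (length(records) == 0) stop("empty training set")
  if (any(vapply(records, function(r) is.null(r[[modality]]), logical(1)))) {
    stop("all training records must carry the ", modality, " modality")
  }
  y <- record_labels(records)
  if (need_both_classes && length(unique(y)) < 2) {
    stop("single-class training set")
  }
  invisible(y)
}

#' Pretrain the feature-embedding module with triplet metric learning
#'
#' Stage one of the small-sample strategy: each epoch the training records
#' are expanded by the augmentation policy, embedded, triplets are mined
#' within each minibatch and the triplet margin loss is backpropagated
#' through the embedding module only — the evaluation head is untouched.
#'
#' @param branch An `mcat_branch`.
#' @param records Training [lesion_record()]s, all carrying the branch
#'   modality.
#' @param policy An [augmentation_policy()] or `NULL` for no augmentation.
#' @param cfg A [training_config()] with `stage = "pretrain"`.
#' @return List with the trained `branch` and a `history` data frame of mean
#'   per-epoch triplet loss.
#' @export
pretrain_embedding <- function(branch, records, policy, cfg) {
  stopifnot(inherits(branch, "mcat_branch"), cfg$stage == "pretrain")
  modality <- branch$cfg$modality
  check_trainable(records, modality)
  if (cfg$epochs > 0) branch <- fit_branch_norm(branch, records)
  state <- sgd_state(net_params(branch$embed))
  history <- numeric(0)
  with_seed(derive_seed(cfg$seed, "pretrain"), {
    for (ep in seq_len(cfg$epochs)) {
      dat <- epoch_arrays(records, modality, policy)
      ord <- sample(length(dat$y))
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        if (length(idx) < 3 || length(unique(dat$y[idx])) < 2) next
        xb <- apply_input_norm(dat$x[, , , idx, drop = FALSE], branch$norm)
        fw <- net_forward(branch$embed, xb, train = TRUE)
        branch$embed <- net_commit_bn(branch$embed, fw$bn)
        Z <- fw$out
        tb <- mine_triplets(Z, dat$y[idx], cfg$mining)
        li <- triplet_loss(Z[tb$anchor, , drop = FALSE],
                           Z[tb$positive, , drop = FALSE],
                           Z[tb$negative, , drop = FALSE], cfg$margin)
        losses <- c(losses, mean(li))
        active <- li > 0
        if (!any(active)) next
        dZ <- matrix(0, nrow(Z), ncol(Z))
        w <- 1 / nrow(tb)
        for (t in which(active)) {
          a <- tb$anchor[t]; p <- tb$positive[t]; ng <- tb$negative[t]
          dZ[a, ] <- dZ[a, ] + 2 * w * (Z[ng, ] - Z[p, ])
          dZ[p, ] <- dZ[p, ] - 2 * w * (Z[a, ] - Z[p, ])
          dZ[ng, ] <- dZ[ng, ] + 2 * w * (Z[a, ] - Z[ng, ])
        }
        bw <- net_backward(branch$embed, fw$caches, dZ)
        upd <- net_update(branch$embed, bw$grads, state, cfg$lr, cfg$momentum,
                          cfg$weight_decay)
        branch$embed <- upd$layers
        state <- upd$state
      }
      history[ep] <- if (length(losses)) mean(losses) else NA_real_
    }
  })
  list(branch = branch,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = history))
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Shared BCE minibatch loop over a branch; which parts get updated and at
# what rate distinguishes fine-tuning from end-to-end training.
run_bce_epochs <- function(branch, records, policy, cfg, epochs_with_aug,
                           epochs_total, embed_lr, head_lr, seed_tag) {
  modality <- branch$cfg$modality
  if (epochs_total > 0) branch <- fit_branch_norm(branch, records)
  state_e <- sgd_state(net_params(branch$embed))
  state_h <- sgd_state(net_params(branch$head))
  history <- numeric(0)
  with_seed(derive_seed(cfg$seed, seed_tag), {
    for (ep in seq_len(epochs_total)) {
      use_policy <- if (ep <= epochs_with_aug) policy else NULL
      dat <- epoch_arrays(records, modality, use_policy)
      ord <- sample(length(dat$y))
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        xb <- apply_input_norm(dat$x[, , , idx, drop = FALSE], branch$norm)
        yb <- dat$y[idx]
        # frozen embedding: inference mode (running BN stats), no caches
        fe <- net_forward(branch$embed, xb, train = embed_lr > 0)
        if (embed_lr > 0) {
          branch$embed <- net_commit_bn(branch$embed, fe$bn)
        }
        fh <- net_forward(branch$head, fe$out, train = TRUE)
        prob <- sigmoid(as.numeric(fh$out))
        losses <- c(losses, bce_loss(prob, yb))
        dlogit <- matrix((prob - yb) / length(yb), ncol = 1)
        bh <- net_backward(branch$head, fh$caches, dlogit)
        if (head_lr > 0) {
          upd <- net_update(branch$head, bh$grads, state_h, head_lr,
                            cfg$momentum, cfg$weight_decay)
          branch$head <- upd$layers
          state_h <- upd$state
        }
        if (embed_lr > 0) {
          be <- net_backward(branch$embed, fe$caches, bh$dx)
          upd <- net_update(branch$embed, be$grads, state_e, embed_lr,
                            cfg$momentum, cfg$weight_decay)
          branch$embed <- upd$layers
          state_e <- upd$state
        }
      }
      history[ep] <- mean(losses)
    }
  })
  list(branch = branch,
       history = data.frame(epoch = seq_len(epochs_total), loss = history))
}

#' Fine-tune the evaluation head (stage two)
#'
#' Binary cross-entropy on the MVI probability; the head trains at `cfg$lr`
#' while the pretrained embedding follows at `cfg$lr * embed_lr_factor`
#' (or not at all with `freeze_embedding`).  No augmentation by default.
#'
#' @param branch A pretrained `mcat_branch`.
#' @param records Training records.
#' @param cfg A [training_config()] with `stage = "finetune"`.
#' @param policy Optional augmentation policy (off by default).
#' @return List with the trained `branch` and the loss `history`.
#' @export
finetune_classifier <- function(branch, records, cfg, policy = NULL) {
  stopifnot(inherits(branch, "mcat_branch"), cfg$stage == "finetune")
  check_trainable(records, branch$cfg$modality)
  embed_lr <- if (cfg$freeze_embedding) 0 else cfg$lr * cfg$embed_lr_factor
  run_bce_epochs(branch, records, policy, cfg,
                 epochs_with_aug = if (is.null(policy)) 0L else cfg$epochs,
                 epochs_total = cfg$epochs,
                 embed_lr = embed_lr, head_lr = cfg$lr, seed_tag = "finetune")
}

#' End-to-end comparator under the two-stage step budget
#'
#' Joint cross-entropy training of the embedding and head in one stage.  For
#' budget parity with `pretrain(epochs_aug) + finetune(epochs_raw)`, the
#' first `epochs_aug` epochs see the augmented training set and the
#' remaining `cfg$epochs - epochs_aug` the raw one, so the total number of
#' gradient steps matches the two-stage schedule up to batch rounding.
#'
#' @param branch An `mcat_branch` (freshly initialised).
#' @param records Training records.
#' @param policy Augmentation policy shared with the two-stage schedule.
#' @param cfg A [training_config()] with `stage = "end_to_end"`; `cfg$epochs`
#'   is the total epoch count.
#' @param epochs_aug Number of leading epochs trained on augmented data
#'   (default: all of them).
#' @return List with the trained `branch` and the loss `history`.
#' @export
train_end_to_end <- function(branch, records, policy, cfg,
                             epochs_aug = cfg$epochs) {
  stopifnot(inherits(branch, "mcat_branch"), cfg$stage == "end_to_end")
  check_trainable(records, branch$cfg$modality)
  run_bce_epochs(branch, records, policy, cfg,
                 epochs_with_aug = min(epochs_aug, cfg$epochs),
                 epochs_total = cfg$epochs,
                 embed_lr = cfg$lr, head_lr = cfg$lr, seed_tag = "end_to_end")
}

#' Train one branch under either training mode
#'
#' Convenience wrapper used by the cross-validation harness: `"two_stage"`
#' runs triplet pretraining followed by fine-tuning; `"end_to_end"` runs the
#' budget-matched single-stage comparator (same augmented epochs, same total
#' epochs, same seed).
#'
#' @param branch An `mcat_branch`.
#' @param records Training records.
#' @param mode `"two_stage"` or `"end_to_end"`.
#' @param policy Augmentation policy.
#' @param pretrain_epochs,finetune_epochs Epochs of the two stages.
#' @param seed Integer seed.
#' @param batch_size,margin,mining Passed to [training_config()].
#' @return The trained branch.
#' @export
train_branch <- function(branch, records, mode = c("two_stage", "end_to_end"),
                         policy = augmentation_policy(),
                         pretrain_epochs = 30L, finetune_epochs = 30L,
                         seed = 1L, batch_size = 16L, margin = 0.3,
                         mining = "batch_all") {
  mode <- match.arg(mode)
  if (mode == "two_stage") {
    cfg_p <- training_config("pretrain", epochs = pretrain_epochs,
                             batch_size = batch_size, margin = margin,
                             mining = mining, seed = seed)
    branch <- pretrain_embedding(branch, records, policy, cfg_p)$branch
    cfg_f <- training_config("finetune", epochs = finetune_epochs,
                             batch_size = batch_size, seed = seed)
    finetune_classifier(branch, records, cfg_f)$branch
  } else {
    cfg <- training_config("end_to_end",
                           epochs = pretrain_epochs + finetune_epochs,
                           batch_size = batch_size, seed = seed)
    train_end_to_end(branch, records, policy, cfg,
                     epochs_aug = pretrain_epochs)$branch
  }
}
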