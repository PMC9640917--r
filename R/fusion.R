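# Double-branch model: late (probability-level) weighted fusion of the CT
# and MRI branches, joint updating of both branches on mixed-modality data,
# and availability-based routing at prediction time.

#' Fusion configuration
#'
#' @param w_ct,w_mr Fusion weights on the simplex (`w_ct + w_mr = 1`,
#'   both nonnegative); default equal weighting.
#' @param epochs Joint-update epochs on mixed data.
#' @param lr Joint-update learning rate.
#' @param batch_size Minibatch size.
#' @param momentum SGD momentum.
#' @param learn_weights Also learn the fusion weights during the joint
#'   update, re-projected onto the simplex after every step.
#' @param weight_lr Learning rate for the two fusion weights (two scalars
#'   fed by whole-batch gradients need a far larger step than the network
#'   parameters).
#' @param seed Integer seed.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(w_ct = 0.5, w_mr = 0.5, epochs = 10L, lr = 0.003,
                          batch_size = 16L, momentum = 0.9,
                          learn_weights = FALSE, weight_lr = 0.1,
                          seed = 1L) {
  check_simplex(c(w_ct, w_mr))
  stopifnot(epochs >= 0, lr > 0, weight_lr > 0)
  structure(list(w_ct = w_ct, w_mr = w_mr, epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 momentum = momentum, learn_weights = learn_weights,
                 weight_lr = weight_lr, seed = as.integer(seed)),
            class = "fusion_config")
}

check_simplex <- function(w, tol = 1e-8) {
  if (any(w < 0) || abs(sum(w) - 1) > tol) {
    stop("fusion weights must be nonnegative and sum to 1")
  }
  invisible(w)
}

project_simplex <- function(w) {
  w <- pmax(w, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w / sum(w)
}

#' Fuse a trained CT branch and MRI branch
#'
#' The fused MVI probability of a both-modality lesion is the convex
#' combination `w_ct * p_ct + w_mr * p_mr`; both branches remain callable
#' individually for single-modality lesions.
#'
#' @param ct_branch,mri_branch Trained `mcat_branch`es of the two modalities.
#' @param cfg A [fusion_config()].
#' @return A `double_branch_model`.
#' @export
fuse_branches <- function(ct_branch, mri_branch, cfg = fusion_config()) {
  stopifnot(inherits(ct_branch, "mcat_branch"),
            inherits(mri_branch, "mcat_branch"),
            ct_branch$cfg$modality == "ct", mri_branch$cfg$modality == "mri")
  check_simplex(c(cfg$w_ct, cfg$w_mr))
  structure(list(ct = ct_branch, mri = mri_branch,
                 weights = c(ct = cfg$w_ct, mr = cfg$w_mr), cfg = cfg),
            class = "double_branch_model")
}

#' Jointly update both branches on mixed-modality data
#'
#' Cross-entropy on the fused probability is backpropagated into both
#' branches (each weighted by its fusion coefficient); with
#' `learn_weights = TRUE` the fusion weights receive gradients too and are
#' re-projected onto the simplex after every step.
#'
#' @param model A `double_branch_model`.
#' @param records Mixed records (availability `"both"` only).
#' @param cfg Optional [fusion_config()] overriding the one stored in the
#'   model.
#' @return The updated `double_branch_model`.
#' @export
joint_update <- function(model, records, cfg = NULL) {
  stopifnot(inherits(model, "double_branch_model"))
  if (is.null(cfg)) cfg <- model$cfg
  if (length(records) == 0) stop("empty mixed training set")
  if (any(vapply(records, function(r) r$availability != "both", logical(1)))) {
    stop("joint update requires records with both modalities")
  }
  if (cfg$epochs == 0L) return(model)
  y_all <- record_labels(records)
  x_ct <- stack_array(records, "ct")
  x_mr <- stack_array(records, "mri")
  w <- model$weights
  st_ct_e <- sgd_state(net_params(model$ct$embed))
  st_ct_h <- sgd_state(net_params(model$ct$head))
  st_mr_e <- sgd_state(net_params(model$mri$embed))
  st_mr_h <- sgd_state(net_params(model$mri$head))
  with_seed(derive_seed(cfg$seed, "joint_update"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(y_all))
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        yb <- y_all[idx]
        fe_ct <- net_forward(model$ct$embed,
                             apply_input_norm(x_ct[, , , idx, drop = FALSE],
                                              model$ct$norm), TRUE)
        model$ct$embed <- net_commit_bn(model$ct$embed, fe_ct$bn)
        fh_ct <- net_forward(model$ct$head, fe_ct$out, TRUE)
        p_ct <- sigmoid(as.numeric(fh_ct$out))
        fe_mr <- net_forward(model$mri$embed,
                             apply_input_norm(x_mr[, , , idx, drop = FALSE],
                                              model$mri$norm), TRUE)
        model$mri$embed <- net_commit_bn(model$mri$embed, fe_mr$bn)
        fh_mr <- net_forward(model$mri$head, fe_mr$out, TRUE)
        p_mr <- sigmoid(as.numeric(fh_mr$out))
        p <- w["ct"] * p_ct + w["mr"] * p_mr
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        dp <- (p - yb) / (p * (1 - p)) / length(yb)
        upd_branch <- function(branch, fe, fh, p_b, w_b, st_e, st_h) {
          dlogit <- matrix(dp * w_b * p_b * (1 - p_b), ncol = 1)
          bh <- net_backward(branch$head, fh$caches, dlogit)
          uh <- net_update(branch$head, bh$grads, st_h, cfg$lr, cfg$momentum)
          branch$head <- uh$layers
          be <- net_backward(branch$embed, fe$caches, bh$dx)
          ue <- net_update(branch$embed, be$grads, st_e, cfg$lr, cfg$momentum)
          branch$embed <- ue$layers
          list(branch = branch, st_e = ue$state, st_h = uh$state)
        }
        r_ct <- upd_branch(model$ct, fe_ct, fh_ct, p_ct, w["ct"], st_ct_e, st_ct_h)
        model$ct <- r_ct$branch; st_ct_e <- r_ct$st_e; st_ct_h <- r_ct$st_h
        r_mr <- upd_branch(model$mri, fe_mr, fh_mr, p_mr, w["mr"], st_mr_e, st_mr_h)
        model$mri <- r_mr$branch; st_mr_e <- r_mr$st_e; st_mr_h <- r_mr$st_h
        if (cfg$learn_weights) {
          gw <- c(ct = sum(dp * p_ct), mr = sum(dp * p_mr))
          w <- project_simplex(w - cfg$weight_lr * gw)
        }
      }
    }
  })
  model$weights <- w
  model
}

#' Predict the MVI probability of one lesion, routed by availability
#'
#' Lesions with both modalities get the fused probability; CT-only and
#' MRI-only lesions are routed through the corresponding branch alone.
#'
#' @param object A `double_branch_model`.
#' @param record A [lesion_record()].
#' @param ... Unused.
#' @return List with `prob` (MVI-positive probability) and `route`
#'   (`"fused"`, `"ct"` or `"mri"`).
#' @export
predict.double_branch_model <- function(object, record, ...) {
  stopifnot(inherits(record, "lesion_record"))
  one <- function(branch, stack) {
    x <- array(stack$pixels, c(dim(stack$pixels), 1L))
    branch_forward(branch, x)$prob
  }
  if (record$availability == "both") {
    p <- object$weights["ct"] * one(object$ct, record$ct) +
      object$weights["mr"] * one(object$mri, record$mri)
    list(prob = unname(p), route = "fused")
  } else if (record$availability == "ct") {
    list(prob = unname(one(object$ct, record$ct)), route = "ct")
  } else {
    list(prob = unname(one(object$mri, record$mri)), route = "mri")
  }
}

#' Batch predictions for a record list
#'
#' @param model A `double_branch_model`.
#' @param records List of [lesion_record()]s.
#' @param threshold Positive-call threshold (strictly greater than).
#' @return Data frame with `lesion_id`, `route`, `prob`, `predicted`, `label`.
#' @export
predict_cohort <- function(model, records, threshold = 0.5) {
  rows <- lapply(records, function(r) {
    pr <- predict(model, r)
    data.frame(lesion_id = r$lesion_id, route = pr$route, prob = pr$prob,
               predicted = as.integer(pr$prob > threshold), label = r$label)
  })
  do.call(rbind, rows)
}
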