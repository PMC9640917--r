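# Packaged replication experiments: attention recovery, the two-stage
# pretraining benefit, and the double-branch fusion benefit, each run on the
# synthetic cohort generator under its default study-like composition.
# These functions are what the acceptance script and the heavier tests call.

#' Attention recovery on a single-channel planted signal
#'
#' Generates CT-only cohorts whose class signal lives in exactly one channel,
#' trains a branch (uniform attention prior, so any preference must be
#' learned) and reports the batch-averaged input-MAWM gates.  Recovery means
#' the planted channel's gate exceeds every other channel's.  Training uses
#' light augmentation: with it, noise memorisation is suppressed and the
#' gate ordering reflects genuine channel utility rather than in-sample
#' overfitting.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param channel The CT channel carrying the signal (default arterial
#'   phase).
#' @param d Planted standardised effect size.
#' @param n Cohort size (balanced classes).
#' @param epochs Training epochs (end-to-end).
#' @param side Patch side.
#' @param lr Learning rate.
#' @param policy Augmentation policy (default: multiplicity 2,
#'   freshly drawn each epoch).
#' @return Data frame with one row per seed: the per-channel gates and
#'   whether the planted channel was recovered.
#' @export
attention_recovery_experiment <- function(seeds = 1:3, channel = "AP",
                                          d = 1.5, n = 200, epochs = 30,
                                          side = 64, lr = 0.05,
                                          policy = augmentation_policy(multiplicity = 2L)) {
  eff <- c(plain = 0, AP = 0, PVP = 0)
  eff[channel] <- d
  rows <- lapply(seeds, function(s) {
    sp <- cohort_spec(n_ct_only = n, n_mri_only = 0, n_mixed = 0,
                      pos_fraction = c(0.5, 0, 0), side = side,
                      effect_ct = eff, seed = s)
    co <- generate_cohort(sp)
    br <- build_single_branch(branch_config("ct", prior = c(1, 1, 1)),
                              seed = s)
    cfg <- training_config("end_to_end", epochs = epochs, lr = lr, seed = s)
    br <- train_end_to_end(br, co, policy, cfg)$branch
    g <- attention_profile(br, stack_array(co, "ct"))
    out <- as.data.frame(as.list(g))
    out$seed <- s
    out$recovered <- names(g)[which.max(g)] == channel
    out
  })
  do.call(rbind, rows)
}

#' Two-stage pretraining versus budget-matched end-to-end training
#'
#' On the default synthetic cohort, runs stratified 5-fold cross-validation
#' of the CT branch under both training modes (identical seeds, folds,
#' augmentation and total step budget), and probes embedding separability:
#' the silhouette of held-out embeddings at random initialisation versus
#' after triplet pretraining.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param spec Cohort specification (defaults to the study-like cohort).
#' @param opts Harness options from [cv_options()].
#' @return List with `summary` (per-seed mean 5-fold AUC of each mode and
#'   the silhouette pair) and `reports` (the underlying metrics reports).
#' @export
pretraining_benefit_experiment <- function(seeds = 1:3,
                                           spec = cohort_spec(),
                                           opts = cv_options()) {
  grid <- data.frame(branch = "ct", network = "mcat",
                     mode = c("two_stage", "end_to_end"))
  reports <- list()
  rows <- lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- s
    cohort <- generate_cohort(sp)
    rep <- run_cv_experiment(cohort, grid, seed = s, opts = opts)
    reports[[as.character(s)]] <<- rep
    mean_auc <- function(mode) {
      rep$auc[rep$mode == mode & rep$fold == "mean"]
    }
    # silhouette probe on one held-out fold
    elig <- eligible_records(cohort, "ct")
    split <- stratified_kfold(elig, k = 5, seed = s)
    va <- elig[split$folds[[1]]]
    tr <- elig[setdiff(seq_along(elig), split$folds[[1]])]
    br0 <- build_single_branch(branch_config("ct"), seed = s)
    xva <- stack_array(va, "ct")
    sil_init <- silhouette_score(branch_forward(br0, xva)$embedding,
                                 record_labels(va))
    pre <- pretrain_embedding(
      br0, tr, opts$policy,
      training_config("pretrain", epochs = opts$pretrain_epochs,
                      batch_size = opts$batch_size, mining = opts$mining,
                      seed = s)
    )$branch
    sil_pre <- silhouette_score(branch_forward(pre, xva)$embedding,
                                record_labels(va))
    data.frame(seed = s, auc_two_stage = mean_auc("two_stage"),
               auc_end_to_end = mean_auc("end_to_end"),
               silhouette_init = sil_init, silhouette_pretrained = sil_pre)
  })
  list(summary = do.call(rbind, rows), reports = reports)
}

#' Double-branch fusion versus the single branches
#'
#' On the default complementary-signal cohort (CT arterial phase and MRI
#' diffusion channel informative), stratified 5-fold cross-validation over
#' the mixed (CT&MRI) group: in each fold the CT and MRI branches are
#' trained on their eligible lesions outside the validation fold, fused
#' with equal weights and jointly updated on the mixed training lesions,
#' and all three predictors — CT branch alone, MRI branch alone, fused —
#' are evaluated on the *same* mixed validation lesions.  The paired design
#' makes the fused-versus-single comparison a within-fold contrast.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param spec Cohort specification.
#' @param opts Harness options from [cv_options()].
#' @param mode Training mode for the branches.  Defaults to end-to-end so
#'   that the fusion contrast is measured on the strongest available
#'   branches and is not masked by branch undertraining.
#' @return List with `summary` (per-seed mean 5-fold AUC of each predictor)
#'   and `folds` (per-seed, per-fold AUC table).
#' @export
fusion_benefit_experiment <- function(seeds = 1:3, spec = cohort_spec(),
                                      opts = cv_options(),
                                      mode = c("end_to_end", "two_stage")) {
  mode <- match.arg(mode)
  fold_tabs <- list()
  rows <- lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- s
    cohort <- generate_cohort(sp)
    ids <- vapply(cohort, function(r) r$lesion_id, character(1))
    av <- vapply(cohort, function(r) r$availability, character(1))
    mixed <- cohort[av == "both"]
    split <- stratified_kfold(mixed, k = 5, seed = s)
    per_fold <- lapply(seq_len(split$k), function(f) {
      va <- mixed[split$folds[[f]]]
      va_ids <- vapply(va, function(r) r$lesion_id, character(1))
      pool <- cohort[!ids %in% va_ids]
      pav <- vapply(pool, function(r) r$availability, character(1))
      fseed <- derive_seed(s, paste("fusion fold", f))
      ct_b <- train_branch(
        build_single_branch(branch_config("ct"), seed = fseed),
        pool[pav %in% c("ct", "both")], mode = mode,
        policy = opts$policy, pretrain_epochs = opts$pretrain_epochs,
        finetune_epochs = opts$finetune_epochs, seed = fseed,
        batch_size = opts$batch_size, mining = opts$mining
      )
      mr_b <- train_branch(
        build_single_branch(branch_config("mri"), seed = fseed),
        pool[pav %in% c("mri", "both")], mode = mode,
        policy = opts$policy, pretrain_epochs = opts$pretrain_epochs,
        finetune_epochs = opts$finetune_epochs, seed = fseed,
        batch_size = opts$batch_size, mining = opts$mining
      )
      model <- fuse_branches(ct_b, mr_b,
                             fusion_config(epochs = opts$joint_epochs,
                                           batch_size = opts$batch_size,
                                           learn_weights = TRUE,
                                           seed = fseed))
      mixed_tr <- pool[pav == "both"]
      if (opts$joint_epochs > 0 && length(mixed_tr) > 0) {
        model <- joint_update(model, mixed_tr)
      }
      y <- record_labels(va)
      data.frame(
        seed = s, fold = f,
        auc_ct = roc_auc(y, branch_probs(model$ct, va)),
        auc_mri = roc_auc(y, branch_probs(model$mri, va)),
        auc_double = roc_auc(y, predict_cohort(model, va)$prob)
      )
    })
    tab <- do.call(rbind, per_fold)
    fold_tabs[[as.character(s)]] <<- tab
    data.frame(seed = s, auc_ct = mean(tab$auc_ct),
               auc_mri = mean(tab$auc_mri),
               auc_double = mean(tab$auc_double))
  })
  list(summary = do.call(rbind, rows), folds = fold_tabs)
}
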