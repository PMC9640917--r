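# mcatnet

Small-sample multimodal deep learning for predicting microvascular invasion
(MVI) of hepatocellular carcinoma from segmented CT and MRI lesions.

Preoperative MVI status guides treatment of liver cancer but is only
established histologically after resection. Imaging cohorts with pathology
ground truth are small (~10² lesions) and heterogeneous — some patients have
contrast-enhanced CT only (3 phases), some multi-sequence MRI only
(6 channel images), some both. `mcatnet` implements a double-branch,
multimodality-contribution-aware TripNet (MCAT) built for exactly this
regime, plus everything needed to evaluate it: ROI preprocessing, baseline
networks, a stratified cross-validation harness, and a synthetic cohort
generator with an analytic oracle so every claim is testable without
patient data.

The model has three ingredients:

1. **MAWM channel attention with a radiologist prior.** Each branch gates
   its modality channels with a squeeze-and-excitation bottleneck whose
   logits carry an additive prior bias `log(p_c / mean(p))` plus a learnable
   per-channel offset:

   `g = sigmoid(W2 ReLU(W1 s + b1) + b2 + log(p/p̄) + β)`, `x̃_c = g_c x_c`,

   where `s` is the per-channel global average. The CT default prior
   `(1, 2, 1)` upweights the arterial phase.
2. **Two-stage small-sample training.** The feature-embedding module
   (3-stage residual backbone → L2-normalised 128-d embedding) is first
   pretrained with a triplet margin loss
   `max(0, ‖e_a−e_p‖² − ‖e_a−e_n‖² + m)` on augmented lesions; the linear
   evaluation head is then fine-tuned with cross-entropy. A budget-matched
   end-to-end mode (same augmented epochs, same total steps) is the
   comparator.
3. **Double-branch late fusion.** Trained CT and MRI branches are combined
   as `p = w_ct p_ct + w_mr p_mr` on the weight simplex (default ½/½),
   jointly updated on mixed-modality lesions, and routed by availability at
   prediction time (CT-only → CT branch, MRI-only → MRI branch, both →
   fused).

Evaluation mirrors the clinical-study protocol: stratified 5-fold
cross-validation (4:1), accuracy / sensitivity / precision / F1 at the
strict 0.5 threshold, Mann–Whitney AUC, and unpaired Z tests on AUC pairs
with Hanley–McNeil standard errors.

The convolutional layers and their backward passes are implemented in the
package (im2col + GEMM via RcppArmadillo); no external deep-learning
runtime is required.

## Worked example

Generate a study-like synthetic cohort (121 lesions: 49 CT-only, 32
MRI-only, 40 mixed; class signal planted in the CT arterial phase and the
MRI diffusion channel), train both branches, fuse, and predict:

```r
library(mcatnet)

spec   <- cohort_spec(seed = 7)
cohort <- generate_cohort(spec)

ct  <- train_branch(build_single_branch(branch_config("ct"),  seed = 7),
                    eligible_records(cohort, "ct"),  mode = "end_to_end",
                    policy = augmentation_policy(multiplicity = 1),
                    pretrain_epochs = 10, finetune_epochs = 10, seed = 7)
mri <- train_branch(build_single_branch(branch_config("mri"), seed = 7),
                    eligible_records(cohort, "mri"), mode = "end_to_end",
                    policy = augmentation_policy(multiplicity = 1),
                    pretrain_epochs = 10, finetune_epochs = 10, seed = 7)

model <- joint_update(fuse_branches(ct, mri, fusion_config(epochs = 3, seed = 7)),
                      eligible_records(cohort, "double"))

preds <- predict_cohort(model, cohort)
head(preds, 3)
#>   lesion_id route      prob predicted label
#> 1      L001    ct 0.2176993         0     0
#> 2      L002    ct 0.8862663         1     1
#> 3      L003    ct 0.7352060         1     0

y <- record_labels(cohort)
round(c(fused_auc = roc_auc(y, preds$prob)), 3)
#> fused_auc
#>         1
```

`prob` is the predicted probability that the lesion is MVI-positive,
`route` shows which branch produced it (here CT-only lesions use the CT
branch), and a probability strictly above 0.5 is called positive. The
resubstitution AUC of 1 reflects performance on the *training* cohort
(the network memorises 121 lesions easily) — use `run_cv_experiment()`
for honest held-out numbers:

```r
report <- run_cv_experiment(cohort,
                            data.frame(branch = "double", network = "mcat",
                                       mode = "end_to_end"),
                            seed = 7)
print(report)
#> Cross-validated metrics (per fold and aggregate):
#>  branch network       mode fold  n accuracy sensitivity precision    f1   auc
#>  double    mcat end_to_end    1  8    0.750       0.000     0.000 0.000 0.417
#>  double    mcat end_to_end    2  8    0.625       0.333     0.500 0.400 0.600
#>  double    mcat end_to_end    3  8    0.625       0.000     0.000 0.000 0.867
#>  double    mcat end_to_end    4  8    0.750       0.333     1.000 0.500 0.600
#>  double    mcat end_to_end    5  8    0.625       0.333     0.500 0.400 0.800
#>  double    mcat end_to_end mean 40    0.675       0.200     0.400 0.260 0.657
#>  double    mcat end_to_end   sd 40    0.068       0.183     0.418 0.241 0.179
```

Each fold row is one validation fold of the stratified 5-fold split of the
mixed (CT&MRI) group; `mean ± sd` aggregates the fold rows. The generator's
analytic oracle (`planted_bayes_auc(spec, "both")`) bounds what any
classifier could achieve on this cohort.

A command-line wrapper over the same pipeline lives at `inst/cli/mcat.R`
(`simulate` / `preprocess` / `train` / `fuse` / `evaluate` / `full`, each
driven by a YAML config).

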