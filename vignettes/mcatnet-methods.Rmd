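---
title: "Methods: double-branch multimodality-contribution-aware TripNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-branch multimodality-contribution-aware TripNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcatnet)
```

## The problem

Microvascular invasion (MVI) of hepatocellular carcinoma is a strong
predictor of early recurrence but is only established histologically after
resection. Predicting it preoperatively from imaging is therefore
attractive, but the available data are small (on the order of a hundred
annotated lesions) and heterogeneous: some patients have contrast-enhanced
CT only, some multi-sequence MRI only, and some both. `mcatnet` implements
a double-branch, modality-contribution-aware network (MCAT) designed for
exactly this regime, together with the synthetic cohort machinery needed to
test its claims without patient data.

A lesion enters the model as a fixed-size 2D patch stack: the slice with
the largest segmented lesion area is selected per channel, cropped to the
mask bounding box plus a margin, bilinearly resampled to $S \times S$
(default $S = 64$) and min-max normalised to $[0,1]$. CT stacks have three
channels (plain scan, arterial phase, portal-venous phase); MRI stacks have
six (T2WI, DWI, and T1WI pre-contrast, arterial, portal-venous and
equilibrium phases).

## Model

### Channel attention with a radiologist prior (MAWM)

Each branch starts with a multimodal adaptive weighted module: a
squeeze-and-excitation gate over the *modality channels*. For input
$x \in \mathbb{R}^{S\times S\times C}$,

$$ s_c = \operatorname{mean}(x_{\cdot\cdot c}), \qquad
   g = \sigma\!\big(W_2\,\mathrm{ReLU}(W_1 s + b_1) + b_2
        + \log(p/\bar p) + \beta\big), \qquad
   \tilde x_{\cdot\cdot c} = g_c\, x_{\cdot\cdot c}. $$

The prior weights $p$ encode radiological experience — the CT default
$(1, 2, 1)$ upweights the arterial phase — and enter as a log-ratio bias,
so only ratios of prior weights matter and a uniform prior contributes
nothing. $\beta$ is a learnable per-channel offset: the "contribution
awareness" the network can move away from the prior during training. The
excitation weights $W_2$ start at zero, so the initial gates are exactly
$\sigma(\log(p/\bar p))$ (one half under a uniform prior).

### Branch and baselines

A branch is: input MAWM $\to$ a three-stage residual backbone
(3×3 convolutions, stride-2 stem, stage widths 8/16/32 by default, an
SE-style gate per stage) $\to$ global average pooling $\to$ batch
normalisation of the pooled features $\to$ a bias-free linear map to an
L2-normalised 128-dimensional embedding (the *feature embedding module*),
followed by a linear + sigmoid *evaluation head* producing the
MVI-positive probability. The stage widths are a desk-scale choice: they
keep a full 5-fold × 3-seed experiment grid runnable on one CPU; widths are
configurable through `branch_config()`.

Two of these details are load-bearing rather than cosmetic. Pooled
features of small lesion batches are a large shared component plus tiny
per-sample fluctuations; batch-normalising them is what lets both
objectives see the fluctuations at unit scale (without it, training
stalls near chance at any practical learning rate). And the embedding
layer carries no bias: with a bias, the triplet objective can satisfy
itself by shrinking the input-dependent part until the shared bias fixes
every embedding direction — a collapse onto one point of the unit sphere
that we observed before removing it.

Baselines built by `build_baseline()`: a four-layer strided CNN (`2dcnn`),
`resnet18` (CIFAR-style 3×3 stem, widths 64–512), and `senet18` /
`ecanet18`, which add SE or efficient-channel-attention gates to every
residual block. Baselines train end-to-end only.

All networks, including baselines, subtract the per-channel training-set
mean image and divide by the residual standard deviation before the first
convolution (dataset normalisation). With segmented, centred lesion
patches the shared anatomy dominates the raw intensities; without this
step the embeddings of different lesions are nearly identical at
initialisation and the triplet objective collapses onto its margin.

### Two-stage small-sample training

Stage one (`pretrain_embedding()`) trains only the embedding module with a
triplet margin loss,
$\max(0, \lVert e_a - e_p\rVert^2 - \lVert e_a - e_n\rVert^2 + m)$,
$m = 0.3$, on augmented copies of the training lesions. Both `batch_hard`
and `batch_all` mining are implemented; the cross-validation harness
defaults to `batch_all` with batch 32, because at weak planted effects the
hardest triplets are dominated by augmentation noise while the all-triplet
average is a lower-variance gradient (the number of triplets per batch
grows roughly cubically with batch size). Stage two
(`finetune_classifier()`) trains the evaluation head with binary
cross-entropy while the embedding follows at a tenth of the head's
learning rate (a freeze switch exists). The end-to-end comparator
(`train_end_to_end()`) trains embedding and head jointly under *budget
parity*: the same augmented epochs followed by the same raw epochs, so
total gradient steps match the two-stage schedule up to batch rounding.

Augmentation (`augmentation_policy()`) applies one shared geometric
transform per stack — flips, rotation within ±15°, scale jitter within
±10% — plus a per-channel intensity offset (SD 0.02), and re-clips to
$[0,1]$. Augmentation is used on training folds only; validation lesions
are always raw.

### Optimisation

Plain SGD with momentum 0.9 and L2 weight decay $10^{-3}$. Defaults:
learning rate 0.05 for pretraining and end-to-end training, 0.01 for
fine-tuning. Two groups carry a 10× learning-rate multiplier: the MAWM
parameters (a handful of weights fed by spatially pooled gradients) and
the linear evaluation head (a logistic layer on unit-norm embeddings,
whose gradients are an order of magnitude smaller than the convolutional
ones). Without these multipliers the head moves so slowly that predicted
probabilities stay within ±0.01 of one half over a realistic epoch budget.
These rates were chosen on development fixtures; they are exposed through
`training_config()`.

### Double-branch fusion

`fuse_branches()` combines trained CT and MRI branches at the probability
level: $p = w_{ct}\, p_{ct} + w_{mr}\, p_{mr}$ with $(w_{ct}, w_{mr})$ on
the simplex, default $(0.5, 0.5)$. `joint_update()` backpropagates
cross-entropy on the fused probability into both branches using
mixed-modality lesions only; with `learn_weights = TRUE` the fusion
weights receive gradients too and are re-projected onto the simplex after
every step. Prediction routes by availability: both modalities → fused;
CT-only / MRI-only → the corresponding branch.

## Evaluation protocol

`stratified_kfold()` deals each class evenly into $k = 5$ folds
(4:1 train:validation), remainders going to the smallest folds, so
per-fold positive counts deviate from perfect stratification by at most
one. `confusion_metrics()` reports accuracy, sensitivity, precision and F1
at the strictly-greater-than 0.5 threshold, defining precision and F1 as 0
(flagged) when no positive calls are made. `roc_auc()` is the Mann–Whitney
statistic (ties ½, computed by midranks). AUC pairs are compared by an
unpaired Z test with Hanley–McNeil standard errors — a bare "Z test"
label leaves the variant ambiguous, so the package standardises on this
form and documents it. Fold aggregates are the
arithmetic mean and the $n-1$ sample SD over fold rows; metrics are
computed per fold and then aggregated (not pooled).

`run_cv_experiment()` crosses branches (CT / MRI / double) with networks
and training modes. The CT branch cross-validates within CT-only plus
mixed lesions, the MRI branch within MRI-only plus mixed, and the double
branch folds over the mixed group only — single-modality lesions remain
available to branch training in every fold, and no mixed validation lesion
ever enters any training stage of that fold. For baseline networks the
double branch is the plain 0.5/0.5 probability average of the two
independently trained classifiers (they have no shared structure for a
joint update). `project_embeddings()` gives the deterministic 2D
principal-component view of an embedding space used to visualise class
separation; a seeded stochastic-neighbour embedding was considered and
dropped because no suitable implementation is available in the package's
dependency set and determinism was the priority.

## The synthetic cohort and its oracle

`generate_cohort()` emulates the study composition: 121 lesions split
49 CT-only / 32 MRI-only / 40 mixed with 18 / 12 / 14 MVI-positive. Each
channel image is

$$ x_c = B_c + y\, d_c\, \sigma\, T_c + \varepsilon,
   \qquad \varepsilon \sim \mathcal N(0, \sigma^2)\ \text{iid}, $$

with $y$ the label, $\sigma = 0.05$, $B_c$ a base texture and $T_c$ a
unit-L2 signal template. Under this model the matched filter
$\langle T_c, x_c - B_c\rangle/\sigma$ separates the classes by exactly
$d_c$ standard deviations, channels combine to
$d_\mathrm{eff} = \sqrt{\sum_c d_c^2}$, and the oracle AUC is
$\Phi(d_\mathrm{eff}/\sqrt 2)$ (`planted_bayes_auc()`), which is what
makes generator calibration testable. Defaults plant $d = 1.5$ in the CT
arterial phase and — complementarily — in the MRI diffusion channel, so
the combined oracle ($\Phi(1.5) \approx 0.93$) strictly dominates each
single modality ($\Phi(1.06) \approx 0.86$): the analytic version of the
fusion argument.

Two structural choices matter:

* The base texture is generated **once per cohort** and shared by all
  lesions, so the only lesion-to-lesion variation is noise plus signal and
  the closed form above is exact.
* Base textures and templates are **radially symmetric** about the patch
  centre (smoothed radial noise profiles; per-channel Gaussian *rings*
  distinguished by radius). Rotations and flips about the centre therefore
  preserve anatomy and signal while decorrelating pixel noise — the regime
  in which augmentation genuinely suppresses noise memorisation, which is
  the premise of the small-sample training strategy. An earlier
  non-symmetric draft made geometric augmentation destroy the planted
  signal outright, which no realistic cohort does.

What the generator does **not** emulate: per-lesion anatomical
variability, texture differences between classes, scanner effects,
inter-channel registration error, or any spatial correlation in the noise.
Passing tests on this cohort show that the implementation trains,
attends, fuses and evaluates as designed — not that the architecture would
reach any particular performance on clinical data.

## Replication experiments and problem sizes

Three packaged experiments mirror the study's comparisons at desk scale
(sizes chosen once for a single-CPU budget and fixed):

* `attention_recovery_experiment()` — CT-only cohorts of $n = 200$ with
  $d = 1.5$ planted in one channel, uniform prior (so preference must be
  learned), 30 end-to-end epochs, no augmentation; recovery means the
  planted channel's mean gate exceeds every other channel's.
* `pretraining_benefit_experiment()` — the default 121-lesion cohort,
  CT branch, 5-fold CV of two-stage versus budget-matched end-to-end
  training (12 + 12 epochs, batch 32, `batch_all` mining, augmentation
  multiplicity 1 with fresh draws each epoch), plus a held-out silhouette
  probe of the embedding space before and after pretraining.
* `fusion_benefit_experiment()` — the default complementary cohort,
  5-fold CV over the mixed (CT&MRI) group with a *paired* design: in each
  fold the CT and MRI branches are trained end-to-end on their eligible
  lesions, fused and jointly updated (5 epochs, learnable simplex
  weights), and the CT-alone, MRI-alone and fused predictors are all
  evaluated on the same mixed validation lesions. End-to-end branches are
  used so the fusion contrast is not masked by branch undertraining.

Each is run at three seeds; directional claims are asserted as
two-of-three majorities. Generator calibration uses cohorts of
$n = 2000$ at $S = 32$ — the oracle is side-invariant because templates
are unit-L2 at any side.

## Numerical choices and degenerate inputs

* Bounding boxes are 0-based, half-open; slice selection breaks ties
  toward the lowest index; constant patches normalise to all zeros.
* Embeddings carry an $\epsilon = 10^{-12}$ guard in the L2
  normalisation; probabilities are clipped to $[10^{-12}, 1-10^{-12}]$
  inside cross-entropy.
* Single-class training sets, empty masks, missing/duplicate channels,
  off-simplex fusion weights and classes smaller than $k$ all raise
  immediate errors rather than degrading silently.
* Every stochastic component draws its seed through `derive_seed(seed,
  component_tag)`, a deterministic fan-out, so one integer reproduces a
  run and new components never perturb existing streams. Minibatches that
  contain a single class are skipped during triplet pretraining (triplets
  are undefined there).

## What the desk-scale experiments do and do not show

Three directional findings deserve honest framing.

Attention recovery — the claim that after training on a cohort whose
signal lives in exactly one channel, that channel's mean input-MAWM gate
ranks first — holds at the three canonical replicate seeds the test uses,
but wider seed screens put the per-seed recovery probability near chance
(one in three channels), occasionally with the planted channel decisively
suppressed. At the stipulated effect size and epoch budget the network
learns too little of the signal for the gates to track it; without
augmentation, memorisation inflates every gate; and because this
generator is radially symmetric, ring-averaged pixel noise survives the
geometric augmentations as a per-lesion fingerprint that competes with
the planted signal. We therefore do not regard gate recovery as an
established property of this configuration; the gates remain
interpretable as learned channel weightings, but their ordering at weak
effects is noise-dominated.

First, under the strict budget-parity contract — the end-to-end
comparator receives the *same augmentation* and the same total gradient
steps as pretraining plus fine-tuning — two-stage training did **not**
beat end-to-end on this generator at these problem sizes (the packaged
experiment computes both numbers; the corresponding test asserts the
directional claim and fails). The embedding-separability part of the
claim (held-out silhouette after pretraining at least at its
initialisation level) does hold. Our reading: the clinical report of a
two-stage advantage plausibly reflects an unaugmented conventional
comparator, so that augmentation and metric learning were bundled;
isolated from augmentation, and against an end-to-end baseline already
regularised by augmentation, batch normalisation and weight decay, the
pure triplet objective extracts a weak planted signal more slowly than
direct supervision at an equal step budget. The triplet machinery itself
is healthy: at a strongly separable planted effect it drives the loss to
zero and held-out silhouette to 0.6–0.7.

Second, the fused double branch robustly matches or beats the weaker
(MRI) branch, and the analytic dominance of the combined oracle over each
single-modality oracle always holds and is asserted separately. The
comparison against the *stronger* (CT) branch, however, is fragile: at
the default effect size the single-modality oracle is already 0.983, so
the analytic headroom for fusion (0.9998 combined) is smaller than the
estimation noise of 8-lesion validation folds, and the per-seed outcome
of that contrast flips between epoch budgets (it met the 2-of-3 majority
at the default 12+12 epochs and missed it in a 15+15 variant). We report
the direction the experiment computes and flag the contrast as
noise-dominated rather than established.

## Known limitations

* Batch normalisation is applied to the pooled feature vector only, not
  after every convolution; very deep configurations would need more care.
* The 2DCNN baseline layout is a documented design choice (four strided
  convolutions); other plain-CNN layouts would serve equally.
* MAWM placement is a design choice: the package applies an input MAWM
  plus SE-style stage gates, both switchable in `branch_config()`.
* Fine-tuning defaults to a reduced embedding learning rate rather than a
  hard freeze; augmentation defaults to the pretraining stage only. Both
  have switches.
* The joint update uses mixed-modality lesions only; replaying
  single-modality lesions through their branch during the update is not
  implemented.
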