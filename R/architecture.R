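# Network definitions: the MAWM channel-attention block, the single-branch
# TripNet (feature-embedding module + evaluation head) and the four baseline
# classifiers used for comparison.

CT_CHANNELS <- c("plain", "AP", "PVP")
MRI_CHANNELS <- c("T2WI", "DWI", "T1pre", "T1AP", "T1PVP", "T1EP")

modality_channels <- function(modality) {
  switch(modality, ct = CT_CHANNELS, mri = MRI_CHANNELS,
         stop("unknown modality: ", modality))
}

#' Configuration of a MAWM channel-attention block
#'
#' The multimodal adaptive weighted module (MAWM) is a squeeze-and-excitation
#' gate acting on the modality-channel axis: a per-channel global-average
#' "squeeze" feeds a two-layer bottleneck whose sigmoid output gates each
#' channel.  A radiologist prior enters as an additive `log(p_c / mean(p))`
#' bias on the gate logits, so only prior ratios matter; a learnable
#' per-channel offset lets training move channel contributions away from the
#' prior.  The CT default upweights the arterial phase, reflecting its
#' perceived importance for microvascular invasion.
#'
#' @param n_channels Number of modality channels gated.
#' @param r Bottleneck reduction ratio (hidden width = ceiling(n_channels/r)).
#' @param prior Nonnegative per-channel prior weights; default uniform.
#' @return A `mawm_config` list.
#' @export
mawm_config <- function(n_channels, r = 2, prior = rep(1, n_channels)) {
  stopifnot(n_channels >= 1, r >= 1, length(prior) == n_channels,
            all(is.finite(prior)), all(prior >= 0))
  structure(list(n_channels = as.integer(n_channels), r = r, prior = prior),
            class = "mawm_config")
}

#' Apply a MAWM block to a channel-stacked array
#'
#' @param x Array `H x W x C x N` (or `H x W x C`, treated as one sample).
#' @param cfg A [mawm_config()].
#' @param params Optional MAWM parameter list (as produced inside a branch);
#'   when omitted, a zero-initialised excitation is used, so all gates equal
#'   `sigmoid(prior bias)` (0.5 under a uniform prior).
#' @param force_gates Optional vector of fixed gate values (length C) that
#'   bypasses the excitation entirely; used for identity-reduction checks.
#' @return List with `out` (reweighted array, same shape as `x`) and
#'   `profile`, the per-channel gate values averaged over the batch.
#' @export
mawm_forward <- function(x, cfg, params = NULL, force_gates = NULL) {
  stopifnot(inherits(cfg, "mawm_config"))
  squeeze <- FALSE
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    squeeze <- TRUE
  }
  if (dim(x)[3] != cfg$n_channels) {
    stop("mawm_forward: input has ", dim(x)[3], " channels, config expects ",
         cfg$n_channels)
  }
  layer <- nn_mawm(cfg$n_channels, r = cfg$r, prior = cfg$prior)
  layer$params$w1 <- layer$params$w1 * 0 # deterministic standalone application
  if (!is.null(params)) layer$params <- params
  layer$force_gates <- force_gates
  f <- nn_forward(layer, x)
  out <- f$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  list(out = out, profile = colMeans(f$gates))
}

#' Configuration of a single TripNet branch
#'
#' A branch is the per-modality network: an input MAWM over the raw modality
#' channels, a three-stage residual convolutional backbone (optionally with
#' SE gates per stage), a global average pool feeding an L2-normalised
#' embedding, and a linear evaluation head emitting the MVI-positive logit.
#'
#' @param modality `"ct"` (3 input channels) or `"mri"` (6).
#' @param widths Filter counts of the three backbone stages.
#' @param embed_dim Embedding dimension E.
#' @param input_mawm Apply the MAWM block on the raw modality channels.
#' @param stage_attn Per-stage channel attention: `"se"`, `"eca"` or `"none"`.
#' @param mawm_r,prior Reduction ratio and prior weights of the input MAWM.
#'   The CT default prior `(1, 2, 1)` upweights the arterial phase; the MRI
#'   default is uniform.
#' @return A `branch_config` list.
#' @export
branch_config <- function(modality = c("ct", "mri"), widths = c(8, 16, 32),
                          embed_dim = 128, input_mawm = TRUE,
                          stage_attn = c("se", "eca", "none"),
                          mawm_r = 2, prior = NULL) {
  modality <- match.arg(modality)
  stage_attn <- match.arg(stage_attn)
  channels <- modality_channels(modality)
  if (is.null(prior)) {
    prior <- if (modality == "ct") c(1, 2, 1) else rep(1, length(channels))
  }
  stopifnot(length(widths) == 3, embed_dim > 0,
            length(prior) == length(channels))
  structure(list(modality = modality, in_channels = length(channels),
                 channel_names = channels, widths = as.integer(widths),
                 embed_dim = as.integer(embed_dim), input_mawm = input_mawm,
                 stage_attn = stage_attn, mawm_r = mawm_r, prior = prior),
            class = "branch_config")
}

#' Build a single-branch TripNet
#'
#' @param cfg A [branch_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mcat_branch` holding the embedding layers and
#'   the evaluation head.
#' @export
build_single_branch <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "branch_config"))
  w <- cfg$widths
  attn <- if (cfg$stage_attn == "none") "none" else cfg$stage_attn
  with_seed(derive_seed(seed, paste0("branch/", cfg$modality)), {
    embed <- list()
    if (cfg$input_mawm) {
      maw <- nn_mawm(cfg$in_channels, r = cfg$mawm_r, prior = cfg$prior)
      maw$lr_mult <- 10 # few parameters, spatially pooled gradients
      embed <- c(embed, list(maw))
    }
    embed <- c(embed, list(
      nn_conv(cfg$in_channels, w[1], stride = 2L),
      nn_relu(),
      nn_resblock(w[1], w[1], attn = attn),
      nn_resblock(w[1], w[2], stride = 2L, attn = attn),
      nn_resblock(w[2], w[3], stride = 2L, attn = attn),
      nn_gap(),
      nn_bnorm(w[3]), # standardise pooled features; see nn_bnorm()
      nn_linear(w[3], cfg$embed_dim, bias = FALSE), # bias-free before L2 norm
      nn_l2norm()
    ))
    head_lin <- nn_linear(cfg$embed_dim, 1L)
    head_lin$lr_mult <- 10 # logistic layer on unit-norm embeddings
    structure(list(cfg = cfg, embed = embed, head = list(head_lin),
                   norm = default_input_norm()),
              class = "mcat_branch")
  })
}

# Input normalisation stats.  Training data in this domain is dominated by
# anatomy shared across lesions; subtracting the per-channel training-set
# mean image and scaling by the residual SD puts the lesion-to-lesion
# differences (the discriminative part) on unit scale, the usual dataset
# normalisation step.  The default (mean 0.5, SD 0.5) maps [0, 1] onto
# [-1, 1] until stats are fitted.
default_input_norm <- function() {
  list(mean = 0.5, sd = 0.5, fitted = FALSE)
}

fit_input_norm <- function(x) {
  d <- dim(x)
  mu <- array(rowMeans(matrix(x, d[1] * d[2] * d[3], d[4])), d[1:3])
  resid <- x - as.vector(mu)
  per_chan <- matrix(aperm(resid, c(1, 2, 4, 3)), ncol = d[3])
  list(mean = mu, sd = pmax(sqrt(colMeans(per_chan^2)), 1e-6), fitted = TRUE)
}

apply_input_norm <- function(x, norm) {
  d <- dim(x)
  if (length(norm$mean) > 1) {
    x <- x - rep(as.vector(norm$mean), d[4])
  } else {
    x <- x - norm$mean
  }
  if (length(norm$sd) > 1) {
    x / rep(rep(norm$sd, each = d[1] * d[2]), d[4])
  } else {
    x / norm$sd
  }
}

# Fit the branch's input normalisation from training records (no-op when
# stats were already fitted, so fine-tuning reuses the pretraining stats).
fit_branch_norm <- function(branch, records) {
  if (isTRUE(branch$norm$fitted)) return(branch)
  branch$norm <- fit_input_norm(stack_array(records, branch$cfg$modality))
  branch
}

#' Forward pass of a branch
#'
#' @param branch An `mcat_branch`.
#' @param x Array `H x W x C x N` of stacked modality channels.
#' @param train Keep caches for backpropagation.
#' @return List with `embedding` (`N x E`, unit rows), `prob` (`N`
#'   MVI-positive probabilities), `logit`, `gates` (input-MAWM gate matrix
#'   `N x C`, or `NULL`), and caches when `train = TRUE`.
#' @export
branch_forward <- function(branch, x, train = FALSE) {
  stopifnot(inherits(branch, "mcat_branch"))
  if (dim(x)[3] != branch$cfg$in_channels) {
    stop("branch_forward: expected ", branch$cfg$in_channels, " channels")
  }
  x <- apply_input_norm(x, branch$norm)
  fe <- net_forward(branch$embed, x, train)
  fh <- net_forward(branch$head, fe$out, train)
  logit <- as.numeric(fh$out)
  gates <- if (branch$cfg$input_mawm && !is.null(fe$gates)) {
    g <- fe$gates
    colnames(g) <- branch$cfg$channel_names
    g
  }
  list(embedding = fe$out, logit = logit, prob = sigmoid(logit),
       gates = gates,
       embed_caches = if (train) fe$caches, head_caches = if (train) fh$caches)
}

#' Batch-averaged attention profile of the input MAWM
#'
#' @param branch An `mcat_branch` with an input MAWM.
#' @param x Input array `H x W x C x N`.
#' @return Named numeric vector of per-channel gate values in `[0, 1]`,
#'   averaged over the batch.
#' @export
attention_profile <- function(branch, x) {
  stopifnot(inherits(branch, "mcat_branch"))
  if (!branch$cfg$input_mawm) stop("branch has no input MAWM")
  g <- colMeans(branch_forward(branch, x)$gates)
  names(g) <- branch$cfg$channel_names
  g
}

#' Pin or release the gates of every attention block in a branch
#'
#' With `gates = 1` the branch reduces exactly (bit-for-bit) to its gate-free
#' backbone; with a unit vector zeroed at channel k the input MAWM suppresses
#' that channel entirely.
#'
#' @param branch An `mcat_branch`.
#' @param input_gates Vector of fixed input-MAWM gates, a single value
#'   recycled over channels, or `NULL` to restore adaptive gating.
#' @param stage_gates Same for the per-stage gates.
#' @return The modified branch.
#' @export
pin_gates <- function(branch, input_gates = NULL, stage_gates = NULL) {
  stopifnot(inherits(branch, "mcat_branch"))
  for (i in seq_along(branch$embed)) {
    l <- branch$embed[[i]]
    if (l$type == "mawm") {
      branch$embed[[i]]$force_gates <-
        if (is.null(input_gates)) NULL else rep(input_gates, length.out = l$channels)
    } else if (l$type == "resblock" && !is.null(l$gate)) {
      branch$embed[[i]]$gate$force_gates <-
        if (is.null(stage_gates)) NULL else rep(stage_gates, length.out = l$gate$channels)
    }
  }
  branch
}

#' Remove every attention block from a branch, keeping all other weights
#'
#' @param branch An `mcat_branch`.
#' @return A branch with the input MAWM dropped and stage gates removed;
#'   convolutional, linear and head parameters are shared with the input.
#' @export
strip_attention <- function(branch) {
  stopifnot(inherits(branch, "mcat_branch"))
  embed <- list()
  for (l in branch$embed) {
    if (l$type == "mawm") next
    if (l$type == "resblock" && !is.null(l$gate)) {
      l$gate <- NULL
      l$params$gate <- NULL
    }
    embed <- c(embed, list(l))
  }
  branch$embed <- embed
  branch$cfg$input_mawm <- FALSE
  branch$cfg$stage_attn <- "none"
  branch
}

# Baselines --------------------------------------------------------------------

#' Build a baseline classifier network
#'
#' `2dcnn` is a four-layer strided convolutional network; `resnet18` is the
#' 18-layer residual network adapted to small greyscale stacks (3x3 stem, no
#' max-pool); `senet18` and `ecanet18` add squeeze-and-excitation or
#' efficient-channel-attention gates to every residual block.
#'
#' @param kind One of `"2dcnn"`, `"resnet18"`, `"senet18"`, `"ecanet18"`.
#' @param channels Number of input channels (3 for CT, 6 for MRI).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mcat_classifier`.
#' @export
build_baseline <- function(kind, channels, seed = 0L) {
  if (!kind %in% c("2dcnn", "resnet18", "senet18", "ecanet18")) {
    stop("unknown baseline kind: ", kind)
  }
  with_seed(derive_seed(seed, paste0("baseline/", kind)), {
    out_lin <- function(width) {
      l <- nn_linear(width, 1L)
      l$lr_mult <- 10 # match the branch head's step size
      l
    }
    layers <- if (kind == "2dcnn") {
      list(
        nn_conv(channels, 16, stride = 2L), nn_relu(),
        nn_conv(16, 32, stride = 2L), nn_relu(),
        nn_conv(32, 64, stride = 2L), nn_relu(),
        nn_conv(64, 64, stride = 2L), nn_relu(),
        nn_gap(), nn_bnorm(64), out_lin(64)
      )
    } else {
      attn <- switch(kind, resnet18 = "none", senet18 = "se", ecanet18 = "eca")
      widths <- c(64, 128, 256, 512)
      ls <- list(nn_conv(channels, widths[1]), nn_relu())
      for (s in seq_along(widths)) {
        in_w <- if (s == 1) widths[1] else widths[s - 1]
        stride <- if (s == 1) 1L else 2L
        ls <- c(ls, list(nn_resblock(in_w, widths[s], stride = stride, attn = attn, r = 16),
                         nn_resblock(widths[s], widths[s], attn = attn, r = 16)))
      }
      c(ls, list(nn_gap(), nn_bnorm(widths[4]), out_lin(widths[4])))
    }
    structure(list(kind = kind, channels = channels, layers = layers,
                   norm = default_input_norm()),
              class = "mcat_classifier")
  })
}

#' Forward pass of a baseline classifier
#'
#' @param model An `mcat_classifier`.
#' @param x Array `H x W x C x N`.
#' @param train Keep caches for backpropagation.
#' @return List with `prob`, `logit` and caches when `train = TRUE`.
#' @export
classifier_forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "mcat_classifier"))
  x <- apply_input_norm(x, model$norm)
  f <- net_forward(model$layers, x, train)
  logit <- as.numeric(f$out)
  list(logit = logit, prob = sigmoid(logit), caches = if (train) f$caches)
}

#' Number of trainable parameters of a network
#'
#' @param model An `mcat_branch` or `mcat_classifier`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "mcat_branch")) {
    n_params(net_params(model$embed)) + n_params(net_params(model$head))
  } else if (inherits(model, "mcat_classifier")) {
    n_params(net_params(model$layers))
  } else {
    stop("unsupported model")
  }
}
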