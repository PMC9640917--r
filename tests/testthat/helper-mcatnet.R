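# Shared fixture builders: everything is generated in code at test time.

# Small mixed cohort for fast training tests (32x32 patches).
tiny_cohort <- function(n_ct = 8, n_mri = 6, n_mixed = 6, side = 32,
                        d = 1.5, seed = 42, complementary = TRUE) {
  generate_cohort(cohort_spec(
    n_ct_only = n_ct, n_mri_only = n_mri, n_mixed = n_mixed,
    pos_fraction = c(0.5, 0.5, 0.5), side = side, d_signal = d,
    complementary = complementary, seed = seed
  ))
}

# A volume with a known blob on a known slice.
blob_volume <- function(n_slices = 4, nr = 12, nc = 14, areas = c(0, 5, 9, 3),
                        channel = "AP", seed = 7) {
  set.seed(seed)
  img <- array(runif(n_slices * nr * nc), c(n_slices, nr, nc))
  mask <- array(0, c(n_slices, nr, nc))
  for (s in seq_len(n_slices)) {
    if (areas[s] > 0) mask[s, 2, seq_len(areas[s])] <- 1
  }
  annotated_volume(img, mask, channel)
}

# Exhaustive pairwise AUC oracle (ties counted 1/2), independent of roc_auc.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Independent Hanley-McNeil oracle, coded separately from auc_z_test.
hm_z_oracle <- function(a1, np1, nn1, a2, np2, nn2) {
  se <- function(a, np, nn) {
    q1 <- a / (2 - a); q2 <- 2 * a * a / (1 + a)
    sqrt((a * (1 - a) + (np - 1) * (q1 - a * a) + (nn - 1) * (q2 - a * a)) /
           (np * nn))
  }
  (a2 - a1) / sqrt(se(a1, np1, nn1)^2 + se(a2, np2, nn2)^2)
}
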