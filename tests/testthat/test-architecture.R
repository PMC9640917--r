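test_that("MAWM gating follows the squeeze-excite-prior forward formula", {
  set.seed(10)
  x <- array(runif(8 * 8 * 3 * 4), c(8, 8, 3, 4))

  # zero-initialised excitation, uniform prior: every gate is sigmoid(0) = 0.5
  out <- mawm_forward(x, mawm_config(3))
  expect_equal(out$profile, rep(0.5, 3), ignore_attr = TRUE)
  expect_equal(out$out, x * 0.5)

  # prior enters as a log-ratio bias on the gate logits
  pri <- mawm_forward(x, mawm_config(3, prior = c(1, 2, 1)))
  expect_equal(pri$profile,
               plogis(log(c(1, 2, 1) / mean(c(1, 2, 1)))),
               ignore_attr = TRUE, tolerance = 1e-12)

  # gates are invariant to a global rescaling of the prior weights
  a <- mawm_forward(x, mawm_config(3, prior = c(1, 2, 1)))$profile
  b <- mawm_forward(x, mawm_config(3, prior = c(5, 10, 5)))$profile
  expect_equal(a, b)

  # forced gates: identity and exact channel suppression
  id <- mawm_forward(x, mawm_config(3), force_gates = c(1, 1, 1))
  expect_identical(id$out, x)
  z2 <- mawm_forward(x, mawm_config(3), force_gates = c(1, 0, 1))
  expect_true(all(z2$out[, , 2, ] == 0))
  expect_identical(z2$out[, , 1, ], x[, , 1, ])
  expect_identical(z2$out[, , 3, ], x[, , 3, ])

  expect_error(mawm_forward(x, mawm_config(4)), "channels")
})

test_that("branches respect modality channel conventions and contracts", {
  set.seed(11)
  ct <- build_single_branch(branch_config("ct"), seed = 3)
  x3 <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  f <- branch_forward(ct, x3)
  expect_equal(dim(f$embedding), c(2, 128))
  expect_equal(sqrt(rowSums(f$embedding^2)), c(1, 1), tolerance = 1e-5)
  expect_true(all(f$prob >= 0 & f$prob <= 1))
  expect_equal(dim(f$gates), c(2, 3))
  expect_true(all(f$gates >= 0 & f$gates <= 1))

  mri <- build_single_branch(branch_config("mri"), seed = 3)
  x6 <- array(runif(32 * 32 * 6 * 2), c(32, 32, 6, 2))
  expect_length(branch_forward(mri, x6)$prob, 2)
  expect_error(branch_forward(ct, x6), "channels")
})

test_that("pinning all gates to 1 reduces the branch to its gate-free backbone", {
  set.seed(12)
  br <- build_single_branch(branch_config("ct"), seed = 5)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  pinned <- pin_gates(br, input_gates = 1, stage_gates = 1)
  bare <- strip_attention(br)
  # bit-identical, not merely close
  expect_identical(branch_forward(pinned, x)$logit,
                   branch_forward(bare, x)$logit)
  expect_identical(branch_forward(pinned, x)$embedding,
                   branch_forward(bare, x)$embedding)

  # zeroing the input gate of channel k suppresses that channel's influence
  zk <- pin_gates(br, input_gates = c(1, 0, 1))
  x_perturbed <- x
  x_perturbed[, , 2, ] <- runif(32 * 32 * 3)
  expect_equal(branch_forward(zk, x)$logit,
               branch_forward(zk, x_perturbed)$logit)
})

test_that("baseline networks expose the documented family differences", {
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  for (kind in c("2dcnn", "resnet18", "senet18", "ecanet18")) {
    m <- build_baseline(kind, 3, seed = 1)
    p <- classifier_forward(m, x)$prob
    expect_true(all(p >= 0 & p <= 1), info = kind)
  }
  n_res <- count_params(build_baseline("resnet18", 3))
  n_se <- count_params(build_baseline("senet18", 3))
  n_eca <- count_params(build_baseline("ecanet18", 3))
  expect_gt(n_se, n_res)   # SE blocks add bottleneck weights per stage
  expect_gt(n_eca, n_res)  # ECA adds a shared 1D kernel
  expect_lt(n_eca - n_res, n_se - n_res)
  expect_error(build_baseline("foo", 3), "unknown baseline")
})
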