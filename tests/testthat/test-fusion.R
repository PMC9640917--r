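make_pair <- function(seed = 1) {
  list(ct = build_single_branch(branch_config("ct", widths = c(4, 8, 16),
                                              embed_dim = 16), seed = seed),
       mri = build_single_branch(branch_config("mri", widths = c(4, 8, 16),
                                               embed_dim = 16), seed = seed))
}

test_that("fused probability is the stated convex combination", {
  br <- make_pair()
  co <- tiny_cohort(n_ct = 0, n_mri = 0, n_mixed = 4, side = 32, seed = 21)

  expect_error(fusion_config(w_ct = 0.7, w_mr = 0.4), "sum to 1")
  expect_error(fusion_config(w_ct = -0.2, w_mr = 1.2), "nonnegative")

  m_ct_only <- fuse_branches(br$ct, br$mri, fusion_config(w_ct = 1, w_mr = 0))
  m_even <- fuse_branches(br$ct, br$mri, fusion_config())
  for (rec in co) {
    p_ct <- predict(m_ct_only, rec)
    single <- lesion_record(rec$lesion_id, rec$label, ct = rec$ct)
    expect_equal(p_ct$prob, predict(m_ct_only, single)$prob)
    both <- predict(m_even, rec)
    p_mr <- predict(m_even, lesion_record(rec$lesion_id, rec$label,
                                          mri = rec$mri))
    expect_equal(both$prob, 0.5 * predict(m_even, single)$prob +
                   0.5 * p_mr$prob)
    # convexity: fused probability between the branch probabilities
    lo <- min(predict(m_even, single)$prob, p_mr$prob)
    hi <- max(predict(m_even, single)$prob, p_mr$prob)
    expect_gte(both$prob, lo - 1e-12)
    expect_lte(both$prob, hi + 1e-12)
  }
})

test_that("prediction routes by modality availability", {
  br <- make_pair(2)
  model <- fuse_branches(br$ct, br$mri, fusion_config())
  co <- tiny_cohort(n_ct = 2, n_mri = 2, n_mixed = 2, side = 32, seed = 22)
  routes <- vapply(co, function(r) predict(model, r)$route, character(1))
  av <- vapply(co, function(r) r$availability, character(1))
  expect_equal(routes, c(ct = "ct", mri = "mri", both = "fused")[av],
               ignore_attr = TRUE)
  pred <- predict_cohort(model, co)
  expect_equal(nrow(pred), length(co))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_equal(pred$predicted, as.integer(pred$prob > 0.5))
  expect_error(lesion_record("x", 1), "at least one modality")
})

test_that("joint updating trains both branches on mixed data only", {
  br <- make_pair(3)
  co <- tiny_cohort(n_ct = 4, n_mri = 0, n_mixed = 10, side = 32, d = 3,
                    seed = 23)
  mixed <- eligible_records(co, "double")
  model <- fuse_branches(br$ct, br$mri,
                         fusion_config(epochs = 4, batch_size = 5, seed = 7))

  m0 <- joint_update(model, mixed, fusion_config(epochs = 0))
  expect_identical(m0, model)

  expect_error(joint_update(model, co), "both modalities")

  m1 <- joint_update(model, mixed)
  m2 <- joint_update(model, mixed)
  expect_identical(m1, m2) # deterministic given the config seed
  expect_false(identical(m1$ct, model$ct))
  expect_false(identical(m1$mri, model$mri))
  # loss on the mixed training records decreases after the joint update
  y <- record_labels(mixed)
  bce <- function(m) {
    p <- pmin(pmax(predict_cohort(m, mixed)$prob, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  expect_lt(bce(m1), bce(model))
})

test_that("learnable fusion weights stay on the simplex at every step", {
  br <- make_pair(4)
  co <- tiny_cohort(n_ct = 0, n_mri = 0, n_mixed = 10, side = 32, d = 3,
                    seed = 25)
  model <- fuse_branches(br$ct, br$mri,
                         fusion_config(epochs = 3, batch_size = 4,
                                       learn_weights = TRUE, seed = 5))
  m1 <- joint_update(model, co)
  expect_equal(sum(m1$weights), 1, tolerance = 1e-6)
  expect_true(all(m1$weights >= 0))
})
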