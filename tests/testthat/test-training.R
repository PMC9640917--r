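test_that("augmentation applies one shared transform per stack and re-clips", {
  co <- tiny_cohort(n_ct = 2, n_mri = 0, n_mixed = 0, side = 32, seed = 1)
  st <- co[[1]]$ct

  idpol <- augmentation_policy(hflip = FALSE, vflip = FALSE, rotate = 0,
                               scale = 0, intensity_sd = 0, multiplicity = 1)
  set.seed(1)
  expect_identical(augment(st, idpol)$pixels, st$pixels)

  pol <- augmentation_policy()
  set.seed(7); a1 <- augment(st, pol)
  set.seed(7); a2 <- augment(st, pol)
  expect_identical(a1$pixels, a2$pixels)
  expect_true(all(a1$pixels >= 0 & a1$pixels <= 1))

  # horizontal flip moves an impulse from column j to S - 1 - j in every channel
  S <- 32L
  imp <- st
  imp$pixels[] <- 0
  j <- 9L
  for (ch in 1:3) imp$pixels[16, j + 1, ch] <- 1
  flip <- augmentation_policy(hflip = TRUE, vflip = FALSE, rotate = 0,
                              scale = 0, intensity_sd = 0, multiplicity = 1)
  repeat { # draw until the 50% flip fires
    f <- augment(imp, flip)
    if (!identical(f$pixels, imp$pixels)) break
  }
  for (ch in 1:3) {
    peak <- which(f$pixels[, , ch] == max(f$pixels[, , ch]), arr.ind = TRUE)[1, ]
    expect_equal(unname(peak["row"]), 16)
    expect_equal(unname(peak["col"]), S - j) # 0-based S-1-j, 1-based S-j
  }
})

test_that("triplet loss matches its closed form on constructed embeddings", {
  # margin satisfied
  e_a <- c(1, 0); e_p <- e_a - c(0.2, 0) # d2 = 0.04
  e_n <- c(-0.5, 0) # d2(a, n) = 2.25
  expect_equal(triplet_loss(e_a, e_p, e_n, margin = 0.3), 0, ignore_attr = TRUE)
  # violated margin: d2(a,p) = 1.0, d2(a,n) = 0.5 -> 1.0 - 0.5 + 0.3 = 0.8
  expect_equal(triplet_loss(c(0, 0), c(1, 0), c(0.5, 0.5), 0.3), 0.8,
               ignore_attr = TRUE, tolerance = 1e-12)
  # collapsed triplet gives exactly the margin
  e <- runif(8)
  expect_equal(triplet_loss(e, e, e, 0.3), 0.3, ignore_attr = TRUE)
  expect_error(triplet_loss(c(1, 0), c(1, 0, 0), c(0, 1)), "dimension")

  # zero whenever inter-class exceeds intra-class distance by >= margin
  set.seed(5)
  for (rep in 1:25) {
    a <- rnorm(6); p <- a + rnorm(6, sd = 0.05)
    dir <- rnorm(6); dir <- dir / sqrt(sum(dir^2))
    need <- sqrt(sum((a - p)^2) + 0.3)
    n <- a + dir * (need + runif(1, 0.01, 1))
    expect_equal(triplet_loss(a, p, n, 0.3), 0, ignore_attr = TRUE)
  }
})

test_that("triplet mining enumerates batch_all and selects hard examples", {
  emb <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  tb <- mine_triplets(emb, c(1, 1, 0), "batch_all")
  expect_equal(nrow(tb), 2)
  expect_setequal(paste(tb$anchor, tb$positive, tb$negative),
                  c("1 2 3", "2 1 3"))
  expect_error(mine_triplets(emb, c(1, 1, 1)), "no valid triplets")

  # batch_hard is a subset of batch_all; hardest positive is the farthest one
  set.seed(6)
  emb2 <- matrix(rnorm(8 * 4), 8)
  lab2 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  all_t <- mine_triplets(emb2, lab2, "batch_all")
  hard <- mine_triplets(emb2, lab2, "batch_hard")
  key <- function(d) paste(d$anchor, d$positive, d$negative)
  expect_true(all(key(hard) %in% key(all_t)))
  d2 <- as.matrix(dist(emb2))^2
  for (i in seq_len(nrow(hard))) {
    a <- hard$anchor[i]
    ps <- setdiff(which(lab2 == lab2[a]), a)
    ns <- which(lab2 != lab2[a])
    expect_equal(hard$positive[i], ps[which.max(d2[a, ps])])
    expect_equal(hard$negative[i], ns[which.min(d2[a, ns])])
  }
  # anchors and positives share labels; negatives differ
  expect_true(all(lab2[all_t$anchor] == lab2[all_t$positive]))
  expect_true(all(lab2[all_t$anchor] != lab2[all_t$negative]))
})

test_that("embedding pretraining lowers triplet loss and is seed-deterministic", {
  co <- tiny_cohort(n_ct = 12, n_mri = 0, n_mixed = 0, side = 32, d = 3,
                    seed = 31)
  br <- build_single_branch(branch_config("ct", widths = c(4, 8, 16),
                                          embed_dim = 16), seed = 2)
  pol <- augmentation_policy(multiplicity = 2)
  cfg <- training_config("pretrain", epochs = 6, batch_size = 8, seed = 9)

  r1 <- pretrain_embedding(br, co, pol, cfg)
  expect_lt(r1$history$loss[6], r1$history$loss[1])
  # the evaluation head is untouched by pretraining
  expect_identical(r1$branch$head, br$head)
  # determinism
  r2 <- pretrain_embedding(br, co, pol, cfg)
  expect_identical(r1$branch, r2$branch)
  # zero epochs change nothing
  r0 <- pretrain_embedding(br, co, pol,
                           training_config("pretrain", epochs = 0, seed = 9))
  expect_identical(r0$branch, br)

  ones <- co[record_labels(co) == 1]
  expect_error(pretrain_embedding(br, ones, pol, cfg), "single-class")
})

test_that("fine-tuning fits a separable cohort and respects stage contracts", {
  # strong planted effect: the classes are separable by construction
  co <- tiny_cohort(n_ct = 80, n_mri = 0, n_mixed = 0, side = 32, d = 6,
                    seed = 33)
  br <- build_single_branch(branch_config("ct", widths = c(4, 8, 16),
                                          embed_dim = 16), seed = 2)
  br <- pretrain_embedding(br, co, NULL,
                           training_config("pretrain", epochs = 8,
                                           mining = "batch_all",
                                           batch_size = 16, seed = 9))$branch
  ft <- finetune_classifier(br, co,
                            training_config("finetune", epochs = 30,
                                            batch_size = 16, seed = 9))
  acc <- mean((branch_forward(ft$branch, stack_array(co, "ct"))$prob > 0.5) ==
                record_labels(co))
  expect_gte(acc, 0.9)

  r0 <- finetune_classifier(br, co,
                            training_config("finetune", epochs = 0, seed = 9))
  expect_identical(r0$branch$head, br$head)

  frozen <- finetune_classifier(
    br, co, training_config("finetune", epochs = 3, seed = 9,
                            freeze_embedding = TRUE)
  )
  expect_identical(frozen$branch$embed, br$embed)
})

test_that("end-to-end training is deterministic and honours the parity budget", {
  co <- tiny_cohort(n_ct = 10, n_mri = 0, n_mixed = 0, side = 32, seed = 35)
  br <- build_single_branch(branch_config("ct", widths = c(4, 8, 16),
                                          embed_dim = 16), seed = 4)
  pol <- augmentation_policy(multiplicity = 2)
  cfg <- training_config("end_to_end", epochs = 4, batch_size = 8, seed = 12)
  r1 <- train_end_to_end(br, co, pol, cfg, epochs_aug = 2)
  r2 <- train_end_to_end(br, co, pol, cfg, epochs_aug = 2)
  expect_identical(r1$branch, r2$branch)
  expect_equal(nrow(r1$history), 4)
  p <- branch_forward(r1$branch, stack_array(co, "ct"))$prob
  expect_true(all(p >= 0 & p <= 1))
})
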