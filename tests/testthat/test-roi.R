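test_that("largest-lesion slice selection maximises mask area with low-index ties", {
  vol <- blob_volume(areas = c(0, 5, 9, 3))
  expect_identical(select_largest_lesion_slice(vol), 2L)

  tie <- blob_volume(n_slices = 3, areas = c(4, 4, 1))
  expect_identical(select_largest_lesion_slice(tie), 0L)

  # exhaustive-scan invariant on random masks
  set.seed(1)
  for (rep in 1:20) {
    mask <- array(rbinom(5 * 8 * 8, 1, 0.2), c(5, 8, 8))
    if (all(mask == 0)) mask[2, 1, 1] <- 1
    vol <- annotated_volume(array(0, dim(mask)), mask, "plain")
    k <- select_largest_lesion_slice(vol)
    areas <- apply(mask, 1, sum)
    expect_true(all(areas[k + 1] >= areas))
    expect_equal(k, min(which(areas == max(areas))) - 1L)
  }

  empty <- annotated_volume(array(0, c(2, 3, 3)), array(0, c(2, 3, 3)), "DWI")
  expect_error(select_largest_lesion_slice(empty), "empty mask")
})

test_that("crop_roi returns the margin-expanded tight box, clipped to bounds", {
  img <- matrix(seq_len(72), 8, 9)
  mask <- matrix(0, 8, 9)
  mask[3:6, 4:8] <- 1 # rows 2-5, cols 3-7 in 0-based terms

  tight <- crop_roi(img, mask, margin = 0)
  expect_equal(tight$box, list(rows = c(2, 6), cols = c(3, 8)))
  expect_equal(dim(tight$pixels), c(4, 5))
  expect_equal(tight$pixels, img[3:6, 4:8])

  clipped <- crop_roi(img, mask, margin = 3)
  expect_equal(clipped$box, list(rows = c(0, 8), cols = c(0, 9)))
  expect_equal(dim(clipped$pixels), dim(img))

  expect_error(crop_roi(img, matrix(0, 8, 9)), "empty mask")
})

test_that("greyscale normalization is a min-max map with degenerate-range convention", {
  expect_equal(normalize_greyscale(matrix(c(0, 128, 255), 1)),
               matrix(c(0, 128 / 255, 1), 1))
  expect_equal(normalize_greyscale(matrix(7, 3, 3)), matrix(0, 3, 3))
  ident <- matrix(c(0, 0.25, 0.5, 1), 2)
  expect_equal(normalize_greyscale(ident), ident)
  expect_error(normalize_greyscale(matrix(c(1, NA), 1)), "non-finite")

  # idempotence on its own output
  set.seed(2)
  for (rep in 1:10) {
    p <- matrix(rnorm(30, sd = 50), 5, 6)
    q <- normalize_greyscale(p)
    expect_equal(normalize_greyscale(q), q, tolerance = 1e-6)
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("modality stacks enforce canonical channel sets and order", {
  p <- function() matrix(runif(16), 4, 4)
  ct <- assemble_modality_stack(list(PVP = p(), plain = p(), AP = p()), "ct")
  expect_equal(ct$channel_names, c("plain", "AP", "PVP"))
  expect_equal(dim(ct$pixels), c(4, 4, 3))

  mri_chans <- list(T2WI = p(), DWI = p(), T1pre = p(), T1AP = p(),
                    T1PVP = p(), T1EP = p())
  expect_s3_class(assemble_modality_stack(mri_chans, "mri"), "modality_stack")
  expect_error(assemble_modality_stack(mri_chans[1:5], "mri"),
               "missing channel T1EP")
  expect_error(assemble_modality_stack(list(plain = p(), AP = p()), "ct"),
               "missing channel")
  expect_error(
    assemble_modality_stack(stats::setNames(list(p(), p(), p()),
                                            c("plain", "AP", "AP")), "ct"),
    "duplicate"
  )
  expect_error(assemble_modality_stack(list(plain = p(), AP = p(), foo = p()), "ct"),
               "unknown channel")
})

test_that("crop-resample-normalize pipeline preserves an impulse location", {
  set.seed(3)
  for (rep in 1:10) {
    img <- matrix(0, 40, 40)
    r <- sample(10:30, 1); c <- sample(10:30, 1)
    img[r, c] <- 1
    mask <- matrix(0, 40, 40)
    mask[8:32, 8:32] <- 1
    vol <- annotated_volume(array(img, c(1, 40, 40)),
                            array(mask, c(1, 40, 40)), "plain")
    out <- extract_roi_patch(vol, side = 64, margin = 2)
    peak <- which(out$pixels == max(out$pixels), arr.ind = TRUE)[1, ]
    # map the impulse through crop + resample analytically
    scale <- 64 / (out$box$rows[2] - out$box$rows[1])
    exp_r <- (r - out$box$rows[1] - 0.5) * scale + 0.5
    exp_c <- (c - out$box$cols[1] - 0.5) * (64 / (out$box$cols[2] - out$box$cols[1])) + 0.5
    expect_lt(abs(peak["row"] - exp_r), 1.5)
    expect_lt(abs(peak["col"] - exp_c), 1.5)
  }
})

test_that("cohorts round-trip through the PNG + manifest layout", {
  co <- tiny_cohort(n_ct = 2, n_mri = 1, n_mixed = 1, side = 32, seed = 9)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  back <- load_cohort(manifest, side = 32)
  expect_length(back, 4)
  expect_equal(vapply(back, function(r) r$availability, character(1)),
               vapply(co, function(r) r$availability, character(1)))
  expect_equal(record_labels(back), record_labels(co))
  for (i in seq_along(back)) {
    expect_true(all(back[[i]]$ct$pixels >= 0 & back[[i]]$ct$pixels <= 1,
                    na.rm = TRUE))
  }
})

test_that("NIfTI volumes feed the same pipeline as in-memory arrays", {
  skip_if_not_installed("RNifti")
  set.seed(4)
  img <- array(runif(6 * 20 * 20), c(20, 20, 6)) # x, y, z on disk
  msk <- array(0, c(20, 20, 6))
  msk[6:14, 6:14, 3] <- 1
  dir <- withr::local_tempdir()
  ip <- file.path(dir, "img.nii.gz"); mp <- file.path(dir, "msk.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), ip)
  RNifti::writeNifti(RNifti::asNifti(msk), mp)
  vol <- annotated_volume(mcatnet:::read_image_any(ip),
                          round(mcatnet:::read_image_any(mp)), "T2WI")
  expect_identical(select_largest_lesion_slice(vol), 2L)
  patch <- extract_roi_patch(vol, side = 32)
  expect_equal(dim(patch$pixels), c(32, 32))
  expect_true(all(patch$pixels >= 0 & patch$pixels <= 1))
})
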