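test_that("background removal recovers the phantom foreground", {
  coh <- tiny_cohort(n = 1, size = 128, seed = 3)
  faces <- cohort_faces(coh)
  for (i in seq_len(min(4, nrow(faces)))) {
    res <- remove_background(faces$image[[i]])
    ref <- as.matrix(EBImage::fillHull(
      matrix(as.numeric(faces$mask[[i]] != 0), 128, 128))) > 0.5
    iou <- sum(res$foreground & ref) / sum(res$foreground | ref)
    expect_gte(iou, 0.95)
  }
  # idempotence: running twice equals running once
  once <- remove_background(faces$image[[1]])
  twice <- remove_background(once$image)
  expect_equal(twice$image, once$image)
  # all-background image errors
  flat <- array(10, c(80, 80, 3))
  expect_error(remove_background(flat), "no foreground")
})

test_that("padding centres content on a square canvas filled with the fill value", {
  img <- array(runif(100 * 60 * 3, 0, 255), c(100, 60, 3))
  p <- pad_to_square(img, fill = 0)
  expect_equal(dim(p), c(100, 100, 3))
  expect_true(all(p[, 1:20, ] == 0))
  expect_equal(p[, 21:80, ], img)
  sq <- array(1, c(64, 64, 3))
  expect_identical(pad_to_square(sq), sq)
  m <- matrix(3L, 50, 20)
  pm <- pad_to_square(m, fill = 0L)
  expect_equal(dim(pm), c(50, 50))
  expect_setequal(unique(as.vector(pm)), c(0L, 3L))
})

test_that("resizing keeps masks inside their class set and is identity at own size", {
  withr::with_seed(4, {
    m <- matrix(sample(c(0L, 2L, 3L), 768 * 768, replace = TRUE), 768, 768)
  })
  r <- resize_uniform(m, 96)
  expect_true(all(r %in% c(0L, 2L, 3L)))
  expect_identical(resize_uniform(m, 768), m)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  expect_identical(resize_uniform(img, 64), img)
  expect_error(resize_uniform(array(0, c(10, 20, 3)), 16), "not square")
})

test_that("SSIM is 1 on identity, symmetric, and matches the closed form", {
  withr::with_seed(5, {
    a <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
    b <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  })
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(ssim(a, array(0, c(32, 32, 3))), "shape mismatch")
  # constant vs constant-offset: variances vanish, so any window gives
  # (2 mu_a mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  x <- matrix(100, 16, 16); y <- matrix(140, 16, 16)
  c1 <- (0.01 * 255)^2
  expect_equal(ssim(x, y), (2 * 100 * 140 + c1) / (100^2 + 140^2 + c1),
               tolerance = 1e-12)
})

test_that("PSNR matches its closed form and returns Inf for identical images", {
  a <- array(100, c(32, 32, 3))
  expect_equal(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 1), 20 * log10(255), tolerance = 1e-9)  # 48.13 dB
  zero <- array(0, c(8, 8, 3)); full <- array(255, c(8, 8, 3))
  expect_equal(psnr(zero, full), 0)
  expect_error(psnr(a, array(0, c(16, 16, 3))), "shape mismatch")
})

test_that("SSIM and PSNR agree with brute-force formula evaluation on small images", {
  withr::with_seed(6, {
    a <- matrix(runif(24 * 24, 0, 255), 24, 24)
    b <- a + rnorm(24 * 24, 0, 12)
  })
  expect_equal(ssim(a, b, window = 7), oracle_ssim(a, b, window = 7),
               tolerance = 1e-10)
  expect_equal(psnr(a, b), 10 * log10(255^2 / mean((a - b)^2)), tolerance = 1e-12)
})

test_that("quality report reproduces order statistics and flags empty cohorts", {
  imgs <- withr::with_seed(7, lapply(1:3, function(i) {
    array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  }))
  q <- quality_report(imgs, 64)           # no-op resize -> perfect quality
  expect_true(all(q$ssim == 1))
  expect_true(all(is.infinite(q$psnr_db)))
  expect_error(quality_report(list(), 64), "empty cohort")
  # phantom cohort at its own generation scale keeps high structural quality
  coh <- tiny_cohort(n = 1, size = 128, seed = 3)
  q2 <- quality_report(cohort_faces(coh)$image[1:4], 96)
  expect_gte(attr(q2, "summary")$median[1], 0.9)
  expect_s3_class(glance(q2), "tbl_df")
})

test_that("preprocess chain keeps image and mask geometrically aligned", {
  coh <- tiny_cohort(n = 1, size = 128, seed = 3)
  f <- cohort_faces(coh)
  out <- preprocess_face(f$image[[1]], f$mask[[1]], size = 96, remove_bg = FALSE)
  expect_equal(dim(out$image)[1:2], dim(out$mask))
  # downsampled mask must agree with the mask of a pixel-classified image:
  # compare LV fractions before and after the chain
  a0 <- areas_from_mask(f$mask[[1]]); a1 <- areas_from_mask(out$mask)
  lv0 <- (a0[["infarct"]] + a0[["aar_non_infarcted"]]) / sum(a0[2:4])
  lv1 <- (a1[["infarct"]] + a1[["aar_non_infarcted"]]) / sum(a1[2:4])
  expect_lt(abs(lv0 - lv1), 0.02)
})
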