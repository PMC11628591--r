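test_that("network maps 3-channel input to 5 normalized class maps", {
  m <- build_unet(image_size = 96, depth = 2, base_channels = 4, seed = 2)
  img <- withr::with_seed(1, array(runif(96 * 96 * 3, 0, 255), c(96, 96, 3)))
  p <- predict(m, img)
  expect_equal(dim(p), c(96, 96, 5))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(range(apply(p, c(1, 2), sum)), c(1, 1), tolerance = 1e-10)
  # inference is deterministic
  expect_identical(p, predict(m, img))
  # same seed -> identical initial parameters; different seed -> different
  expect_identical(m$par, build_unet(96, 2, 4, seed = 2)$par)
  expect_false(identical(m$par, build_unet(96, 2, 4, seed = 3)$par))
  expect_error(predict(m, array(0, c(64, 64, 3))), "preprocess")
  expect_error(build_unet(image_size = 100, depth = 3), "divisible")
})

test_that("decoder widths follow the encoder spec (dynamic sizing)", {
  m <- build_unet(image_size = 64, depth = 3, base_channels = 5, seed = 1)
  lt <- m$layer_table
  # decoder rows: input = upsampled channels + skip channels
  expect_equal(lt[8, 1], 40 + 20)  # bottleneck 40 up + level-3 skip 20
  expect_equal(lt[9, 1], 20 + 10)
  expect_equal(lt[10, 1], 10 + 5)
  expect_equal(lt[nrow(lt), 2], 5)  # five class logits
  img <- array(0, c(64, 64, 3))
  expect_equal(dim(predict(m, img)), c(64, 64, 5))
})

test_that("composite loss obeys its limits and component isolation", {
  withr::with_seed(8, {
    target <- matrix(sample(0:4, 16 * 16, TRUE), 16, 16)
  })
  onehot <- array(0, c(16, 16, 5))
  for (k in 0:4) onehot[, , k + 1] <- as.numeric(target == k)
  perfect <- composite_loss(onehot, target)
  expect_equal(perfect$ce, 0, tolerance = 1e-10)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$dice, 0, tolerance = 1e-5)
  expect_equal(perfect$loss, 0, tolerance = 1e-5)
  # uniform probabilities: per pixel (0.8 + 4 * 0.2)/5 = 0.32 MAE
  unif <- array(0.2, c(16, 16, 5))
  r <- composite_loss(unif, target)
  expect_equal(r$mae, 0.32)
  # component isolation: weights (1, 0, 0) leave pure weighted cross-entropy
  w <- c(2, 1, 1, 0.5, 1)
  ce_only <- composite_loss(unif, target, class_weights = w,
                            component_weights = c(1, 0, 0))
  expect_equal(ce_only$loss, ce_only$ce)
  expect_equal(ce_only$ce, -log(0.2), tolerance = 1e-12)
  expect_error(composite_loss(unif, matrix(0L, 8, 8)), "disagree")
})

test_that("C++ loss/gradient agree with the R loss and finite differences", {
  m <- build_unet(image_size = 16, depth = 2, base_channels = 2, seed = 4)
  withr::with_seed(5, {
    img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
    mask <- matrix(sample(0:4, 16 * 16, TRUE), 16, 16)
  })
  cw <- c(1, 2, 0.5, 1, 1.5); lw <- c(1, 0.7, 0.9)
  x <- img / 255 - 0.5
  r <- cpp_unet_lossgrad(m$par, x, mask, cw, lw, m$layer_table, m$depth, 5L, 0)
  expect_equal(r$loss, composite_loss(predict(m, img), mask, cw, lw)$loss,
               tolerance = 1e-12)
  f_at <- function(par) cpp_unet_lossgrad(par, x, mask, cw, lw, m$layer_table,
                                          m$depth, 5L, 0)$loss
  idx <- withr::with_seed(6, sample(length(m$par), 8))
  for (i in idx) {
    h <- 1e-5
    pp <- m$par; pp[i] <- pp[i] + h; up <- f_at(pp)
    pp[i] <- pp[i] - 2 * h; dn <- f_at(pp)
    expect_equal(r$grad[i], (up - dn) / (2 * h), tolerance = 1e-4)
  }
})

test_that("augmentation is seed-reproducible and keeps pairs synchronized", {
  coh <- tiny_cohort(n = 1, size = 96, seed = 13)
  f <- cohort_faces(coh)
  img <- f$image[[1]]; mask <- f$mask[[1]]
  a1 <- withr::with_seed(10, augment(img, mask))
  a2 <- withr::with_seed(10, augment(img, mask))
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% 0:4))
  expect_equal(dim(a1$image), dim(img))
  # paired erasing: with only erasing active, zeroed image pixels are class 0
  erase_only <- augment_config(max_rotate = 0, zoom_range = c(1, 1),
                               max_warp = 0, p_flip = 0, brightness = 0,
                               contrast = 0, saturation = 0, p_erase = 1,
                               p_blur = 0)
  ae <- withr::with_seed(11, augment(img, mask, erase_only))
  erased <- ae$image[, , 1] == 0 & ae$image[, , 2] == 0 & ae$image[, , 3] == 0 &
    !(img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 0)
  expect_gt(sum(erased), 0)
  expect_true(all(ae$mask[erased] == 0))
  # geometry-only transform moves mask and image identically: class areas of
  # the mask match pixel-classified areas of the palette image
  geom_only <- augment_config(max_rotate = 30, zoom_range = c(0.9, 1.1),
                              max_warp = 0.05, p_flip = 0.5, brightness = 0,
                              contrast = 0, saturation = 0, p_erase = 0,
                              p_blur = 0)
  ag <- withr::with_seed(12, augment(img, mask, geom_only))
  infarct_px <- ag$mask == 3
  if (sum(infarct_px) > 50) {
    # infarct renders near-white: the aligned image must be bright there
    expect_gt(mean(ag$image[, , 1][infarct_px]), 180)
  }
})

test_that("probability maps collapse to masks with low-index tie-breaking", {
  maps <- array(0.1, c(2, 2, 5))
  maps[1, 1, 4] <- 0.6
  maps[1, 2, 2] <- 0.5; maps[1, 2, 4] <- 0.5   # tie class 1 vs 3
  m <- maps_to_mask(maps)
  expect_equal(m[1, 1], 3L)
  expect_equal(m[1, 2], 1L)
  # one-hot maps invert exactly
  withr::with_seed(14, {
    target <- matrix(sample(0:4, 64, TRUE), 8, 8)
  })
  onehot <- array(0, c(8, 8, 5))
  for (k in 0:4) onehot[, , k + 1] <- as.numeric(target == k)
  expect_equal(maps_to_mask(onehot), target)
})

test_that("training learns a tiny fixture and returns the best checkpoint", {
  coh <- tiny_cohort(n = 4, size = 64, seed = 23)
  faces <- cohort_faces(coh)
  ids <- unique(faces$experiment_id)
  tr <- faces[faces$experiment_id %in% ids[1:3], ]
  va <- faces[faces$experiment_id %in% ids[4], ]
  cfg <- train_config("tiny", image_size = 64, min_epochs = 6, seed = 3)
  fit <- train_unet(tr, va, cfg)
  h <- fit$history
  expect_equal(nrow(h), 6)
  expect_lt(h$loss[fit$best_epoch], h$loss[1])
  expect_gte(fit$best_val_dsc, max(h$val_dsc) - 1e-12)  # best-selection contract
  expect_equal(fit$best_val_dsc, h$val_dsc[fit$best_epoch])
  # errors: empty sets and leakage are rejected
  expect_error(train_unet(tr[0, ], va, cfg), "non-empty")
  expect_error(train_unet(tr, tr, cfg), "share experiments")
  # reproducibility of the full run under a fixed seed
  fit2 <- train_unet(tr, va, cfg)
  expect_identical(fit$model$par, fit2$model$par)
  expect_identical(fit$history, fit2$history)
})

test_that("cross-validation pools out-of-fold predictions without leakage", {
  coh <- tiny_cohort(n = 4, size = 64, seed = 23)
  faces <- cohort_faces(coh)
  folds <- make_folds(unique(faces$experiment_id), k = 2, seed = 1)
  cfg <- train_config("tiny", image_size = 64, min_epochs = 2, seed = 3)
  cv <- cross_validate(faces, folds, cfg)
  expect_length(cv$models, 2)
  expect_setequal(unique(cv$predictions$experiment_id), unique(faces$experiment_id))
  expect_equal(nrow(cv$predictions), nrow(faces))       # each face exactly once
  for (f in 1:2) {
    predicted <- unique(cv$predictions$experiment_id[cv$predictions$fold == f])
    expect_length(intersect(predicted, folds$train_ids[[f]]), 0)
  }
})
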