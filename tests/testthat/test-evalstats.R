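test_that("Dice coefficient matches hand counts and empty-set conventions", {
  m <- matrix(0L, 4, 4)
  p <- m; g <- m
  p[1, 1:4] <- 3L; g[1, 3:4] <- 3L; g[2, 1:2] <- 3L   # 4 vs 4 px, overlap 2
  expect_equal(dsc(p, g, 3), 0.5)
  expect_equal(dsc(p, p, 3), 1)
  expect_equal(dsc(p, g, 4), 1)                       # absent from both
  expect_equal(dsc(p, matrix(4L, 4, 4), 4), 0)        # absent from one
  disj <- matrix(0L, 4, 4); disj[4, ] <- 3L
  expect_equal(dsc(p, disj, 3), 0)
  expect_error(dsc(p, matrix(0L, 3, 3), 3), "shape mismatch")
})

test_that("accuracy is one-vs-rest with true negatives; weighting by share", {
  p <- matrix(0L, 2, 5); g <- matrix(0L, 2, 5)
  g[1, 1] <- 3L          # false negative for class 3
  p[2, 5] <- 3L          # false positive
  expect_equal(acc(p, g, 3), 0.8)                     # (10 - 2) / 10
  expect_equal(acc(g, g, 3), 1)
  expect_equal(weighted_acc(g, g), 1)
  withr::with_seed(3, {
    pr <- random_mask(7, 9); gr <- random_mask(7, 9)
  })
  accs <- vapply(0:4, function(k) acc(pr, gr, k), numeric(1))
  expect_gte(weighted_acc(pr, gr), min(accs))
  expect_lte(weighted_acc(pr, gr), max(accs))
})

test_that("boundary F1 matches the exhaustive oracle on a shifted square", {
  g <- matrix(0L, 8, 8); g[3:6, 3:6] <- 3L
  p <- matrix(0L, 8, 8); p[3:6, 4:7] <- 3L            # shifted 1 px right
  for (tol in c(0, 1, 2)) {
    expect_equal(boundary_f1(p, g, 3, tol), oracle_bf1(p, g, 3, tol))
  }
  expect_equal(boundary_f1(p, p, 3, 0), 1)
  expect_equal(boundary_f1(p, g, 4, 2), 1)            # absent from both
  expect_equal(boundary_f1(g, matrix(0L, 8, 8), 3, 2), 0)
})

test_that("average precision reproduces ranking enumeration and tie handling", {
  expect_equal(average_precision(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2, tolerance = 1e-12)    # 0.8333
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  # uniform scores: one tie group, AP = prevalence
  expect_equal(average_precision(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_warning(ap0 <- average_precision(runif(5), rep(0, 5)), "no positive")
  expect_true(is.na(ap0))
  expect_equal(mean_ap(c(0.5, NA, 1)), 0.75)
})

test_that("metrics report is exact on self-comparison and matches schema", {
  withr::with_seed(4, {
    masks <- lapply(1:3, function(i) random_mask(12, 12))
  })
  rep_self <- metrics_report(masks, masks)
  expect_equal(nrow(rep_self), 6)
  expect_equal(rep_self$area[6], "overall")
  expect_true(all(unlist(rep_self[c("dsc", "acc", "bf1")]) == 1))
  expect_true(all(rep_self$ap == 1))
  expect_error(metrics_report(list(), list()), "empty")
})

test_that("metrics report equals per-image brute-force oracles", {
  withr::with_seed(5, {
    preds <- lapply(1:3, function(i) random_mask(10, 10))
    gts <- lapply(1:3, function(i) random_mask(10, 10))
    probs <- lapply(1:3, function(i) random_probs(10, 10))
  })
  got <- metrics_report(preds, gts, probs, tolerance_px = 1)
  for (k in 0:4) {
    expect_equal(got$dsc[k + 1],
                 mean(mapply(function(p, g) oracle_dsc(p, g, k), preds, gts)),
                 tolerance = 1e-9)
    expect_equal(got$acc[k + 1],
                 mean(mapply(function(p, g) oracle_acc(p, g, k), preds, gts)),
                 tolerance = 1e-9)
    expect_equal(got$bf1[k + 1],
                 mean(mapply(function(p, g) oracle_bf1(p, g, k, 1), preds, gts)),
                 tolerance = 1e-9)
    sc <- unlist(lapply(probs, function(p) as.vector(p[, , k + 1])))
    lb <- unlist(lapply(gts, function(g) as.vector(g == k)))
    expect_equal(got$ap[k + 1], oracle_ap(sc, lb), tolerance = 1e-9)
  }
  expect_equal(got$dsc[6], mean(got$dsc[1:5]), tolerance = 1e-12)
  expect_equal(got$ap[6], mean(got$ap[1:5]), tolerance = 1e-12)
  expect_equal(got$acc[6],
               mean(mapply(oracle_weighted_acc, preds, gts)), tolerance = 1e-9)
})

test_that("regression and correlation match closed forms", {
  r <- pearson_linreg(c(0, 1, 2), c(1, 3, 5))
  expect_equal(r$slope, 2); expect_equal(r$intercept, 1); expect_equal(r$r, 1)
  x <- c(1, 2, 3, 4)
  self <- pearson_linreg(x, x)
  expect_equal(unlist(self[c("r", "slope", "intercept")]),
               c(r = 1, slope = 1, intercept = 0))
  expect_error(pearson_linreg(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_linreg(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman limits are bias +/- 1.96 sample SD", {
  ba <- bland_altman(c(2, 4, 6), c(1, 2, 3))        # differences 1, 2, 3
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  same <- bland_altman(1:5, 1:5)
  expect_equal(unlist(same[c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))
  withr::with_seed(6, {
    a <- rnorm(200); b <- rnorm(200)
  })
  r <- bland_altman(a, b)
  expect_equal(r$loa_high - r$bias, 1.96 * sd(a - b))
  # limits contain about 95% of differences for normal data
  d <- a - b
  expect_gte(mean(d >= r$loa_low & d <= r$loa_high), 0.93)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("ANCOVA-vs-identity rejects shifted data and accepts identity", {
  x <- seq(0, 50, length.out = 50)
  expect_equal(ancova_identity(x, x)$p, 1)
  withr::with_seed(7, {
    y_shift <- x + 10 + rnorm(50, 0, 1)
    y_id <- x + rnorm(50, 0, 1)
  })
  expect_lt(ancova_identity(x, y_shift)$p, 0.05)
  expect_gt(ancova_identity(x, y_id)$p, 0.05)
  expect_error(ancova_identity(rep(1, 10), 1:10), "degenerate")
  expect_error(ancova_identity(1:3, 1:3), "at least 4")
})

test_that("KS normality check behaves on normal and bimodal samples", {
  withr::with_seed(8, {
    normal <- rnorm(200)
    bimodal <- c(rnorm(100, -3, 0.3), rnorm(100, 3, 0.3))
  })
  kn <- ks_normality(normal)
  expect_gt(kn$p, 0.05)
  expect_gte(kn$statistic, 0); expect_lte(kn$statistic, 1)
  expect_lt(ks_normality(bimodal)$p, 0.05)
  expect_error(ks_normality(rep(2, 10)), "constant")
  expect_error(ks_normality(1:3), "at least 5")
})

test_that("agreement report combines the statistics per subgroup", {
  withr::with_seed(9, {
    d <- tibble::tibble(
      ann = runif(40, 0, 60),
      grp = rep(c("IR", "IR_protected"), each = 20)
    )
    d$pred <- d$ann + rnorm(40, 0, 2)
  })
  rep <- agreement_report(d, "pred", "ann", group = "grp")
  expect_setequal(rep$subset, c("all", "IR", "IR_protected"))
  all_row <- rep[rep$subset == "all", ]
  expect_gt(all_row$r, 0.9)
  expect_true(all_row$loa_low <= all_row$bias & all_row$bias <= all_row$loa_high)
  pl <- pearson_linreg(d$pred, d$ann); ba <- bland_altman(d$pred, d$ann)
  expect_equal(all_row$r, pl$r)
  expect_equal(all_row$bias, ba$bias)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
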