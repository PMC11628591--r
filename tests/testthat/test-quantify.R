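lv_areas <- function(inf, aar_ni, rem, rv = 0, remaining = 0) {
  c(remaining = remaining, remote = rem, aar_non_infarcted = aar_ni,
    infarct = inf, right_ventricle = rv)
}

test_that("slice masses average the faces and normalize to slice mass", {
  a <- lv_areas(100, 100, 800)
  m <- slice_class_masses(a, a, mass_g = 10)
  expect_equal(unname(m[c("infarct", "aar_non_infarcted", "remote")]), c(1, 1, 8))
  # single imaged face falls back to that face's areas
  expect_equal(slice_class_masses(a, NULL, 10), m)
  # face averaging: (100+300)/2 = 200 of 1000
  m2 <- slice_class_masses(lv_areas(100, 100, 800), lv_areas(300, 100, 600), 10)
  expect_equal(unname(m2[["infarct"]]), 2)
  # RV and remaining areas receive no LV mass
  m3 <- slice_class_masses(lv_areas(100, 100, 800, rv = 5000, remaining = 9000),
                           NULL, 10)
  expect_equal(sum(m3), 10)
  expect_equal(m3, m)
  expect_equal(unname(slice_class_masses(lv_areas(0, 200, 800), NULL, 10)[["infarct"]]), 0)
  expect_error(slice_class_masses(NULL, NULL, 10), "no imaged cut face")
  expect_error(slice_class_masses(lv_areas(0, 0, 0), NULL, 10), "degenerate")
  expect_error(slice_class_masses(a, a, -1), "positive")
})

test_that("infarct size is the mass ratio of infarct to AAR over all slices", {
  s <- tibble::tibble(mass_g = c(10, 20), mass_infarct = c(1, 0),
                      mass_aar_ni = c(1, 4), mass_remote = c(8, 16))
  r <- infarct_size(s)
  expect_equal(r$is_pct_aar, 100 / 6)          # 1 / (1+1+4)
  expect_equal(r$aar_pct_lv, 100 * 6 / 30)
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$mass_lv_g, 30)
  # no infarct anywhere
  s0 <- dplyr::mutate(s, mass_infarct = 0)
  expect_equal(infarct_size(s0)$is_pct_aar, 0)
  # fully infarcted AAR
  s1 <- dplyr::mutate(s, mass_infarct = mass_infarct + mass_aar_ni, mass_aar_ni = 0)
  expect_equal(infarct_size(s1)$is_pct_aar, 100)
  expect_error(infarct_size(dplyr::mutate(s, mass_infarct = 0, mass_aar_ni = 0)),
               "area-at-risk mass is zero")
})

test_that("hand-constructed two-slice geometry gives IS = 16.67% of AAR", {
  # masses 10 g / 20 g; (infarct, AAR, remote) face fractions 0.1/0.1/0.8 and
  # 0/0.2/0.8 -> infarct 1 g, AAR (non-inf) 1 + 4 g -> 1/6 of AAR
  m1 <- slice_class_masses(lv_areas(100, 100, 800), lv_areas(100, 100, 800), 10)
  m2 <- slice_class_masses(lv_areas(0, 200, 800), lv_areas(0, 200, 800), 20)
  r <- infarct_size(tibble::tibble(
    mass_g = c(10, 20),
    mass_infarct = c(m1[["infarct"]], m2[["infarct"]]),
    mass_aar_ni = c(m1[["aar_non_infarcted"]], m2[["aar_non_infarcted"]]),
    mass_remote = c(m1[["remote"]], m2[["remote"]])
  ))
  expect_equal(r$is_pct_aar, 16.6667, tolerance = 1e-4)
})

test_that("quantification is invariant to pixel-area scale and conserves mass", {
  withr::with_seed(11, {
    base <- lapply(1:4, function(i) {
      list(ap = lv_areas(sample(50:200, 1), sample(100:300, 1), sample(500:900, 1)),
           ba = lv_areas(sample(50:200, 1), sample(100:300, 1), sample(500:900, 1)),
           mass = runif(1, 5, 30))
    })
  })
  build <- function(scale) {
    rows <- lapply(base, function(s) {
      m <- slice_class_masses(s$ap * scale, s$ba * scale, s$mass)
      tibble::tibble(mass_g = s$mass, mass_infarct = m[["infarct"]],
                     mass_aar_ni = m[["aar_non_infarcted"]],
                     mass_remote = m[["remote"]])
    })
    infarct_size(dplyr::bind_rows(rows))
  }
  r1 <- build(1); r7 <- build(7.3)
  expect_equal(r1$is_pct_aar, r7$is_pct_aar)
  expect_equal(r1$aar_pct_lv, r7$aar_pct_lv)
  # mass conservation: per-slice class masses sum to the slice mass
  expect_equal(sum(r1$slices$mass_infarct + r1$slices$mass_aar_ni +
                     r1$slices$mass_remote), sum(r1$slices$mass_g))
})

test_that("doubling a slice's mass doubles its contribution", {
  ap <- lv_areas(100, 100, 800)
  other <- lv_areas(0, 500, 500)
  one <- function(mass1) {
    m1 <- slice_class_masses(ap, ap, mass1)
    m2 <- slice_class_masses(other, other, 10)
    infarct_size(tibble::tibble(
      mass_g = c(mass1, 10),
      mass_infarct = c(m1[["infarct"]], m2[["infarct"]]),
      mass_aar_ni = c(m1[["aar_non_infarcted"]], m2[["aar_non_infarcted"]]),
      mass_remote = c(m1[["remote"]], m2[["remote"]])
    ))
  }
  r1 <- one(10); r2 <- one(20)
  expect_equal(r2$mass_infarct_g, 2 * r1$mass_infarct_g)
})

test_that("identical predicted and annotated masks give identical results", {
  coh <- tiny_cohort(n = 1, size = 96, seed = 21)
  ex <- coh$experiments[[1]]
  faces <- cohort_faces(coh)
  pm <- rlang::set_names(faces$mask, paste0(faces$slice_index, "_", faces$face))
  expect_equal(quantify_from_masks(ex, pm), quantify_from_masks(ex))
})

test_that("pixel-based quantification recovers generator truth at 256 px", {
  coh <- generate_cohort(phantom_config(n_experiments = 3, image_size = 256, seed = 31))
  for (ex in coh$experiments) {
    r <- quantify_from_masks(ex)
    tr <- true_is(coh, ex$experiment_id)
    expect_lt(abs(r$is_pct_aar - tr$true_is_pct_aar), 1)
    expect_lt(abs(r$aar_pct_lv - tr$true_aar_pct_lv), 1)
  }
})
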