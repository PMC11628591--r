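#' Run configuration for the end-to-end pipeline
#'
#' Bundles the phantom, training and evaluation settings for [run_all()].
#' Two execution profiles exist: `"tiny"` (96-px images, 20 epochs, the
#' desk-scale setting used by the test-suite) and `"paper"` (384-px images,
#' 300 epochs, batch 26 — the full-scale reference setting).
#'
#' @param profile `"tiny"` or `"paper"`.
#' @param phantom A [phantom_config()]; its `image_size` should match the
#'   training `image_size`.
#' @param train A [train_config()].
#' @param n_test Experiments held out as the test set.
#' @param k Cross-validation folds.
#' @param tolerance_px Boundary-F1 tolerance (pixels).
#' @param seed Master seed for splitting.
#' @param out_dir Optional directory; when set, [run_all()] writes JSON/CSV
#'   reports there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(profile = c("tiny", "paper"), phantom = NULL,
                       train = NULL, n_test = NULL, k = NULL,
                       tolerance_px = 2, seed = 1L, out_dir = NULL) {
  profile <- match.arg(profile)
  if (profile == "tiny") {
    phantom <- phantom %||% phantom_config(n_experiments = 24, image_size = 96,
                                           seed = seed)
    train <- train %||% train_config("tiny", seed = seed)
    n_test <- n_test %||% 6L
    k <- k %||% 3L
  } else {
    phantom <- phantom %||% phantom_config(n_experiments = 390, image_size = 384,
                                           seed = seed)
    train <- train %||% train_config("paper", seed = seed)
    n_test <- n_test %||% 170L
    k <- k %||% 5L
  }
  structure(list(profile = profile, phantom = phantom, train = train,
                 n_test = as.integer(n_test), k = as.integer(k),
                 tolerance_px = tolerance_px, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys `profile`, `n_test`, `k`, `tolerance_px`, `seed` plus
#' nested `phantom:` and `train:` blocks whose entries are passed to
#' [phantom_config()] and [train_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "tiny"
  phantom <- if (!is.null(y$phantom)) do.call(phantom_config, y$phantom) else NULL
  train <- if (!is.null(y$train)) {
    do.call(train_config, c(list(profile = profile), y$train))
  } else NULL
  run_config(profile = profile, phantom = phantom, train = train,
             n_test = y$n_test, k = y$k,
             tolerance_px = y$tolerance_px %||% 2,
             seed = y$seed %||% 1L, out_dir = y$out_dir)
}

#' Quantify every experiment of a cohort from annotation and predicted masks
#'
#' @param cohort A `phantom_cohort`.
#' @param predictions Prediction tibble (from [cross_validate()] or
#'   [predict_experiments()]): columns `experiment_id`, `slice_index`,
#'   `face`, list-column `pred_mask`.
#' @return Tibble with one row per predicted experiment: annotation-derived
#'   and prediction-derived IS (% of AAR) and AAR (% of LV), plus the
#'   generator truth and group.
#' @export
quantify_cohort <- function(cohort, predictions) {
  ids <- unique(predictions$experiment_id)
  purrr::map_dfr(ids, function(eid) {
    ex <- cohort$experiments[[eid]]
    pr <- predictions[predictions$experiment_id == eid, ]
    pm <- rlang::set_names(pr$pred_mask, paste0(pr$slice_index, "_", pr$face))
    ann <- quantify_from_masks(ex)
    pred <- quantify_from_masks(ex, pm)
    tr <- true_is(cohort, eid)
    tibble::tibble(
      experiment_id = eid, group = ex$group,
      is_annotation = ann$is_pct_aar, is_prediction = pred$is_pct_aar,
      aar_annotation = ann$aar_pct_lv, aar_prediction = pred$aar_pct_lv,
      is_true = tr$true_is_pct_aar, aar_true = tr$true_aar_pct_lv
    )
  })
}

#' Predict all faces of a set of experiments with one model
#'
#' @param model A trained `unet_model` (or `trained_unet`).
#' @param faces Faces tibble with list-column `image`.
#' @return `faces` with list-columns `prob` and `pred_mask` added.
#' @export
predict_experiments <- function(model, faces) {
  if (inherits(model, "trained_unet")) model <- model$model
  faces |>
    dplyr::mutate(prob = purrr::map(image, ~ predict(model, .x)),
                  pred_mask = purrr::map(prob, maps_to_mask))
}

#' Run the complete phantom-to-report pipeline
#'
#' Generates a phantom cohort, splits it by experiment into test and
#' cross-validation sets, assesses resize quality, trains one segmentation
#' model per fold, pools out-of-fold predictions, quantifies infarct size
#' from annotations and predictions through the identical code path,
#' computes the segmentation metric table and the method-agreement report
#' (overall and per subgroup), and finally applies the first fold's model to
#' the held-out test set. Every artifact is stamped with the seed and a hash
#' of the configuration.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return A list of class `run_report`: `cohort`, `split`, `folds`,
#'   `quality` ([quality_report()]), `cv` ([cross_validate()]),
#'   `is_table` / `is_table_test` ([quantify_cohort()]), `metrics` /
#'   `metrics_test` ([metrics_report()]), `agreement` / `agreement_test`
#'   ([agreement_report()]), `config_hash`, `seed`.
#' @export
run_all <- function(config = run_config("tiny"), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                                stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg_hash <- substr(rlang::hash(config[setdiff(names(config), "out_dir")]), 1, 12)
  say("generate", "cohort of %d experiments (%d px, seed %d)",
      config$phantom$n_experiments, config$phantom$image_size, config$phantom$seed)
  cohort <- stage("generate", generate_cohort(config$phantom))
  faces <- cohort_faces(cohort)
  ids <- unique(faces$experiment_id)
  say("split", "%d experiments -> %d test / %d cv; %d folds",
      length(ids), config$n_test, length(ids) - config$n_test, config$k)
  split <- stage("split", split_experiments(ids, config$n_test, seed = config$seed))
  folds <- stage("split", make_folds(split$cv_ids, k = config$k, seed = config$seed))
  say("preprocess", "resize-quality assessment at %d px", config$train$image_size)
  quality <- stage("preprocess", {
    qset <- faces$image[seq_len(min(20, nrow(faces)))]
    quality_report(qset, config$train$image_size)
  })
  cv_faces <- faces[faces$experiment_id %in% split$cv_ids, ]
  say("train", "cross-validating %d experiments (%d faces)",
      length(split$cv_ids), nrow(cv_faces))
  cv <- stage("train", cross_validate(cv_faces, folds, config$train, quiet = quiet))
  say("quantify", "infarct size from annotations and out-of-fold predictions")
  is_table <- stage("quantify", quantify_cohort(cohort, cv$predictions))
  say("evaluate", "segmentation metrics and agreement statistics")
  metrics <- stage("evaluate", metrics_report(
    cv$predictions$pred_mask, cv$predictions$mask, cv$predictions$prob,
    tolerance_px = config$tolerance_px))
  agreement <- stage("evaluate", agreement_report(
    is_table, "is_prediction", "is_annotation", group = "group"))
  # held-out test set, predicted with the first fold's model
  test_faces <- faces[faces$experiment_id %in% split$test_ids, ]
  say("test", "predicting %d held-out experiments", length(split$test_ids))
  test_pred <- stage("test", predict_experiments(cv$models[[1]], test_faces))
  is_table_test <- stage("test", quantify_cohort(cohort, test_pred))
  metrics_test <- stage("test", metrics_report(
    test_pred$pred_mask, test_pred$mask, test_pred$prob,
    tolerance_px = config$tolerance_px))
  agreement_test <- stage("test", agreement_report(
    is_table_test, "is_prediction", "is_annotation", group = "group"))
  report <- structure(list(
    cohort = cohort, split = split, folds = folds, quality = quality,
    cv = cv, is_table = is_table, metrics = metrics, agreement = agreement,
    is_table_test = is_table_test, metrics_test = metrics_test,
    agreement_test = agreement_test,
    config = config, config_hash = cfg_hash, seed = config$seed
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline report [%s profile, seed %d, config %s]\n",
              x$config$profile, x$seed, x$config_hash))
  cat(sprintf("  cv: %d experiments, overall DSC %.3f; IS agreement r = %.3f, bias %.2f%% AAR\n",
              length(x$split$cv_ids),
              x$metrics$dsc[x$metrics$area == "overall"],
              x$agreement$r[1], x$agreement$bias[1]))
  cat(sprintf("  test: %d experiments, overall DSC %.3f; IS agreement r = %.3f, bias %.2f%% AAR\n",
              length(x$split$test_ids),
              x$metrics_test$dsc[x$metrics_test$area == "overall"],
              x$agreement_test$r[1], x$agreement_test$bias[1]))
  invisible(x)
}

#' Write a pipeline report to disk as JSON and CSV
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(profile = report$config$profile, seed = report$seed,
               config_hash = report$config_hash,
               generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  utils::write.csv(report$metrics, file.path(dir, "metrics_cv.csv"), row.names = FALSE)
  utils::write.csv(report$metrics_test, file.path(dir, "metrics_test.csv"), row.names = FALSE)
  utils::write.csv(report$is_table, file.path(dir, "is_cv.csv"), row.names = FALSE)
  utils::write.csv(report$is_table_test, file.path(dir, "is_test.csv"), row.names = FALSE)
  history <- purrr::imap_dfr(report$cv$models, ~ dplyr::mutate(.x$history, fold = .y))
  utils::write.csv(history, file.path(dir, "training_history.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    meta = meta,
    quality = attr(report$quality, "summary"),
    metrics_cv = report$metrics,
    metrics_test = report$metrics_test,
    agreement_cv = as.data.frame(report$agreement),
    agreement_test = as.data.frame(report$agreement_test)
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
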