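#' The five-class tissue labelling scheme
#'
#' Every mask in the package is an integer matrix over five classes:
#' 0 = remaining (background, lumina, epicardial projection), 1 = remote
#' myocardium, 2 = non-infarcted area at risk (AAR), 3 = infarct,
#' 4 = right ventricle. The indices are stable across the whole package;
#' the display palette is the one used for rendering phantoms and plotting.
#'
#' @return A tibble with columns `class` (integer index), `name`, and
#'   `r`, `g`, `b` (display colour, 0-255).
#' @export
#' @examples
#' class_scheme()
class_scheme <- function() {
  tibble::tibble(
    class = 0:4,
    name  = c("remaining", "remote", "aar_non_infarcted", "infarct", "right_ventricle"),
    r = c(0L, 142L, 225L, 242L, 168L),
    g = c(0L,  46L, 120L, 236L,  66L),
    b = c(0L,  40L, 108L, 205L,  58L)
  )
}

n_classes <- function() 5L

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    stop(sprintf("`%s` must be an integer matrix", arg), call. = FALSE)
  }
  bad <- setdiff(unique(as.integer(mask)), 0:4)
  if (length(bad) > 0) {
    stop(sprintf("`%s` contains class indices outside 0..4: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(mask)
}

#' Write / read a label mask as an 8-bit PNG
#'
#' Masks are stored as single-channel 8-bit PNG files whose pixel value IS
#' the class index (0-4), giving a lossless round-trip. On read, any pixel
#' value outside the five-class scheme raises a format error.
#'
#' @param mask Integer matrix with values in 0..4.
#' @param path File path to write to / read from.
#' @return `read_mask` returns the integer matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  if (!nzchar(path)) stop("empty path", call. = FALSE)
  png::writePNG(matrix(as.integer(mask) / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("cannot read mask: no such file '%s'", path), call. = FALSE)
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  m <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  bad <- setdiff(unique(as.vector(m)), 0:4)
  if (length(bad) > 0) {
    stop(sprintf("mask file '%s' contains class indices outside 0..4: %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  m
}

#' Per-class pixel areas of a label mask
#'
#' Counts pixels per class. The five counts always sum to the number of
#' pixels in the mask.
#'
#' @param mask Integer matrix with values in 0..4.
#' @return Named integer vector of length 5 (names from [class_scheme()]),
#'   in class-index order.
#' @export
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1:3] <- 3L
#' areas_from_mask(m)
areas_from_mask <- function(mask) {
  assert_mask(mask)
  counts <- tabulate(as.integer(mask) + 1L, nbins = n_classes())
  names(counts) <- class_scheme()$name
  counts
}

#' Area table for a set of labelled faces
#'
#' Tidy long-format planimetry table: one row per (experiment, slice, face,
#' class) with the pixel area of that class on that face.
#'
#' @param faces A tibble/data frame with columns `experiment_id`,
#'   `slice_index`, `face` and a list-column `mask` of label masks.
#' @return A tibble with columns `experiment_id`, `slice_index`, `face`,
#'   `class`, `name`, `pixel_area`.
#' @export
area_table <- function(faces) {
  stopifnot(is.data.frame(faces), all(c("experiment_id", "slice_index", "face", "mask") %in% names(faces)))
  scheme <- class_scheme()
  purrr::pmap_dfr(
    faces[c("experiment_id", "slice_index", "face", "mask")],
    function(experiment_id, slice_index, face, mask) {
      a <- areas_from_mask(mask)
      tibble::tibble(
        experiment_id = experiment_id, slice_index = slice_index, face = face,
        class = scheme$class, name = scheme$name, pixel_area = as.integer(a)
      )
    }
  )
}

#' Split experiments into test and cross-validation sets
#'
#' Splitting is always by experiment, never by image, so no heart can
#' contribute faces to both sides (leakage control).
#'
#' @param ids Vector of experiment identifiers.
#' @param n_test Number of experiments in the held-out test set.
#' @param seed Integer seed; the same seed reproduces the split.
#' @return A list with elements `test_ids` and `cv_ids` (disjoint, covering
#'   `ids`).
#' @export
#' @examples
#' split_experiments(sprintf("e%03d", 1:390), n_test = 170, seed = 1)$cv_ids |> length()
split_experiments <- function(ids, n_test, seed = 1L) {
  ids <- unique(ids)
  if (n_test >= length(ids)) {
    stop(sprintf("n_test (%d) must be smaller than the number of experiments (%d)",
                 n_test, length(ids)), call. = FALSE)
  }
  if (n_test < 1) stop("n_test must be at least 1", call. = FALSE)
  test <- withr::with_seed(as.integer(seed), sample(ids, n_test))
  list(test_ids = sort(test), cv_ids = sort(setdiff(ids, test)))
}

#' k-fold cross-validation folds over experiments
#'
#' Validation sets partition `cv_ids`; each fold trains on the remaining
#' (k-1)/k share. With `k = 5` this is the classical 80/20 fivefold layout.
#'
#' @param cv_ids Experiment identifiers of the cross-validation set.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A tibble with one row per fold and list-columns `train_ids`,
#'   `val_ids`.
#' @export
make_folds <- function(cv_ids, k = 5L, seed = 1L) {
  cv_ids <- unique(cv_ids)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > length(cv_ids)) {
    stop(sprintf("k (%d) exceeds the number of experiments (%d)", k, length(cv_ids)),
         call. = FALSE)
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(cv_ids))
  # rep_len assigns folds as evenly as possible (sizes differ by at most 1)
  fold_of <- rep_len(seq_len(k), length(cv_ids))
  tibble::tibble(
    fold = seq_len(k),
    val_ids = purrr::map(seq_len(k), ~ sort(shuffled[fold_of == .x])),
    train_ids = purrr::map(seq_len(k), ~ sort(shuffled[fold_of != .x]))
  )
}
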