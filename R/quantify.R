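#' Per-class left-ventricular masses of one heart slice
#'
#' Converts per-face pixel areas plus the weighed slice mass into tissue
#' masses. The apical and basal areas of each left-ventricular class
#' (infarct, non-infarcted AAR, remote) are averaged over the available cut
#' faces and normalized to the slice mass:
#' \deqn{m_c = m_{slice} \cdot \bar A_c / (\bar A_{inf} + \bar A_{aarNI} + \bar A_{rem})}
#' Right-ventricular and remaining areas receive no left-ventricular mass.
#' Mass normalization counteracts varying slice thicknesses: a thick slice
#' contributes in proportion to its weighed mass, not its face area.
#'
#' @param areas_apical,areas_basal Named numeric vectors of per-class pixel
#'   areas as returned by [areas_from_mask()]; either may be `NULL` when that
#'   face was not imaged (outermost surfaces are not cut faces).
#' @param mass_g Slice mass in grams (> 0).
#' @return Named numeric vector of masses in grams for
#'   `infarct`, `aar_non_infarcted`, `remote` (summing to `mass_g` times the
#'   LV share, which is `mass_g` itself under the LV-mass convention used
#'   here).
#' @export
#' @examples
#' a <- c(remaining = 0, remote = 800, aar_non_infarcted = 100,
#'        infarct = 100, right_ventricle = 0)
#' slice_class_masses(a, a, mass_g = 10)   # 1 g infarct, 1 g AAR, 8 g remote
slice_class_masses <- function(areas_apical, areas_basal, mass_g) {
  if (is.null(areas_apical) && is.null(areas_basal)) {
    stop("slice has no imaged cut face: both apical and basal areas are missing",
         call. = FALSE)
  }
  if (!is.numeric(mass_g) || length(mass_g) != 1L || !is.finite(mass_g) || mass_g <= 0) {
    stop("mass_g must be a single positive number", call. = FALSE)
  }
  lv <- c("infarct", "aar_non_infarcted", "remote")
  pick <- function(a) {
    if (is.null(a)) return(NULL)
    if (!all(lv %in% names(a))) stop("area vector lacks LV class names", call. = FALSE)
    a[lv]
  }
  faces <- purrr::compact(list(pick(areas_apical), pick(areas_basal)))
  abar <- purrr::reduce(faces, `+`) / length(faces)
  a_lv <- sum(abar)
  if (a_lv <= 0) {
    stop("degenerate slice: zero left-ventricular area on every imaged face",
         call. = FALSE)
  }
  mass_g * abar / a_lv
}

#' Experiment-level infarct size from per-slice class masses
#'
#' Sums the per-slice left-ventricular masses of infarcted and non-infarcted
#' AAR tissue over all slices of one heart and reports
#' IS = 100 * infarct mass / AAR mass (% of AAR) and
#' AAR = 100 * AAR mass / LV mass (% of LV).
#'
#' @param slices A data frame with one row per slice and columns `mass_g`,
#'   `mass_infarct`, `mass_aar_ni`, `mass_remote` (grams), e.g. built from
#'   [slice_class_masses()]. Extra columns are kept in the per-slice table.
#' @return An object of class `is_result`: list with scalar `is_pct_aar`,
#'   `aar_pct_lv`, total masses, and the per-slice tibble.
#' @export
#' @examples
#' s <- tibble::tibble(mass_g = c(10, 20), mass_infarct = c(1, 0),
#'                     mass_aar_ni = c(1, 4), mass_remote = c(8, 16))
#' infarct_size(s)$is_pct_aar   # 16.67% of AAR
infarct_size <- function(slices) {
  stopifnot(is.data.frame(slices),
            all(c("mass_g", "mass_infarct", "mass_aar_ni", "mass_remote") %in% names(slices)))
  if (nrow(slices) < 1) stop("need at least one slice", call. = FALSE)
  m_inf <- sum(slices$mass_infarct)
  m_aarni <- sum(slices$mass_aar_ni)
  m_rem <- sum(slices$mass_remote)
  m_aar <- m_inf + m_aarni
  m_lv <- m_aar + m_rem
  if (m_aar <= 0) {
    stop("undefined infarct size: total area-at-risk mass is zero", call. = FALSE)
  }
  structure(
    list(
      is_pct_aar = 100 * m_inf / m_aar,
      aar_pct_lv = 100 * m_aar / m_lv,
      mass_infarct_g = m_inf,
      mass_aar_g = m_aar,
      mass_lv_g = m_lv,
      slices = tibble::as_tibble(slices)
    ),
    class = "is_result"
  )
}

#' @export
print.is_result <- function(x, ...) {
  cat(sprintf("Infarct size: %.2f%% of AAR | AAR: %.2f%% of LV | LV mass: %.2f g (%d slices)\n",
              x$is_pct_aar, x$aar_pct_lv, x$mass_lv_g, nrow(x$slices)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-slice masses of an infarct-size result
#' @param x An `is_result`.
#' @param ... Unused.
#' @return The per-slice tibble of LV class masses.
#' @export
tidy.is_result <- function(x, ...) x$slices

#' One-row summary of an infarct-size result
#' @param x An `is_result`.
#' @param ... Unused.
#' @export
glance.is_result <- function(x, ...) {
  tibble::tibble(
    is_pct_aar = x$is_pct_aar, aar_pct_lv = x$aar_pct_lv,
    mass_infarct_g = x$mass_infarct_g, mass_aar_g = x$mass_aar_g,
    mass_lv_g = x$mass_lv_g, n_slices = nrow(x$slices)
  )
}

#' Quantify infarct size of one experiment from label masks
#'
#' Composes [areas_from_mask()], [slice_class_masses()] and [infarct_size()].
#' The identical code path serves hand annotations and model predictions, so
#' the two can be compared on equal footing. Slices whose outermost face was
#' not imaged fall back to the single available face.
#'
#' @param experiment An experiment record: list with `experiment_id` and
#'   `slices`, each slice a list with `slice_index`, `mass_g`, and optional
#'   `apical`/`basal` faces. See [generate_cohort()].
#' @param masks Optional named replacement masks, keyed
#'   `"<slice_index>_<face>"` (e.g. `"3_apical"`); faces without an entry use
#'   the mask stored on the record. Pass predicted masks here to quantify a
#'   model's output.
#' @return An `is_result` (see [infarct_size()]).
#' @export
quantify_from_masks <- function(experiment, masks = NULL) {
  stopifnot(is.list(experiment), !is.null(experiment$slices))
  rows <- purrr::map_dfr(experiment$slices, function(sl) {
    face_areas <- function(face) {
      key <- paste0(sl$slice_index, "_", face)
      m <- if (!is.null(masks) && !is.null(masks[[key]])) masks[[key]] else sl[[face]]$mask
      if (is.null(m)) return(NULL)
      areas_from_mask(m)
    }
    mm <- slice_class_masses(face_areas("apical"), face_areas("basal"), sl$mass_g)
    tibble::tibble(
      slice_index = sl$slice_index, mass_g = sl$mass_g,
      mass_infarct = mm[["infarct"]], mass_aar_ni = mm[["aar_non_infarcted"]],
      mass_remote = mm[["remote"]]
    )
  })
  infarct_size(rows)
}
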