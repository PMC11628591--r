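#' Configuration for the synthetic TTC-phantom generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults emulate a porcine ischemia/reperfusion cohort: 5-7 transverse
#' slices of 10-20 mm thickness per heart, an area at risk (AAR) spanning
#' 9-38% of the left ventricle and infarct sizes spanning 0-73% of the AAR,
#' with a protected (cardioprotection) subgroup drawn from a low-IS regime.
#' The `rat` profile switches to an isolated-perfused-rat-heart geometry:
#' 5-6 slices of about 2 mm, a much smaller ventricle, and optionally
#' degraded colour contrast (`degrade_contrast`) to emulate the weaker
#' staining contrast of that preparation.
#'
#' @param n_experiments Number of hearts to simulate.
#' @param protection_fraction Fraction of experiments drawn from the low-IS
#'   (protected) regime, in [0, 1].
#' @param slices_per_heart Integer range `c(lo, hi)` of slices per heart.
#' @param slice_thickness_mm Range of slice thickness in millimetres.
#' @param aar_lv_fraction Range of the AAR as a fraction of the LV.
#' @param is_aar_fraction Range of infarct size as a fraction of the AAR.
#' @param image_size Rendered image side length in pixels (>= 64).
#' @param palette Data frame with columns `class`, `r`, `g`, `b`, `jitter_sd`:
#'   mean colour and per-pixel noise SD per tissue class. Defaults to the
#'   TTC palette (brick-red remote, light-red non-infarcted AAR, white
#'   infarct, red-brown right ventricle, near-black background).
#' @param illumination_jitter Range of the per-image global illumination
#'   multiplier.
#' @param blur_sigma Range of the Gaussian blur SD (pixels) applied to the
#'   rendered image (never the mask).
#' @param species_profile `"pig"` or `"rat"`.
#' @param degrade_contrast If `TRUE`, pulls all tissue colours toward their
#'   mean, weakening class contrast (rat-profile option).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   cohort bit for bit.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(n_experiments = 10,
                           protection_fraction = 0.42,
                           slices_per_heart = c(5L, 7L),
                           slice_thickness_mm = c(10, 20),
                           aar_lv_fraction = c(0.09, 0.38),
                           is_aar_fraction = c(0, 0.73),
                           image_size = 384L,
                           palette = default_palette(),
                           illumination_jitter = c(0.92, 1.08),
                           blur_sigma = c(0.5, 1.2),
                           species_profile = c("pig", "rat"),
                           degrade_contrast = FALSE,
                           seed = 1L) {
  species_profile <- match.arg(species_profile)
  if (species_profile == "rat") {
    if (missing(slices_per_heart)) slices_per_heart <- c(5L, 6L)
    if (missing(slice_thickness_mm)) slice_thickness_mm <- c(1.5, 2.5)
  }
  if (n_experiments < 1) stop("invalid `n_experiments`: must be >= 1", call. = FALSE)
  if (protection_fraction < 0 || protection_fraction > 1) {
    stop("invalid `protection_fraction`: must lie in [0, 1]", call. = FALSE)
  }
  check_range(slices_per_heart, "slices_per_heart", lo = 1)
  check_range(slice_thickness_mm, "slice_thickness_mm", lo = 0)
  check_range(aar_lv_fraction, "aar_lv_fraction", lo = 0, hi = 1)
  check_range(is_aar_fraction, "is_aar_fraction", lo = 0, hi = 1)
  check_range(illumination_jitter, "illumination_jitter", lo = 0)
  check_range(blur_sigma, "blur_sigma", lo = 0)
  if (image_size < 64) stop("invalid `image_size`: must be >= 64", call. = FALSE)
  stopifnot(is.data.frame(palette),
            all(c("class", "r", "g", "b", "jitter_sd") %in% names(palette)),
            nrow(palette) == 5)
  structure(list(
    n_experiments = as.integer(n_experiments),
    protection_fraction = protection_fraction,
    slices_per_heart = as.integer(slices_per_heart),
    slice_thickness_mm = slice_thickness_mm,
    aar_lv_fraction = aar_lv_fraction,
    is_aar_fraction = is_aar_fraction,
    image_size = as.integer(image_size),
    palette = tibble::as_tibble(palette),
    illumination_jitter = illumination_jitter,
    blur_sigma = blur_sigma,
    species_profile = species_profile,
    degrade_contrast = isTRUE(degrade_contrast),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_palette <- function() {
  tibble::tibble(
    class = 0:4,
    r = c(16, 142, 225, 242, 168),
    g = c(16, 46, 120, 236, 66),
    b = c(18, 40, 108, 205, 58),
    jitter_sd = c(4, 9, 10, 7, 9)
  )
}

# --- continuous slice-face geometry ------------------------------------------
#
# One cut face is a perturbed annulus (the LV wall) between radii
# r_in(theta) and r_out(theta), each a Fourier-perturbed circle. The AAR is
# the angular sector of the annulus centred at `theta_aar` whose continuous
# area is exactly `aar_frac` of the LV area; the infarct is a transmural
# (endocardium-outward, relative depth `transmurality`) sub-sector of the AAR
# whose area is exactly `inf_frac` of the AAR. The right ventricle is a
# tapered crescent appended outside the wall opposite the AAR. Lumen and
# background are "remaining". Sector half-spans are solved numerically on a
# fine angular grid so that the continuous class areas hit the requested
# fractions; the rasterizer then applies the same inequalities to pixel
# centres, so pixel counts differ from the continuous truth only by
# rasterization error.

face_geometry <- function(image_size, radius_frac, wall_frac, aar_frac,
                          inf_frac, theta_aar, fourier_out, fourier_in,
                          center_jitter = c(0, 0), rv_span = 2.2,
                          rv_width_frac = 0.45, n_grid = 4096L) {
  list(image_size = as.integer(image_size), radius_frac = radius_frac,
       wall_frac = wall_frac, aar_frac = aar_frac, inf_frac = inf_frac,
       theta_aar = theta_aar, fourier_out = fourier_out,
       fourier_in = fourier_in, center_jitter = center_jitter,
       rv_span = rv_span, rv_width_frac = rv_width_frac,
       n_grid = as.integer(n_grid))
}

fourier_radius <- function(theta, base, coef) {
  # coef: list(amp = numeric k, phase = numeric k) for harmonics 2..(k+1)
  r <- rep(base, length(theta))
  if (length(coef$amp)) {
    for (j in seq_along(coef$amp)) {
      r <- r + base * coef$amp[j] * cos((j + 1) * theta + coef$phase[j])
    }
  }
  r
}

# half-span delta so that the integral of `w` over |theta - center| <= delta
# equals `target` (w tabulated on the full-circle grid `theta`)
solve_halfspan <- function(theta, w, center, target) {
  if (target <= 0) return(0)
  d <- abs(((theta - center + pi) %% (2 * pi)) - pi)
  o <- order(d)
  cw <- cumsum(w[o])
  if (target >= cw[length(cw)]) return(pi)
  i <- which(cw >= target)[1]
  d[o][i]
}

# continuous class areas and rendering parameters for one face
face_solve <- function(geom) {
  S <- geom$image_size
  R <- geom$radius_frac * S
  r_in_base <- R * geom$wall_frac
  M <- geom$n_grid
  theta <- 2 * pi * (seq_len(M) - 0.5) / M
  dth <- 2 * pi / M
  r_out <- fourier_radius(theta, R, geom$fourier_out)
  r_in <- pmin(fourier_radius(theta, r_in_base, geom$fourier_in), 0.95 * r_out)
  w_ann <- (r_out^2 - r_in^2) / 2 * dth          # annulus area element
  a_lv <- sum(w_ann)
  # AAR: angular sector with exact area fraction
  d_aar <- solve_halfspan(theta, w_ann, geom$theta_aar, geom$aar_frac * a_lv)
  a_aar <- geom$aar_frac * a_lv
  # infarct: transmural sub-sector, area element rho * w_ann inside the AAR
  rho <- clamp(max(geom$inf_frac, 0.45 + 0.7 * geom$inf_frac), 0, 1)
  in_aar <- abs(((theta - geom$theta_aar + pi) %% (2 * pi)) - pi) <= d_aar
  w_inf <- ifelse(in_aar, rho * w_ann, 0)
  d_inf <- solve_halfspan(theta, w_inf, geom$theta_aar, geom$inf_frac * a_aar)
  a_inf <- geom$inf_frac * a_aar
  # RV crescent opposite the AAR, cosine-tapered width
  theta_rv <- geom$theta_aar + pi
  d_rv <- abs(((theta - theta_rv + pi) %% (2 * pi)) - pi)
  w0 <- geom$rv_width_frac * (R - r_in_base)
  rv_w <- ifelse(d_rv <= geom$rv_span / 2,
                 w0 * cos(pi * d_rv / geom$rv_span), 0)
  a_rv <- sum(((r_out + rv_w)^2 - r_out^2) / 2 * dth)
  list(R = R, r_in_base = r_in_base, theta = theta, d_aar = d_aar,
       d_inf = d_inf, rho = rho, theta_rv = theta_rv, rv_w0 = w0,
       areas = c(a_lv = a_lv, a_aar = a_aar, a_inf = a_inf, a_rv = a_rv))
}

#' Render one slice-face phantom image and its ground-truth mask
#'
#' Rasterizes the continuous face geometry (perturbed LV annulus, AAR
#' sector, transmural infarct, RV crescent) into a label mask and paints it
#' with the TTC palette plus per-pixel colour jitter, a global illumination
#' multiplier and Gaussian blur (image only). Uses the current R random
#' stream; seed it for reproducibility.
#'
#' @param geom Face geometry from the generator (see [generate_cohort()]);
#'   a list with the LV radius/wall fractions, exact AAR and infarct
#'   fractions and perturbation coefficients.
#' @param palette Palette tibble as in [phantom_config()].
#' @param illumination Scalar illumination multiplier.
#' @param blur_sigma Gaussian blur SD in pixels (0 = none).
#' @param degrade_contrast Pull tissue colours toward their mean.
#' @return A list with `image` (S x S x 3 array, 0-255), `mask` (S x S
#'   integer matrix, classes 0-4) and `areas` (named continuous areas in
#'   px^2: `a_lv`, `a_aar`, `a_inf`, `a_rv`).
#' @export
render_slice_face <- function(geom, palette = default_palette(),
                              illumination = 1, blur_sigma = 0,
                              degrade_contrast = FALSE) {
  S <- geom$image_size
  if (S < 64) stop("image_size must be >= 64", call. = FALSE)
  sol <- face_solve(geom)
  if (sol$areas[["a_lv"]] <= 0) stop("degenerate geometry: zero LV area", call. = FALSE)
  cx <- S / 2 + geom$center_jitter[1] * S
  cy <- S / 2 + geom$center_jitter[2] * S
  xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S) - cx   # column coord
  ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S) - cy  # row coord
  r <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs) %% (2 * pi)
  r_out <- fourier_radius(th, sol$R, geom$fourier_out)
  r_in <- pmin(fourier_radius(th, sol$r_in_base, geom$fourier_in), 0.95 * r_out)
  d_aar <- abs(((th - geom$theta_aar + pi) %% (2 * pi)) - pi)
  d_rv <- abs(((th - sol$theta_rv + pi) %% (2 * pi)) - pi)
  r_m <- sqrt(r_in^2 + sol$rho * (r_out^2 - r_in^2))   # transmural depth
  rv_w <- ifelse(d_rv <= geom$rv_span / 2,
                 sol$rv_w0 * cos(pi * d_rv / geom$rv_span), 0)
  mask <- matrix(0L, S, S)
  wall <- r >= r_in & r <= r_out
  mask[wall] <- 1L
  mask[wall & d_aar <= sol$d_aar] <- 2L
  mask[wall & d_aar <= sol$d_inf & r <= r_m] <- 3L
  mask[!wall & r > r_out & r <= r_out + rv_w] <- 4L
  # paint
  pal <- as.matrix(palette[order(palette$class), c("r", "g", "b")])
  jit <- palette$jitter_sd[order(palette$class)]
  if (isTRUE(degrade_contrast)) {
    mu <- colMeans(pal[2:5, , drop = FALSE])
    pal[2:5, ] <- sweep(0.45 * pal[2:5, , drop = FALSE], 2, 0.55 * mu, `+`)
  }
  idx <- as.integer(mask) + 1L
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    base <- pal[idx, ch] + stats::rnorm(S * S, 0, jit[idx])
    img[, , ch] <- matrix(base, S, S) * illumination
  }
  if (blur_sigma > 0) {
    img <- as.array(EBImage::gblur(img, sigma = blur_sigma))
  }
  img <- clamp(img, 0, 255)
  list(image = img, mask = mask, areas = sol$areas)
}

#' Generate a synthetic TTC-phantom cohort with known ground truth
#'
#' Simulates `n_experiments` hearts. Each heart gets a slice count, per-slice
#' thickness and mass, and per-slice apical/basal face geometries sharing
#' slice parameters with small independent perturbations (realistic
#' within-slice disagreement). Only cut surfaces are imaged: the outermost
#' apical face of slice 1 and the outermost basal face of the last slice are
#' not rendered, so a heart with n slices yields 2n - 2 face images. Slice
#' mass is a tissue-density constant times thickness times the mean physical
#' LV+RV area of the two faces, so mass normalization in the quantification
#' is exercised non-trivially. The protected subgroup draws its infarct-size
#' target from a low-IS regime.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom_cohort` with elements
#'   \describe{
#'     \item{experiments}{list of experiment records: `experiment_id`,
#'       `group`, `slices` (each with `slice_index`, `mass_g`, and imaged
#'       faces `apical`/`basal` holding `image` + `mask`).}
#'     \item{truth}{tibble of generator ground truth per experiment:
#'       `true_is_pct_aar`, `true_aar_pct_lv`, computed from the continuous
#'       face geometry through the same mass-normalized formula as the
#'       pixel-based quantification.}
#'     \item{faces}{tibble of per-face continuous class areas (px^2) and an
#'       `imaged` flag.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(phantom_config(n_experiments = 2, image_size = 96, seed = 7))
#' length(coh$experiments)
#' coh$truth
#' }
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_experiments
  n_protected <- round(cfg$protection_fraction * n)
  groups <- sample(c(rep("IR_protected", n_protected), rep("IR", n - n_protected)))
  is_lo <- cfg$is_aar_fraction[1]; is_hi <- cfg$is_aar_fraction[2]
  density_g_mm3 <- 1.05e-3
  radius_mm_range <- if (cfg$species_profile == "rat") c(5.5, 7.5) else c(25, 35)
  experiments <- vector("list", n)
  truth_rows <- faces_rows <- list()
  for (e in seq_len(n)) {
    eid <- sprintf("exp%03d", e)
    group <- groups[e]
    n_slices <- sample(seq(cfg$slices_per_heart[1], cfg$slices_per_heart[2]), 1)
    # experiment-level targets; protected regime skews infarct size low
    beta_draw <- if (group == "IR_protected") stats::rbeta(1, 1.2, 3.2) else stats::rbeta(1, 2.8, 1.8)
    is_t <- is_lo + (is_hi - is_lo) * beta_draw
    aar_t <- runif_range(1, cfg$aar_lv_fraction)
    radius_mm <- runif_range(1, radius_mm_range)
    radius_frac <- stats::runif(1, 0.30, 0.36)
    mm_per_px <- radius_mm / (radius_frac * cfg$image_size)
    wall_frac <- stats::runif(1, 0.45, 0.58)
    theta_aar <- stats::runif(1, 0, 2 * pi)
    slices <- vector("list", n_slices)
    slice_truth <- list()
    for (s in seq_len(n_slices)) {
      thickness <- runif_range(1, cfg$slice_thickness_mm)
      # mid-ventricular slices are widest; apex (slice 1) narrowest
      size_scale <- 0.78 + 0.22 * sin(pi * (s - 0.25) / n_slices)
      aar_s <- clamp(aar_t + stats::rnorm(1, 0, 0.015), cfg$aar_lv_fraction[1], cfg$aar_lv_fraction[2])
      inf_s <- clamp(is_t + stats::rnorm(1, 0, 0.04), is_lo, is_hi)
      face_names <- c("apical", "basal")
      imaged <- c(s != 1L, s != n_slices)
      fg <- fa <- list()
      for (fi in 1:2) {
        coef_out <- list(amp = stats::runif(3, -0.025, 0.025), phase = stats::runif(3, 0, 2 * pi))
        coef_in <- list(amp = stats::runif(3, -0.04, 0.04), phase = stats::runif(3, 0, 2 * pi))
        geom <- face_geometry(
          image_size = cfg$image_size,
          radius_frac = radius_frac * size_scale * stats::runif(1, 0.98, 1.02),
          wall_frac = clamp(wall_frac * stats::runif(1, 0.97, 1.03), 0.3, 0.8),
          aar_frac = clamp(aar_s + stats::rnorm(1, 0, 0.01), cfg$aar_lv_fraction[1], cfg$aar_lv_fraction[2]),
          inf_frac = clamp(inf_s + stats::rnorm(1, 0, 0.02), is_lo, is_hi),
          theta_aar = theta_aar + stats::rnorm(1, 0, 0.05),
          fourier_out = coef_out, fourier_in = coef_in,
          center_jitter = stats::runif(2, -0.03, 0.03)
        )
        fg[[fi]] <- geom
        fa[[fi]] <- face_solve(geom)$areas
      }
      # mass from the physical LV+RV area of both faces (imaged or not)
      area_mm2 <- vapply(fa, function(a) (a[["a_lv"]] + a[["a_rv"]]) * mm_per_px^2, numeric(1))
      mass_g <- density_g_mm3 * thickness * mean(area_mm2)
      slice <- list(slice_index = s, mass_g = mass_g, thickness_mm = thickness)
      for (fi in 1:2) {
        if (imaged[fi]) {
          rendered <- render_slice_face(
            fg[[fi]], palette = cfg$palette,
            illumination = runif_range(1, cfg$illumination_jitter),
            blur_sigma = runif_range(1, cfg$blur_sigma),
            degrade_contrast = cfg$degrade_contrast
          )
          slice[[face_names[fi]]] <- rendered[c("image", "mask")]
        }
        faces_rows[[length(faces_rows) + 1L]] <- tibble::tibble(
          experiment_id = eid, slice_index = s, face = face_names[fi],
          imaged = imaged[fi],
          a_lv = fa[[fi]][["a_lv"]], a_aar = fa[[fi]][["a_aar"]],
          a_inf = fa[[fi]][["a_inf"]], a_rv = fa[[fi]][["a_rv"]]
        )
      }
      # continuous-truth masses mirror slice_class_masses on imaged faces
      use <- fa[imaged]
      abar <- Reduce(`+`, use) / length(use)
      slice_truth[[s]] <- c(
        mass_g = mass_g,
        m_inf = mass_g * abar[["a_inf"]] / abar[["a_lv"]],
        m_aar = mass_g * abar[["a_aar"]] / abar[["a_lv"]]
      )
      slices[[s]] <- slice
    }
    st <- do.call(rbind, slice_truth)
    m_inf <- sum(st[, "m_inf"]); m_aar <- sum(st[, "m_aar"]); m_lv <- sum(st[, "mass_g"])
    truth_rows[[e]] <- tibble::tibble(
      experiment_id = eid, group = group,
      true_is_pct_aar = if (m_aar > 0) 100 * m_inf / m_aar else 0,
      true_aar_pct_lv = 100 * m_aar / m_lv,
      n_slices = n_slices, mass_lv_g = m_lv
    )
    experiments[[e]] <- list(experiment_id = eid, group = group, slices = slices)
  }
  structure(list(
    experiments = rlang::set_names(experiments, purrr::map_chr(experiments, "experiment_id")),
    truth = dplyr::bind_rows(truth_rows),
    faces = dplyr::bind_rows(faces_rows),
    config = cfg
  ), class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TTC phantom cohort: %d experiments (%s), %d rendered faces, %d px\n",
              length(x$experiments), x$config$species_profile,
              sum(x$faces$imaged), x$config$image_size))
  invisible(x)
}

#' Generator ground-truth infarct size for one experiment
#'
#' Returns the generator's exact infarct size and AAR share, computed from
#' the continuous face geometry through the same averaging and
#' mass-normalization as the pixel-based quantification — the oracle for
#' parameter-recovery tests.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param experiment_id Experiment identifier.
#' @return One-row tibble with `true_is_pct_aar` and `true_aar_pct_lv`.
#' @export
true_is <- function(cohort, experiment_id) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  row <- cohort$truth[cohort$truth$experiment_id == experiment_id, , drop = FALSE]
  if (nrow(row) == 0) {
    stop(sprintf("unknown experiment id '%s'", experiment_id), call. = FALSE)
  }
  row[c("experiment_id", "group", "true_is_pct_aar", "true_aar_pct_lv")]
}

#' Flatten a cohort into a tidy table of imaged faces
#'
#' @param cohort A `phantom_cohort`.
#' @return Tibble with `experiment_id`, `slice_index`, `face` and list-columns
#'   `image`, `mask` — the shape consumed by training and evaluation.
#' @export
cohort_faces <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  purrr::map_dfr(cohort$experiments, function(ex) {
    purrr::map_dfr(ex$slices, function(sl) {
      purrr::map_dfr(c("apical", "basal"), function(f) {
        if (is.null(sl[[f]])) return(NULL)
        tibble::tibble(experiment_id = ex$experiment_id,
                       slice_index = sl$slice_index, face = f,
                       image = list(sl[[f]]$image), mask = list(sl[[f]]$mask))
      })
    })
  })
}
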