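#' Dice similarity coefficient for one class
#'
#' DSC = 2|P intersect G| / (|P| + |G|) between the predicted and reference
#' pixel sets of one class. When the class is absent from both masks the
#' score is 1 (correct absence, e.g. an infarct-free slice); absent from
#' exactly one, 0.
#'
#' @param pred,gt Label masks (integer matrices, same shape).
#' @param class Class index in 0..4.
#' @return Dice coefficient in [0, 1].
#' @export
dsc <- function(pred, gt, class) {
  check_same_shape(pred, gt)
  p <- pred == class; g <- gt == class
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(1)
  2 * sum(p & g) / (np + ng)
}

#' Per-class and pixel-weighted accuracy
#'
#' Per class, one-vs-rest binary accuracy (TP + TN) / total pixels — true
#' negatives count, so accuracies of small classes can exceed their Dice
#' score. The weighted overall accuracy averages the per-class accuracies
#' with weights equal to each class's reference pixel share.
#'
#' @inheritParams dsc
#' @return A value in [0, 1].
#' @export
acc <- function(pred, gt, class) {
  check_same_shape(pred, gt)
  mean((pred == class) == (gt == class))
}

#' @rdname acc
#' @export
weighted_acc <- function(pred, gt) {
  check_same_shape(pred, gt)
  share <- tabulate(as.integer(gt) + 1L, nbins = n_classes()) / length(gt)
  accs <- vapply(0:4, function(k) acc(pred, gt, k), numeric(1))
  sum(share * accs)
}

#' Boundary F1 score for one class
#'
#' Measures shape delineation. Boundary pixels of a class are its pixels
#' 4-adjacent to any other class (image borders count as outside). Precision
#' is the fraction of predicted boundary pixels within `tolerance_px`
#' (Euclidean) of a reference boundary pixel, recall symmetrically; bF1 is
#' their harmonic mean. Both boundaries empty scores 1; exactly one empty
#' scores 0.
#'
#' @inheritParams dsc
#' @param tolerance_px Match tolerance in pixels (>= 0).
#' @return Boundary F1 in [0, 1].
#' @export
boundary_f1 <- function(pred, gt, class, tolerance_px = 2) {
  check_same_shape(pred, gt)
  stopifnot(tolerance_px >= 0)
  bp <- class_boundary(pred, class)
  bg <- class_boundary(gt, class)
  np <- sum(bp); ng <- sum(bg)
  if (np == 0 && ng == 0) return(1)
  if (np == 0 || ng == 0) return(0)
  prec <- mean(boundary_within(bp, bg, tolerance_px))
  rec <- mean(boundary_within(bg, bp, tolerance_px))
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# boundary = class pixels with a 4-neighbour of another class (or image edge)
class_boundary <- function(mask, class) {
  m <- mask == class
  pad <- function(shift_r, shift_c) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + shift_r; cs <- seq_len(ncol(m)) + shift_c
    ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  m & !interior
}

# for each TRUE pixel of `from`, is a TRUE pixel of `to` within tol (Euclid)?
# exact pairwise distances: boundary sets are O(perimeter), small enough
boundary_within <- function(from, to, tol) {
  fi <- which(from, arr.ind = TRUE)
  ti <- which(to, arr.ind = TRUE)
  if (nrow(ti) == 0) return(rep(FALSE, nrow(fi)))
  d2 <- outer(fi[, 1], ti[, 1], "-")^2 + outer(fi[, 2], ti[, 2], "-")^2
  d2min <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
  sqrt(d2min) <= tol + 1e-9
}

#' Average precision of a class probability map
#'
#' Pixels are pooled over the evaluation set and ranked by the class
#' probability; AP is the area under the precision-recall curve,
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} over descending score groups (tied
#' scores form one group, so uninformative constant scores give AP equal to
#' the positive prevalence).
#'
#' @param scores Numeric vector (or array) of per-pixel class probabilities.
#' @param labels Logical/0-1 vector of the same length: pixel belongs to the
#'   class in the reference mask.
#' @return AP in [0, 1]; `NA` with a warning when the class has no positive
#'   pixel anywhere (it is then excluded from mAP).
#' @export
average_precision <- function(scores, labels) {
  scores <- as.vector(scores); labels <- as.logical(as.vector(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0) {
    warning("class has no positive pixels; AP undefined", call. = FALSE)
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  ctp <- cumsum(y)[grp_end]
  cn <- grp_end
  prec <- ctp / cn
  rec <- ctp / P
  sum(diff(c(0, rec)) * prec)
}

#' @rdname average_precision
#' @param ap_per_class Numeric vector of per-class APs (NAs excluded).
#' @export
mean_ap <- function(ap_per_class) mean(ap_per_class, na.rm = TRUE)

#' Segmentation performance report
#'
#' Assembles the per-class and overall metric table used to judge the
#' segmentation model: Dice (DSC), accuracy (ACC), boundary F1 (bF1) and
#' average precision (AP) per class, plus the overall row (mean DSC,
#' pixel-weighted ACC, mean bF1, mean AP). DSC, ACC and bF1 are averaged
#' over images; AP is computed on pixels pooled over the whole set.
#'
#' @param predictions List of predicted label masks.
#' @param annotations List of reference label masks (same length/order).
#' @param prob_maps Optional list of probability arrays (H x W x 5) matching
#'   `predictions`; when absent, AP is computed from the hard predicted masks
#'   (0/1 scores).
#' @param tolerance_px Boundary-F1 tolerance, in pixels.
#' @return A tibble with 6 rows (five classes + `overall`) and columns
#'   `area`, `dsc`, `acc`, `bf1`, `ap`.
#' @export
metrics_report <- function(predictions, annotations, prob_maps = NULL,
                           tolerance_px = 2) {
  stopifnot(length(predictions) == length(annotations))
  if (length(predictions) == 0) stop("empty evaluation set", call. = FALSE)
  scheme <- class_scheme()
  per_image <- purrr::map2_dfr(predictions, annotations, function(p, g) {
    tibble::tibble(
      class = 0:4,
      dsc = purrr::map_dbl(0:4, ~ dsc(p, g, .x)),
      acc = purrr::map_dbl(0:4, ~ acc(p, g, .x)),
      bf1 = purrr::map_dbl(0:4, ~ boundary_f1(p, g, .x, tolerance_px)),
      wacc = weighted_acc(p, g),
      share = tabulate(as.integer(g) + 1L, nbins = 5L) / length(g)
    )
  })
  ap <- purrr::map_dbl(0:4, function(k) {
    scores <- if (is.null(prob_maps)) {
      unlist(purrr::map(predictions, ~ as.numeric(.x == k)))
    } else {
      unlist(purrr::map(prob_maps, ~ as.vector(.x[, , k + 1L])))
    }
    labels <- unlist(purrr::map(annotations, ~ as.vector(.x == k)))
    suppressWarnings(average_precision(scores, labels))
  })
  cls <- per_image |>
    dplyr::group_by(class) |>
    dplyr::summarise(dsc = mean(dsc), acc = mean(acc), bf1 = mean(bf1),
                     .groups = "drop") |>
    dplyr::mutate(area = scheme$name[class + 1L], ap = ap) |>
    dplyr::select(area, dsc, acc, bf1, ap)
  overall <- tibble::tibble(
    area = "overall",
    dsc = mean(cls$dsc),
    acc = mean(purrr::map_dbl(seq_along(predictions),
                              ~ weighted_acc(predictions[[.x]], annotations[[.x]]))),
    bf1 = mean(cls$bf1),
    ap = mean_ap(ap)
  )
  dplyr::bind_rows(cls, overall)
}

#' Pearson correlation and least-squares line
#'
#' @param x,y Numeric vectors, length >= 3, finite, non-constant.
#' @return A tibble with `r`, `slope`, `intercept`, `n`.
#' @export
pearson_linreg <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    r = stats::cor(x, y),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x)
  )
}

#' Bland-Altman agreement between two measurement methods
#'
#' Paired differences d = a - b; bias = mean(d); limits of agreement are
#' bias -/+ 1.96 times the sample SD of the differences.
#'
#' @param method_a,method_b Paired numeric vectors (n >= 2).
#' @return A tibble with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
#' @examples
#' bland_altman(c(2, 4, 6), c(1, 2, 3))   # bias 2, limits 0.04 / 3.96
bland_altman <- function(method_a, method_b) {
  if (length(method_a) != length(method_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(method_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- method_a - method_b
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(d))
}

#' ANCOVA-style test of divergence from the identity line
#'
#' Joint extra-sum-of-squares F-test of H0: slope = 1 and intercept = 0.
#' The restricted model is the fixed identity line y = x (zero parameters);
#' the full model the ordinary least-squares line. A perfect identity fit
#' returns p = 1 as a no-divergence sentinel.
#'
#' @param x,y Numeric vectors (n >= 4), `x` non-constant.
#' @return A tibble with `F`, `p`, `df1`, `df2`.
#' @export
ancova_identity <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate x: zero variance", call. = FALSE)
  rss0 <- sum((y - x)^2)
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::residuals(fit)^2)
  if (rss0 <= .Machine$double.eps * max(1, sum(y^2))) {
    return(tibble::tibble(F = 0, p = 1, df1 = 2L, df2 = n - 2L))
  }
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 2))
  tibble::tibble(F = Fstat, p = stats::pf(Fstat, 2, n - 2, lower.tail = FALSE),
                 df1 = 2L, df2 = n - 2L)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' the sample's own mean and SD (Lilliefors-style plug-in, so the p-value is
#' approximate and anti-conservative for small n; documented caveat).
#'
#' @param sample Numeric vector, n >= 5, non-constant.
#' @return A tibble with `statistic`, `p`, `n`.
#' @export
ks_normality <- function(sample) {
  if (length(sample) < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(sample) == 0) stop("constant sample: normality test undefined", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean = mean(sample), sd = stats::sd(sample))
  )
  tibble::tibble(statistic = unname(kt$statistic), p = kt$p.value, n = length(sample))
}

#' Full method-agreement report
#'
#' Combines Pearson/linear regression, Bland-Altman, ANCOVA-vs-identity and
#' per-variable KS normality for two paired IS quantification methods,
#' overall and (when `group` is given) per subgroup — the layout used to
#' compare annotation-derived and prediction-derived infarct sizes.
#'
#' @param data Data frame with the paired measurements.
#' @param a,b Column names (strings) of the two methods.
#' @param group Optional column name of a subgroup factor.
#' @return An object of class `agreement_report`: tibble with one row per
#'   subgroup (plus `"all"`), carrying r, slope, intercept, bias, limits of
#'   agreement, ANCOVA p and KS p-values; the data are attached for plotting.
#' @export
agreement_report <- function(data, a, b, group = NULL) {
  stopifnot(is.data.frame(data), a %in% names(data), b %in% names(data))
  # sub-reports degrade gracefully: statistics whose sample-size or variance
  # preconditions fail are reported as NA instead of aborting the report
  one <- function(d, label) {
    pl <- tryCatch(pearson_linreg(d[[a]], d[[b]]), error = function(e) {
      tibble::tibble(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                     n = nrow(d))
    })
    ba <- bland_altman(d[[a]], d[[b]])
    an <- tryCatch(ancova_identity(d[[a]], d[[b]]), error = function(e) {
      tibble::tibble(F = NA_real_, p = NA_real_)
    })
    ks_a <- tryCatch(ks_normality(d[[a]])$p, error = function(e) NA_real_)
    ks_b <- tryCatch(ks_normality(d[[b]])$p, error = function(e) NA_real_)
    tibble::tibble(subset = label, n = pl$n, r = pl$r, slope = pl$slope,
                   intercept = pl$intercept, bias = ba$bias,
                   loa_low = ba$loa_low, loa_high = ba$loa_high,
                   ancova_F = an$F, ancova_p = an$p, ks_p_a = ks_a, ks_p_b = ks_b)
  }
  out <- one(data, "all")
  if (!is.null(group) && group %in% names(data)) {
    for (g in unique(data[[group]])) {
      d <- data[data[[group]] == g, , drop = FALSE]
      if (nrow(d) >= 4 && stats::sd(d[[a]]) > 0 && stats::sd(d[[b]]) > 0) {
        out <- dplyr::bind_rows(out, one(d, as.character(g)))
      }
    }
  }
  structure(out, class = c("agreement_report", class(out)),
            data = tibble::as_tibble(data[c(a, b)]) |> rlang::set_names(c("a", "b")))
}

#' @export
glance.agreement_report <- function(x, ...) x[x$subset == "all", , drop = FALSE]
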