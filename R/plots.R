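#' Plot an agreement report
#'
#' `type = "bland_altman"` draws the paired-difference plot: per-experiment
#' differences against means, the bias line (solid) and the upper/lower
#' limits of agreement at bias +/- 1.96 SD (dashed). `type = "regression"`
#' draws the scatter with the least-squares line and the identity line.
#'
#' @param object An [agreement_report()].
#' @param type `"bland_altman"` or `"regression"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, type = c("bland_altman", "regression"), ...) {
  type <- match.arg(type)
  d <- attr(object, "data")
  all_row <- object[object$subset == "all", ]
  if (type == "bland_altman") {
    dd <- tibble::tibble(mean = (d$a + d$b) / 2, diff = d$a - d$b)
    ggplot2::ggplot(dd, ggplot2::aes(x = mean, y = diff)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(yintercept = all_row$bias, linewidth = 0.6) +
      ggplot2::geom_hline(yintercept = c(all_row$loa_low, all_row$loa_high),
                          linetype = "dashed") +
      ggplot2::labs(x = "Mean of both methods (% of AAR)",
                    y = "Difference (% of AAR)",
                    title = sprintf("Bland-Altman: bias %.2f [%.2f, %.2f]",
                                    all_row$bias, all_row$loa_low, all_row$loa_high)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tibble::tibble(a = d$a, b = d$b), ggplot2::aes(x = b, y = a)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_abline(slope = all_row$slope, intercept = all_row$intercept,
                           colour = "steelblue") +
      ggplot2::labs(x = "Method B (% of AAR)", y = "Method A (% of AAR)",
                    title = sprintf("r = %.3f, slope %.2f, intercept %.2f",
                                    all_row$r, all_row$slope, all_row$intercept)) +
      ggplot2::theme_minimal()
  }
}

#' Plot the training history of a fitted segmentation model
#'
#' Per-epoch composite training loss and validation overall Dice, with the
#' selected best epoch marked.
#'
#' @param object A `trained_unet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trained_unet <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("loss", "val_dsc"), names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(~series, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(loss = "training loss", val_dsc = "validation DSC"))) +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Display a label mask or phantom image
#'
#' @param mask Integer label mask.
#' @return A ggplot raster plot using the class display palette.
#' @export
plot_mask <- function(mask) {
  scheme <- class_scheme()
  dd <- tibble::tibble(
    row = rep(seq_len(nrow(mask)), times = ncol(mask)),
    col = rep(seq_len(ncol(mask)), each = nrow(mask)),
    class = factor(as.vector(mask), levels = 0:4, labels = scheme$name)
  )
  cols <- rlang::set_names(grDevices::rgb(scheme$r, scheme$g, scheme$b,
                                          maxColorValue = 255), scheme$name)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
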