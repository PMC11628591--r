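#' Remove the background of a slice photograph
#'
#' Deterministic chroma-distance background removal: the background colour is
#' estimated from the image border, pixels within `threshold` Euclidean RGB
#' distance of it are marked background, the largest connected foreground
#' component is kept (the dominant central object), closed morphologically,
#' and its enclosed holes (e.g. ventricular lumina) are filled so the
#' foreground is one solid object. Background pixels are set to the constant
#' `fill` value.
#'
#' @param img H x W x 3 numeric array, channels 0-255.
#' @param threshold RGB distance below which a pixel counts as background.
#' @param fill Fill value (scalar, 0-255) for background pixels.
#' @param closing_radius Radius (px) of the morphological closing brush.
#' @return A list with `image` (background set to `fill`) and `foreground`
#'   (logical matrix).
#' @export
remove_background <- function(img, threshold = 40, fill = 0, closing_radius = 3) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  border <- rbind(
    cbind(1L, seq_len(w)), cbind(h, seq_len(w)),
    cbind(seq_len(h), 1L), cbind(seq_len(h), w)
  )
  bg_col <- vapply(1:3, function(ch) stats::median(img[, , ch][border]), numeric(1))
  d2 <- (img[, , 1] - bg_col[1])^2 + (img[, , 2] - bg_col[2])^2 +
    (img[, , 3] - bg_col[3])^2
  fg <- d2 > threshold^2
  if (!any(fg)) stop("no foreground found: image is all background", call. = FALSE)
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), h, w))
  sizes <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(sizes)
  fg <- matrix(as.integer(lab) == keep, h, w)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    fg <- as.matrix(EBImage::closing(matrix(as.numeric(fg), h, w), brush)) > 0.5
  }
  fg <- as.matrix(EBImage::fillHull(matrix(as.numeric(fg), h, w))) > 0.5
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!fg] <- fill
    out[, , ch] <- plane
  }
  list(image = out, foreground = fg)
}

#' Pad an image or mask to a square
#'
#' Aspect-ratio correction: the content is centred on a max(H, W) square
#' canvas filled with `fill` (black for images, class 0 for masks).
#'
#' @param x H x W x 3 image array or H x W mask matrix.
#' @param fill Padding value.
#' @return The padded square array/matrix.
#' @export
pad_to_square <- function(x, fill = 0) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h == w) return(x)
  s <- max(h, w)
  r0 <- (s - h) %/% 2; c0 <- (s - w) %/% 2
  if (length(d) == 3) {
    out <- array(fill, c(s, s, d[3]))
    out[r0 + seq_len(h), c0 + seq_len(w), ] <- x
  } else {
    out <- matrix(if (is.integer(x)) as.integer(fill) else fill, s, s)
    out[r0 + seq_len(h), c0 + seq_len(w)] <- x
  }
  out
}

#' Resize a square image or mask to a uniform size
#'
#' Images are interpolated bilinearly; masks use nearest-neighbour index
#' mapping so that no new class labels can appear.
#'
#' @param x Square H x H x 3 image array or H x H mask matrix.
#' @param size Target side length in pixels.
#' @param kind `"image"` (smooth) or `"mask"` (nearest-neighbour); guessed
#'   from the dimensionality when omitted.
#' @return The resized array/matrix.
#' @export
resize_uniform <- function(x, size, kind = NULL) {
  d <- dim(x)
  if (d[1] != d[2]) stop("input is not square: pad_to_square() first", call. = FALSE)
  kind <- kind %||% if (length(d) == 3) "image" else "mask"
  if (d[1] == size) return(x)
  if (kind == "image") {
    out <- as.array(EBImage::resize(x, w = size, h = size))
    clamp(out, 0, 255)
  } else {
    idx <- pmin(pmax(ceiling(seq_len(size) / size * d[1]), 1L), d[1])
    x[idx, idx]
  }
}

# mean over channels of per-window SSIM maps; uniform window
ssim_gray <- function(a, b, window = 7, dynamic_range = 255,
                      k1 = 0.01, k2 = 0.03) {
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  box <- matrix(1 / window^2, window, window)
  f <- function(m) as.matrix(EBImage::filter2(m, box, boundary = "replicate"))
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  vab <- f(a * b) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
         ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
}

#' Structural similarity index measure (SSIM)
#'
#' Windowed SSIM on a 0-255 dynamic range (uniform `window` x `window`
#' window, standard stabilization constants k1 = 0.01, k2 = 0.03), averaged
#' over windows and channels. Ranges from -1 (perfect anticorrelation)
#' through 0 (no similarity) to 1 (identical images).
#'
#' @param a,b Images (H x W x 3 arrays) or matrices of identical dimensions,
#'   channel values 0-255.
#' @param window Window side length in pixels.
#' @return SSIM in [-1, 1]; symmetric in its arguments.
#' @export
ssim <- function(a, b, window = 7) {
  check_same_shape(a, b)
  if (length(dim(a)) == 3) {
    mean(vapply(seq_len(dim(a)[3]),
                function(ch) ssim_gray(a[, , ch], b[, , ch], window), numeric(1)))
  } else {
    ssim_gray(a, b, window)
  }
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(255^2 / MSE)` over all pixels and channels on the 8-bit-per-
#' channel scale; identical images return `Inf`. Values between 30 and 50 dB
#' indicate low quality loss for 24-bit images.
#'
#' @inheritParams ssim
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b) {
  check_same_shape(a, b)
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Resize-quality report for a set of images
#'
#' Quantifies the quality loss of the uniform-resize step: each image is
#' resized down to `target_size` and back up to its native dimensions
#' (bilinear both ways), then compared with the original via SSIM and PSNR.
#' Reports per-image values plus cohort median and IQR of each.
#'
#' @param images List of H x W x 3 image arrays (square).
#' @param target_size Side length of the model input, px.
#' @return An object of class `quality_report`: tibble of per-image `ssim`
#'   and `psnr_db` with attributes `summary` (median/IQR tibble) and
#'   `target_size`.
#' @export
quality_report <- function(images, target_size) {
  if (length(images) == 0) stop("empty cohort: no images to assess", call. = FALSE)
  rows <- purrr::imap_dfr(images, function(img, i) {
    down <- resize_uniform(img, target_size, kind = "image")
    back <- resize_uniform(down, dim(img)[1], kind = "image")
    tibble::tibble(image = as.integer(i), ssim = ssim(img, back),
                   psnr_db = psnr(img, back))
  })
  finite_psnr <- rows$psnr_db[is.finite(rows$psnr_db)]
  summ <- tibble::tibble(
    metric = c("ssim", "psnr_db"),
    median = c(stats::median(rows$ssim),
               if (length(finite_psnr)) stats::median(rows$psnr_db) else Inf),
    iqr = c(stats::IQR(rows$ssim),
            if (length(finite_psnr) == nrow(rows)) stats::IQR(rows$psnr_db) else NA_real_)
  )
  structure(rows, class = c("quality_report", class(rows)),
            summary = summ, target_size = target_size)
}

#' @export
glance.quality_report <- function(x, ...) attr(x, "summary")

#' Full preprocessing chain for one face
#'
#' Background removal, square padding and uniform resizing, applied with
#' identical geometric operations to the image and (when given) its mask so
#' pixel alignment is preserved.
#'
#' @param img H x W x 3 image array.
#' @param mask Optional aligned label mask.
#' @param size Target side length.
#' @param remove_bg Run [remove_background()] first.
#' @return List with `image` and (if supplied) `mask`.
#' @export
preprocess_face <- function(img, mask = NULL, size = 384, remove_bg = TRUE) {
  if (remove_bg) img <- remove_background(img)$image
  img <- resize_uniform(pad_to_square(img, fill = 0), size, kind = "image")
  out <- list(image = img)
  if (!is.null(mask)) {
    out$mask <- resize_uniform(pad_to_square(mask, fill = 0L), size, kind = "mask")
  }
  out
}
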