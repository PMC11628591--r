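#' Training configuration for the segmentation network
#'
#' Two profiles are provided. `"paper"` mirrors the reference training
#' conditions: 384-px inputs, Adam with learning rate 1e-4, at least 300
#' epochs, batch size 26, 50% dropout, 0.5% weight decay. `"tiny"` is the
#' desk-scale profile used throughout the test-suite and examples: 96-px
#' inputs, 20 epochs, batch size 8 and a proportionally smaller network with
#' a larger learning rate (3e-3) appropriate for its roughly hundredfold
#' fewer optimizer steps.
#'
#' @param profile `"tiny"` or `"paper"`.
#' @param learning_rate Adam learning rate (> 0).
#' @param min_epochs Number of training epochs (training never stops early).
#' @param batch_size Images per optimizer step (>= 1).
#' @param dropout_fraction Dropout on the bottleneck activations, in [0, 1).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param image_size Input side length; must be divisible by `2^depth`.
#' @param depth Number of encoder pooling levels.
#' @param base_channels Channels of the first encoder block; deeper blocks
#'   double it and the decoder widths are derived from the encoder shapes.
#' @param loss_weights Numeric length-3 vector `c(w_ce, w_mae, w_dice)` of
#'   composite-loss component weights.
#' @param class_weighting `"inverse"` (inverse pixel frequency on the
#'   training split, mean-normalized) or `"uniform"` cross-entropy weights.
#' @param augment Logical: apply data augmentation during training.
#' @param augment_config See [augment_config()].
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(profile = c("tiny", "paper"),
                         learning_rate = NULL, min_epochs = NULL,
                         batch_size = NULL, dropout_fraction = 0.5,
                         weight_decay = 0.005, image_size = NULL,
                         depth = NULL, base_channels = NULL,
                         loss_weights = c(1, 1, 1),
                         class_weighting = c("inverse", "uniform"),
                         augment = TRUE, augment_config = NULL, seed = 1L) {
  profile <- match.arg(profile)
  class_weighting <- match.arg(class_weighting)
  def <- if (profile == "paper") {
    list(learning_rate = 1e-4, min_epochs = 300L, batch_size = 26L,
         image_size = 384L, depth = 4L, base_channels = 16L)
  } else {
    list(learning_rate = 3e-3, min_epochs = 20L, batch_size = 8L,
         image_size = 96L, depth = 2L, base_channels = 6L)
  }
  cfg <- list(
    profile = profile,
    learning_rate = learning_rate %||% def$learning_rate,
    min_epochs = as.integer(min_epochs %||% def$min_epochs),
    batch_size = as.integer(batch_size %||% def$batch_size),
    dropout_fraction = dropout_fraction,
    weight_decay = weight_decay,
    image_size = as.integer(image_size %||% def$image_size),
    depth = as.integer(depth %||% def$depth),
    base_channels = as.integer(base_channels %||% def$base_channels),
    loss_weights = loss_weights,
    class_weighting = class_weighting,
    augment = isTRUE(augment),
    augment_config = augment_config %||% augment_config(),
    seed = as.integer(seed)
  )
  if (cfg$learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (cfg$dropout_fraction < 0 || cfg$dropout_fraction >= 1) {
    stop("dropout_fraction must be in [0, 1)", call. = FALSE)
  }
  if (cfg$batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (cfg$image_size %% (2^cfg$depth) != 0) {
    stop(sprintf("image_size %d is not divisible by 2^depth = %d",
                 cfg$image_size, 2^cfg$depth), call. = FALSE)
  }
  if (length(cfg$loss_weights) != 3 || any(cfg$loss_weights < 0)) {
    stop("loss_weights must be 3 non-negative numbers (ce, mae, dice)", call. = FALSE)
  }
  structure(cfg, class = "train_config")
}

#' Build the encoder-decoder segmentation network
#'
#' A U-Net with `depth` pooling levels. Encoder block i has
#' `base_channels * 2^(i-1)` channels (two 3x3 convolutions + ReLU); the
#' bottleneck doubles the deepest width. Decoder stages upsample (nearest,
#' x2), concatenate the matching encoder skip and convolve; their input
#' widths are derived from the actual encoder feature shapes at build time —
#' the "dynamic" sizing contract — so changing the encoder automatically
#' re-sizes the decoder. A final 1x1 convolution maps to the 5 class logits;
#' probabilities come from a per-pixel softmax.
#'
#' @param image_size Input side length (divisible by `2^depth`).
#' @param depth Encoder depth (pooling levels).
#' @param base_channels First-level channel count.
#' @param n_classes Number of output classes.
#' @param seed Seed for the (He) weight initialization.
#' @return An object of class `unet_model`.
#' @export
build_unet <- function(image_size = 96, depth = 2, base_channels = 4,
                       n_classes = 5, seed = 1L) {
  if (image_size %% (2^depth) != 0) {
    stop(sprintf("image_size %d is not divisible by 2^depth = %d",
                 image_size, 2^depth), call. = FALSE)
  }
  enc <- base_channels * 2^(seq_len(depth) - 1)
  bott <- base_channels * 2^depth
  rows <- list()
  cin <- 3L
  for (i in seq_len(depth)) {
    rows[[length(rows) + 1]] <- c(cin, enc[i], 3L)
    rows[[length(rows) + 1]] <- c(enc[i], enc[i], 3L)
    cin <- enc[i]
  }
  rows[[length(rows) + 1]] <- c(enc[depth], bott, 3L)
  up_ch <- bott
  for (i in rev(seq_len(depth))) {
    # dynamic sizing: decoder input = upsampled width + encoder skip width
    rows[[length(rows) + 1]] <- c(up_ch + enc[i], enc[i], 3L)
    up_ch <- enc[i]
  }
  rows[[length(rows) + 1]] <- c(enc[1], as.integer(n_classes), 1L)
  layer_table <- do.call(rbind, rows)
  storage.mode(layer_table) <- "integer"
  npar <- cpp_unet_npar(layer_table, depth, n_classes)
  par <- withr::with_seed(as.integer(seed), {
    p <- numeric(npar)
    off <- 0
    for (i in seq_len(nrow(layer_table))) {
      cin_i <- layer_table[i, 1]; cout_i <- layer_table[i, 2]; k <- layer_table[i, 3]
      nw <- cout_i * cin_i * k * k
      p[off + seq_len(nw)] <- stats::rnorm(nw, 0, sqrt(2 / (cin_i * k * k)))
      off <- off + nw + cout_i   # biases stay 0
    }
    p
  })
  structure(list(par = par, layer_table = layer_table, depth = as.integer(depth),
                 image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("U-Net: depth %d, base %d channels, %d-px input, %d classes, %d parameters\n",
              x$depth, x$base_channels, x$image_size, x$n_classes, length(x$par)))
  invisible(x)
}

normalize_image <- function(img) img / 255 - 0.5

#' Per-pixel class probability maps for one image
#'
#' @param object A `unet_model`.
#' @param img H x W x 3 image array (0-255) at the model's input size.
#' @param ... Unused.
#' @return H x W x 5 array of class probabilities; each pixel's five values
#'   sum to 1.
#' @export
predict.unet_model <- function(object, img, ...) {
  d <- dim(img)
  if (length(d) != 3 || d[1] != object$image_size || d[2] != object$image_size) {
    stop(sprintf("input must be %dx%dx3 (got %s): preprocess to the model size first",
                 object$image_size, object$image_size, paste(d, collapse = "x")),
         call. = FALSE)
  }
  cpp_unet_forward(object$par, normalize_image(img), object$layer_table,
                   object$depth, object$n_classes)
}

#' Collapse probability maps to a label mask
#'
#' Per-pixel argmax over the class maps; exact ties resolve to the lowest
#' class index.
#'
#' @param maps H x W x 5 probability array.
#' @return H x W integer label mask.
#' @export
maps_to_mask <- function(maps) {
  d <- dim(maps)
  m <- matrix(maps, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Composite segmentation loss
#'
#' `w_ce * weighted cross-entropy + w_mae * MAE + w_dice * (1 - mean soft
#' Dice)`, computed from probability maps against an integer target mask.
#' The cross-entropy is the class-weighted mean of `-log p` at the true
#' class; MAE is the mean absolute difference between the probability maps
#' and the one-hot target over all pixels and classes; the Dice component
#' uses soft (probability-mass) per-class Dice averaged over classes. All
#' three components are zero exactly when the prediction is the one-hot
#' target.
#'
#' @param probs H x W x 5 probability array.
#' @param target H x W integer mask.
#' @param class_weights Positive length-5 vector of cross-entropy weights.
#' @param component_weights Length-3 vector `c(w_ce, w_mae, w_dice)`.
#' @return Named list: `loss`, `ce`, `mae`, `dice`.
#' @export
composite_loss <- function(probs, target, class_weights = rep(1, 5),
                           component_weights = c(1, 1, 1)) {
  d <- dim(probs)
  if (length(d) != 3 || !all(d[1:2] == dim(target))) {
    stop("probability maps and target mask shapes disagree", call. = FALSE)
  }
  if (any(class_weights <= 0)) stop("class weights must be positive", call. = FALSE)
  C <- d[3]; N <- d[1] * d[2]
  onehot <- array(0, d)
  for (c in seq_len(C)) onehot[, , c] <- as.numeric(target == c - 1L)
  w_px <- matrix(class_weights[as.integer(target) + 1L], d[1], d[2])
  p_true <- probs[cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]),
                        as.integer(target) + 1L)]
  ce <- sum(w_px * -log(pmax(p_true, 1e-12))) / sum(w_px)
  mae <- mean(abs(probs - onehot))
  eps <- 1e-7
  dice_c <- vapply(seq_len(C), function(c) {
    p <- probs[, , c]; y <- onehot[, , c]
    (2 * sum(p * y)) / (sum(p) + sum(y) + eps)
  }, numeric(1))
  dice <- 1 - mean(dice_c)
  w <- component_weights
  list(loss = w[1] * ce + w[2] * mae + w[3] * dice, ce = ce, mae = mae, dice = dice)
}

#' Augmentation policy
#'
#' @param max_rotate Max absolute rotation, degrees.
#' @param zoom_range Multiplicative zoom range.
#' @param max_warp Max shear coefficient (affine warp).
#' @param p_flip Probability of a horizontal flip.
#' @param brightness,contrast,saturation Max absolute photometric jitter.
#' @param p_erase Probability of random erasing; the erased image region is
#'   zeroed and the matching mask region set to class 0 (paired erasing).
#' @param erase_frac Max side fraction of the erased rectangle.
#' @param p_blur Probability of Gaussian blur; `blur_sigma` its SD.
#' @param blur_sigma Blur SD in pixels.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(max_rotate = 15, zoom_range = c(0.9, 1.1),
                           max_warp = 0.08, p_flip = 0.5, brightness = 0.12,
                           contrast = 0.12, saturation = 0.12, p_erase = 0.25,
                           erase_frac = 0.2, p_blur = 0.2, blur_sigma = 0.8) {
  structure(as.list(environment()), class = "augment_config")
}

# affine inverse-mapped resampling; bilinear for images, nearest for masks
affine_resample <- function(x, A, bilinear = TRUE) {
  d <- dim(x)
  S <- d[1]
  ctr <- (S + 1) / 2
  rr <- matrix(rep(seq_len(S), times = S), S, S) - ctr
  cc <- matrix(rep(seq_len(S), each = S), S, S) - ctr
  Ai <- solve(A)
  sr <- Ai[1, 1] * rr + Ai[1, 2] * cc + ctr
  sc <- Ai[2, 1] * rr + Ai[2, 2] * cc + ctr
  if (bilinear) {
    r0 <- clamp(floor(sr), 1, S); c0 <- clamp(floor(sc), 1, S)
    r1 <- clamp(r0 + 1, 1, S); c1 <- clamp(c0 + 1, 1, S)
    fr <- as.vector(sr - r0); fc <- as.vector(sc - c0)
    inside <- as.vector(sr >= 1 & sr <= S & sc >= 1 & sc <= S)
    # linear indices into the first plane; channels offset by S^2
    l00 <- as.vector(r0 + (c0 - 1) * S); l10 <- as.vector(r1 + (c0 - 1) * S)
    l01 <- as.vector(r0 + (c1 - 1) * S); l11 <- as.vector(r1 + (c1 - 1) * S)
    w00 <- (1 - fr) * (1 - fc); w10 <- fr * (1 - fc)
    w01 <- (1 - fr) * fc; w11 <- fr * fc
    sample_plane <- function(p, off) {
      v <- w00 * p[l00 + off] + w10 * p[l10 + off] +
        w01 * p[l01 + off] + w11 * p[l11 + off]
      v[!inside] <- 0
      v
    }
    if (length(d) == 3) {
      out <- array(0, d)
      for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(x, (ch - 1) * S * S)
      out
    } else matrix(sample_plane(x, 0), S, S)
  } else {
    ri <- round(sr); ci <- round(sc)
    inside <- ri >= 1 & ri <= S & ci >= 1 & ci <= S
    ri <- clamp(ri, 1, S); ci <- clamp(ci, 1, S)
    v <- x[as.vector(ri + (ci - 1) * S)]
    v[!as.vector(inside)] <- 0L
    matrix(as.integer(v), S, S)
  }
}

#' Augment an image/mask pair
#'
#' Geometric transforms (rotation, zoom, shear warp, flip, random erasing)
#' are applied identically to image and mask; photometric transforms
#' (brightness, contrast, saturation, Gaussian blur) to the image only. The
#' mask never leaves the 5-class scheme. Uses the current R random stream.
#'
#' @param img H x W x 3 image (0-255).
#' @param mask Aligned H x W integer mask.
#' @param config An [augment_config()].
#' @return List with augmented `image` and `mask`.
#' @export
augment <- function(img, mask, config = augment_config()) {
  check_same_shape(img[, , 1], mask)
  S <- dim(img)[1]
  ang <- stats::runif(1, -config$max_rotate, config$max_rotate) * pi / 180
  zoom <- runif_range(1, config$zoom_range)
  warp <- stats::runif(1, -config$max_warp, config$max_warp)
  A <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2) %*%
    matrix(c(zoom, warp, 0, zoom), 2, 2)
  img <- affine_resample(img, A, bilinear = TRUE)
  mask <- affine_resample(mask, A, bilinear = FALSE)
  if (stats::runif(1) < config$p_flip) {
    img <- img[, rev(seq_len(S)), , drop = FALSE]
    mask <- mask[, rev(seq_len(S)), drop = FALSE]
  }
  # photometric, image only
  b <- 1 + stats::runif(1, -config$brightness, config$brightness)
  ct <- 1 + stats::runif(1, -config$contrast, config$contrast)
  sat <- 1 + stats::runif(1, -config$saturation, config$saturation)
  mu <- mean(img)
  img <- (img * b - mu) * ct + mu
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * sat
  if (stats::runif(1) < config$p_blur) {
    img <- as.array(EBImage::gblur(img, sigma = config$blur_sigma))
  }
  if (stats::runif(1) < config$p_erase) {
    eh <- max(2L, round(stats::runif(1, 0.05, config$erase_frac) * S))
    ew <- max(2L, round(stats::runif(1, 0.05, config$erase_frac) * S))
    r0 <- sample.int(S - eh, 1); c0 <- sample.int(S - ew, 1)
    img[r0:(r0 + eh - 1), c0:(c0 + ew - 1), ] <- 0
    mask[r0:(r0 + eh - 1), c0:(c0 + ew - 1)] <- 0L
  }
  list(image = clamp(img, 0, 255), mask = mask)
}

# inverse pixel-frequency class weights, mean-normalized
class_weights_from <- function(masks, mode = "inverse") {
  if (mode == "uniform") return(rep(1, n_classes()))
  counts <- Reduce(`+`, lapply(masks, function(m) tabulate(as.integer(m) + 1L, nbins = n_classes())))
  freq <- pmax(counts, 1) / sum(counts)
  w <- 1 / freq
  w / mean(w)
}

# mean per-class DSC over an evaluation set (the best-model criterion)
overall_dsc <- function(pred_masks, gt_masks) {
  per <- purrr::map2(pred_masks, gt_masks, function(p, g) {
    vapply(0:4, function(k) dsc(p, g, k), numeric(1))
  })
  mean(rowMeans(do.call(cbind, per)))
}

#' Train the segmentation network
#'
#' Adam with decoupled weight decay on the composite loss. Runs exactly
#' `min_epochs` epochs (no early stopping); after each epoch the overall
#' Dice coefficient on the validation set is logged and the returned
#' checkpoint is the epoch that maximizes it (best-model selection on
#' validation performance). A fixed `seed` in the configuration makes the
#' whole run reproducible on one machine. Aborts with a diagnostic if the
#' loss turns non-finite.
#'
#' @param train_faces,val_faces Tibbles of faces with list-columns `image`
#'   and `mask` (see [cohort_faces()]), already at the model input size.
#' @param config A [train_config()].
#' @param quiet Suppress per-epoch progress.
#' @return An object of class `trained_unet`: the best-epoch `model`, the
#'   per-epoch `history` tibble (loss components + validation DSC),
#'   `best_epoch`, and the cross-entropy `class_weights` used.
#' @export
train_unet <- function(train_faces, val_faces, config = train_config("tiny"),
                       quiet = TRUE) {
  stopifnot(inherits(config, "train_config"))
  if (nrow(train_faces) == 0 || nrow(val_faces) == 0) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  both <- intersect(unique(train_faces$experiment_id), unique(val_faces$experiment_id))
  if (length(both) > 0) {
    stop("training and validation sets share experiments: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(config$seed, train_unet_impl(train_faces, val_faces, config, quiet))
}

train_unet_impl <- function(train_faces, val_faces, cfg, quiet) {
  model <- build_unet(cfg$image_size, cfg$depth, cfg$base_channels,
                      seed = cfg$seed)
  cls_w <- class_weights_from(train_faces$mask, cfg$class_weighting)
  xs <- lapply(train_faces$image, normalize_image)
  ys <- lapply(train_faces$mask, function(m) {
    storage.mode(m) <- "integer"; m
  })
  val_x <- lapply(val_faces$image, identity)
  n <- length(xs)
  par <- model$par
  m1 <- numeric(length(par)); m2 <- numeric(length(par))
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- vector("list", cfg$min_epochs)
  best <- list(dsc = -Inf, par = par, epoch = 0L)
  for (epoch in seq_len(cfg$min_epochs)) {
    ord <- sample.int(n)
    ep_loss <- ep_ce <- ep_mae <- ep_dice <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      gsum <- numeric(length(par))
      lsum <- csum <- msum <- dsum <- 0
      for (i in idx) {
        if (cfg$augment) {
          aug <- augment(train_faces$image[[i]], train_faces$mask[[i]],
                         cfg$augment_config)
          x_i <- normalize_image(aug$image)
          y_i <- aug$mask; storage.mode(y_i) <- "integer"
        } else {
          x_i <- xs[[i]]; y_i <- ys[[i]]
        }
        r <- cpp_unet_lossgrad(par, x_i, y_i, cls_w, cfg$loss_weights,
                               model$layer_table, model$depth, model$n_classes,
                               cfg$dropout_fraction)
        if (!is.finite(r$loss)) {
          stop(sprintf("non-finite loss at epoch %d: training aborted (lower the learning rate?)",
                       epoch), call. = FALSE)
        }
        gsum <- gsum + r$grad
        lsum <- lsum + r$loss; csum <- csum + r$ce
        msum <- msum + r$mae; dsum <- dsum + r$dice
      }
      g <- gsum / length(idx)
      t_step <- t_step + 1
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      mh <- m1 / (1 - b1^t_step)
      vh <- m2 / (1 - b2^t_step)
      par <- par - cfg$learning_rate * (mh / (sqrt(vh) + eps) + cfg$weight_decay * par)
      ep_loss <- ep_loss + lsum; ep_ce <- ep_ce + csum
      ep_mae <- ep_mae + msum; ep_dice <- ep_dice + dsum
    }
    model$par <- par
    preds <- lapply(val_x, function(img) maps_to_mask(predict(model, img)))
    vd <- overall_dsc(preds, val_faces$mask)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / n, ce = ep_ce / n, mae = ep_mae / n,
      dice = ep_dice / n, val_dsc = vd
    )
    if (vd > best$dsc) best <- list(dsc = vd, par = par, epoch = epoch)
    if (!quiet) {
      message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", epoch,
                      ep_loss / n, vd))
    }
  }
  model$par <- best$par
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val_dsc = best$dsc,
                 class_weights = cls_w, config = cfg),
            class = "trained_unet")
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("Trained U-Net: best epoch %d/%d, validation DSC %.3f\n",
              x$best_epoch, nrow(x$history), x$best_val_dsc))
  invisible(x)
}

#' @export
tidy.trained_unet <- function(x, ...) x$history

#' @export
glance.trained_unet <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_val_dsc = x$best_val_dsc,
                 epochs = nrow(x$history), final_loss = x$history$loss[nrow(x$history)])
}

#' k-fold cross-validation of the segmentation network
#'
#' Trains one model per fold on that fold's training experiments, validates
#' on its held-out experiments, and pools the out-of-fold predictions so
#' every cross-validation experiment is predicted exactly once — by a model
#' that never saw it.
#'
#' @param faces Tibble of faces (list-columns `image`, `mask`) for the whole
#'   cross-validation set.
#' @param folds Fold tibble from [make_folds()].
#' @param config A [train_config()].
#' @param quiet Suppress progress.
#' @return List of class `cv_result`: `models` (one `trained_unet` per
#'   fold) and `predictions` (tibble of out-of-fold faces with list-columns
#'   `prob` and `pred_mask`, tagged by `fold`).
#' @export
cross_validate <- function(faces, folds, config = train_config("tiny"),
                           quiet = TRUE) {
  models <- vector("list", nrow(folds))
  preds <- vector("list", nrow(folds))
  for (f in seq_len(nrow(folds))) {
    tr <- faces[faces$experiment_id %in% folds$train_ids[[f]], ]
    va <- faces[faces$experiment_id %in% folds$val_ids[[f]], ]
    fit <- tryCatch(
      train_unet(tr, va, config, quiet = quiet),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE)
    )
    models[[f]] <- fit
    preds[[f]] <- va |>
      dplyr::mutate(
        prob = purrr::map(image, ~ predict(fit$model, .x)),
        pred_mask = purrr::map(prob, maps_to_mask),
        fold = f
      )
  }
  structure(list(models = models, predictions = dplyr::bind_rows(preds)),
            class = "cv_result")
}
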