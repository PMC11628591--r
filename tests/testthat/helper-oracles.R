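# Independently coded brute-force oracles: explicit loops and enumeration,
# kept deliberately naive and separate from the package implementations.

oracle_dsc <- function(pred, gt, k) {
  np <- ng <- ni <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] == k; g <- gt[i, j] == k
    np <- np + p; ng <- ng + g; ni <- ni + (p && g)
  }
  if (np + ng == 0) 1 else 2 * ni / (np + ng)
}

oracle_acc <- function(pred, gt, k) {
  ok <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    ok <- ok + ((pred[i, j] == k) == (gt[i, j] == k))
  }
  ok / length(pred)
}

oracle_weighted_acc <- function(pred, gt) {
  total <- 0
  for (k in 0:4) {
    share <- sum(gt == k) / length(gt)
    total <- total + share * oracle_acc(pred, gt, k)
  }
  total
}

oracle_boundary <- function(mask, k) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != k) next
    edge <- i == 1 || i == H || j == 1 || j == W
    if (!edge) {
      edge <- mask[i - 1, j] != k || mask[i + 1, j] != k ||
        mask[i, j - 1] != k || mask[i, j + 1] != k
    }
    out[i, j] <- edge
  }
  out
}

oracle_bf1 <- function(pred, gt, k, tol) {
  bp <- which(oracle_boundary(pred, k), arr.ind = TRUE)
  bg <- which(oracle_boundary(gt, k), arr.ind = TRUE)
  if (nrow(bp) == 0 && nrow(bg) == 0) return(1)
  if (nrow(bp) == 0 || nrow(bg) == 0) return(0)
  near <- function(a, b) {
    hits <- 0
    for (i in seq_len(nrow(a))) {
      dmin <- Inf
      for (j in seq_len(nrow(b))) {
        dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
      }
      hits <- hits + (dmin <= tol + 1e-9)
    }
    hits / nrow(a)
  }
  prec <- near(bp, bg); rec <- near(bg, bp)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# AP by explicit threshold enumeration over descending unique scores
oracle_ap <- function(scores, labels) {
  P <- sum(labels)
  if (P == 0) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / P
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}

random_mask <- function(h, w, classes = 0:4) {
  matrix(sample(classes, h * w, replace = TRUE,
                prob = stats::runif(length(classes), 0.2, 1)), h, w)
}

random_probs <- function(h, w, c = 5) {
  p <- array(stats::rexp(h * w * c), c(h, w, c))
  s <- apply(p, c(1, 2), sum)
  for (k in seq_len(c)) p[, , k] <- p[, , k] / s
  p
}

# naive windowed SSIM: per-pixel window statistics via explicit loops,
# replicate boundary handling, uniform window
oracle_ssim <- function(a, b, window = 7) {
  h <- nrow(a); w <- ncol(a)
  half <- (window - 1) / 2
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  vals <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    wa <- wb <- numeric(window^2); idx <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1), h); jj <- min(max(j + dj, 1), w)
      idx <- idx + 1
      wa[idx] <- a[ii, jj]; wb[idx] <- b[ii, jj]
    }
    mu_a <- mean(wa); mu_b <- mean(wb)
    va <- mean(wa^2) - mu_a^2; vb <- mean(wb^2) - mu_b^2
    vab <- mean(wa * wb) - mu_a * mu_b
    vals[i, j] <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  }
  mean(vals)
}
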