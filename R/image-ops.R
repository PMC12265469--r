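#' Preprocess a raw image for the network
#'
#' Resizes an RGB image to `size x size` with bilinear interpolation and
#' normalizes pixel values to \[0, 1\] (8-bit inputs with values above 1 are
#' divided by 255). Already-conforming inputs pass through unchanged.
#'
#' @param raw `H x W x 3` numeric array (0-1 or 0-255).
#' @param size Target side length in pixels (default 224).
#' @return `size x size x 3` array with values in \[0, 1\].
#' @export
preprocess_image <- function(raw, size = 224L) {
  d <- dim(raw)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("input must be an H x W x 3 RGB array")
  if (d[1] < 1 || d[2] < 1) stop("input must have at least one pixel")
  if (max(raw) > 1) raw <- raw / 255
  if (d[1] != size || d[2] != size) {
    img <- EBImage::Image(aperm(raw, c(2, 1, 3)), colormode = "Color")
    img <- EBImage::resize(img, w = size, h = size)
    raw <- aperm(EBImage::imageData(img), c(2, 1, 3))
  }
  raw[raw < 0] <- 0; raw[raw > 1] <- 1
  raw
}

#' Random augmentation of a training image
#'
#' Applies, in order: a horizontal flip with probability 0.5 (when `flip`),
#' and a single affine transform combining rotation by up to `rotate`
#' degrees, width/height shifts of up to `shift` (fraction of the side
#' length) and zoom in `[1 - zoom, 1 + zoom]`, all sampled uniformly within
#' their bounds. Vacated pixels are filled with the edge-mean colour. Output
#' has the input shape with values clamped to \[0, 1\]; the same seed gives
#' the same output.
#'
#' @param img `H x W x 3` array in \[0, 1\].
#' @param seed Integer seed.
#' @param rotate Max absolute rotation in degrees (default 45).
#' @param shift Max absolute shift fraction (default 0.15).
#' @param flip Allow horizontal flipping (default TRUE).
#' @param zoom Zoom half-range (default 0.5, i.e. scale in \[0.5, 1.5\]).
#' @return Augmented `H x W x 3` array.
#' @export
augment <- function(img, seed = NULL, rotate = 45, shift = 0.15,
                    flip = TRUE, zoom = 0.5) {
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3)
  with_seed(seed, {
    do_flip <- flip && runif(1) < 0.5
    ang <- if (rotate > 0) runif(1, -rotate, rotate) * pi / 180 else 0
    dx <- if (shift > 0) runif(1, -shift, shift) * d[2] else 0
    dy <- if (shift > 0) runif(1, -shift, shift) * d[1] else 0
    sc <- if (zoom > 0) runif(1, 1 - zoom, 1 + zoom) else 1
    if (do_flip) img <- img[, d[2]:1, , drop = FALSE]
    if (ang != 0 || dx != 0 || dy != 0 || sc != 1) {
      ## affine about the image centre: x' = s R (x - c) + c + t
      cx <- (d[2] + 1) / 2; cy <- (d[1] + 1) / 2
      A <- sc * matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
      off <- c(cx + dx, cy + dy) - A %*% c(cx, cy)
      m <- rbind(t(A), as.numeric(off))    # EBImage 3x2 affine layout
      edge <- c(mean(img[c(1, d[1]), , 1]), mean(img[c(1, d[1]), , 2]),
                mean(img[c(1, d[1]), , 3]))
      eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
      eb <- EBImage::affine(eb, m, filter = "bilinear",
                            bg.col = grDevices::rgb(edge[1], edge[2], edge[3]))
      img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    img
  })
}

#' Detect the leaf bounding box in an image
#'
#' Deterministic colour-based detector: pixels whose green channel dominates
#' red and blue by a margin form the leaf mask; the largest 4-connected
#' component is selected and its tight axis-aligned bounding box padded by
#' 5% per side (clamped to the frame).
#'
#' @param img `H x W x 3` array in \[0, 1\].
#' @param margin Green-dominance margin (default 0.04).
#' @return A list with 1-based inclusive `row_lo`, `row_hi`, `col_lo`,
#'   `col_hi` and the component pixel count `n_pixels`, or `NULL` when no
#'   leaf-like component is found.
#' @export
detect_leaf_bbox <- function(img, margin = 0.04) {
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3)
  green <- img[, , 2] > img[, , 1] + margin & img[, , 2] > img[, , 3] + margin
  if (!any(green)) return(NULL)
  lab <- EBImage::bwlabel(green)
  tab <- tabulate(lab[lab > 0])
  biggest <- which.max(tab)
  if (tab[biggest] < 9) return(NULL)      # specks are not a leaf
  comp <- lab == biggest
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  pad_r <- ceiling(0.05 * (rows[2] - rows[1] + 1))
  pad_c <- ceiling(0.05 * (cols[2] - cols[1] + 1))
  list(row_lo = max(1, rows[1] - pad_r), row_hi = min(d[1], rows[2] + pad_r),
       col_lo = max(1, cols[1] - pad_c), col_hi = min(d[2], cols[2] + pad_c),
       n_pixels = tab[biggest])
}

#' Crop an image to a detected bounding box
#'
#' @param img `H x W x 3` array.
#' @param bbox A bounding box from [detect_leaf_bbox()].
#' @return The cropped array.
#' @export
crop_bbox <- function(img, bbox) {
  img[bbox$row_lo:bbox$row_hi, bbox$col_lo:bbox$col_hi, , drop = FALSE]
}

#' Classification metrics from predicted probabilities
#'
#' Thresholds sigmoid outputs at 0.5 and reports accuracy
#' `(TP + TN) / N`, F1 `2PR / (P + R)` and the confusion matrix.
#'
#' @param probs Predicted severe-probabilities in \[0, 1\].
#' @param labels True 0/1 labels.
#' @return A list with `accuracy`, `f1` and `confusion` (2x2 matrix,
#'   rows = truth, columns = prediction).
#' @export
evaluate_classifier <- function(probs, labels) {
  if (length(probs) == 0) stop("empty test set")
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  pred <- as.integer(probs >= 0.5)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  conf <- matrix(c(tn, fn, fp, tp), 2, 2,
                 dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  list(accuracy = (tp + tn) / length(labels), f1 = f1, confusion = conf)
}

#' Regression metrics for predicted damage scores
#'
#' Mean squared error, mean absolute error, Pearson correlation and
#' `R2 = r^2` of the (prediction, label) pairs. Zero-variance predictions
#' make the correlation undefined (`NA` with a warning).
#'
#' @param preds Predicted scores.
#' @param labels True scores.
#' @return A list with `mse`, `mae`, `pearson_r`, `r2`.
#' @export
evaluate_regressor <- function(preds, labels) {
  stopifnot(length(preds) == length(labels), length(preds) >= 3)
  r <- if (sd(preds) == 0 || sd(labels) == 0) {
    warning("correlation undefined: zero-variance predictions or labels")
    NA_real_
  } else cor(preds, labels)
  list(mse = mean((preds - labels)^2), mae = mean(abs(preds - labels)),
       pearson_r = r, r2 = r^2)
}
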