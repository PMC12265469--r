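#' Damage labels from a leaf-area damage fraction
#'
#' Maps the fraction of leaf area removed by herbivory to the two label
#' systems used throughout the package: a binary severe/mild label (severe
#' iff strictly more than 25% of the leaf area is damaged) and a 1-5
#' severity class in 20% steps (class 1 covers up to 20% damage, each
#' further 20% adds one class, class 5 is damage above 80%).
#'
#' The two rules intentionally use different thresholds: a leaf with 22%
#' damage is binary-mild (0) but severity class 2. There is no severity
#' class 0; an untouched leaf is class 1.
#'
#' @param f Numeric vector of damage fractions in \[0, 1\].
#' @return A list with integer vectors `binary` (0/1) and `severity` (1-5).
#' @examples
#' label_from_fraction(c(0.1, 0.25, 0.85))
#' @export
label_from_fraction <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  if (any(f < 0 | f > 1)) stop("damage fraction must be in [0, 1]")
  binary <- as.integer(f > 0.25)
  ## small epsilon keeps exact bin edges (0.4/0.2 = 2 + 2e-16 in floating
  ## point) in their closed-upper bin
  severity <- pmin(5L, pmax(1L, as.integer(ceiling(f / 0.2 - 1e-9))))
  list(binary = binary, severity = severity)
}

#' Render a synthetic damaged leaf image
#'
#' Draws a green elliptical leaf with a midrib, lateral veins and low-frequency
#' colour mottling on a contrasting soil-coloured background, then removes
#' randomly placed background-coloured holes (clipped to the leaf mask) until
#' the realized damaged area divided by the total leaf area is within
#' +/- 0.02 of `damage_fraction`. The renderer emulates the post-detection
#' crops a leaf detector would produce, so the leaf fills most of the frame.
#'
#' Only the area contract matters downstream: the binary and severity labels
#' attached to the image are computed from the *realized* fraction via
#' [label_from_fraction()], and the ground-truth mask and fraction are kept
#' so that trained scoring models can be validated against truth.
#'
#' @param damage_fraction Requested damaged-area fraction in \[0, 0.95\].
#' @param size Image side length in pixels (square image, >= 32).
#' @param seed Integer seed; the same seed gives a bit-identical image.
#' @param accession_id Optional accession identifier carried in the object.
#' @return An object of class `leaf_image`: a list with `pixels`
#'   (`size x size x 3` array in \[0,1\]), `leaf_mask` (logical matrix),
#'   `damage_fraction` (realized), `binary_label`, `severity_class`,
#'   `accession_id` and `seed`.
#' @examples
#' leaf <- generate_leaf_image(0.3, size = 64, seed = 1)
#' leaf$damage_fraction
#' @export
generate_leaf_image <- function(damage_fraction, size = 64L, seed = NULL,
                                accession_id = NA_character_) {
  stopifnot(length(damage_fraction) == 1, is.finite(damage_fraction))
  if (damage_fraction < 0 || damage_fraction > 0.95)
    stop("damage_fraction must be in [0, 0.95]")
  if (size < 32) stop("size must be >= 32")
  size <- as.integer(size)

  with_seed(seed, {
    h <- size; w <- size
    yy <- matrix(seq_len(h), h, w)          # row coordinate
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)

    ## --- background: mottled soil ---
    bg_base <- c(0.50, 0.40, 0.28) + runif(3, -0.06, 0.06)
    bg_noise <- matrix(runif(h * w, -0.05, 0.05), h, w)
    px <- array(0, c(h, w, 3))
    for (c3 in 1:3) px[, , c3] <- bg_base[c3] + bg_noise

    ## --- leaf ellipse ---
    cx <- w / 2 + runif(1, -0.03, 0.03) * w
    cy <- h / 2 + runif(1, -0.03, 0.03) * h
    a <- runif(1, 0.40, 0.46) * w           # semi-major
    b <- runif(1, 0.28, 0.36) * h           # semi-minor
    th <- runif(1, 0, pi)
    xr <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    yr <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    leaf_mask <- (xr / a)^2 + (yr / b)^2 <= 1
    leaf_area <- sum(leaf_mask)

    ## --- leaf colouring: green base + mottling + veins ---
    green <- c(0.16, 0.46, 0.13) + runif(3, -0.04, 0.04)
    ph <- runif(3, 0, 2 * pi); fr <- runif(3, 1.5, 4)
    mottle <- 0
    for (k in 1:3)
      mottle <- mottle + sin(2 * pi * fr[k] * (xr / w) + ph[k]) *
                         cos(2 * pi * fr[k] * (yr / h) + ph[k]) / 3
    mottle <- 0.06 * mottle
    ## midrib along the major axis and lateral veins branching off it
    vein <- exp(-(yr / 1.2)^2)
    lat_spacing <- a / 4.5
    lat <- exp(-((abs(yr) - abs(xr %% lat_spacing - lat_spacing / 2) * 0.9)^2) / 8)
    vein <- pmin(1, vein + 0.55 * lat)
    for (c3 in 1:3) {
      col <- green[c3] * (1 + mottle) * (1 - 0.35 * vein)
      px[, , c3][leaf_mask] <- col[leaf_mask]
    }

    ## --- holes: background-coloured blobs clipped to the leaf ---
    hole_mask <- matrix(FALSE, h, w)
    target <- damage_fraction
    if (target > 0) {
      leaf_idx <- which(leaf_mask)
      for (iter in 1:400) {
        realized <- sum(hole_mask) / leaf_area
        if (realized >= target - 0.01) break
        remaining_px <- (target - realized) * leaf_area
        ctr <- leaf_idx[sample.int(length(leaf_idx), 1)]
        hcy <- (ctr - 1) %% h + 1
        hcx <- (ctr - 1) %/% h + 1
        r <- max(1, sqrt(remaining_px / pi) * runif(1, 0.35, 0.95))
        ## irregular blob: ellipse-ish hole with random eccentricity/rotation
        er <- runif(1, 0.6, 1); hth <- runif(1, 0, pi)
        repeat {
          hxr <- (xx - hcx) * cos(hth) + (yy - hcy) * sin(hth)
          hyr <- -(xx - hcx) * sin(hth) + (yy - hcy) * cos(hth)
          disk <- (hxr / r)^2 + (hyr / (r * er))^2 <= 1
          cand <- disk & leaf_mask & !hole_mask
          new_realized <- (sum(hole_mask) + sum(cand)) / leaf_area
          if (new_realized <= target + 0.015 || r <= 1) {
            if (new_realized <= target + 0.015) hole_mask <- hole_mask | cand
            break
          }
          r <- r * 0.8
        }
      }
    }
    realized <- sum(hole_mask) / leaf_area
    if (target > 0 && abs(realized - target) > 0.02)
      stop("leaf renderer failed to reach the requested damage fraction")

    if (any(hole_mask)) {
      hn <- matrix(runif(h * w, -0.05, 0.05), h, w)
      for (c3 in 1:3) {
        bgc <- bg_base[c3] * 0.92 + hn      # holes slightly darker than bg
        px[, , c3][hole_mask] <- bgc[hole_mask]
      }
    }
    px[px < 0] <- 0; px[px > 1] <- 1

    lab <- label_from_fraction(realized)
    structure(list(
      pixels = px, leaf_mask = leaf_mask, hole_mask = hole_mask,
      damage_fraction = realized, binary_label = lab$binary,
      severity_class = lab$severity, accession_id = accession_id,
      seed = seed), class = "leaf_image")
  })
}

#' @export
print.leaf_image <- function(x, ...) {
  cat(sprintf("leaf_image: %dx%d px, damage %.3f, binary %d, severity %d\n",
              nrow(x$leaf_mask), ncol(x$leaf_mask), x$damage_fraction,
              x$binary_label, x$severity_class))
  invisible(x)
}

#' Generate a batch of synthetic leaves
#'
#' Convenience wrapper around [generate_leaf_image()]. Damage fractions
#' default to independent uniform draws on \[0, 0.95\] (the distribution of
#' real damage is unknown; uniform exercises the whole label range).
#'
#' @param n Number of leaves.
#' @param size Image side length in pixels.
#' @param seed Master seed; each leaf gets a derived child seed.
#' @param fractions Optional vector of requested damage fractions (length `n`
#'   or recycled).
#' @param accession_ids Optional accession ids (recycled to length `n`).
#' @return A list of `leaf_image` objects.
#' @export
generate_leaf_dataset <- function(n, size = 64L, seed = 1L, fractions = NULL,
                                  accession_ids = NA_character_) {
  stopifnot(n >= 1)
  if (is.null(fractions))
    fractions <- with_seed(derive_seed(seed, 0L), runif(n, 0, 0.95))
  fractions <- rep_len(fractions, n)
  accession_ids <- rep_len(accession_ids, n)
  lapply(seq_len(n), function(i)
    generate_leaf_image(fractions[i], size = size,
                        seed = derive_seed(seed, i),
                        accession_id = accession_ids[i]))
}

#' Write a leaf dataset as PNG files plus a sidecar TSV
#'
#' Writes each image as `leaf_<i>.png` and a sidecar table
#' (`image_path`, `accession_id`, `damage_fraction`, `binary_label`,
#' `severity_class`) alongside.
#'
#' @param leaves A list of `leaf_image` objects.
#' @param dir Output directory (created if needed).
#' @param sidecar Filename of the sidecar TSV inside `dir`.
#' @return Invisibly, the sidecar data frame.
#' @export
write_leaf_dataset <- function(leaves, dir, sidecar = "leaves.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("leaf_%04d.png", seq_along(leaves))
  for (i in seq_along(leaves))
    png::writePNG(leaves[[i]]$pixels, file.path(dir, paths[i]))
  sc <- data.frame(
    image_path = paths,
    accession_id = vapply(leaves, function(l) l$accession_id, character(1)),
    damage_fraction = vapply(leaves, function(l) l$damage_fraction, numeric(1)),
    binary_label = vapply(leaves, function(l) l$binary_label, integer(1)),
    severity_class = vapply(leaves, function(l) l$severity_class, integer(1)),
    stringsAsFactors = FALSE)
  write_tsv(sc, file.path(dir, sidecar))
  invisible(sc)
}

#' Read a leaf dataset written by [write_leaf_dataset()]
#'
#' @param dir Directory containing PNGs and the sidecar TSV.
#' @param sidecar Sidecar filename.
#' @return A list with `images` (list of H x W x 3 arrays) and `table`
#'   (the sidecar data frame).
#' @export
read_leaf_dataset <- function(dir, sidecar = "leaves.tsv") {
  sc <- read.delim(file.path(dir, sidecar), stringsAsFactors = FALSE)
  imgs <- lapply(sc$image_path, function(p) png::readPNG(file.path(dir, p)))
  list(images = imgs, table = sc)
}

# TSV writer shared by all modules: fixed formatting so identical inputs give
# byte-identical files (the determinism contract of the pipeline stages).
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
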