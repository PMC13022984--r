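# Dataset I/O, stratified splitting, preprocessing, augmentation, and the
# synthetic six-category fixture generator that emulates category-dependent
# texture, contrast and lesion-scale structure of H&E-stained colorectal
# sections, so the whole pipeline runs offline.

#' Synthetic dataset configuration
#'
#' Per-category texture specifications: dominant background frequency band
#' (cycles relative to Nyquist), lesion contrast, lesion count and radius
#' range (fraction of image size), and boundary style. The defaults are the
#' package's fixed study conditions: the low-grade-IN-like category is the
#' low-contrast one (contrast 0.10 against noise sd 0.07), Normal-like
#' images are 70% lesion-free otherwise carrying a faint blob (contrast
#' 0.05), and the remaining categories are high-contrast (0.30-0.45).
#' @param n_per_category images per category
#' @param size square image size in pixels (64 for tests, 256 for demos)
#' @param seed integer seed; the generator is fully reproducible
#' @return a `synth_config` list
#' @export
synth_config <- function(n_per_category = 10L, size = 64L, seed = 1L) {
  specs <- list(
    "Normal" = list(band = c(0.35, 0.7), contrast = 0.05, n_lesions = 0:1,
                    radius = c(0.18, 0.30), style = "smooth",
                    lesion_prob = 0.3),
    "Polyp" = list(band = c(0.05, 0.25), contrast = 0.45, n_lesions = 1:2,
                   radius = c(0.15, 0.28), style = "smooth",
                   lesion_prob = 1),
    "Low-grade IN" = list(band = c(0.02, 0.15), contrast = 0.10,
                          n_lesions = 2:4, radius = c(0.08, 0.16),
                          style = "smooth", lesion_prob = 1),
    "High-grade IN" = list(band = c(0.10, 0.40), contrast = 0.40,
                           n_lesions = 3:6, radius = c(0.05, 0.12),
                           style = "smooth", lesion_prob = 1),
    "Serrated adenoma" = list(band = c(0.05, 0.30), contrast = 0.45,
                              n_lesions = 1:2, radius = c(0.15, 0.28),
                              style = "serrated", lesion_prob = 1),
    "Adenocarcinoma" = list(band = c(0.08, 0.35), contrast = 0.30,
                            n_lesions = 1:3, radius = c(0.12, 0.25),
                            style = "irregular", lesion_prob = 1))
  structure(list(n_per_category = as.integer(n_per_category),
                 size = as.integer(size), seed = as.integer(seed),
                 noise_sd = 0.07, specs = specs),
            class = "synth_config")
}

band_noise <- function(size, band, stream) {
  # seeded noise with energy concentrated in a radial frequency band
  z <- matrix(stream_rnorm(stream, size * size), size)
  sp <- stats::fft(z)
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  rad <- sqrt(outer(fr^2, fr^2, "+")) / 0.5   # 0..~1.4 of Nyquist
  mask <- exp(-((rad - mean(band)) / (diff(band) / 2 + 0.05))^2)
  out <- Re(stats::fft(sp * mask, inverse = TRUE)) / (size * size)
  out / max(stats::sd(out), 1e-8)
}

blob_mask <- function(size, cx, cy, r, style, stream) {
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  ang <- atan2(ys - cy, xs - cx)
  rho <- sqrt((xs - cx)^2 + (ys - cy)^2)
  rmod <- switch(style,
    smooth = {
      a <- stream_runif(stream, 2, -0.15, 0.15)
      ph <- stream_runif(stream, 2, 0, 2 * pi)
      r * (1 + a[1] * cos(2 * ang + ph[1]) + a[2] * cos(3 * ang + ph[2]))
    },
    serrated = {
      # saw-toothed glandular outline: high-order angular scalloping
      ph <- stream_runif(stream, 1, 0, 2 * pi)
      a <- stream_runif(stream, 1, -0.1, 0.1)
      r * (1 + 0.18 * cos(9 * ang + ph) + a * cos(2 * ang))
    },
    irregular = {
      a <- stream_runif(stream, 3, -0.25, 0.25)
      ph <- stream_runif(stream, 3, 0, 2 * pi)
      r * (1 + a[1] * cos(2 * ang + ph[1]) + a[2] * cos(3 * ang + ph[2]) +
             a[3] * cos(5 * ang + ph[3]))
    })
  (rho <= rmod) * 1
}

#' Generate a synthetic six-category dataset
#'
#' Backgrounds are seeded colored noise at a category-specific dominant
#' band over an H&E-like base tint; lesions are smoothed random blobs
#' (count, radius and boundary style from the category spec; serrated
#' adenoma-like lesions carry a scalloped outline) whose interior receives a
#' contrast shift plus a distinct texture band. The mask is the exact blob
#' support.
#' @param cfg a [synth_config()]
#' @return list of sample pairs; each has `image` (`(H, W, 3)` array in
#'   `[0, 1]`), `mask` (binary matrix), `category`, `id`
#' @export
generate_synthetic <- function(cfg = synth_config()) {
  out <- list()
  cats <- histoseg_categories()
  for (ci in seq_along(cats)) {
    cat_ <- cats[ci]
    spec <- cfg$specs[[cat_]]
    for (i in seq_len(cfg$n_per_category)) {
      stream <- rng_stream(cfg$seed + 7919L * ci + 131L * i)
      size <- cfg$size
      bg <- band_noise(size, spec$band, stream)
      mask <- matrix(0, size, size)
      has_lesion <- stream_runif(stream, 1) < spec$lesion_prob
      if (has_lesion && max(spec$n_lesions) > 0) {
        nl <- if (length(spec$n_lesions) > 1)
          stream_sample(stream, spec$n_lesions, 1L) else spec$n_lesions
        for (k in seq_len(nl)) {
          r <- stream_runif(stream, 1, spec$radius[1], spec$radius[2]) * size
          cx <- stream_runif(stream, 1, 0.2 * size, 0.8 * size)
          cy <- stream_runif(stream, 1, 0.2 * size, 0.8 * size)
          mask <- pmax(mask, blob_mask(size, cx, cy, r, spec$style, stream))
        }
      }
      # lesion interior: contrast shift + its own texture band
      les_tex <- band_noise(size, pmin(spec$band + 0.3, c(0.6, 1)), stream)
      lum <- 0.55 + 0.10 * bg +
        mask * (spec$contrast + 0.05 * les_tex) +
        cfg$noise_sd * matrix(stream_rnorm(stream, size * size), size)
      lum <- pmin(pmax(lum, 0), 1)
      # H&E-like tint: purple-pink background, darker lesion
      img <- array(0, c(size, size, 3L))
      img[, , 1] <- pmin(pmax(0.75 * lum + 0.15, 0), 1)
      img[, , 2] <- pmin(pmax(0.55 * lum, 0), 1)
      img[, , 3] <- pmin(pmax(0.80 * lum + 0.10, 0), 1)
      out[[length(out) + 1L]] <-
        list(image = img, mask = mask, category = cat_,
             id = sprintf("%s_%03d", gsub("[^A-Za-z]", "", cat_), i))
    }
  }
  out
}

#' Load an image/mask dataset from a category-folder tree
#'
#' Expects `root/<category>/images/*.png|jpg` with name-matched masks in
#' `root/<category>/masks/` (same stem; an optional suffix such as `_mask`
#' is accepted via `mask_suffix`). Masks are 8-bit images binarized at
#' threshold 127. Unpaired images are skipped with a warning.
#' @param root dataset root directory
#' @param mask_suffix optional stem suffix of mask files
#' @return list of sample pairs as in [generate_synthetic()]
#' @export
load_dataset <- function(root, mask_suffix = "") {
  if (!dir.exists(root)) stop("dataset root not found: ", root, call. = FALSE)
  cats <- list.dirs(root, recursive = FALSE)
  out <- list()
  skipped <- 0L
  for (cd in cats) {
    cat_ <- basename(cd)
    imgs <- list.files(file.path(cd, "images"),
                       pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                       full.names = TRUE)
    for (ip in imgs) {
      stem <- tools::file_path_sans_ext(basename(ip))
      cand <- list.files(file.path(cd, "masks"),
                         pattern = paste0("^", stem, mask_suffix,
                                          "\\.(png|jpg|jpeg)$"),
                         ignore.case = TRUE, full.names = TRUE)
      if (length(cand) == 0L) { skipped <- skipped + 1L; next }
      img <- EBImage::imageData(EBImage::readImage(ip))
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      img <- aperm(img[, , 1:3, drop = FALSE], c(2L, 1L, 3L))  # to (row, col)
      mk <- EBImage::imageData(EBImage::readImage(cand[[1L]]))
      if (length(dim(mk)) == 3L) mk <- mk[, , 1L]
      mk <- t(mk)
      mask <- (mk * 255 > 127) * 1
      out[[length(out) + 1L]] <- list(image = img, mask = mask,
                                      category = cat_, id = stem)
    }
  }
  if (skipped > 0L)
    warning(skipped, " image(s) without a mask partner were skipped")
  attr(out, "n_skipped") <- skipped
  out
}

#' Write a sample list as a category-folder dataset
#' @param samples list of sample pairs
#' @param root output directory
#' @return invisibly, `root`
#' @export
write_dataset <- function(samples, root) {
  for (s in samples) {
    idir <- file.path(root, s$category, "images")
    mdir <- file.path(root, s$category, "masks")
    dir.create(idir, recursive = TRUE, showWarnings = FALSE)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    img <- EBImage::Image(aperm(s$image, c(2L, 1L, 3L)), colormode = "Color")
    EBImage::writeImage(img, file.path(idir, paste0(s$id, ".png")))
    EBImage::writeImage(EBImage::Image(t(s$mask)),
                        file.path(mdir, paste0(s$id, ".png")))
  }
  invisible(root)
}

#' Stratified train/val/test split
#'
#' Per-category seeded shuffling; validation and test sizes are rounded
#' shares of the category count and the training set absorbs remainders.
#' Categories with fewer than 3 samples go entirely to training with a
#' warning.
#' @param samples sample list
#' @param ratios positive weights for (train, val, test); default 8:1:1
#' @param seed integer seed
#' @return the samples with a `split` field added
#' @export
stratified_split <- function(samples, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(all(ratios > 0))
  cats <- vapply(samples, function(s) s$category, character(1))
  total <- sum(ratios)
  for (cat_ in unique(cats)) {
    idx <- which(cats == cat_)
    n <- length(idx)
    if (n < 3L) {
      warning("category ", cat_, " has fewer than 3 samples; all to train")
      for (i in idx) samples[[i]]$split <- "train"
      next
    }
    stream <- rng_stream(seed + utf8ToInt(substr(cat_, 1L, 1L)))
    perm <- stream_sample(stream, idx)
    n_val <- max(1L, round(n * ratios[2] / total))
    n_test <- max(1L, round(n * ratios[3] / total))
    split <- rep("train", n)
    split[seq_len(n_val)] <- "val"
    split[n_val + seq_len(n_test)] <- "test"
    for (j in seq_len(n)) samples[[perm[j]]]$split <- split[j]
  }
  samples
}

#' Resize and scale a sample
#'
#' Bilinear resize for the image, nearest-neighbor for the mask (so it stays
#' binary); intensities clamped to `[0, 1]`.
#' @param sample a sample pair
#' @param size target square size
#' @return the resized sample
#' @export
preprocess <- function(sample, size = 256L) {
  d <- dim(sample$mask)
  if (all(d == size)) return(sample)
  img <- EBImage::resize(EBImage::Image(aperm(sample$image, c(2L, 1L, 3L)),
                                        colormode = "Color"),
                         w = size, h = size)
  msk <- EBImage::resize(EBImage::Image(t(sample$mask)),
                         w = size, h = size, filter = "none")
  sample$image <- pmin(pmax(aperm(EBImage::imageData(img), c(2L, 1L, 3L)),
                            0), 1)
  sample$mask <- (t(EBImage::imageData(msk)) > 0.5) * 1
  sample
}

rotate_nearest_map <- function(size, angle_deg) {
  # integer source indices of an inverse rotation about the image center,
  # reflected at the borders (usable both as an augmentation and to invert
  # predictions for the consistency loss)
  th <- angle_deg * pi / 180
  ctr <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size)   # cols
  ys <- matrix(rep(seq_len(size), times = size), size)  # rows
  sx <- ctr + cos(th) * (xs - ctr) - sin(th) * (ys - ctr)
  sy <- ctr + sin(th) * (xs - ctr) + cos(th) * (ys - ctr)
  reflect1 <- function(v) {
    v <- abs(v - 1) + 1
    v <- size - abs(size - v)
    pmin(pmax(round(v), 1L), size)
  }
  list(r = reflect1(sy), c = reflect1(sx))
}

rotate_bilinear <- function(m, angle_deg) {
  size <- nrow(m)
  th <- angle_deg * pi / 180
  ctr <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  sx <- ctr + cos(th) * (xs - ctr) - sin(th) * (ys - ctr)
  sy <- ctr + sin(th) * (xs - ctr) + cos(th) * (ys - ctr)
  reflectf <- function(v) {
    v <- abs(v - 1) + 1
    size - abs(size - v)
  }
  sx <- reflectf(sx); sy <- reflectf(sy)
  x0 <- pmin(pmax(floor(sx), 1), size - 1); y0 <- pmin(pmax(floor(sy), 1), size - 1)
  wx <- sx - x0; wy <- sy - y0
  at <- function(r, c) m[cbind(as.vector(r), as.vector(c))]
  v <- (1 - wx) * (1 - wy) * at(y0, x0) + wx * (1 - wy) * at(y0, x0 + 1) +
    (1 - wx) * wy * at(y0 + 1, x0) + wx * wy * at(y0 + 1, x0 + 1)
  matrix(v, size, size)
}

#' Random augmentation of a sample
#'
#' Rotation by Uniform(-15, 15) degrees (bilinear for the image, nearest for
#' the mask, reflection padding), horizontal flip with probability 1/2, and
#' a brightness offset Uniform(-0.2, 0.2) added to the image and clipped to
#' `[0, 1]` (the mask is unaffected by brightness). The drawn parameters are
#' attached as the `params` attribute so geometric transforms can be
#' inverted (consistency regularization).
#' @param sample a sample pair
#' @param stream an [rng_stream()] (or integer seed)
#' @return augmented sample with attribute `params`
#' @export
augment <- function(sample, stream = rng_stream(1L)) {
  if (is.numeric(stream)) stream <- rng_stream(stream)
  angle <- stream_runif(stream, 1, -15, 15)
  flip <- stream_runif(stream, 1) < 0.5
  bright <- stream_runif(stream, 1, -0.2, 0.2)
  size <- nrow(sample$mask)
  img <- sample$image
  for (ch in 1:3) img[, , ch] <- rotate_bilinear(img[, , ch], angle)
  map <- rotate_nearest_map(size, angle)
  msk <- matrix(sample$mask[cbind(as.vector(map$r), as.vector(map$c))],
                size, size)
  if (flip) {
    img <- img[, rev(seq_len(size)), , drop = FALSE]
    msk <- msk[, rev(seq_len(size)), drop = FALSE]
  }
  img <- pmin(pmax(img + bright, 0), 1)
  sample$image <- img
  sample$mask <- msk
  attr(sample, "params") <- list(angle = angle, flip = flip,
                                 brightness = bright)
  sample
}

#' Stack samples into image/mask batch arrays
#' @param samples list of sample pairs (equal sizes)
#' @return list with `x` (`(H, W, 3, N)`) and `y` (`(H, W, N)`)
#' @export
batch_arrays <- function(samples) {
  d <- dim(samples[[1]]$image)
  N <- length(samples)
  x <- array(0, c(d[1], d[2], 3L, N))
  y <- array(0, c(d[1], d[2], N))
  for (i in seq_len(N)) {
    x[, , , i] <- samples[[i]]$image
    y[, , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

#' Threshold baseline segmentation
#'
#' Otsu threshold on the green channel (lesions are darker/brighter than the
#' tinted background); picks the polarity with the larger foreground
#' contrast. A deliberately trivial reference against which the synthetic
#' benchmark's difficulty is calibrated.
#' @param image `(H, W, 3)` array
#' @return binary mask matrix
#' @export
threshold_baseline <- function(image) {
  g <- image[, , 2]
  th <- EBImage::otsu(EBImage::Image(t(g)), range = c(0, 1))
  m1 <- (g > th) * 1
  # choose the polarity covering less than half the image (lesions are the
  # minority class)
  if (mean(m1) > 0.5) m1 <- 1 - m1
  m1
}

#' Write a split manifest CSV
#' @param samples samples carrying `split` fields
#' @param path output CSV path
#' @param seed seed recorded alongside
#' @export
write_split_manifest <- function(samples, path, seed = NA) {
  df <- data.frame(id = vapply(samples, function(s) s$id, character(1)),
                   category = vapply(samples, function(s) s$category,
                                     character(1)),
                   split = vapply(samples, function(s)
                     s$split %||% NA_character_, character(1)),
                   seed = seed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
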