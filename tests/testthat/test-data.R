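# Synthetic generator, dataset round trip, stratified splitting,
# preprocessing and augmentation.

test_that("the generator is seeded-deterministic and category-complete", {
  cfg <- synth_config(5L, 32L, seed = 19L)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_length(a, 30L)
  expect_identical(a, b)
  expect_setequal(unique(vapply(a, function(s) s$category, character(1))),
                  histoseg_categories())
  for (s in a) {
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_equal(dim(s$image), c(32L, 32L, 3L))
  }
})

test_that("low-contrast category has lower lesion contrast than the
           high-contrast ones", {
  samples <- generate_synthetic(synth_config(20L, 32L, seed = 23L))
  contrast <- function(cat_) {
    ss <- Filter(function(s) s$category == cat_ && sum(s$mask) > 0 &&
                   sum(1 - s$mask) > 0, samples)
    mean(vapply(ss, function(s) {
      lum <- 0.2 * s$image[, , 1] + 0.7 * s$image[, , 2] +
        0.1 * s$image[, , 3]
      abs(mean(lum[s$mask == 1]) - mean(lum[s$mask == 0]))
    }, numeric(1)))
  }
  expect_lt(contrast("Low-grade IN"), contrast("Polyp"))
  expect_lt(contrast("Low-grade IN"), contrast("Serrated adenoma"))
})

test_that("threshold baseline separates high-contrast categories but fails
           on the low-contrast one", {
  samples <- generate_synthetic(synth_config(10L, 64L, seed = 7L))
  base_dice <- function(cat_) {
    ss <- Filter(function(s) s$category == cat_ && sum(s$mask) > 0, samples)
    mean(vapply(ss, function(s)
      overlap_metrics(threshold_baseline(s$image), s$mask)$dice,
      numeric(1)))
  }
  expect_gte(base_dice("Polyp"), 0.6)
  expect_gte(base_dice("Serrated adenoma"), 0.6)
  expect_lt(base_dice("Low-grade IN"), 0.4)
})

test_that("dataset writes and loads through the category-folder layout", {
  td <- withr::local_tempdir()
  samples <- generate_synthetic(synth_config(2L, 32L, seed = 3L))[1:6]
  write_dataset(samples, td)
  back <- load_dataset(td)
  expect_length(back, 6L)
  ids <- vapply(back, function(s) s$id, character(1))
  for (s in samples) {
    match_ <- back[[which(ids == s$id)]]
    expect_equal(match_$category, s$category)
    expect_equal(match_$mask, s$mask)
    expect_lt(max(abs(match_$image - s$image)), 0.01)  # 8-bit quantization
  }
  # an unpaired image is skipped with a warning
  extra <- file.path(td, "Polyp", "images", "orphan.png")
  EBImage::writeImage(EBImage::Image(matrix(0.5, 32, 32)), extra)
  expect_warning(back2 <- load_dataset(td), "skipped")
  expect_equal(attr(back2, "n_skipped"), 1L)
})

test_that("stratified split follows 8:1:1 with train absorbing remainders", {
  samples <- generate_synthetic(synth_config(10L, 32L, seed = 5L))
  sp <- stratified_split(samples, seed = 9L)
  for (cat_ in histoseg_categories()) {
    splits <- vapply(Filter(function(s) s$category == cat_, sp),
                     function(s) s$split, character(1))
    expect_equal(sum(splits == "train"), 8L)
    expect_equal(sum(splits == "val"), 1L)
    expect_equal(sum(splits == "test"), 1L)
  }
  sp2 <- stratified_split(samples, seed = 9L)
  expect_identical(vapply(sp, function(s) s$split, character(1)),
                   vapply(sp2, function(s) s$split, character(1)))
  # 100 samples of one category -> 80/10/10
  one <- lapply(1:100, function(i)
    list(image = array(0, c(4, 4, 3)), mask = matrix(0, 4, 4),
         category = "Polyp", id = as.character(i)))
  so <- stratified_split(one, seed = 2L)
  expect_equal(as.vector(table(vapply(so, function(s) s$split,
                                      character(1)))[c("train", "val",
                                                       "test")]),
               c(80L, 10L, 10L))
  tiny <- one[1:2]
  expect_warning(st_ <- stratified_split(tiny, seed = 2L), "fewer than 3")
  expect_true(all(vapply(st_, function(s) s$split, character(1)) == "train"))
})

test_that("preprocess resizes images bilinearly and masks to binary", {
  s <- generate_synthetic(synth_config(1L, 64L, seed = 13L))[[2]]
  expect_gt(sum(s$mask), 0)
  r <- preprocess(s, 32L)
  expect_equal(dim(r$image), c(32L, 32L, 3L))
  expect_true(all(r$mask %in% c(0, 1)))
  expect_gt(sum(r$mask), 0)
  same <- preprocess(s, 64L)
  expect_identical(same$image, s$image)
})

test_that("augmentation is seeded, mask-safe and parameter-recoverable", {
  s <- generate_synthetic(synth_config(1L, 64L, seed = 17L))[[2]]
  a1 <- augment(s, rng_stream(5L))
  a2 <- augment(s, rng_stream(5L))
  expect_identical(a1$image, a2$image)
  expect_true(all(a1$mask %in% c(0, 1)))
  pars <- attr(a1, "params")
  expect_true(abs(pars$angle) <= 15)
  expect_true(abs(pars$brightness) <= 0.2)
  # brightness clipping: +0.2 on a 0.9 pixel saturates at 1
  expect_equal(min(pmin(0.9 + 0.2, 1)), 1)
  expect_true(max(a1$image) <= 1 && min(a1$image) >= 0)
  # flip is an involution on the mask
  flipped <- s
  flipped$mask <- s$mask[, rev(seq_len(ncol(s$mask)))]
  twice <- flipped$mask[, rev(seq_len(ncol(s$mask)))]
  expect_identical(twice, s$mask)
})

test_that("rotating a centered disk by 15 degrees changes its area by less
           than 15 percent", {
  size <- 64L
  disk <- matrix(0, size, size)
  disk[outer((1:size - 32.5)^2, (1:size - 32.5)^2, "+") <= 15^2] <- 1
  map <- histoseg:::rotate_nearest_map(size, 15)
  rot <- matrix(disk[cbind(as.vector(map$r), as.vector(map$c))], size)
  expect_true(all(rot %in% c(0, 1)))
  expect_lt(abs(sum(rot) - sum(disk)) / sum(disk), 0.15)
})
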