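# Frequency/texture enhancement block: band-mask partition against a grid
# enumeration oracle, Fourier identity and linearity, Gabor bank geometry,
# the hard-LBP oracle vs the learnable layer's initialization, preset
# mixing, and the residual fusion arithmetic.

test_that("band masks partition every grid up to 64 x 64", {
  for (dims in list(c(1L, 1L), c(5L, 9L), c(16L, 16L), c(17L, 32L),
                    c(64L, 64L))) {
    bm <- build_band_masks(dims[1], dims[2])
    expect_true(all(bm$low + bm$mid + bm$high == 1))
  }
  # brute-force enumeration oracle on the 16 x 16 grid
  bm <- build_band_masks(16L, 16L)
  s <- sqrt(16^2 + 16^2)
  cnt <- 0L
  for (u in 0:15) for (v in 0:15)
    if (sqrt((u - 8)^2 + (v - 8)^2) < 0.15 * s) cnt <- cnt + 1L
  expect_equal(sum(bm$low), cnt)
  # DC bin sits at the (0-based) floor(H/2) center and is always low
  expect_equal(bm$low[9, 9], 1)
  expect_equal(attr(bm, "r1"), 0.15 * s)
})

test_that("frequency enhancement is the identity at unit multipliers and
           linear in its input", {
  m <- afetam_new(3L, rng_stream(2L))
  m$theta$v <- rep(1e9, 3)   # sigmoid -> 1
  x <- tiny_feature(16L, 16L, 3L, 2L, seed = 5L)
  y <- frequency_enhance(m, x, c(1, 1, 1))
  expect_lt(max(abs(y$v - x)) / max(abs(x)), 1e-4)
  # all-zero multipliers annihilate
  expect_lt(max(abs(frequency_enhance(m, x, c(0, 0, 0))$v)), 1e-12)
  # linearity: f(a x + b z) = a f(x) + b f(z)
  m$theta$v <- c(0.3, -0.2, 0.5)
  z <- tiny_feature(16L, 16L, 3L, 2L, seed = 6L)
  lhs <- frequency_enhance(m, 2 * x - 3 * z, c(0.7, 1, 0.4))$v
  rhs <- 2 * frequency_enhance(m, x, c(0.7, 1, 0.4))$v -
    3 * frequency_enhance(m, z, c(0.7, 1, 0.4))$v
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_error(frequency_enhance(m, x, c(-1, 1, 1)), "nonnegative")
})

test_that("the highest representable frequencies follow the literal band
           radii", {
  # Under the literal cut radii (r2 = 0.45 sqrt(H^2 + W^2)), an axis-aligned
  # Nyquist cosine (period 2 px along rows) sits at distance H/2 = 8 < r2
  # from the center: the mask enumerator places it in the MID band. Only
  # diagonal corner frequencies (d = sqrt(2) H / 2) reach the high band.
  H <- 16L
  bm <- build_band_masks(H, H)
  cosine <- matrix(rep(cos(pi * (0:(H - 1))), times = H), H)
  sp <- histoseg:::fftshift2(stats::fft(cosine))
  hot <- which(Mod(sp) > 1e-6, arr.ind = TRUE)
  for (k in seq_len(nrow(hot)))
    expect_equal(bm$mid[hot[k, 1], hot[k, 2]], 1)
  m <- afetam_new(1L, rng_stream(3L))
  m$theta$v <- rep(1e9, 3)
  # so the axis-aligned Nyquist cosine is removed by zeroing the mid band
  y <- frequency_enhance(m, array(cosine, c(H, H, 1L, 1L)), c(1, 0, 1))
  expect_lt(max(abs(y$v)), 1e-10)
  # while the diagonal checkerboard (corner frequency, d = 11.3 >= r2)
  # is removed by zeroing the high band
  diagcb <- outer(0:(H - 1), 0:(H - 1), function(i, j) cos(pi * (i + j)))
  sp2 <- histoseg:::fftshift2(stats::fft(diagcb))
  hot2 <- which(Mod(sp2) > 1e-6, arr.ind = TRUE)
  for (k in seq_len(nrow(hot2)))
    expect_equal(bm$high[hot2[k, 1], hot2[k, 2]], 1)
  y2 <- frequency_enhance(m, array(diagcb, c(H, H, 1L, 1L)), c(1, 1, 0))
  expect_lt(max(abs(y2$v)), 1e-10)
})

test_that("the Gabor bank has 32 kernels with the expected symmetries", {
  bank <- build_gabor_bank()
  expect_length(bank, 32L)
  for (k in bank) {
    sz <- nrow(k$kernel)
    expect_true(all(is.finite(k$kernel)))
    # center value at psi = 0: exp(0) * cos(0) = 1
    expect_equal(k$kernel[(sz + 1) / 2, (sz + 1) / 2], 1)
  }
  # theta and theta + 180 degrees coincide at psi = 0 (even symmetry),
  # leaving at most 16 distinct kernels
  k45 <- gabor_kernel(pi / 4, 4)
  k225 <- gabor_kernel(5 * pi / 4, 4)
  expect_equal(k45, k225)
  # count kernels distinct beyond floating-point jitter (sin(pi) != 0)
  n_distinct <- 0L
  seen <- list()
  for (k in bank) {
    dup <- any(vapply(seen, function(s)
      all(dim(s) == dim(k$kernel)) && max(abs(s - k$kernel)) < 1e-10,
      logical(1)))
    if (!dup) { seen[[length(seen) + 1L]] <- k$kernel
                n_distinct <- n_distinct + 1L }
  }
  expect_lte(n_distinct, 16L)
})

test_that("hard LBP reference codes and rotation invariance", {
  up <- matrix(0, 3, 3); up[2, 2] <- -1
  expect_equal(lbp_reference(up)$code, 255L)
  down <- matrix(0, 3, 3); down[2, 2] <- 5
  expect_equal(lbp_reference(down)$code, 0L)
  # any single set bit rotates down to 1
  for (p in 1:8) {
    nb <- rbind(c(2, 3), c(1, 3), c(1, 2), c(1, 1),
                c(2, 1), c(3, 1), c(3, 2), c(3, 3))
    patch <- matrix(-1, 3, 3); patch[2, 2] <- 0
    patch[nb[p, 1], nb[p, 2]] <- 1
    expect_equal(lbp_reference(patch)$ri_code, 1)
  }
})

test_that("the learnable LBP layer reproduces hard codes at initialization", {
  m <- afetam_new(1L, rng_stream(4L))
  # neighbor-center gaps all exceed the steep sigmoid's soft zone and no
  # two adjacent cells tie: (i + 2j) mod 4 differs on every king-move
  img <- 1.2 * outer(1:10, 1:10, function(i, j) (i + 2 * j) %% 4)
  proj <- ad_const(array(img, c(10, 10, 1, 1)))
  diffs <- ad_conv2d(proj, m$lbp_conv$W, m$lbp_conv$b, pad = 1L)
  soft <- ad_sigmoid(ad_scale(diffs, m$lbp_temperature))
  code <- ad_conv2d(soft, ad_const(array(2^(0:7), c(1, 1, 8, 1))),
                    NULL)$v[, , 1, 1]
  for (i in 2:9) for (j in 2:9) {
    ref <- lbp_reference(img[(i - 1):(i + 1), (j - 1):(j + 1)])$code
    expect_equal(round(code[i, j]), ref)
  }
})

test_that("texture branch: attention responds to local variance", {
  m <- afetam_new(4L, rng_stream(5L))
  # constant input: variance 0, standardized map 0, attention exactly 1/2
  xc <- array(1.3, c(8, 8, 4, 1))
  proj <- histoseg:::mean_channels(histoseg:::as_feature_tensor(xc))
  tvar <- ad_sub(histoseg:::box_mean_5(ad_pow(proj, 2)), ad_pow(histoseg:::box_mean_5(proj), 2))
  expect_lt(max(abs(tvar$v)), 1e-10)
  out_c <- texture_branch(m, xc)
  expect_equal(dim(out_c$v), c(8L, 8L, 4L, 1L))
  # checkerboard: strictly larger 5x5 variance than a constant everywhere
  cb <- array(rep(outer(1:8, 1:8, function(i, j) (i + j) %% 2), 4),
              c(8, 8, 4, 1))
  pcb <- histoseg:::mean_channels(histoseg:::as_feature_tensor(cb))
  vcb <- ad_sub(histoseg:::box_mean_5(ad_pow(pcb, 2)), ad_pow(histoseg:::box_mean_5(pcb), 2))
  expect_true(all(vcb$v[3:6, 3:6, , ] > 1e-4))
  expect_error(texture_branch(m, array(1, c(1, 1, 4, 1))), "2x2")
})

test_that("category detector and preset mixing follow the probability
           algebra", {
  m <- afetam_new(4L, rng_stream(6L))
  p <- category_detector(m, tiny_feature(6L, 6L, 4L, 3L, seed = 7L))
  expect_equal(dim(p$v), c(6L, 3L))
  expect_true(all(p$v > 0))
  expect_equal(colSums(p$v), rep(1, 3), tolerance = 1e-12)
  onehot <- function(i) { v <- rep(0, 6); v[i] <- 1; v }
  expect_equal(as.vector(mix_presets(onehot(1))$v), c(0.3, 0.3, 0.4))
  expect_equal(as.vector(mix_presets(onehot(3))$v), c(0.4, 0.4, 0.2))
  unif <- rep(1 / 6, 6)
  expect_equal(as.vector(mix_presets(unif)$v),
               as.vector(rowMeans(category_presets())))
  expect_error(mix_presets(c(0.5, 0.5, 0.5, 0, 0, 0)), "sum to 1")
})

test_that("residual fusion: identity at zero weights, printed inits,
           shape preservation", {
  m <- afetam_new(4L, rng_stream(8L))
  expect_equal(as.numeric(m$alpha_freq$v), 0.5)
  expect_equal(as.numeric(m$beta_texture$v), 0.5)
  x <- tiny_feature(8L, 8L, 4L, 2L, seed = 9L)
  m$alpha_freq$v <- 0; m$beta_texture$v <- 0
  expect_equal(afetam_forward(m, x)$v, x)
  m$alpha_freq$v <- 0.5; m$beta_texture$v <- 0.5
  out <- afetam_forward(m, x)
  expect_equal(dim(out$v), dim(x))
  # scalar arithmetic of the fusion rule: 1 + 0.5 * 2 + 0.5 * 4 = 4
  f <- ad_const(array(1, c(1, 1, 1, 1)))
  fr <- ad_const(array(2, c(1, 1, 1, 1)))
  tx <- ad_const(array(4, c(1, 1, 1, 1)))
  fused <- ad_add(f, ad_add(ad_smul(fr, m$alpha_freq),
                            ad_smul(tx, m$beta_texture)))
  expect_equal(as.numeric(fused$v), 4)
  # works at the 4 x 4 (1/16 of a 64 px input) insertion size
  expect_equal(dim(afetam_forward(m, tiny_feature(4L, 4L, 4L, 1L))$v),
               c(4L, 4L, 4L, 1L))
})

test_that("band weights start neutral and stay in (0, 1)", {
  m <- afetam_new(4L, rng_stream(9L))
  expect_equal(as.vector(m$theta$v), c(0, 0, 0))
  w <- 1 / (1 + exp(-m$theta$v))
  expect_equal(as.vector(w), rep(0.5, 3))
  m$theta$v <- c(-8, 0, 8)
  w <- 1 / (1 + exp(-m$theta$v))
  expect_true(all(w > 0 & w < 1))
})

test_that("band weights are trainable: high-frequency class evidence drives
           w_high up while w_low does not increase", {
  # two-class task whose evidence is exclusively high-frequency energy
  wins <- 0L
  for (seed in 1:3) {
    st <- rng_stream(900L + seed)
    H <- 16L
    bm <- build_band_masks(H, H)
    make_x <- function(high) {
      base <- histoseg:::band_filter_channel(matrix(stream_rnorm(st, H * H), H), bm$low)
      if (high)
        base <- base + 0.8 * histoseg:::band_filter_channel(
          matrix(stream_rnorm(st, H * H), H), bm$high)
      array(base, c(H, H, 1L, 1L))
    }
    n <- 64L
    labels <- rep(c(0, 1), length.out = n)
    xs <- lapply(labels, function(l) make_x(l == 1))
    m <- afetam_new(1L, st)
    wlin <- ad_param(1)
    blin <- ad_param(0)
    params <- list(m$theta, wlin, blin)
    opt <- adam_new(params, lr = 0.05)
    for (ep in 1:25) for (i in seq_len(n)) {
      en <- ad_mean(ad_pow(frequency_enhance(m, xs[[i]], c(1, 1, 1)), 2))
      logit <- ad_add(ad_smul(en, wlin), blin)
      y <- labels[i]
      p <- ad_sigmoid(logit)
      loss <- ad_scale(ad_add(
        ad_scale(ad_log(p), -y),
        ad_scale(ad_log(ad_sub(ad_const(1 + 1e-8), p)), -(1 - y))), 1)
      ad_backward(loss)
      adam_step(opt)
    }
    w <- 1 / (1 + exp(-m$theta$v))
    if (w[3] > 0.5 && w[1] <= 0.5 + 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
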