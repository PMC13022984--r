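# Multi-scale atrous pyramid block: branch shapes, attention bounds, the
# edge detector's difference-stencil behavior, fusion arithmetic, and the
# block-level differentiability and parameter-economy properties.

test_that("branch extraction produces five C/4 branches and a 5C/4 concat", {
  m <- msaspp_new(aspp_config(16L), rng_stream(1L))
  x <- tiny_feature(8L, 8L, 16L, 2L)
  br <- extract_branches(m, x)
  expect_length(setdiff(names(br), "concat"), 5L)
  for (nm in setdiff(names(br), "concat"))
    expect_equal(dim(br[[nm]]$v), c(8L, 8L, 4L, 2L))
  expect_equal(dim(br$concat$v), c(8L, 8L, 20L, 2L))
  # spatially constant input: the pooled context branch is constant too
  xc <- array(2.5, c(8, 8, 16, 1))
  brc <- extract_branches(m, xc)
  expect_lt(max(apply(brc$F5$v, 3, function(ch) diff(range(ch)))), 1e-10)
  expect_error(extract_branches(m, tiny_feature(8L, 8L, 12L)), "channels")
  expect_error(aspp_config(10L), "divisible by 4")
  expect_error(aspp_config(16L, spatial_kernel = 6L), "odd")
})

test_that("dilated branches have the predicted effective receptive field", {
  # brute-force dependency tracing: perturb one central pixel of a large
  # grid and measure the nonzero output support of an untrained dilated conv
  for (r in c(1L, 6L, 12L)) {
    n <- 31L
    x <- array(0, c(n, n, 1L, 1L))
    x[16L, 16L, 1L, 1L] <- 1
    w <- new_tensor(array(1, c(3L, 3L, 1L, 1L)))
    y <- ad_conv2d(ad_const(x), w, NULL, pad = r, dil = r)
    nz <- which(abs(y$v[, , 1L, 1L]) > 0, arr.ind = TRUE)
    side <- diff(range(nz[, 1L])) + 1L
    expect_equal(side, dilated_receptive_field(3L, r))
    expect_equal(diff(range(nz[, 2L])) + 1L, dilated_receptive_field(3L, r))
  }
  expect_equal(dilated_receptive_field(3, 6), 13)
  expect_equal(dilated_receptive_field(3, 12), 25)
})

test_that("channel and spatial attention are bounded in (0, 1)", {
  m <- msaspp_new(aspp_config(16L), rng_stream(3L))
  jitter_params(m)
  x <- tiny_feature(8L, 8L, 16L, 2L, seed = 21L)
  br <- extract_branches(m, x)
  wc <- channel_attention(m, br$concat)
  ws <- spatial_attention(m, br$concat)
  expect_equal(dim(wc$v), c(20L, 2L))
  expect_equal(dim(ws$v), c(8L, 8L, 1L, 2L))
  expect_true(all(wc$v > 0 & wc$v < 1))
  expect_true(all(ws$v > 0 & ws$v < 1))
  # hidden bottleneck width: floor(5C/32) with a floor of 1
  expect_equal(nrow(m$fc1$W$v), max(1L, 20L %/% 8L))
  m4 <- msaspp_new(aspp_config(4L), rng_stream(4L))
  expect_equal(nrow(m4$fc1$W$v), 1L)
})

test_that("dual attention is an elementwise product with broadcasting", {
  x <- tiny_feature(4L, 4L, 8L, 1L, seed = 31L)
  ones_c <- matrix(1, 8L, 1L)
  ones_s <- array(1, c(4L, 4L, 1L, 1L))
  expect_equal(apply_dual_attention(x, ones_c, ones_s)$v, x)
  expect_equal(max(abs(apply_dual_attention(x, ones_c, 0 * ones_s)$v)), 0)
  # single-cell arithmetic: F = 2, w_c = 0.5, w_s = 0.5 -> 0.5
  f1 <- array(2, c(1, 1, 1, 1))
  expect_equal(
    apply_dual_attention(f1, matrix(0.5, 1, 1), array(0.5, c(1, 1, 1, 1)))$v,
    array(0.5, c(1, 1, 1, 1)))
  expect_error(apply_dual_attention(x, matrix(1, 5L, 1L), ones_s),
               "mismatch")
})

test_that("edge branch: zero response on constant input, 5C/4 channels,
           trainable via gradients", {
  m <- msaspp_new(aspp_config(16L), rng_stream(5L))
  xc <- array(3.7, c(8, 8, 16, 1))
  e <- edge_branch(m, xc)
  expect_lt(max(abs(e$v)), 1e-12)
  expect_equal(dim(e$v)[3], 20L)
  # gradient reaches the depthwise detector weights from a downstream loss
  x <- ad_const(tiny_feature(8L, 8L, 16L, 1L, seed = 41L))
  loss <- ad_mean(ad_pow(edge_branch(m, x), 2))
  ad_backward(loss)
  expect_false(is.null(m$edge_dw$W$grad))
  expect_gt(max(abs(m$edge_dw$W$grad)), 0)
})

test_that("depthwise-separable edge detector is cheaper than a dense conv", {
  cfg <- aspp_config(16L)
  m <- msaspp_new(cfg, rng_stream(6L))
  Cc <- 20L
  dw_weights <- length(m$edge_dw$W$v) + length(m$edge_dw$b$v) +
    length(m$edge_pw$W$v) + length(m$edge_pw$b$v)
  dense_weights <- 3L * 3L * 16L * Cc + Cc
  expect_lt(dw_weights, dense_weights)
})

test_that("fusion uses lambda (init 0.3) and projects back to C channels", {
  m <- msaspp_new(aspp_config(16L), rng_stream(7L))
  expect_equal(as.numeric(m$lambda$v), 0.3)
  fa <- tiny_feature(4L, 4L, 20L, 1L, seed = 51L)
  fe <- array(0, c(4L, 4L, 20L, 1L))
  # additive identity: zero edge features leave the fused map unchanged
  fused0 <- ad_add(as_tensor(fa), ad_smul(as_tensor(fe), m$lambda))
  expect_equal(fused0$v, fa)
  # scalar arithmetic: 1 + 0.3 * 2 = 1.6 before projection
  one <- array(1, c(1, 1, 1, 1)); two <- array(2, c(1, 1, 1, 1))
  expect_equal(as.numeric(ad_add(as_tensor(one),
                                 ad_smul(as_tensor(two), m$lambda))$v), 1.6)
  out <- msaspp_forward(m, tiny_feature(8L, 8L, 16L, 2L, seed = 61L))
  expect_equal(dim(out$v), c(8L, 8L, 16L, 2L))
})

test_that("block output shape equals input shape across configurations", {
  for (C in c(4L, 8L, 16L)) for (hw in list(c(5L, 7L), c(8L, 8L))) {
    m <- msaspp_new(aspp_config(C), rng_stream(C))
    x <- tiny_feature(hw[1], hw[2], C, 1L, seed = C + hw[1])
    expect_equal(dim(msaspp_forward(m, x)$v), c(hw, C, 1L))
  }
})

test_that("the full block passes a finite-difference gradient check", {
  m <- msaspp_new(aspp_config(4L), rng_stream(9L))
  jitter_params(m, sd = 0.05, seed = 13L)
  x <- ad_param(tiny_feature(8L, 8L, 4L, 1L, seed = 71L))
  loss_fn <- function() ad_mean(ad_pow(msaspp_forward(m, x), 2))
  err <- grad_check(loss_fn, c(list(x), collect_params(m)), n_probe = 2L,
                    stream = rng_stream(17L))
  expect_lt(err, 1e-3)
})

test_that("a third dilation rate adds a sixth branch", {
  cfg <- aspp_config(16L, dilation_rates = c(6L, 12L, 18L))
  m <- msaspp_new(cfg, rng_stream(10L))
  br <- extract_branches(m, tiny_feature(8L, 8L, 16L, 1L, seed = 81L))
  expect_length(setdiff(names(br), "concat"), 6L)
  expect_equal(dim(br$concat$v)[3], 24L)
  out <- msaspp_forward(m, tiny_feature(8L, 8L, 16L, 1L, seed = 82L))
  expect_equal(dim(out$v)[3], 16L)
})
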