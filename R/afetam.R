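# Adaptive frequency-enhancement and texture-aware (AFE-TAM) block.
#
# Spectral path: per-channel 2-D FFT, centered band decomposition into low /
# mid / high rings, learnable sigmoid band weights combined with
# category-adaptive preset weights, inverse transform. Texture path: a fixed
# Gabor filter bank (8 orientations x 4 wavelengths) and a learnable
# local-binary-pattern layer on a single-channel projection, gated by a
# texture-complexity attention map. Residual fusion with learnable scalars.

#' Centered frequency-band masks
#'
#' Partitions the FFT-shifted frequency grid into low / mid / high rings by
#' distance from the center bin `(floor(H/2), floor(W/2))` (0-based). With
#' scale `s = sqrt(H^2 + W^2)` the cut radii are `r1 = 0.15 s` and
#' `r2 = 0.45 s`; half-open intervals (`d < r1`, `r1 <= d < r2`, `d >= r2`)
#' make the three masks an exact partition of the grid.
#' @param H,W grid size (positive integers)
#' @return list with binary matrices `low`, `mid`, `high` and attributes
#'   `r1`, `r2`
#' @export
build_band_masks <- function(H, W) {
  stopifnot(H >= 1L, W >= 1L)
  s <- sqrt(H^2 + W^2)
  r1 <- 0.15 * s
  r2 <- 0.45 * s
  uc <- floor(H / 2); vc <- floor(W / 2)
  d <- sqrt(outer((seq_len(H) - 1 - uc)^2, (seq_len(W) - 1 - vc)^2, "+"))
  out <- list(low = (d < r1) * 1, mid = (d >= r1 & d < r2) * 1,
              high = (d >= r2) * 1)
  attr(out, "r1") <- r1
  attr(out, "r2") <- r2
  out
}

#' Gabor kernel sampled on a centered integer grid
#'
#' `g = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`.
#' @param theta orientation in radians
#' @param lambda wavelength in pixels
#' @param psi phase offset
#' @param sigma Gaussian envelope standard deviation
#' @param gamma spatial aspect ratio
#' @param size odd kernel size
#' @return a `size x size` matrix
#' @export
gabor_kernel <- function(theta, lambda, psi = 0, sigma = 0.56 * lambda,
                         gamma = 0.5, size = NULL) {
  if (is.null(size)) size <- min(2L * ceiling(2.5 * sigma) + 1L, 31L)
  stopifnot(size %% 2L == 1L)
  half <- (size - 1L) / 2L
  xs <- matrix(rep(-half:half, each = size), size)   # x varies over columns
  ys <- matrix(rep(-half:half, times = size), size)  # y varies over rows
  xp <- xs * cos(theta) + ys * sin(theta)
  yp <- -xs * sin(theta) + ys * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + psi)
}

#' Fixed Gabor filter bank
#'
#' 8 orientations (0 to 315 degrees in 45-degree steps) times 4 wavelengths
#' (2, 4, 8, 16 px) = 32 kernels. Kernel size follows the envelope
#' (`2 ceil(2.5 sigma) + 1`, capped at 31). With `psi = 0` the kernels for
#' theta and theta + 180 degrees coincide (even symmetry), a documented
#' redundancy of the published parameterization.
#' @param orientations number of orientations
#' @param wavelengths wavelengths in pixels
#' @param psi,gamma,sigma_factor free Gabor parameters (`sigma =
#'   sigma_factor * lambda`, about one octave of bandwidth)
#' @return list of class `gabor_bank`; each element has `kernel`, `theta`,
#'   `lambda`
#' @export
build_gabor_bank <- function(orientations = 8L, wavelengths = c(2, 4, 8, 16),
                             psi = 0, gamma = 0.5, sigma_factor = 0.56) {
  thetas <- (seq_len(orientations) - 1L) * 2 * pi / orientations
  bank <- list()
  for (lam in wavelengths) for (th in thetas) {
    bank[[length(bank) + 1L]] <-
      list(kernel = gabor_kernel(th, lam, psi = psi,
                                 sigma = sigma_factor * lam, gamma = gamma),
           theta = th, lambda = lam)
  }
  structure(bank, class = "gabor_bank")
}

#' Reference local binary pattern of a 3x3 patch
#'
#' Hard LBP code (P = 8, R = 1): neighbors ordered counter-clockwise starting
#' east; bit p set when `neighbor >= center`. The rotation-invariant code is
#' the minimum over the 8 circular bit rotations. Serves as the oracle for
#' the learnable LBP layer's initialization.
#' @param patch 3x3 numeric matrix (row 1 = top)
#' @return list with integer `code` (0-255) and `ri_code`
#' @export
lbp_reference <- function(patch) {
  stopifnot(all(dim(patch) == c(3L, 3L)))
  gc <- patch[2L, 2L]
  # (row, col) offsets counter-clockwise from east, image rows growing down
  nb <- rbind(c(2, 3), c(1, 3), c(1, 2), c(1, 1),
              c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  bits <- as.integer(patch[nb] >= gc)
  code <- sum(bits * 2^(0:7))
  rots <- vapply(0:7, function(i) {
    # circular right rotation of the 8-bit code by i positions
    b <- bits[(seq_len(8L) - 1L + i) %% 8L + 1L]
    sum(b * 2^(0:7))
  }, numeric(1))
  list(code = code, ri_code = min(rots))
}

#' Category presets for the band weights
#'
#' One 3-vector (low, mid, high) per pathological category. Defaults:
#' Normal-like tissue emphasizes high frequency, low-grade IN emphasizes
#' low/mid frequency; remaining categories are uniform.
#' @param presets optional named list of 3-vectors overriding the defaults
#' @return a 3 x 6 matrix with category columns
#' @export
category_presets <- function(presets = NULL) {
  cats <- histoseg_categories()
  P <- matrix(1 / 3, 3L, 6L, dimnames = list(c("low", "mid", "high"), cats))
  P[, "Normal"] <- c(0.3, 0.3, 0.4)
  P[, "Low-grade IN"] <- c(0.4, 0.4, 0.2)
  if (!is.null(presets)) {
    for (nm in names(presets)) {
      v <- presets[[nm]]
      stopifnot(length(v) == 3L, all(v >= 0))
      P[, nm] <- v
    }
  }
  P
}

#' The six pathological categories
#' @return character vector of category names
#' @export
histoseg_categories <- function() {
  c("Normal", "Polyp", "Low-grade IN", "High-grade IN",
    "Serrated adenoma", "Adenocarcinoma")
}

#' Build an AFE-TAM module
#'
#' @param channels number of feature channels C' at the insertion point
#' @param stream [rng_stream()] for initialization
#' @param combine how the learnable band weights and the category-adaptive
#'   weights combine into the effective per-band multiplier:
#'   `"multiplicative"` (`w_b * alpha_mode[b]`, default) or `"convex"`
#'   (`(w_b + alpha_mode[b]) / 2`)
#' @param presets optional preset override, see [category_presets()]
#' @param lbp_temperature slope of the soft sign in the learnable LBP layer
#' @return a module list
#' @export
afetam_new <- function(channels, stream = rng_stream(1L),
                       combine = c("multiplicative", "convex"),
                       presets = NULL, lbp_temperature = 10) {
  combine <- match.arg(combine)
  m <- list(channels = as.integer(channels), combine = combine,
            lbp_temperature = lbp_temperature)
  m$theta <- ad_param(c(0, 0, 0))          # band logits; sigmoid(0) = 0.5
  m$presets <- category_presets(presets)
  bank <- build_gabor_bank()
  sizes <- vapply(bank, function(k) nrow(k$kernel), numeric(1))
  m$gabor_groups <- lapply(sort(unique(sizes)), function(sz) {
    ks <- bank[sizes == sz]
    W <- array(0, c(sz, sz, 1L, length(ks)))
    for (i in seq_along(ks)) W[, , 1L, i] <- ks[[i]]$kernel
    list(W = ad_const(W), pad = (sz - 1L) %/% 2L)
  })
  m$bank <- bank
  m$proj <- nn_conv(channels, 1L, 1L, stream)      # shared texture projection
  m$gabor_compress <- nn_conv(32L, 8L, 1L, stream)
  # learnable LBP: 8 signed neighbor-difference stencils on the projection
  lbpW <- array(0, c(3L, 3L, 1L, 8L))
  nb <- rbind(c(2, 3), c(1, 3), c(1, 2), c(1, 1),
              c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  for (p in 1:8) {
    lbpW[2L, 2L, 1L, p] <- -1
    lbpW[nb[p, 1L], nb[p, 2L], 1L, p] <- lbpW[nb[p, 1L], nb[p, 2L], 1L, p] + 1
  }
  m$lbp_conv <- list(W = ad_param(lbpW), b = ad_param(rep(0, 8L)))
  m$lbp_pool <- ad_const(array(2^(0:7) / 255, c(1L, 1L, 8L, 1L)))
  m$tex_attn_conv <- nn_conv(1L, 1L, 3L, stream)
  m$tex_out <- nn_conv(9L, channels, 1L, stream)
  m$det_fc1 <- nn_linear(channels, 16L, stream)
  m$det_fc2 <- nn_linear(16L, 6L, stream)
  m$alpha_freq <- ad_param(0.5)
  m$beta_texture <- ad_param(0.5)
  m
}

effective_band_multiplier <- function(m, alpha_mode, N) {
  # alpha_mode: (3, N) tensor of category-mixed presets
  w <- ad_rep_cols(ad_sigmoid(m$theta), N)
  if (m$combine == "multiplicative") ad_emul(w, alpha_mode)
  else ad_scale(ad_add(w, alpha_mode), 0.5)
}

#' Frequency-domain enhancement
#'
#' Per channel: FFT, center shift, per-band multiplication by the effective
#' multiplier `sigmoid(theta_b) * alpha_mode[b]`, inverse shift and FFT, real
#' part. Linear in its input for fixed weights; with all effective
#' multipliers equal to 1 it is the identity up to floating-point error.
#' @param m an [afetam_new()] module
#' @param f feature map (array `(H, W, C[, N])` or tensor)
#' @param alpha_mode 3-vector (or `(3, N)` matrix/tensor) of nonnegative
#'   category band weights; default all 1
#' @param masks optional precomputed [build_band_masks()] for the map size
#' @return enhanced feature tensor, same shape as input
#' @export
frequency_enhance <- function(m, f, alpha_mode = c(1, 1, 1), masks = NULL) {
  f <- as_feature_tensor(f)
  d <- dim(f$v)
  if (is.null(masks)) masks <- build_band_masks(d[1], d[2])
  if (!inherits(alpha_mode, "ad_tensor")) {
    am <- as.matrix(alpha_mode)
    if (any(am < 0)) stop("alpha_mode entries must be nonnegative",
                          call. = FALSE)
    if (ncol(am) == 1L) am <- matrix(am, 3L, d[4])
    alpha_mode <- ad_const(am)
  }
  mult <- effective_band_multiplier(m, alpha_mode, d[4])
  ad_fft_band(f, mult, list(masks$low, masks$mid, masks$high))
}

box_mean_5 <- function(x) {
  # 5x5 box filter with reflection padding on a (H, W, 1, N) tensor
  W <- ad_const(array(1 / 25, c(5L, 5L, 1L, 1L)))
  ad_conv2d(ad_reflect_pad(x, 2L), W, NULL, pad = 0L)
}

#' Texture-aware branch
#'
#' (a) Gabor responses of a single-channel 1x1 projection, compressed to 8
#' channels; (b) learnable LBP soft codes (signed neighbor-difference
#' stencils, steep sigmoid, binary-weight pooling scaled to 0-1); (c)
#' texture-complexity attention from the 5x5 local variance of the
#' channel-mean map, standardized per sample and passed through a 3x3 conv
#' and sigmoid; (d) the concatenated (a, b) features gated by (c) and
#' projected back to C' channels.
#' @inheritParams frequency_enhance
#' @param training batch-statistics mode flag (kept for interface symmetry)
#' @return texture feature tensor with C' channels
#' @export
texture_branch <- function(m, f, training = TRUE) {
  f <- as_feature_tensor(f)
  d <- dim(f$v)
  if (d[1] < 2L || d[2] < 2L)
    stop("texture branch needs at least a 2x2 map", call. = FALSE)
  proj <- m$proj$fwd(f)
  # (a) Gabor bank on the projection
  gparts <- lapply(m$gabor_groups, function(gr)
    ad_conv2d(proj, gr$W, NULL, pad = gr$pad))
  gab <- m$gabor_compress$fwd(ad_concat_c(gparts))
  # (b) learnable LBP soft codes
  diffs <- ad_conv2d(proj, m$lbp_conv$W, m$lbp_conv$b, pad = 1L)
  soft <- ad_sigmoid(ad_scale(diffs, m$lbp_temperature))
  lbp <- ad_conv2d(soft, m$lbp_pool, NULL, pad = 0L)
  # (c) texture-complexity attention on the channel-mean of the input
  cmean <- mean_channels(f)
  tvar <- ad_sub(box_mean_5(ad_pow(cmean, 2)), ad_pow(box_mean_5(cmean), 2))
  stats_ <- complexity_stats(tvar$v)
  tstd <- ad_affine_per_sample(tvar, 1 / (stats_$sd + 1e-5),
                               -stats_$mu / (stats_$sd + 1e-5))
  attn <- ad_sigmoid(m$tex_attn_conv$fwd(tstd))
  # (d) gate and project
  tex <- ad_concat_c(list(gab, lbp))
  tex <- ad_mul_spatial(tex, attn)
  m$tex_out$fwd(tex)
}

mean_channels <- function(f) {
  d <- dim(f$v)
  W <- ad_const(array(1 / d[3], c(1L, 1L, d[3], 1L)))
  ad_conv2d(f, W, NULL, pad = 0L)
}

complexity_stats <- function(tv) {
  # per-sample mean/sd of the complexity map; treated as constants in the
  # backward pass (gradient stops through the normalization statistics)
  d <- dim(tv)
  mm <- matrix(tv, prod(d[1:3]), d[4])
  mu <- colMeans(mm)
  sd_ <- sqrt(pmax(colMeans(mm^2) - mu^2, 0))
  list(mu = mu, sd = sd_)
}

#' Pathological-category detector
#'
#' GAP, a two-layer perceptron and a softmax over the six categories.
#' Trained implicitly through the segmentation loss; no category labels are
#' consumed at run time.
#' @inheritParams frequency_enhance
#' @return `(6, N)` probability tensor (columns sum to 1)
#' @export
category_detector <- function(m, f) {
  f <- as_feature_tensor(f)
  ad_col_softmax(m$det_fc2$fwd(ad_relu(m$det_fc1$fwd(ad_gap(f)))))
}

#' Mix the category presets with detected probabilities
#'
#' `alpha_mode = sum_m p_m * preset_m`, a probability-weighted average of the
#' per-category band-weight vectors.
#' @param p probability 6-vector, `(6, N)` matrix, or tensor; columns must
#'   sum to 1 (tolerance 1e-6)
#' @param presets 3 x 6 preset matrix, see [category_presets()]
#' @return `(3, N)` tensor of mixed band weights
#' @export
mix_presets <- function(p, presets = category_presets()) {
  if (!inherits(p, "ad_tensor")) {
    pm <- as.matrix(p)
    if (nrow(pm) != 6L) pm <- t(pm)
    if (any(abs(colSums(pm) - 1) > 1e-6))
      stop("category probabilities must sum to 1", call. = FALSE)
    p <- ad_const(pm)
  } else if (any(abs(colSums(p$v) - 1) > 1e-6)) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  ad_matmul(ad_const(presets), p)
}

#' Full AFE-TAM forward pass
#'
#' Residual fusion `F + alpha_freq * F_freq + beta_texture * F_texture`, with
#' the frequency path driven by the category detector's preset mix.
#' @inheritParams texture_branch
#' @return output tensor with the input shape
#' @export
afetam_forward <- function(m, f, training = TRUE) {
  afetam_forward_detail(m, f, training = training)$output
}

#' AFE-TAM forward pass returning intermediates
#'
#' Like [afetam_forward()] but also returns the detector probabilities (for
#' an optional auxiliary classification loss) and the mixed band weights.
#' @inheritParams texture_branch
#' @return list with `output`, `probs` (`(6, N)` tensor) and `alpha_mode`
#'   (`(3, N)` tensor)
#' @export
afetam_forward_detail <- function(m, f, training = TRUE) {
  f <- as_feature_tensor(f)
  probs <- category_detector(m, f)
  amode <- mix_presets(probs, m$presets)
  freq <- frequency_enhance(m, f, amode)
  tex <- texture_branch(m, f, training = training)
  out <- ad_add(f, ad_add(ad_smul(freq, m$alpha_freq),
                          ad_smul(tex, m$beta_texture)))
  list(output = out, probs = probs, alpha_mode = amode)
}
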