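# Multi-scale atrous spatial pyramid pooling (MS-ASPP) block.
#
# Five parallel branches over an input feature map with C channels (1x1 conv,
# 3x3 conv, two 3x3 dilated convs, global-average-pool context), each emitting
# C/4 channels; channel + spatial attention over the concatenation; a
# learnable edge branch (depthwise-separable detector initialized to a
# Laplacian stencil); fusion F_attn + lambda * F_edge and a 1x1 projection
# back to C channels. Feature maps are arrays indexed (row, col, channel) with
# an optional trailing sample dimension.

#' MS-ASPP configuration
#'
#' @param in_channels number of input channels C; must be divisible by 4
#' @param dilation_rates dilation rates of the atrous branches (default
#'   `c(6, 12)`, giving the standard five-branch block; a third rate adds a
#'   sixth branch of the same C/4 width)
#' @param spatial_kernel odd kernel size of the spatial-attention convolution
#' @param edge_weight_init initial value of the learnable edge-fusion weight
#'   lambda
#' @return an `aspp_config` list
#' @export
aspp_config <- function(in_channels, dilation_rates = c(6L, 12L),
                        spatial_kernel = 7L, edge_weight_init = 0.3) {
  if (in_channels %% 4L != 0L)
    stop("in_channels must be divisible by 4", call. = FALSE)
  if (any(dilation_rates < 1L))
    stop("dilation rates must be >= 1", call. = FALSE)
  if (spatial_kernel %% 2L != 1L)
    stop("spatial_kernel must be odd", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 dilation_rates = as.integer(dilation_rates),
                 spatial_kernel = as.integer(spatial_kernel),
                 edge_weight_init = edge_weight_init),
            class = "aspp_config")
}

# number of channels after branch concatenation
aspp_concat_channels <- function(cfg) {
  (3L + length(cfg$dilation_rates)) * (cfg$in_channels %/% 4L)
}

as_feature_tensor <- function(f) {
  if (inherits(f, "ad_tensor")) return(f)
  f <- as.array(f)
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  if (length(dim(f)) != 4L)
    stop("feature maps must be (H, W, C) or (H, W, C, N) arrays", call. = FALSE)
  if (any(dim(f)[1:3] < 1L)) stop("feature map has an empty dimension",
                                  call. = FALSE)
  if (!all(is.finite(f))) stop("feature map contains non-finite values",
                               call. = FALSE)
  ad_const(f)
}

#' Build an MS-ASPP module
#'
#' @param cfg an [aspp_config()]
#' @param stream an [rng_stream()] used for weight initialization
#' @return a module list with trainable parameters and layer closures
#' @export
msaspp_new <- function(cfg, stream = rng_stream(1L)) {
  C <- cfg$in_channels
  Cb <- C %/% 4L
  Cc <- aspp_concat_channels(cfg)
  hidden <- max(1L, Cc %/% 8L)

  m <- list(cfg = cfg)
  m$b1 <- nn_conv(C, Cb, 1L, stream)
  m$b2 <- nn_conv(C, Cb, 3L, stream)
  m$bd <- lapply(cfg$dilation_rates, function(r)
    nn_conv(C, Cb, 3L, stream, dil = as.integer(r)))
  m$b5 <- nn_conv(C, Cb, 1L, stream)          # applied after GAP
  m$bn <- lapply(seq_len(3L + length(cfg$dilation_rates)),
                 function(i) nn_bn(Cb))
  m$fc1 <- nn_linear(Cc, hidden, stream)
  m$fc2 <- nn_linear(hidden, Cc, stream)
  m$spconv <- nn_conv(2L, 1L, cfg$spatial_kernel, stream)
  # edge branch: depthwise Laplacian-difference stencil, pointwise C -> Cc,
  # then a 3x3 conv; biases start at zero so a constant input gives zero
  lap <- matrix(-1 / 8, 3L, 3L); lap[2L, 2L] <- 1
  m$edge_dw <- list(W = ad_param(array(rep(lap, C), c(3L, 3L, C))),
                    b = ad_param(rep(0, C)))
  m$edge_pw <- nn_conv(C, Cc, 1L, stream)
  m$edge_conv <- nn_conv(Cc, Cc, 3L, stream)
  m$lambda <- ad_param(cfg$edge_weight_init)
  m$proj <- nn_conv(Cc, C, 1L, stream)
  m
}

#' Extract the parallel multi-scale branches
#'
#' @param m an [msaspp_new()] module
#' @param f feature map array `(H, W, C[, N])` or `ad_tensor`
#' @param training logical; batch-norm statistics mode
#' @return list with branch tensors `F1..` and the channel concatenation
#'   `concat` (`(3 + n_rates) * C/4` channels)
#' @export
extract_branches <- function(m, f, training = TRUE) {
  f <- as_feature_tensor(f)
  d <- dim(f$v)
  if (d[3] != m$cfg$in_channels)
    stop("feature map channels do not match the configuration", call. = FALSE)
  branches <- list(m$b1$fwd(f), m$b2$fwd(f))
  for (conv in m$bd) branches <- c(branches, list(conv$fwd(f)))
  # global context: pool, 1x1 conv on the pooled vector, broadcast to (H, W)
  gapped <- ad_gap(f)
  ctx <- ad_conv2d(ad_broadcast_hw(gapped, 1L, 1L), m$b5$W, m$b5$b)
  ctx <- ad_resize_bilinear(ctx, d[1], d[2])
  branches <- c(branches, list(ctx))
  branches <- lapply(seq_along(branches), function(i)
    ad_relu(m$bn[[i]]$fwd(branches[[i]], training = training)))
  names(branches) <- paste0("F", seq_along(branches))
  c(branches, list(concat = ad_concat_c(branches)))
}

#' Channel-attention weights over the concatenated branches
#'
#' Global average pooling followed by a two-layer bottleneck
#' (`Cc -> max(1, Cc/8) -> Cc`) and a sigmoid; one weight per channel per
#' sample, strictly inside (0, 1).
#' @inheritParams extract_branches
#' @param f_concat concatenated branch features
#' @return `ad_tensor` of shape `(Cc, N)`
#' @export
channel_attention <- function(m, f_concat) {
  f_concat <- as_feature_tensor(f_concat)
  Cc <- aspp_concat_channels(m$cfg)
  if (dim(f_concat$v)[3] != Cc)
    stop("expected ", Cc, " channels in the concatenated features",
         call. = FALSE)
  ad_sigmoid(m$fc2$fwd(ad_relu(m$fc1$fwd(ad_gap(f_concat)))))
}

#' Spatial-attention map over the concatenated branches
#'
#' Per-pixel channel max and mean are stacked into a 2-channel map and passed
#' through a `spatial_kernel`-sized convolution and a sigmoid.
#' @inheritParams channel_attention
#' @return `ad_tensor` of shape `(H, W, 1, N)`, values in (0, 1)
#' @export
spatial_attention <- function(m, f_concat) {
  f_concat <- as_feature_tensor(f_concat)
  ad_sigmoid(m$spconv$fwd(ad_chan_maxmean(f_concat)))
}

#' Apply channel and spatial attention jointly
#'
#' `F[h,w,c,n] * w_c[c,n] * w_s[h,w,n]` (a single elementwise product, not a
#' sequential re-estimation).
#' @param f_concat concatenated features (array or tensor)
#' @param w_c channel weights `(Cc, N)` (array or tensor)
#' @param w_s spatial weights `(H, W, 1, N)` (array or tensor)
#' @return weighted feature tensor
#' @export
apply_dual_attention <- function(f_concat, w_c, w_s) {
  f_concat <- as_feature_tensor(f_concat)
  if (!inherits(w_c, "ad_tensor")) {
    w_c <- as.array(w_c)
    if (is.null(dim(w_c)) || length(dim(w_c)) == 1L)
      w_c <- matrix(w_c, ncol = dim(f_concat$v)[4])
    w_c <- ad_const(w_c)
  }
  if (!inherits(w_s, "ad_tensor")) {
    w_s <- as.array(w_s)
    if (length(dim(w_s)) == 2L)
      dim(w_s) <- c(dim(w_s), 1L, dim(f_concat$v)[4])
    w_s <- ad_const(w_s)
  }
  d <- dim(f_concat$v)
  if (nrow(w_c$v) != d[3]) stop("channel weight length mismatch", call. = FALSE)
  if (!all(dim(w_s$v)[1:2] == d[1:2]))
    stop("spatial weight shape mismatch", call. = FALSE)
  ad_mul_spatial(ad_mul_channel(f_concat, w_c), w_s)
}

#' Learnable edge branch
#'
#' Depthwise 3x3 detector (initialized to a Laplacian difference stencil:
#' +1 center, -1/8 ring, so constant inputs give exactly zero before
#' training), pointwise expansion to the concatenated width, then a 3x3 conv.
#' @inheritParams extract_branches
#' @return `ad_tensor` with `Cc` channels at the input resolution
#' @export
edge_branch <- function(m, f) {
  f <- as_feature_tensor(f)
  if (dim(f$v)[3] != m$cfg$in_channels)
    stop("feature map channels do not match the configuration", call. = FALSE)
  # reflection padding so the difference stencil sees a constant neighborhood
  # at the borders too (a constant input gives an exactly zero response)
  y <- ad_dwconv2d(ad_reflect_pad(f, 1L), m$edge_dw$W, m$edge_dw$b,
                   prepadded = TRUE)
  y <- m$edge_pw$fwd(y)
  m$edge_conv$fwd(y)
}

#' Fuse attention-weighted and edge features, project back to C channels
#'
#' `F_fused = F_attn + lambda * F_edge`, followed by a 1x1 projection.
#' @inheritParams extract_branches
#' @param f_attn attention-weighted features (Cc channels)
#' @param f_edge edge-branch features (Cc channels)
#' @return `ad_tensor` with C channels; same spatial size as the block input
#' @export
fuse_and_project <- function(m, f_attn, f_edge) {
  f_attn <- as_feature_tensor(f_attn)
  f_edge <- as_feature_tensor(f_edge)
  if (!identical(dim(f_attn$v), dim(f_edge$v)))
    stop("fused feature shapes differ", call. = FALSE)
  fused <- ad_add(f_attn, ad_smul(f_edge, m$lambda))
  m$proj$fwd(fused)
}

#' Full MS-ASPP block forward pass
#'
#' @inheritParams extract_branches
#' @return `ad_tensor` with the same shape `(H, W, C, N)` as the input
#' @export
msaspp_forward <- function(m, f, training = TRUE) {
  f <- as_feature_tensor(f)
  br <- extract_branches(m, f, training = training)
  wc <- channel_attention(m, br$concat)
  ws <- spatial_attention(m, br$concat)
  attn <- apply_dual_attention(br$concat, wc, ws)
  edge <- edge_branch(m, f)
  fuse_and_project(m, attn, edge)
}

#' Effective receptive field of a dilated convolution
#'
#' `RF = k + (k - 1) (r - 1)` per side.
#' @param k kernel size
#' @param r dilation rate
#' @return receptive field in pixels
#' @export
dilated_receptive_field <- function(k, r) k + (k - 1) * (r - 1)
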