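# Student CNN backbone and the two teacher networks.
#
# Student: stride-4 stem, three residual stages (C, 2C, 4C at 1/4, 1/8, 1/16),
# MS-ASPP inserted after the 1/8 stage, AFE-TAM after the 1/16 stage, and a
# progressive bilinear-upsampling decoder with skip fusion. Teacher 1 is a
# transformer branch (patch tokens, self-attention encoder) whose last-layer
# attention map supervises the student's attention; teacher 2 is a residual
# encoder U-shaped network. Teachers exist only at training time.

#' Student network configuration
#'
#' @param base_channels C; stage widths are C, 2C, 4C (divisible by 4)
#' @param input_size `(H, W)`, both divisible by 16
#' @param num_classes output classes (2: background / lesion)
#' @param stage_depths residual blocks per stage
#' @return a `student_config` list
#' @export
student_config <- function(base_channels = 64L, input_size = c(256L, 256L),
                           num_classes = 2L, stage_depths = c(2L, 2L, 2L)) {
  if (any(input_size %% 16L != 0L))
    stop("input size must be divisible by 16", call. = FALSE)
  if (base_channels %% 4L != 0L)
    stop("base_channels must be divisible by 4", call. = FALSE)
  structure(list(base_channels = as.integer(base_channels),
                 input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 stage_depths = as.integer(stage_depths)),
            class = "student_config")
}

res_block <- function(c, stream) {
  m <- list(conv1 = nn_conv(c, c, 3L, stream), bn1 = nn_bn(c),
            conv2 = nn_conv(c, c, 3L, stream), bn2 = nn_bn(c))
  m$fwd <- function(x, training = TRUE) {
    y <- ad_relu(m$bn1$fwd(m$conv1$fwd(x), training))
    y <- m$bn2$fwd(m$conv2$fwd(y), training)
    ad_relu(ad_add(y, x))
  }
  m
}

down_block <- function(cin, cout, stream) {
  m <- list(conv = nn_conv(cin, cout, 3L, stream, stride = 2L, pad = 1L),
            bn = nn_bn(cout))
  m$fwd <- function(x, training = TRUE)
    ad_relu(m$bn$fwd(m$conv$fwd(x), training))
  m
}

stage_new <- function(c, depth, stream)
  lapply(seq_len(depth), function(i) res_block(c, stream))

stage_fwd <- function(stage, x, training = TRUE) {
  for (blk in stage) x <- blk$fwd(x, training)
  x
}

#' Build the student network
#'
#' Stem (two stride-2 convs) -> stage1 (C @ 1/4) -> stage2 (2C @ 1/8) ->
#' MS-ASPP -> stage3 (4C @ 1/16) -> AFE-TAM -> decoder with skip fusion and
#' a final 4x bilinear upsampling of the class logits. Feature taps at 1/4,
#' 1/8 (after MS-ASPP) and 1/16 (after AFE-TAM) are retrievable by name.
#' @param cfg a [student_config()]
#' @param stream [rng_stream()] for initialization
#' @param with_blocks include the two inserted enhancement blocks (disabling
#'   them gives a plain backbone with identical output shapes)
#' @return a network module list (class `student_net`)
#' @export
build_student <- function(cfg, stream = rng_stream(1L), with_blocks = TRUE) {
  C <- cfg$base_channels
  m <- list(cfg = cfg, kind = "student", with_blocks = with_blocks)
  m$stem1 <- down_block(3L, C, stream)
  m$stem2 <- down_block(C, C, stream)
  m$stage1 <- stage_new(C, cfg$stage_depths[1], stream)
  m$down2 <- down_block(C, 2L * C, stream)
  m$stage2 <- stage_new(2L * C, cfg$stage_depths[2], stream)
  if (with_blocks) m$msaspp <- msaspp_new(aspp_config(2L * C), stream)
  m$down3 <- down_block(2L * C, 4L * C, stream)
  m$stage3 <- stage_new(4L * C, cfg$stage_depths[3], stream)
  if (with_blocks) m$afetam <- afetam_new(4L * C, stream)
  m$dec3 <- nn_conv(4L * C, 2L * C, 1L, stream)
  m$dec3bn <- nn_bn(2L * C)
  m$dec2 <- nn_conv(2L * C, C, 1L, stream)
  m$dec2bn <- nn_bn(C)
  m$head1 <- nn_conv(C, C, 3L, stream)
  m$head1bn <- nn_bn(C)
  m$head2 <- nn_conv(C, cfg$num_classes, 1L, stream)
  class(m) <- c("student_net", "list")
  m
}

# images arrive in [0, 1]; center them once at the network boundary
center_input <- function(x) ad_add(x, ad_const(array(-0.5, dim(x$v))))

#' Forward pass with named feature taps
#'
#' @param net a network from [build_student()], [build_teacher1()] or
#'   [build_teacher2()]
#' @param x image batch `(H, W, 3, N)` array or tensor, spatial size
#'   divisible by 16
#' @param training batch-statistics mode
#' @return list with `logits` (`(H, W, num_classes, N)` tensor), `taps`
#'   (named list `quarter`, `eighth`, `sixteenth`) and `attention` (row-
#'   stochastic `(N_tok, N_tok, N)` tensor for the transformer teacher,
#'   otherwise `NULL`)
#' @export
forward_with_taps <- function(net, x, training = TRUE) {
  UseMethod("forward_with_taps")
}

#' @export
forward_with_taps.student_net <- function(net, x, training = TRUE) {
  x <- as_feature_tensor(x)
  d <- dim(x$v)
  if (any(d[1:2] %% 16L != 0L))
    stop("input spatial size must be divisible by 16", call. = FALSE)
  x <- center_input(x)
  h <- net$stem2$fwd(net$stem1$fwd(x, training), training)
  h <- stage_fwd(net$stage1, h, training)
  t4 <- h
  h <- net$down2$fwd(h, training)
  h <- stage_fwd(net$stage2, h, training)
  if (net$with_blocks) h <- msaspp_forward(net$msaspp, h, training)
  t8 <- h
  h <- net$down3$fwd(h, training)
  h <- stage_fwd(net$stage3, h, training)
  if (net$with_blocks) h <- afetam_forward(net$afetam, h, training)
  t16 <- h
  # decoder: progressive 2x bilinear upsampling with additive skip fusion
  u <- ad_resize_bilinear(t16, dim(t8$v)[1], dim(t8$v)[2])
  u <- ad_relu(net$dec3bn$fwd(net$dec3$fwd(u), training))
  u <- ad_add(u, t8)
  u <- ad_resize_bilinear(u, dim(t4$v)[1], dim(t4$v)[2])
  u <- ad_relu(net$dec2bn$fwd(net$dec2$fwd(u), training))
  u <- ad_add(u, t4)
  u <- ad_relu(net$head1bn$fwd(net$head1$fwd(u), training))
  logits <- ad_resize_bilinear(net$head2$fwd(u), d[1], d[2])
  list(logits = logits,
       taps = list(quarter = t4, eighth = t8, sixteenth = t16),
       attention = NULL)
}

# ---- teacher 1: transformer branch ------------------------------------------

transformer_layer <- function(dmodel, nheads, dff, stream) {
  stopifnot(dmodel %% nheads == 0L)
  m <- list(dmodel = dmodel, nheads = nheads,
            ln1g = ad_param(rep(1, dmodel)), ln1b = ad_param(rep(0, dmodel)),
            ln2g = ad_param(rep(1, dmodel)), ln2b = ad_param(rep(0, dmodel)),
            wq = nn_linear(dmodel, dmodel, stream),
            wk = nn_linear(dmodel, dmodel, stream),
            wv = nn_linear(dmodel, dmodel, stream),
            wo = nn_linear(dmodel, dmodel, stream),
            ff1 = nn_linear(dmodel, dff, stream),
            ff2 = nn_linear(dff, dmodel, stream))
  m$fwd <- function(tok) {
    # tok: (N_tok, d, N)
    dd <- dim(tok$v); Ntok <- dd[1]; N <- dd[3]
    dh <- m$dmodel %/% m$nheads
    h <- ad_layernorm(tok, m$ln1g, m$ln1b)
    lin_tok <- function(lin, t) {
      # apply a linear layer along the feature dim of (N_tok, d, N)
      tp <- ad_reshape(ad_bmm_identity(t), c(dd[2], Ntok * N))
      y <- lin$fwd(tp)
      ad_bmm_identity_back(ad_reshape(y, c(dd[2], Ntok, N)))
    }
    q <- lin_tok(m$wq, h); k <- lin_tok(m$wk, h); v <- lin_tok(m$wv, h)
    heads <- vector("list", m$nheads)
    attn_maps <- vector("list", m$nheads)
    for (hh in seq_len(m$nheads)) {
      idx <- (hh - 1L) * dh + seq_len(dh)
      qh <- ad_slice_d2(q, idx); kh <- ad_slice_d2(k, idx)
      vh <- ad_slice_d2(v, idx)
      A <- ad_row_softmax(ad_scale(ad_bmm(qh, kh, transB = TRUE),
                                   1 / sqrt(dh)))
      attn_maps[[hh]] <- A
      heads[[hh]] <- ad_bmm(A, vh)
    }
    cat_ <- ad_concat_d2(heads)
    tok <- ad_add(tok, lin_tok(m$wo, cat_))
    h2 <- ad_layernorm(tok, m$ln2g, m$ln2b)
    ff <- function(t) {
      tp <- ad_reshape(ad_bmm_identity(t), c(dd[2], Ntok * N))
      y <- m$ff2$fwd(ad_relu(m$ff1$fwd(tp)))
      ad_bmm_identity_back(ad_reshape(y, c(dd[2], Ntok, N)))
    }
    tok <- ad_add(tok, ff(h2))
    list(tok = tok, attention = attn_maps)
  }
  m
}

# permute (N_tok, d, N) <-> (d, N_tok, N); thin wrappers around an aperm op
ad_bmm_identity <- function(x) ad_aperm(x, c(2L, 1L, 3L))
ad_bmm_identity_back <- function(x) ad_aperm(x, c(2L, 1L, 3L))

ad_aperm <- function(x, perm) {
  inv <- order(perm)
  new_tensor(aperm(x$v, perm), list(x), function(g) list(aperm(g, inv)))
}

ad_slice_d2 <- function(x, idx) {
  d <- dim(x$v)
  new_tensor(x$v[, idx, , drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[, idx, ] <- gx[, idx, , drop = FALSE] + g
    list(gx)
  })
}

ad_concat_d2 <- function(xs) {
  ds <- lapply(xs, function(t) dim(t$v))
  ks <- vapply(ds, function(d) d[2], numeric(1))
  d1 <- ds[[1]]
  y <- array(0, c(d1[1], sum(ks), d1[3]))
  at <- 0L
  for (t in xs) {
    y[, at + seq_len(dim(t$v)[2]), ] <- t$v
    at <- at + dim(t$v)[2]
  }
  new_tensor(y, xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- if (xs[[i]]$req)
        g[, at + seq_len(ks[i]), , drop = FALSE] else NULL
      at <- at + ks[i]
    }
    out
  })
}

tokens_from_map <- function(f) {
  # (H, W, C, N) -> (H*W, C, N)
  d <- dim(f$v)
  ad_reshape(f, c(d[1] * d[2], d[3], d[4]))
}

map_from_tokens <- function(tok, H, W) {
  d <- dim(tok$v)
  ad_reshape(tok, c(H, W, d[2], d[3]))
}

#' Build the transformer teacher (teacher 1)
#'
#' Convolutional patch embedding to 1/4 and 1/8 resolution, two transformer
#' layers on 1/8 tokens, patch merging to 1/16, two further layers whose
#' last-layer attention (averaged over heads) is the supervision surface,
#' and a light upsampling decoder.
#' @param cfg [student_config()] (shared input size / classes)
#' @param stream [rng_stream()]
#' @param dmodel token width (default 4 * base_channels)
#' @param nheads attention heads
#' @return network module (class `teacher1_net`)
#' @export
build_teacher1 <- function(cfg, stream = rng_stream(2L), dmodel = NULL,
                           nheads = 2L, nlayers = c(2L, 2L)) {
  C <- cfg$base_channels
  if (is.null(dmodel)) dmodel <- 4L * C
  m <- list(cfg = cfg, kind = "teacher1", dmodel = dmodel,
            nheads = as.integer(nheads), nlayers = as.integer(nlayers))
  m$embed1 <- down_block(3L, C, stream)
  m$embed2 <- down_block(C, C, stream)            # 1/4
  m$embed3 <- down_block(C, dmodel %/% 2L, stream) # 1/8
  m$layers8 <- lapply(seq_len(nlayers[1]), function(i)
    transformer_layer(dmodel %/% 2L, nheads, dmodel, stream))
  m$merge <- down_block(dmodel %/% 2L, dmodel, stream) # 1/16
  m$layers16 <- lapply(seq_len(nlayers[2]), function(i)
    transformer_layer(dmodel, nheads, 2L * dmodel, stream))
  m$dec <- nn_conv(dmodel, C, 1L, stream)
  m$decbn <- nn_bn(C)
  m$head <- nn_conv(C, cfg$num_classes, 1L, stream)
  class(m) <- c("teacher1_net", "list")
  m
}

#' @export
forward_with_taps.teacher1_net <- function(net, x, training = TRUE) {
  x <- as_feature_tensor(x)
  d <- dim(x$v)
  if (any(d[1:2] %% 16L != 0L))
    stop("input spatial size must be divisible by 16", call. = FALSE)
  x <- center_input(x)
  h4 <- net$embed2$fwd(net$embed1$fwd(x, training), training)
  h8 <- net$embed3$fwd(h4, training)
  d8 <- dim(h8$v)
  tok <- tokens_from_map(h8)
  for (lay in net$layers8) tok <- lay$fwd(tok)$tok
  h8b <- map_from_tokens(tok, d8[1], d8[2])
  h16 <- net$merge$fwd(h8b, training)
  d16 <- dim(h16$v)
  tok <- tokens_from_map(h16)
  attn <- NULL
  for (lay in net$layers16) {
    out <- lay$fwd(tok)
    tok <- out$tok
    attn <- out$attention
  }
  h16b <- map_from_tokens(tok, d16[1], d16[2])
  # average the last layer's attention over heads (row-stochastic)
  amap <- attn[[1]]
  if (length(attn) > 1L)
    for (i in 2:length(attn)) amap <- ad_add(amap, attn[[i]])
  amap <- ad_scale(amap, 1 / length(attn))
  u <- ad_resize_bilinear(h16b, dim(h4$v)[1], dim(h4$v)[2])
  u <- ad_relu(net$decbn$fwd(net$dec$fwd(u), training))
  u <- ad_add(u, h4)
  logits <- ad_resize_bilinear(net$head$fwd(u), d[1], d[2])
  list(logits = logits,
       taps = list(quarter = h4, eighth = h8b, sixteenth = h16b),
       attention = amap)
}

#' Build the residual-encoder U-shaped teacher (teacher 2)
#'
#' Residual encoder at C, 2C, 4C widths with a skip-fused decoder. Encoder
#' weights can optionally be seeded from a generic-image pretrained
#' checkpoint via [teacher2_load_pretrained()]; by default they are randomly
#' initialized.
#' @param cfg [student_config()]
#' @param stream [rng_stream()]
#' @param width encoder base width (default `base_channels`)
#' @param depths residual blocks per encoder stage
#' @return network module (class `teacher2_net`)
#' @export
build_teacher2 <- function(cfg, stream = rng_stream(3L), width = NULL,
                           depths = c(3L, 4L, 6L)) {
  C <- if (is.null(width)) cfg$base_channels else as.integer(width)
  m <- list(cfg = cfg, kind = "teacher2", width = C,
            depths = as.integer(depths))
  m$stem1 <- down_block(3L, C, stream)
  m$stem2 <- down_block(C, C, stream)
  m$stage1 <- stage_new(C, depths[1], stream)
  m$down2 <- down_block(C, 2L * C, stream)
  m$stage2 <- stage_new(2L * C, depths[2], stream)
  m$down3 <- down_block(2L * C, 4L * C, stream)
  m$stage3 <- stage_new(4L * C, depths[3], stream)
  m$dec3 <- nn_conv(4L * C, 2L * C, 1L, stream)
  m$dec3bn <- nn_bn(2L * C)
  m$dec2 <- nn_conv(2L * C, C, 1L, stream)
  m$dec2bn <- nn_bn(C)
  m$head <- nn_conv(C, cfg$num_classes, 1L, stream)
  m$pretrained <- FALSE
  class(m) <- c("teacher2_net", "list")
  m
}

#' Load pretrained encoder weights into teacher 2
#'
#' Reads a serialized named weight list and copies matching encoder entries.
#' When `path` is `NULL` or unreadable the random initialization is kept and
#' the fallback is reported, so desk-scale runs work fully offline.
#' @param net a `teacher2_net`
#' @param path checkpoint path or `NULL`
#' @return the network, with `pretrained` flag set accordingly
#' @export
teacher2_load_pretrained <- function(net, path = NULL) {
  if (is.null(path) || !file.exists(path)) {
    message("teacher2: no pretrained encoder weights available; ",
            "keeping random initialization")
    net$pretrained <- FALSE
    return(net)
  }
  vals <- readRDS(path)
  assign_named_values(net, vals, strict = FALSE)
  net$pretrained <- TRUE
  net
}

#' @export
forward_with_taps.teacher2_net <- function(net, x, training = TRUE) {
  x <- as_feature_tensor(x)
  d <- dim(x$v)
  if (any(d[1:2] %% 16L != 0L))
    stop("input spatial size must be divisible by 16", call. = FALSE)
  x <- center_input(x)
  h <- net$stem2$fwd(net$stem1$fwd(x, training), training)
  t4 <- stage_fwd(net$stage1, h, training)
  t8 <- stage_fwd(net$stage2, net$down2$fwd(t4, training), training)
  t16 <- stage_fwd(net$stage3, net$down3$fwd(t8, training), training)
  u <- ad_resize_bilinear(t16, dim(t8$v)[1], dim(t8$v)[2])
  u <- ad_relu(net$dec3bn$fwd(net$dec3$fwd(u), training))
  u <- ad_add(u, t8)
  u <- ad_resize_bilinear(u, dim(t4$v)[1], dim(t4$v)[2])
  u <- ad_relu(net$dec2bn$fwd(net$dec2$fwd(u), training))
  u <- ad_add(u, t4)
  logits <- ad_resize_bilinear(net$head$fwd(u), d[1], d[2])
  list(logits = logits,
       taps = list(quarter = t4, eighth = t8, sixteenth = t16),
       attention = NULL)  # attention supervision applies to teacher 1 only
}

# ---- checkpointing ----------------------------------------------------------

named_values <- function(m, prefix = "") {
  out <- list()
  walk <- function(o, pre) {
    if (inherits(o, "ad_tensor")) {
      if (o$param) out[[pre]] <<- o$v
    } else if (is.environment(o) && !is.null(o$mu)) {
      out[[paste0(pre, ".running_mu")]] <<- o$mu
      out[[paste0(pre, ".running_va")]] <<- o$va
    } else if (is.list(o)) {
      nms <- names(o)
      for (i in seq_along(o)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        el <- o[[i]]
        if (is.function(el)) next
        walk(el, paste0(pre, if (nzchar(pre)) "." else "", nm))
      }
    }
  }
  walk(m, prefix)
  out
}

assign_named_values <- function(m, vals, strict = TRUE) {
  seen <- new.env(parent = emptyenv())
  walk <- function(o, pre) {
    if (inherits(o, "ad_tensor")) {
      if (o$param) {
        if (!is.null(vals[[pre]])) {
          o$v <- vals[[pre]]
          seen[[pre]] <- TRUE
        } else if (strict) stop("missing checkpoint value: ", pre)
      }
    } else if (is.environment(o) && !is.null(o$mu)) {
      if (!is.null(vals[[paste0(pre, ".running_mu")]])) {
        o$mu <- vals[[paste0(pre, ".running_mu")]]
        o$va <- vals[[paste0(pre, ".running_va")]]
      }
    } else if (is.list(o)) {
      nms <- names(o)
      for (i in seq_along(o)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        el <- o[[i]]
        if (is.function(el)) next
        walk(el, paste0(pre, if (nzchar(pre)) "." else "", nm))
      }
    }
  }
  walk(m, "")
  invisible(m)
}

#' Save a network checkpoint
#'
#' Weights and batch-norm running statistics are serialized; the
#' configuration and training-stage metadata go to a JSON sidecar so a
#' checkpoint is self-describing.
#' @param net a network module
#' @param path file path for the weights (`.rds`); the sidecar is
#'   `<path>.json`
#' @param stage optional training-stage label stored in the sidecar
#' @export
save_checkpoint <- function(net, path, stage = NA) {
  vals <- named_values(net)
  saveRDS(vals, path)
  side <- list(kind = net$kind,
               config = unclass(net$cfg),
               with_blocks = isTRUE(net$with_blocks),
               arch = list(dmodel = net$dmodel, nheads = net$nheads,
                           nlayers = net$nlayers, width = net$width,
                           depths = net$depths),
               stage = stage,
               n_params = n_params(net))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a student checkpoint
#'
#' Rebuilds the network from the JSON sidecar and restores the weights. Only
#' the single student branch is reconstructed: no teacher object is touched,
#' so inference is teacher-free by construction.
#' @param path path given to [save_checkpoint()]
#' @return the restored network
#' @export
load_checkpoint <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- student_config(base_channels = side$config$base_channels,
                        input_size = side$config$input_size,
                        num_classes = side$config$num_classes,
                        stage_depths = side$config$stage_depths)
  ar <- side$arch
  net <- switch(side$kind,
                student = build_student(cfg, rng_stream(1L),
                                        with_blocks = side$with_blocks),
                teacher1 = build_teacher1(cfg, rng_stream(1L),
                                          dmodel = ar$dmodel,
                                          nheads = ar$nheads,
                                          nlayers = ar$nlayers),
                teacher2 = build_teacher2(cfg, rng_stream(1L),
                                          width = ar$width,
                                          depths = ar$depths),
                stop("unknown network kind in checkpoint"))
  assign_named_values(net, readRDS(path))
  net
}
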