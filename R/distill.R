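# Progressive dual-teacher knowledge distillation (PDTKD).
#
# Four distillation losses (logit KL at temperature T, multi-scale feature
# MSE through trainable 1x1 aligners, attention-map Frobenius matching
# against the transformer teacher, batch relation matching on cosine
# similarity), a three-stage schedule (40/40/20) with stage learning rates,
# dynamic teacher weighting from validation Dice, curriculum hard-sample
# mining, stage-3 teacher dropout and augmentation-consistency
# regularization.

#' Knowledge-distillation configuration
#'
#' Defaults follow the published protocol: temperature `T = 4`; loss weights
#' gamma = 0.3 (feature), delta = 0.2 (attention, teacher 1 only), eta = 0.1
#' (relation); initial teacher weights alpha = 0.5, beta = 0.3; validation
#' cadence `K = 5`; hard-sample weight 2.0; stage-3 teacher-dropout
#' probability 0.5; consistency weight 0.1; hard-sample thresholds
#' Dice < 0.7 or HD95 > 20 px (at 256 x 256 evaluation resolution).
#' @param temperature softening temperature T > 0
#' @param gamma,delta,eta loss weights (all >= 0)
#' @param alpha0,beta0 initial teacher weights
#' @param K validation / reweighting cadence in epochs
#' @param w_hard extra weight on hard samples
#' @param p_drop stage-3 teacher-dropout probability
#' @param consistency_weight weight of the augmentation-consistency term
#' @param hard_dice,hard_hd95 difficulty thresholds (strict inequalities)
#' @param kl_direction `"forward"` = KL(student || teacher) as printed;
#'   `"reverse"` for the conventional direction
#' @return a `kd_config` list
#' @export
kd_config <- function(temperature = 4, gamma = 0.3, delta = 0.2, eta = 0.1,
                      alpha0 = 0.5, beta0 = 0.3, K = 5L, w_hard = 2.0,
                      p_drop = 0.5, consistency_weight = 0.1,
                      hard_dice = 0.7, hard_hd95 = 20,
                      kl_direction = "forward") {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (any(c(gamma, delta, eta) < 0)) stop("loss weights must be >= 0",
                                          call. = FALSE)
  if (p_drop < 0 || p_drop > 1) stop("p_drop must be in [0, 1]",
                                     call. = FALSE)
  structure(list(temperature = temperature, gamma = gamma, delta = delta,
                 eta = eta, alpha0 = alpha0, beta0 = beta0, K = as.integer(K),
                 w_hard = w_hard, p_drop = p_drop,
                 consistency_weight = consistency_weight,
                 hard_dice = hard_dice, hard_hd95 = hard_hd95,
                 kl_direction = kl_direction),
            class = "kd_config")
}

#' Three-stage training schedule
#'
#' Stage boundaries at `ceil(0.4 E)` and `ceil(0.8 E)` epochs with per-stage
#' learning rates and an early-stopping patience.
#' @param total_epochs E
#' @param lrs learning rates of stages 1-3
#' @param patience early-stopping patience in epochs (validation loss)
#' @return a `stage_schedule` list
#' @export
stage_schedule <- function(total_epochs, lrs = c(2e-4, 1e-4, 5e-5),
                           patience = 20L) {
  E <- as.integer(total_epochs)
  stopifnot(E >= 1L, length(lrs) == 3L)
  structure(list(total_epochs = E,
                 b1 = as.integer(ceiling(0.4 * E)),
                 b2 = as.integer(ceiling(0.8 * E)),
                 lrs = lrs, patience = as.integer(patience)),
            class = "stage_schedule")
}

#' Training stage of an epoch
#' @param epoch 0-based epoch index in `[0, E)`
#' @param sched a [stage_schedule()]
#' @return 1, 2 or 3
#' @export
stage_of <- function(epoch, sched) {
  if (any(epoch < 0) || any(epoch >= sched$total_epochs))
    stop("epoch out of range", call. = FALSE)
  ifelse(epoch < sched$b1, 1L, ifelse(epoch < sched$b2, 2L, 3L))
}

#' Curriculum hard-sample fraction
#'
#' Grows linearly from 0.20 at the first stage-2 epoch to 0.50 at the last.
#' @param epoch 0-based epoch, must lie in stage 2
#' @param sched a [stage_schedule()]
#' @return fraction in `[0.2, 0.5]`
#' @export
curriculum_fraction <- function(epoch, sched) {
  if (stage_of(epoch, sched) != 2L)
    stop("curriculum fraction is defined for stage-2 epochs only",
         call. = FALSE)
  s <- sched$b1
  e <- sched$b2 - 1L
  if (e == s) return(0.5)
  0.2 + 0.3 * (epoch - s) / (e - s)
}

#' Hard-sample flag
#'
#' A sample is difficult when `dice < dice_thr` OR `hd95 > hd95_thr`; both
#' inequalities are strict, so the boundary values are not hard.
#' @param dice,hd95 per-sample metrics (vectorized)
#' @param dice_thr,hd95_thr thresholds (defaults 0.7 and 20 px)
#' @return logical vector
#' @export
hard_flag <- function(dice, hd95, dice_thr = 0.7, hd95_thr = 20) {
  dice < dice_thr | hd95 > hd95_thr
}

#' Mutable distillation state
#'
#' Holds the current teacher weights (clamped to `[0, 1]`), the curriculum
#' fraction, per-sample difficulty flags and the seeded stream for stage-3
#' dropout draws.
#' @param cfg a [kd_config()]
#' @param seed seed of the dropout stream
#' @return an environment of class `distill_state`
#' @export
distill_state <- function(cfg = kd_config(), seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$alpha <- cfg$alpha0
  st$beta <- cfg$beta0
  st$p_t <- 0.2
  st$hard <- logical(0)
  st$epoch <- 0L
  st$drop_stream <- rng_stream(seed)
  st$last_drop <- NA
  class(st) <- "distill_state"
  st
}

#' Dynamic teacher-weight update
#'
#' Every K stage-2 epochs: if teacher 1's validation Dice exceeds teacher
#' 2's, `alpha += 0.1, beta -= 0.05`; otherwise (including ties)
#' `alpha -= 0.05, beta += 0.1`. Both are clamped to `[0, 1]`; no
#' normalization is applied (the printed update is asymmetric by design).
#' @param state a [distill_state()]
#' @param dice_t1,dice_t2 validation Dice of the two teachers
#' @return the state, updated in place
#' @export
update_teacher_weights <- function(state, dice_t1, dice_t2) {
  if (dice_t1 > dice_t2) {
    state$alpha <- state$alpha + 0.1
    state$beta <- state$beta - 0.05
  } else {
    state$alpha <- state$alpha - 0.05
    state$beta <- state$beta + 0.1
  }
  state$alpha <- min(max(state$alpha, 0), 1)
  state$beta <- min(max(state$beta, 0), 1)
  invisible(state)
}

# ---- distillation losses ----------------------------------------------------

#' Logit distillation loss
#'
#' Temperature-softened KL divergence between student and teacher class
#' distributions, averaged over pixels and samples, scaled by T^2. The
#' printed argument order KL(student || teacher) is the default.
#' @param z_s,z_t student / teacher logit maps `(H, W, K, N)` (arrays or
#'   tensors; the teacher side is treated as a constant target)
#' @param temperature T > 0
#' @param direction `"forward"` (as printed) or `"reverse"`
#' @return scalar loss tensor
#' @export
logit_kd <- function(z_s, z_t, temperature = 4, direction = "forward") {
  z_s <- as_feature_tensor(z_s)
  z_t <- as_feature_tensor(z_t)
  ad_kl_temp(z_s, z_t, temperature, direction)
}

#' Build the per-scale channel aligners for feature distillation
#' @param s_channels,t_channels named vectors of tap channel counts
#'   (`quarter`, `eighth`, `sixteenth`)
#' @param stream [rng_stream()]
#' @return named list of 1x1 conv modules
#' @export
make_aligners <- function(s_channels, t_channels, stream = rng_stream(1L)) {
  scales <- c("quarter", "eighth", "sixteenth")
  out <- lapply(scales, function(sc)
    nn_conv(s_channels[[sc]], t_channels[[sc]], 1L, stream))
  names(out) <- scales
  out
}

#' Feature distillation loss
#'
#' Sum over the 1/4, 1/8 and 1/16 taps of the squared difference between the
#' aligned student features and the teacher features. `reduce = "mean"`
#' (training default) mean-reduces per scale so magnitudes are comparable
#' across feature sizes; `reduce = "sum"` is the plain squared-norm form.
#' @param s_taps,t_taps named tap lists (tensors or arrays)
#' @param aligners result of [make_aligners()]; `NULL` if the features are
#'   already aligned
#' @param reduce `"mean"` or `"sum"`
#' @return scalar loss tensor
#' @export
feature_kd <- function(s_taps, t_taps, aligners = NULL,
                       reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  scales <- c("quarter", "eighth", "sixteenth")
  if (!all(scales %in% names(s_taps)) || !all(scales %in% names(t_taps)))
    stop("feature distillation needs taps at 1/4, 1/8 and 1/16",
         call. = FALSE)
  total <- NULL
  for (sc in scales) {
    fs <- as_feature_tensor(s_taps[[sc]])
    ft <- as_feature_tensor(t_taps[[sc]])
    if (!is.null(aligners)) fs <- aligners[[sc]]$fwd(fs)
    diff2 <- ad_pow(ad_sub(fs, ft), 2)
    term <- if (reduce == "mean") ad_mean(diff2) else ad_sum(diff2)
    total <- if (is.null(total)) term else ad_add(total, term)
  }
  total
}

#' Student self-attention map
#'
#' Flattens the feature map to `N = H W` tokens, forms the scaled similarity
#' matrix `F F^T / d` and row-softmaxes it, giving a row-stochastic
#' `(N, N, batch)` map comparable to the transformer teacher's attention.
#' @param f feature map (tensor or array)
#' @param d scaling divisor; defaults to the channel count
#' @return attention tensor `(N_tok, N_tok, batch)`
#' @export
student_attention <- function(f, d = NULL) {
  f <- as_feature_tensor(f)
  dd <- dim(f$v)
  if (is.null(d)) d <- dd[3]
  tok <- ad_reshape(f, c(dd[1] * dd[2], dd[3], dd[4]))
  ad_row_softmax(ad_scale(ad_bmm(tok, tok, transB = TRUE), 1 / d))
}

#' Attention distillation loss
#'
#' Squared Frobenius norm of the difference between the student's and
#' teacher 1's attention maps (summed within a map, averaged over the
#' batch). Attention supervision exists only for the transformer teacher;
#' passing `teacher_id = 2` is a configuration error.
#' @param a_s,a_t attention tensors/arrays of equal shape
#' @param teacher_id teacher index (must be 1)
#' @return scalar loss tensor
#' @export
attention_kd <- function(a_s, a_t, teacher_id = 1L) {
  if (teacher_id != 1L)
    stop("attention distillation applies to teacher 1 only", call. = FALSE)
  a_s <- as_tensor(a_s); a_t <- as_tensor(a_t)
  if (!identical(dim(a_s$v) %||% length(a_s$v),
                 dim(a_t$v) %||% length(a_t$v)))
    stop("attention map shapes differ", call. = FALSE)
  nb <- if (length(dim(a_s$v)) == 3L) dim(a_s$v)[3] else 1L
  ad_scale(ad_sum(ad_pow(ad_sub(a_s, a_t), 2)), 1 / nb)
}

#' Batch relation distillation loss
#'
#' Cosine-similarity matrices between the per-sample embeddings (GAP of the
#' 1/16 tap) of student and teacher; the loss is the squared Frobenius norm
#' of their difference. With fewer than 2 samples the relation is undefined
#' and the loss is 0 with a warning.
#' @param s_emb,t_emb `(d, B)` embedding matrices (tensors or arrays)
#' @return scalar loss tensor
#' @export
relation_kd <- function(s_emb, t_emb) {
  s_emb <- as_tensor(s_emb); t_emb <- as_tensor(t_emb)
  B <- ncol(s_emb$v)
  if (B < 2L) {
    warning("relation distillation skipped: batch size < 2")
    return(ad_const(0))
  }
  Rs <- ad_crossprod_self(ad_l2normalize_cols(s_emb))
  Rt <- ad_crossprod_self(ad_l2normalize_cols(t_emb))
  ad_sum(ad_pow(ad_sub(Rs, Rt), 2))
}

#' Combine the four distillation parts for one teacher
#'
#' `L_KD = L_logit + gamma L_feat + delta L_attn + eta L_rel`; the attention
#' term is included for teacher 1 only.
#' @param parts named list/tensors: `logit`, `feat`, `attn` (may be missing
#'   for teacher 2), `rel`
#' @param cfg [kd_config()]
#' @param teacher_id 1 or 2
#' @return scalar loss tensor
#' @export
combine_kd <- function(parts, cfg, teacher_id) {
  out <- as_tensor(parts$logit)
  out <- ad_add(out, ad_scale(as_tensor(parts$feat), cfg$gamma))
  if (teacher_id == 1L && !is.null(parts$attn))
    out <- ad_add(out, ad_scale(as_tensor(parts$attn), cfg$delta))
  out <- ad_add(out, ad_scale(as_tensor(parts$rel), cfg$eta))
  out
}

#' Segmentation loss: Dice + focal
#'
#' Dice loss on the foreground probability (smoothing 1) plus an
#' alpha-balanced focal loss (gamma = 2, alpha = 0.25 on the foreground
#' class), equally weighted.
#' @param logits `(H, W, 2, N)` logit tensor/array (channel 2 = lesion)
#' @param mask binary `(H, W[, N])` array
#' @param focal_gamma,focal_alpha focal parameters
#' @param eps Dice smoothing
#' @return scalar loss tensor
#' @export
seg_loss <- function(logits, mask, focal_gamma = 2, focal_alpha = 0.25,
                     eps = 1) {
  logits <- as_feature_tensor(logits)
  d <- dim(logits$v)
  mask <- as.array(mask)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!all(mask %in% c(0, 1)))
    stop("segmentation mask must be binary", call. = FALSE)
  if (!all(dim(mask) == d[c(1, 2, 4)]))
    stop("mask shape does not match logits", call. = FALSE)
  p <- ad_softmax_c(logits)
  pfg <- ad_slice_c(p, 2L)
  m4 <- array(mask, c(d[1], d[2], 1L, d[4]))
  inter <- ad_sum(ad_emul(pfg, ad_const(m4)))
  denom <- ad_add(ad_sum(pfg), ad_const(sum(m4)))
  dice_l <- ad_sub(ad_const(1),
                   ad_div(ad_add(ad_scale(inter, 2), ad_const(eps)),
                          ad_add(denom, ad_const(eps))))
  # focal: pt = p_fg where mask = 1, else 1 - p_fg
  pt <- ad_add(ad_emul(pfg, ad_const(m4)),
               ad_emul(ad_sub(ad_const(array(1, dim(m4))), pfg),
                       ad_const(1 - m4)))
  at <- focal_alpha * m4 + (1 - focal_alpha) * (1 - m4)
  focal <- ad_mean(ad_emul(ad_emul(ad_pow(ad_sub(ad_const(array(1, dim(m4))),
                                                 pt), focal_gamma),
                                   ad_scale(ad_log(pt), -1)),
                           ad_const(at)))
  ad_add(dice_l, focal)
}

#' Stage-dependent total training loss
#'
#' Stage 1: `seg + alpha KD1 + beta KD2`. Stage 2 adds the hard-sample
#' weighted segmentation term and the consistency penalty. Stage 3 draws
#' from the state's seeded dropout stream: with probability `p_drop` the
#' loss is the segmentation term alone, otherwise `seg` plus the KD terms
#' restricted to hard samples plus the consistency penalty. The draw is
#' recorded in `state$last_drop`.
#' @param stage 1, 2 or 3
#' @param seg segmentation loss (tensor or numeric)
#' @param kd1,kd2 distillation losses (full-batch for stages 1-2,
#'   hard-restricted for stage 3)
#' @param hard_seg segmentation loss over hard-flagged samples (stage 2)
#' @param consistency consistency penalty (stages 2-3)
#' @param state [distill_state()] carrying alpha, beta and the dropout
#'   stream
#' @param cfg [kd_config()]
#' @return scalar loss tensor
#' @export
total_loss <- function(stage, seg, kd1 = 0, kd2 = 0, hard_seg = 0,
                       consistency = 0, state = distill_state(),
                       cfg = kd_config()) {
  seg <- as_tensor(seg)
  if (stage == 1L) {
    state$last_drop <- NA
    return(ad_add(seg, ad_add(ad_scale(as_tensor(kd1), state$alpha),
                              ad_scale(as_tensor(kd2), state$beta))))
  }
  if (stage == 2L) {
    state$last_drop <- NA
    out <- ad_add(seg, ad_add(ad_scale(as_tensor(kd1), state$alpha),
                              ad_scale(as_tensor(kd2), state$beta)))
    out <- ad_add(out, ad_scale(as_tensor(hard_seg), cfg$w_hard))
    return(ad_add(out, ad_scale(as_tensor(consistency),
                                cfg$consistency_weight)))
  }
  if (stage == 3L) {
    drop <- stream_runif(state$drop_stream, 1) < cfg$p_drop
    state$last_drop <- drop
    if (drop) return(seg)
    out <- ad_add(seg, ad_add(ad_scale(as_tensor(kd1), state$alpha),
                              ad_scale(as_tensor(kd2), state$beta)))
    return(ad_add(out, ad_scale(as_tensor(consistency),
                                cfg$consistency_weight)))
  }
  stop("stage must be 1, 2 or 3", call. = FALSE)
}

#' Augmentation-consistency penalty
#'
#' Mean over augmented views of the squared difference between the
#' inverse-mapped augmented prediction and the clean prediction.
#' `reduce = "mean"` averages over pixels (training default); `"sum"` is the
#' plain squared-norm form.
#' @param p_clean prediction tensor/array
#' @param p_aug_inv list of inverse-mapped augmented predictions
#' @param reduce `"mean"` or `"sum"`
#' @return scalar tensor
#' @export
consistency_penalty <- function(p_clean, p_aug_inv,
                                reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  p_clean <- as_tensor(p_clean)
  total <- NULL
  for (pa in p_aug_inv) {
    diff2 <- ad_pow(ad_sub(as_tensor(pa), p_clean), 2)
    term <- if (reduce == "mean") ad_mean(diff2) else ad_sum(diff2)
    total <- if (is.null(total)) term else ad_add(total, term)
  }
  ad_scale(total, 1 / length(p_aug_inv))
}

consistency_augs <- c("identity", "flip", "rotation", "brightness")

#' Augmentation-consistency loss for a network
#'
#' Forward-passes the clean and augmented batches, inverts the geometric
#' transform on the augmented prediction grid (exact column reversal for
#' flips; nearest-neighbor inverse warp for rotations; identity for
#' brightness) and penalizes disagreement of the class probabilities.
#' Registering an augmentation without an inverse on the prediction grid is
#' a configuration error.
#' @param net a network with [forward_with_taps()] support
#' @param x clean image batch `(H, W, 3, N)`
#' @param augmentations subset of `"identity"`, `"flip"`, `"rotation"`,
#'   `"brightness"`
#' @param stream [rng_stream()] for the augmentation draws
#' @param reduce see [consistency_penalty()]
#' @param p_clean optional precomputed clean probability tensor (reuses the
#'   training forward pass)
#' @return scalar loss tensor
#' @export
consistency_loss <- function(net, x, augmentations = c("flip", "rotation",
                                                       "brightness"),
                             stream = rng_stream(1L),
                             reduce = c("mean", "sum"), p_clean = NULL) {
  reduce <- match.arg(reduce)
  bad <- setdiff(augmentations, consistency_augs)
  if (length(bad) > 0L)
    stop("non-invertible or unknown augmentation registered: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(p_clean))
    p_clean <- ad_softmax_c(forward_with_taps(net, x, training = TRUE)$logits)
  d <- dim(as_feature_tensor(x)$v)
  views <- list()
  for (aug in augmentations) {
    if (aug == "identity") {
      p_aug <- ad_softmax_c(forward_with_taps(net, x,
                                              training = TRUE)$logits)
      views[[length(views) + 1L]] <- p_aug
    } else if (aug == "flip") {
      xa <- x[, rev(seq_len(d[2])), , , drop = FALSE]
      p_aug <- ad_softmax_c(forward_with_taps(net, xa,
                                              training = TRUE)$logits)
      flipmap <- list(r = matrix(rep(seq_len(d[1]), d[2]), d[1]),
                      c = matrix(rep(rev(seq_len(d[2])), each = d[1]), d[1]))
      views[[length(views) + 1L]] <- ad_gather_hw(p_aug, flipmap)
    } else if (aug == "rotation") {
      angle <- stream_runif(stream, 1, -15, 15)
      xa <- x
      for (n in seq_len(d[4])) for (ch in 1:3)
        xa[, , ch, n] <- rotate_bilinear(x[, , ch, n], angle)
      p_aug <- ad_softmax_c(forward_with_taps(net, xa,
                                              training = TRUE)$logits)
      inv <- rotate_nearest_map(d[1], -angle)
      views[[length(views) + 1L]] <- ad_gather_hw(p_aug, inv)
    } else if (aug == "brightness") {
      off <- stream_runif(stream, 1, -0.2, 0.2)
      xa <- pmin(pmax(x + off, 0), 1)
      p_aug <- ad_softmax_c(forward_with_taps(net, xa,
                                              training = TRUE)$logits)
      views[[length(views) + 1L]] <- p_aug
    }
  }
  consistency_penalty(p_clean, views, reduce = reduce)
}

# ---- prediction and per-sample metrics --------------------------------------

#' Predict binary masks with the student branch
#'
#' Thresholds the foreground probability at 0.5 and removes connected
#' components smaller than `min_size` pixels (standard small-object
#' suppression; set `min_size = 0` to disable).
#' @param net network
#' @param x image batch `(H, W, 3, N)`
#' @param min_size minimum connected-component area in pixels; default
#'   0.5% of the image area
#' @return binary `(H, W, N)` array
#' @export
predict_masks <- function(net, x, min_size = NULL) {
  p <- ad_softmax_c(forward_with_taps(net, x, training = FALSE)$logits)
  d <- dim(p$v)
  out <- (array(p$v[, , 2L, ], d[c(1, 2, 4)]) > 0.5) * 1
  if (is.null(min_size)) min_size <- ceiling(0.005 * d[1] * d[2])
  if (min_size > 0) {
    for (n in seq_len(d[4])) {
      lab <- EBImage::bwlabel(EBImage::Image(t(out[, , n])))
      sizes <- table(lab[lab > 0])
      keep <- as.integer(names(sizes)[sizes >= min_size])
      out[, , n] <- t(matrix(as.integer(lab %in% keep), dim(lab)[1]))
    }
  }
  out
}

eval_samples <- function(net, samples, batch = 8L, with_hd95 = FALSE) {
  n <- length(samples)
  dice <- numeric(n); hd <- numeric(n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch - 1L, n)
    ba <- batch_arrays(samples[idx])
    pred <- predict_masks(net, ba$x)
    for (j in seq_along(idx)) {
      pm <- matrix(pred[, , j], dim(pred)[1])
      rm <- samples[[idx[j]]]$mask
      dice[idx[j]] <- overlap_metrics(pm, rm)$dice
      if (with_hd95) hd[idx[j]] <- surface_distances(pm, rm)$hd95
    }
    i <- i + batch
  }
  list(dice = dice, hd95 = if (with_hd95) hd else NULL)
}

# ---- the training protocol --------------------------------------------------

set_requires <- function(net, value) {
  for (p in collect_params(net)) p$req <- value
  invisible(net)
}

#' Train a student under the progressive dual-teacher protocol
#'
#' Builds the student, the transformer teacher (trained jointly on its own
#' segmentation loss) and the residual U-shaped teacher (warmed up on the
#' segmentation task for `warmup_epochs`, then frozen), and runs the
#' three-stage schedule with multi-level distillation, dynamic teacher
#' weighting, curriculum mining, stage-3 teacher dropout and consistency
#' regularization. With `use_kd = FALSE` the same student is trained on the
#' segmentation loss alone (the no-distillation twin), under the identical
#' schedule and data order.
#' @param samples sample list carrying `split` fields (see
#'   [stratified_split()])
#' @param student_cfg [student_config()]
#' @param kd_cfg [kd_config()]
#' @param sched [stage_schedule()]
#' @param seed master seed; all named streams derive from it
#' @param batch_size minibatch size
#' @param aug_expand augmentation expansion factor: each training epoch
#'   iterates the clean samples plus `aug_expand - 1` freshly augmented
#'   views of each (offline-style expansion of the small training set)
#' @param use_kd run the full protocol (`TRUE`) or the no-distillation twin
#' @param warmup_epochs teacher-2 task-adaptation epochs before distillation
#' @param augment_train apply random augmentation to training batches
#' @param outdir optional run directory for manifest/checkpoints
#' @param verbose print per-epoch progress
#' @return list with `student`, `manifest`, `history` (per-epoch data
#'   frame), `val_dice` (final), `teachers` (or `NULL`)
#' @export
train_pdtkd <- function(samples, student_cfg, kd_cfg = kd_config(),
                        sched = stage_schedule(10L), seed = 1L,
                        batch_size = 2L, aug_expand = 3L, use_kd = TRUE,
                        warmup_epochs = 5L,
                        augment_train = TRUE, outdir = NULL,
                        verbose = FALSE) {
  init_s <- rng_stream(seed)
  aug_s <- rng_stream(seed + 1000L)
  batch_s <- rng_stream(seed + 2000L)
  state <- distill_state(kd_cfg, seed = seed + 3000L)

  train <- Filter(function(s) identical(s$split, "train"), samples)
  val <- Filter(function(s) identical(s$split, "val"), samples)
  stopifnot(length(train) > 0L, length(val) > 0L)
  size <- nrow(train[[1]]$mask)
  hd_thr <- kd_cfg$hard_hd95 * size / 256   # thresholds defined at 256 px

  student <- build_student(student_cfg, init_s)
  sparams <- collect_params(student)
  teacher1 <- NULL; teacher2 <- NULL; aligners1 <- NULL; aligners2 <- NULL
  if (use_kd) {
    teacher1 <- build_teacher1(student_cfg, init_s, nlayers = c(1L, 1L))
    teacher2 <- build_teacher2(student_cfg, init_s, depths = c(2L, 2L, 2L))
    teacher2 <- teacher2_load_pretrained(teacher2, NULL)
    C <- student_cfg$base_channels
    schan <- list(quarter = C, eighth = 2L * C, sixteenth = 4L * C)
    t1chan <- list(quarter = C, eighth = teacher1$dmodel %/% 2L,
                   sixteenth = teacher1$dmodel)
    t2chan <- list(quarter = teacher2$width, eighth = 2L * teacher2$width,
                   sixteenth = 4L * teacher2$width)
    aligners1 <- make_aligners(schan, t1chan, init_s)
    aligners2 <- make_aligners(schan, t2chan, init_s)
    sparams <- c(sparams, collect_params(aligners1),
                 collect_params(aligners2))
  }
  opt_s <- adam_new(sparams, lr = sched$lrs[1])
  # the staged learning rates govern the student; the auxiliary transformer
  # branch keeps its own constant rate so it becomes informative quickly
  opt_t1 <- if (use_kd) adam_new(collect_params(teacher1), lr = 1e-3)
  else NULL

  # epoch ordering over the expanded set: indices > n_train denote freshly
  # augmented views of sample (idx - n_train) etc.
  epoch_order <- function(set) {
    n <- length(set)
    stream_sample(batch_s, seq_len(n * aug_expand))
  }
  get_batch <- function(set, idx) {
    ss <- lapply(idx, function(i) {
      s <- set[[(i - 1L) %% length(set) + 1L]]
      if (i > length(set) || !augment_train) {
        if (i > length(set)) s <- augment(s, aug_s)
        s
      } else if (augment_train && aug_expand == 1L) {
        augment(s, aug_s)
      } else s
    })
    batch_arrays(ss)
  }

  # both teachers are task-adapted on the segmentation loss before
  # distillation begins (their targets would otherwise be noise during the
  # joint-distillation stage); teacher 2 is then frozen, teacher 1 keeps
  # training jointly through stage 1
  if (use_kd && warmup_epochs > 0L) {
    opt_t2 <- adam_new(collect_params(teacher2), lr = 1e-3)
    for (we in seq_len(warmup_epochs)) {
      ord <- epoch_order(train)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        ba <- get_batch(train, b)
        f2 <- forward_with_taps(teacher2, ba$x, training = TRUE)
        ad_backward(seg_loss(f2$logits, ba$y))
        adam_step(opt_t2)
        f1 <- forward_with_taps(teacher1, ba$x, training = TRUE)
        ad_backward(seg_loss(f1$logits, ba$y))
        adam_step(opt_t1)
      }
    }
    set_requires(teacher2, FALSE)
  }

  E <- sched$total_epochs
  history <- list()
  best_val <- Inf; best_epoch <- -1L; patience_left <- sched$patience
  best_weights <- NULL
  drop_draws <- logical(0)

  for (epoch in 0:(E - 1L)) {
    st_id <- stage_of(epoch, sched)
    lr <- sched$lrs[st_id]
    opt_s$lr <- lr
    state$epoch <- epoch

    # stage-2 cadence: teacher weighting + curriculum re-ranking
    if (use_kd && st_id == 2L) {
      state$p_t <- curriculum_fraction(epoch, sched)
      if ((epoch - sched$b1) %% kd_cfg$K == 0L) {
        d1 <- mean(eval_samples(teacher1, val)$dice)
        d2 <- mean(eval_samples(teacher2, val)$dice)
        update_teacher_weights(state, d1, d2)
        tr_m <- eval_samples(student, train, with_hd95 = TRUE)
        difficulty <- 1 / pmax(tr_m$dice, 1e-3)
        k <- ceiling(state$p_t * length(train))
        topk <- order(difficulty, decreasing = TRUE)[seq_len(k)]
        flags <- logical(length(train))
        flags[topk] <- TRUE
        flags <- flags | hard_flag(tr_m$dice, tr_m$hd95,
                                   kd_cfg$hard_dice, hd_thr)
        state$hard <- flags
      }
    }
    if (length(state$hard) == 0L) state$hard <- logical(length(train))

    ord <- epoch_order(train)
    ep_loss <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      ba <- get_batch(train, b)
      kd1 <- kd2 <- hard_seg <- cons <- ad_const(0)
      t1out <- t2out <- NULL
      pre_drop <- FALSE
      if (use_kd && st_id == 3L) {
        # consume the stage-3 dropout draw up front: a dropped step needs no
        # teacher forwards at all
        pre_drop <- stream_runif(state$drop_stream, 1) < kd_cfg$p_drop
      }
      if (use_kd && !pre_drop) {
        # teacher 1 trains jointly on its own segmentation loss during the
        # joint-distillation stage, then is frozen (stages 2-3 shift toward
        # student autonomy)
        f1 <- forward_with_taps(teacher1, ba$x, training = st_id == 1L)
        if (st_id == 1L) {
          ad_backward(seg_loss(f1$logits, ba$y))
          adam_step(opt_t1)
        }
        t1out <- list(logits = ad_detach(f1$logits),
                      taps = lapply(f1$taps, ad_detach),
                      attention = ad_detach(f1$attention))
        f2 <- forward_with_taps(teacher2, ba$x, training = FALSE)
        t2out <- list(logits = ad_detach(f2$logits),
                      taps = lapply(f2$taps, ad_detach))
      }
      fs <- forward_with_taps(student, ba$x, training = TRUE)
      seg <- seg_loss(fs$logits, ba$y)
      hard_idx <- which(state$hard[(b - 1L) %% length(train) + 1L])
      if (use_kd) {
        kd_for <- function(tout, tid, aligners, idx = NULL) {
          logits_s <- fs$logits; taps_s <- fs$taps
          logits_t <- tout$logits; taps_t <- tout$taps
          if (!is.null(idx)) {
            logits_s <- ad_slice_n(logits_s, idx)
            logits_t <- ad_slice_n(logits_t, idx)
            taps_s <- lapply(taps_s, ad_slice_n, idx = idx)
            taps_t <- lapply(taps_t, ad_slice_n, idx = idx)
          }
          parts <- list(
            logit = logit_kd(logits_s, logits_t, kd_cfg$temperature,
                             kd_cfg$kl_direction),
            feat = feature_kd(taps_s, taps_t, aligners))
          if (tid == 1L) {
            as_ <- student_attention(taps_s$sixteenth)
            at_ <- tout$attention
            if (!is.null(idx))
              at_ <- ad_const(at_$v[, , idx, drop = FALSE])
            parts$attn <- attention_kd(as_, at_, 1L)
          }
          ns <- if (is.null(idx)) dim(fs$logits$v)[4] else length(idx)
          parts$rel <- if (ns >= 2L)
            relation_kd(ad_gap(taps_s$sixteenth), ad_gap(taps_t$sixteenth))
          else ad_const(0)
          combine_kd(parts, kd_cfg, tid)
        }
        if (st_id < 3L) {
          kd1 <- kd_for(t1out, 1L, aligners1)
          kd2 <- kd_for(t2out, 2L, aligners2)
        } else if (!pre_drop && length(hard_idx) > 0L) {
          kd1 <- kd_for(t1out, 1L, aligners1, hard_idx)
          kd2 <- kd_for(t2out, 2L, aligners2, hard_idx)
        }
        if (st_id == 2L && length(hard_idx) > 0L)
          hard_seg <- seg_loss(ad_slice_n(fs$logits, hard_idx),
                               ba$y[, , hard_idx, drop = FALSE])
        if (st_id >= 2L && nb %% 2L == 0L) {
          # consistency view on alternating steps (desk-scale cadence)
          p_clean <- ad_softmax_c(fs$logits)
          aug_pick <- consistency_augs[1L + stream_rint(aug_s, 1, 3L)]
          cons <- consistency_loss(student, ba$x, aug_pick, aug_s,
                                   p_clean = p_clean)
        }
      }
      if (st_id == 3L) {
        state$last_drop <- pre_drop
        loss <- if (pre_drop) seg
        else ad_add(seg,
                    ad_add(ad_add(ad_scale(kd1, state$alpha),
                                  ad_scale(kd2, state$beta)),
                           ad_scale(cons, kd_cfg$consistency_weight)))
        drop_draws <- c(drop_draws, pre_drop)
      } else {
        loss <- total_loss(st_id, seg, kd1, kd2, hard_seg, cons, state,
                           kd_cfg)
      }
      ad_backward(loss)
      adam_step(opt_s)
      ep_loss <- ep_loss + as.numeric(loss$v); nb <- nb + 1L
    }

    vm <- eval_samples(student, val)
    val_dice <- mean(vm$dice)
    # validation loss for early stopping
    vb <- batch_arrays(val)
    vl <- as.numeric(seg_loss(
      forward_with_taps(student, vb$x, training = FALSE)$logits, vb$y)$v)
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, stage = st_id, lr = lr,
                 alpha = state$alpha, beta = state$beta, p_t = state$p_t,
                 train_loss = ep_loss / nb, val_loss = vl,
                 val_dice = val_dice)
    if (verbose)
      message(sprintf("epoch %d stage %d lr %.0e loss %.4f val dice %.3f",
                      epoch, st_id, lr, ep_loss / nb, val_dice))
    if (vl < best_val - 1e-6) {
      best_val <- vl; best_epoch <- epoch; patience_left <- sched$patience
      best_weights <- named_values(student)
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) {
        if (verbose) message("early stop at epoch ", epoch)
        break
      }
    }
  }

  # early stopping: the returned student carries the best-validation weights
  if (!is.null(best_weights)) assign_named_values(student, best_weights)
  history <- do.call(rbind, history)
  final_dice <- if (best_epoch >= 0L)
    history$val_dice[history$epoch == best_epoch] else
      utils::tail(history$val_dice, 1L)
  manifest <- list(
    seed = seed,
    streams = list(init = seed, augment = seed + 1000L,
                   batches = seed + 2000L, dropout = seed + 3000L),
    config = list(student = unclass(student_cfg), kd = unclass(kd_cfg),
                  schedule = unclass(sched), batch_size = batch_size,
                  use_kd = use_kd, warmup_epochs = warmup_epochs),
    best_epoch = best_epoch,
    stage3_drop_rate = if (length(drop_draws)) mean(drop_draws) else NA,
    history = history)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    utils::write.csv(history, file.path(outdir, "log.csv"),
                     row.names = FALSE)
    save_checkpoint(student, file.path(outdir, "student.rds"),
                    stage = "final")
  }
  list(student = student, manifest = manifest, history = history,
       val_dice = final_dice,
       teachers = if (use_kd) list(teacher1 = teacher1,
                                   teacher2 = teacher2) else NULL)
}
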