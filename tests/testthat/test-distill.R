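# Distillation losses against scalar hand computations, schedule and state
# machinery, and the end-to-end smoke protocol (shared with the acceptance
# suite through the memoized helpers).

test_that("logit distillation matches the closed-form KL and is nonnegative", {
  zs <- array(0, c(1, 1, 2, 1))
  zt <- array(c(log(3), 0), c(1, 1, 2, 1))
  expect_equal(as.numeric(logit_kd(zs, zt, 1)$v), 0.5 * log(4 / 3),
               tolerance = 1e-12)
  expect_equal(as.numeric(logit_kd(zs, zs, 4)$v), 0)
  st <- rng_stream(3L)
  for (i in 1:200) {
    a <- array(stream_rnorm(st, 8), c(1, 2, 2, 2))
    b <- array(stream_rnorm(st, 8), c(1, 2, 2, 2))
    expect_gte(as.numeric(logit_kd(a, b, 4)$v), 0)
    expect_gte(as.numeric(logit_kd(a, b, 4, "reverse")$v), 0)
  }
  expect_error(logit_kd(array(0, c(1, 1, 2, 1)), array(0, c(1, 1, 2, 2)),
                        4), "differ")
  expect_error(logit_kd(zs, zt, 0), "positive")
})

test_that("feature distillation: zero at equality, sum-mode oracle value,
           aligner absorbs channel permutations", {
  taps1 <- list(quarter = array(1, c(1, 1, 1, 1)),
                eighth = array(2, c(1, 1, 1, 1)),
                sixteenth = array(3, c(1, 1, 1, 1)))
  zero <- lapply(taps1, function(t) t * 0)
  expect_equal(as.numeric(feature_kd(taps1, taps1, NULL)$v), 0)
  expect_equal(as.numeric(feature_kd(taps1, zero, NULL, reduce = "sum")$v),
               14)
  expect_error(feature_kd(taps1[1:2], taps1, NULL), "taps")
  # a 1x1 aligner can absorb a teacher-channel permutation: the optimized
  # loss at the permuting aligner is exactly zero
  st <- rng_stream(9L)
  f <- array(stream_rnorm(st, 4 * 4 * 3), c(4, 4, 3, 1))
  perm <- f[, , c(2, 3, 1), , drop = FALSE]
  al <- make_aligners(list(quarter = 3, eighth = 3, sixteenth = 3),
                      list(quarter = 3, eighth = 3, sixteenth = 3), st)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  for (sc in names(al)) {
    al[[sc]]$W$v <- array(t(P), c(1, 1, 3, 3))
    al[[sc]]$b$v <- rep(0, 3)
  }
  taps_s <- list(quarter = f, eighth = f, sixteenth = f)
  taps_t <- list(quarter = perm, eighth = perm, sixteenth = perm)
  expect_lt(as.numeric(feature_kd(taps_s, taps_t, al)$v), 1e-20)
})

test_that("student attention is row-stochastic and matches the scalar
           softmax example", {
  f <- array(0, c(2, 1, 2, 1))
  f[1, 1, 1, 1] <- 1; f[2, 1, 2, 1] <- 1   # orthogonal unit tokens
  A <- student_attention(f, d = 1)
  e <- exp(1) / (exp(1) + 1)
  expect_equal(A$v[1, , 1], c(e, 1 - e), tolerance = 1e-12)
  expect_equal(A$v[2, , 1], c(1 - e, e), tolerance = 1e-12)
  st <- rng_stream(7L)
  fr <- array(stream_rnorm(st, 4 * 4 * 6 * 2), c(4, 4, 6, 2))
  Ar <- student_attention(fr)
  expect_equal(apply(Ar$v, c(1, 3), sum), matrix(1, 16, 2),
               tolerance = 1e-9)
})

test_that("attention distillation: Frobenius arithmetic, teacher-2
           rejection", {
  expect_equal(as.numeric(attention_kd(matrix(0.5, 2, 2),
                                       matrix(0, 2, 2))$v), 1)
  expect_equal(as.numeric(attention_kd(diag(2), diag(2))$v), 0)
  expect_error(attention_kd(diag(2), diag(2), teacher_id = 2L),
               "teacher 1")
})

test_that("relation distillation: cosine-similarity matrices", {
  S <- diag(2)                      # orthogonal embeddings
  Tm <- matrix(1, 2, 2)             # identical embeddings
  expect_equal(as.numeric(relation_kd(S, Tm)$v), 2)
  expect_equal(as.numeric(relation_kd(Tm, Tm)$v), 0)
  st <- rng_stream(11L)
  E <- matrix(stream_rnorm(st, 12), 4, 3)
  R <- crossprod(E / rep(sqrt(colSums(E^2)), each = 4))
  expect_equal(diag(R), rep(1, 3), tolerance = 1e-12)
  expect_equal(R, t(R), tolerance = 1e-12)
  expect_warning(z <- relation_kd(matrix(1, 3, 1), matrix(1, 3, 1)),
                 "batch size")
  expect_equal(as.numeric(z$v), 0)
})

test_that("per-teacher combination applies the printed weights", {
  cfg <- kd_config()
  p <- list(logit = 1, feat = 1, attn = 1, rel = 1)
  expect_equal(as.numeric(combine_kd(p, cfg, 1L)$v), 1.6)
  expect_equal(as.numeric(combine_kd(list(logit = 1, feat = 1, rel = 1),
                                     cfg, 2L)$v), 1.4)
  expect_equal(as.numeric(combine_kd(list(logit = 0, feat = 0, attn = 0,
                                          rel = 0), cfg, 1L)$v), 0)
})

test_that("segmentation loss: near-zero at a perfect hard prediction, focal
           arithmetic, monotone improvement", {
  mk <- matrix(0, 4, 4); mk[2:3, 2:3] <- 1
  good <- array(0, c(4, 4, 2, 1))
  good[, , 1, 1] <- 20 * (1 - mk); good[, , 2, 1] <- 20 * mk
  expect_lt(as.numeric(seg_loss(good, mk)$v), 1e-3)
  # uniform probabilities at one background pixel: focal part
  # 0.75 * 0.5^2 * ln 2, dice part 1 - 1/1.5
  l0 <- as.numeric(seg_loss(array(0, c(1, 1, 2, 1)), matrix(0, 1, 1))$v)
  expect_equal(l0, 0.75 * 0.25 * log(2) + (1 - 1 / 1.5), tolerance = 1e-12)
  # loss decreases along the segment from a wrong to a right prediction
  wrong <- array(0, c(1, 1, 2, 1)); wrong[, , 1, 1] <- 5
  right <- array(0, c(1, 1, 2, 1)); right[, , 2, 1] <- 5
  m1 <- matrix(1, 1, 1)
  last <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    cur <- as.numeric(seg_loss((1 - t) * wrong + t * right, m1)$v)
    expect_lt(cur, last)
    last <- cur
  }
  expect_error(seg_loss(good, mk * 0.5), "binary")
})

test_that("stage partition covers every epoch with the 40/40/20 rule", {
  s150 <- stage_schedule(150L)
  expect_equal(stage_of(0L, s150), 1L)
  expect_equal(stage_of(59L, s150), 1L)
  expect_equal(stage_of(60L, s150), 2L)
  expect_equal(stage_of(119L, s150), 2L)
  expect_equal(stage_of(120L, s150), 3L)
  expect_equal(stage_of(149L, s150), 3L)
  expect_equal(stage_of(0:9, stage_schedule(10L)),
               c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))
  expect_equal(as.vector(table(stage_of(0:4, stage_schedule(5L)))),
               c(2L, 2L, 1L))
  for (E in c(1L, 2L, 3L, 7L, 10L, 150L)) {
    sd_ <- stage_schedule(E)
    st <- stage_of(0:(E - 1L), sd_)
    expect_true(all(st %in% 1:3))
    expect_equal(sum(st == 1L), ceiling(0.4 * E))
  }
  expect_error(stage_of(10L, stage_schedule(10L)), "range")
})

test_that("teacher weights follow the asymmetric update with clamping", {
  st <- distill_state()
  update_teacher_weights(st, 0.9, 0.8)
  expect_equal(c(st$alpha, st$beta), c(0.6, 0.25))
  st2 <- distill_state()
  update_teacher_weights(st2, 0.7, 0.8)
  expect_equal(c(st2$alpha, st2$beta), c(0.45, 0.4))
  # ties take the "otherwise" branch
  st3 <- distill_state()
  update_teacher_weights(st3, 0.5, 0.5)
  expect_equal(c(st3$alpha, st3$beta), c(0.45, 0.4))
  # repeated wins never escape [0, 1]
  st4 <- distill_state()
  for (i in 1:50) update_teacher_weights(st4, 1, 0)
  expect_lte(st4$alpha, 1)
  expect_gte(st4$beta, 0)
  for (i in 1:50) update_teacher_weights(st4, 0, 1)
  expect_gte(st4$alpha, 0)
  expect_lte(st4$beta, 1)
})

test_that("curriculum fraction interpolates 0.2 -> 0.5 across stage 2", {
  s10 <- stage_schedule(10L)
  expect_equal(curriculum_fraction(4L, s10), 0.2)
  expect_equal(curriculum_fraction(7L, s10), 0.5)
  s150 <- stage_schedule(150L)
  expect_equal(curriculum_fraction(60L, s150), 0.2)
  expect_equal(curriculum_fraction(119L, s150), 0.5)
  mid <- (60 + 119) / 2
  expect_equal(curriculum_fraction(89L, s150) + curriculum_fraction(90L, s150),
               0.7)  # symmetric around the midpoint value 0.35
  expect_error(curriculum_fraction(2L, s10), "stage-2")
  # flagged set size on n validation samples
  expect_equal(ceiling(0.35 * 48), 17)
})

test_that("hard-sample flags use strict inequalities", {
  expect_true(hard_flag(0.69, 5))
  expect_false(hard_flag(0.70, 20))
  expect_true(hard_flag(0.95, 21))
  expect_equal(hard_flag(c(0.5, 0.9), c(1, 25)), c(TRUE, TRUE))
})

test_that("stage totals follow the printed combination rules", {
  st <- distill_state()
  expect_equal(as.numeric(total_loss(1L, 1, 1, 1, state = st)$v), 1.8)
  expect_equal(as.numeric(total_loss(2L, 1, 1, 1, hard_seg = 0.5,
                                     consistency = 1, state = st)$v),
               1.8 + 2.0 * 0.5 + 0.1)
  cfg <- kd_config()
  st3 <- distill_state(cfg, seed = 77L)
  vals <- replicate(400, {
    v <- as.numeric(total_loss(3L, 2, 10, 10, state = st3, cfg = cfg)$v)
    c(v, st3$last_drop)
  })
  # dropped steps return exactly the segmentation loss
  expect_true(all(vals[1, vals[2, ] == 1] == 2))
  expect_true(all(vals[1, vals[2, ] == 0] > 2))
})

test_that("stage-3 dropout draws concentrate at p_drop over seeded steps", {
  cfg <- kd_config()
  st <- distill_state(cfg, seed = 42L)
  draws <- replicate(10000, {
    total_loss(3L, 0, 0, 0, state = st, cfg = cfg)
    st$last_drop
  })
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("consistency penalty: identity augmentation gives zero, squared
           norm arithmetic, non-invertible registration fails", {
  p <- array(0.5, c(2, 2, 1, 1))
  expect_equal(as.numeric(consistency_penalty(p, list(p))$v), 0)
  q <- p + 0.1
  expect_equal(as.numeric(consistency_penalty(p, list(q),
                                              reduce = "sum")$v), 0.04,
               tolerance = 1e-12)
  net <- build_student(student_config(16L, c(64L, 64L)), rng_stream(21L))
  x <- array(stream_runif(rng_stream(22L), 64 * 64 * 3), c(64, 64, 3, 1))
  expect_error(consistency_loss(net, x, augmentations = "elastic_warp"),
               "non-invertible|unknown")
  idl <- consistency_loss(net, x, augmentations = "identity",
                          stream = rng_stream(23L))
  expect_equal(as.numeric(idl$v), 0, tolerance = 1e-12)
})

test_that("all distillation losses vanish when student equals teacher", {
  st <- rng_stream(31L)
  z <- array(stream_rnorm(st, 4 * 4 * 2 * 2), c(4, 4, 2, 2))
  taps <- list(quarter = array(stream_rnorm(st, 16), c(2, 2, 4, 1)),
               eighth = array(stream_rnorm(st, 16), c(2, 2, 4, 1)),
               sixteenth = array(stream_rnorm(st, 16), c(2, 2, 4, 1)))
  A <- student_attention(taps$sixteenth)
  E <- matrix(stream_rnorm(st, 8), 4, 2)
  expect_equal(as.numeric(logit_kd(z, z, 4)$v), 0)
  expect_equal(as.numeric(feature_kd(taps, taps, NULL)$v), 0)
  expect_equal(as.numeric(attention_kd(A, ad_detach(A))$v), 0)
  expect_equal(as.numeric(relation_kd(E, E)$v), 0)
})

test_that("the smoke protocol executes the full three-stage schedule with
           the prescribed learning rates and restores the best weights", {
  res <- smoke_run(smoke_seeds[1], use_kd = TRUE)
  h <- res$history
  expect_equal(h$stage, c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3)[seq_len(nrow(h))])
  expect_equal(unique(h$lr[h$stage == 1]), 2e-4)
  expect_equal(unique(h$lr[h$stage == 2]), 1e-4)
  expect_equal(unique(h$lr[h$stage == 3]), 5e-5)
  # dynamic teacher weights stay clamped and the manifest is complete
  expect_true(all(h$alpha >= 0 & h$alpha <= 1))
  expect_true(all(h$beta >= 0 & h$beta <= 1))
  expect_true(all(h$p_t >= 0.2 & h$p_t <= 0.5))
  man <- res$manifest
  expect_named(man$streams, c("init", "augment", "batches", "dropout"))
  expect_true(man$best_epoch >= 0)
  expect_true(is.finite(man$stage3_drop_rate))
  # the trained student segments the synthetic task far above chance
  expect_gte(res$val_dice, 0.6)
  # single-branch inference: the returned student predicts without any
  # teacher object present
  val <- Filter(function(s) identical(s$split, "val"), smoke_samples())
  ba <- batch_arrays(val)
  pred <- predict_masks(res$student, ba$x)
  expect_equal(dim(pred), c(64L, 64L, length(val)))
})
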