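# Shared fixtures. The end-to-end smoke trainings are expensive, so they are
# computed once per test run and memoized; both the distillation invariants
# and the acceptance suite read from the same cache.

.smoke_cache <- new.env(parent = emptyenv())

smoke_samples <- function() {
  if (is.null(.smoke_cache$samples)) {
    .smoke_cache$samples <- stratified_split(
      generate_synthetic(synth_config(10L, 64L, seed = 7L)), seed = 3L)
  }
  .smoke_cache$samples
}

smoke_run <- function(seed, use_kd = TRUE) {
  key <- paste0(if (use_kd) "full" else "twin", seed)
  if (is.null(.smoke_cache[[key]])) {
    .smoke_cache[[key]] <- suppressMessages(train_pdtkd(
      smoke_samples(), student_config(16L, c(64L, 64L)), kd_config(),
      stage_schedule(10L), seed = seed, use_kd = use_kd))
  }
  .smoke_cache[[key]]
}

smoke_seeds <- 101L

tiny_feature <- function(H = 8L, W = 8L, C = 4L, N = 1L, seed = 11L) {
  array(stream_rnorm(rng_stream(seed), H * W * C * N), c(H, W, C, N))
}

# jitter parameters away from the exact zero-init point (ReLU/batch-norm
# kinks live there) before finite-difference checks
jitter_params <- function(module, sd = 0.02, seed = 5L) {
  st <- rng_stream(seed)
  for (p in collect_params(module))
    p$v <- p$v + stream_rnorm(st, length(p$v), sd = sd)
  invisible(module)
}
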