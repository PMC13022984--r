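# Published EBHI-SEG benchmark tables for this architecture family, shipped
# as plain CSV fixtures, plus the aggregate arithmetic derived from them
# (per-category means, ablation drops, efficiency reductions).

#' Load the shipped benchmark tables
#'
#' @return list with `metrics` (per-network, per-category Dice / Jaccard /
#'   ASD / precision / recall on EBHI-SEG), `complexity` (mIoU, parameters,
#'   FLOPs) and `ablation` (component-removal variants)
#' @export
benchmark_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "histoseg",
                               mustWork = TRUE)
  list(metrics = utils::read.csv(p("ebhi_benchmark_metrics.csv"),
                                 check.names = FALSE),
       complexity = utils::read.csv(p("ebhi_benchmark_complexity.csv"),
                                    check.names = FALSE),
       ablation = utils::read.csv(p("ebhi_ablation_metrics.csv"),
                                  check.names = FALSE))
}

table_row <- function(df, key_col, key, metric = NULL) {
  sub <- df[df[[key_col]] == key, , drop = FALSE]
  if (!is.null(metric)) sub <- sub[sub$metric == metric, , drop = FALSE]
  stopifnot(nrow(sub) == 1L)
  as.numeric(sub[, !(names(sub) %in% c(key_col, "metric")), drop = FALSE])
}

#' Aggregate arithmetic over the benchmark tables
#'
#' Recomputes, from the shipped CSVs, the summary quantities the tables
#' imply: the full model's six-category mean Dice and mean ASD, the
#' mean-Dice drops (percentage points) from removing each component, the
#' mIoU gain over the base network, and the parameter / FLOP reductions
#' relative to the heaviest transformer baseline.
#' @return named list of scalars:
#'   `mean_dice_full`, `mean_asd_full`, `drop_wo_msaspp_pp`,
#'   `drop_wo_afetam_pp`, `drop_wo_pdtkd_pp`, `miou_gain_vs_base_pp`,
#'   `param_reduction_vs_transunet_pct`, `flop_reduction_vs_transunet_pct`
#' @export
benchmark_summary <- function() {
  tb <- benchmark_tables()
  full_dice <- table_row(tb$metrics, "network", "MAPSCTNet", "dice")
  full_asd <- table_row(tb$metrics, "network", "MAPSCTNet", "asd")
  drop_pp <- function(variant) {
    v <- table_row(tb$ablation, "variant", variant, "dice")
    100 * (mean(full_dice) - mean(v))
  }
  comp <- tb$complexity
  miou_full <- comp$miou[comp$network == "MAPSCTNet"]
  miou_base <- comp$miou[comp$network == "SCTNet"]
  p_tu <- comp$params_m[comp$network == "TransUnet"]
  f_tu <- comp$flops_g[comp$network == "TransUnet"]
  p_full <- comp$params_m[comp$network == "MAPSCTNet"]
  f_full <- comp$flops_g[comp$network == "MAPSCTNet"]
  list(mean_dice_full = mean(full_dice),
       mean_asd_full = mean(full_asd),
       drop_wo_msaspp_pp = drop_pp("wo_msaspp"),
       drop_wo_afetam_pp = drop_pp("wo_afetam"),
       drop_wo_pdtkd_pp = drop_pp("wo_pdtkd"),
       miou_gain_vs_base_pp = 100 * (miou_full - miou_base),
       param_reduction_vs_transunet_pct = 100 * (p_tu - p_full) / p_tu,
       flop_reduction_vs_transunet_pct = 100 * (f_tu - f_full) / f_tu)
}
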