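# Segmentation evaluation: overlap metrics (Dice, Jaccard, precision,
# recall), boundary metrics (average symmetric surface distance, 95th
# percentile Hausdorff) and two-class mean IoU, with explicit empty-mask
# conventions. Masks are binary (H, W) matrices, foreground = 1 = lesion.

check_binary_mask <- function(m, name = "mask") {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1)))
    stop(name, " must be binary (0/1)", call. = FALSE)
  m
}

#' Overlap metrics between two binary masks
#'
#' Dice = 2TP / (2TP + FP + FN); Jaccard = TP / (TP + FP + FN);
#' precision = TP / (TP + FP); recall = TP / (TP + FN).
#' Conventions for degenerate cases: both masks empty -> all four metrics 1
#' (perfect agreement); reference empty but prediction non-empty (or vice
#' versa) -> all four 0.
#' @param pred,ref binary (H, W) matrices on the same grid
#' @return named list `dice`, `jaccard`, `precision`, `recall`
#' @export
overlap_metrics <- function(pred, ref) {
  pred <- check_binary_mask(pred, "pred")
  ref <- check_binary_mask(ref, "ref")
  if (!all(dim(pred) == dim(ref)))
    stop("mask shapes differ", call. = FALSE)
  tp <- sum(pred == 1 & ref == 1)
  fp <- sum(pred == 1 & ref == 0)
  fn <- sum(pred == 0 & ref == 1)
  if (tp + fp + fn == 0)
    return(list(dice = 1, jaccard = 1, precision = 1, recall = 1))
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(dice = safe(2 * tp, 2 * tp + fp + fn),
       jaccard = safe(tp, tp + fp + fn),
       precision = safe(tp, tp + fp),
       recall = safe(tp, tp + fn))
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one 4-adjacent background pixel; pixels on
#' the image border count as boundary.
#' @param mask binary matrix
#' @return logical matrix marking boundary pixels
#' @export
mask_boundary <- function(mask) {
  mask <- check_binary_mask(mask)
  d <- dim(mask)
  pad <- matrix(0, d[1] + 2L, d[2] + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2])] <- mask
  inner <- seq_len(d[1]) + 1L
  innc <- seq_len(d[2]) + 1L
  nb_min <- pmin(pad[inner - 1L, innc], pad[inner + 1L, innc],
                 pad[inner, innc - 1L], pad[inner, innc + 1L])
  mask == 1 & nb_min == 0
}

#' Surface distances between two binary masks
#'
#' Boundary point sets are extracted with 4-connectivity; directed distances
#' are Euclidean nearest-boundary distances (computed via a distance
#' transform). ASD is the symmetric mean of both directed distance sets;
#' HD95 is the larger of the two directed 95th percentiles.
#' Conventions: both masks empty -> both metrics 0; exactly one empty -> both
#' metrics equal the image diagonal (a bounded, monotone penalty).
#' @param pred,ref binary matrices on the same grid
#' @return named list `asd`, `hd95` (pixels)
#' @export
surface_distances <- function(pred, ref) {
  pred <- check_binary_mask(pred, "pred")
  ref <- check_binary_mask(ref, "ref")
  if (!all(dim(pred) == dim(ref)))
    stop("mask shapes differ", call. = FALSE)
  pe <- sum(pred) == 0
  re <- sum(ref) == 0
  if (pe && re) return(list(asd = 0, hd95 = 0))
  diag_ <- sqrt(sum(dim(pred)^2))
  if (pe || re) return(list(asd = diag_, hd95 = diag_))
  bp <- mask_boundary(pred)
  br <- mask_boundary(ref)
  # distance of every pixel to the nearest boundary pixel of the other mask
  dist_to <- function(boundary) {
    img <- EBImage::Image(1 - boundary)
    as.matrix(EBImage::distmap(img, metric = "euclidean"))
  }
  d_to_ref <- dist_to(br)
  d_to_pred <- dist_to(bp)
  dpr <- d_to_ref[bp]    # pred boundary -> ref boundary
  drp <- d_to_pred[br]   # ref boundary -> pred boundary
  list(asd = mean(c(dpr, drp)),
       hd95 = max(stats::quantile(dpr, 0.95, names = FALSE),
                  stats::quantile(drp, 0.95, names = FALSE)))
}

#' Two-class mean intersection-over-union
#'
#' Per image, the IoUs of background and foreground are averaged (a class
#' absent from both masks counts as IoU 1); the dataset value is the mean
#' over images. This averaging order (image-level two-class mean, then
#' dataset macro mean) is the definition used in all reports.
#' @param preds,refs lists of binary matrices, matched by position
#' @return scalar mIoU in `[0, 1]`
#' @export
miou <- function(preds, refs) {
  if (length(preds) == 0L) stop("empty mask list", call. = FALSE)
  if (length(preds) != length(refs))
    stop("pred/ref lists differ in length", call. = FALSE)
  per_image <- vapply(seq_along(preds), function(i) {
    p <- check_binary_mask(preds[[i]], "pred")
    r <- check_binary_mask(refs[[i]], "ref")
    iou_class <- function(cls) {
      inter <- sum(p == cls & r == cls)
      uni <- sum(p == cls | r == cls)
      if (uni == 0) 1 else inter / uni
    }
    (iou_class(0) + iou_class(1)) / 2
  }, numeric(1))
  mean(per_image)
}

#' Full metric report for one prediction/reference pair
#' @param pred,ref binary matrices
#' @return named list with dice, jaccard, precision, recall, asd, hd95
#' @export
evaluate_pair <- function(pred, ref) {
  c(overlap_metrics(pred, ref), surface_distances(pred, ref))
}

#' Evaluate matched mask lists and aggregate by category
#'
#' @param preds,refs lists of binary matrices
#' @param categories optional character vector of per-image categories
#' @param ids optional image identifiers
#' @return list with `per_image` (data frame), `by_category` (data frame of
#'   per-category means), `macro` (named means over images) and `miou`
#' @export
evaluate_masks <- function(preds, refs, categories = NULL, ids = NULL) {
  stopifnot(length(preds) == length(refs))
  n <- length(preds)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(n))
  if (is.null(categories)) categories <- rep("all", n)
  rows <- lapply(seq_len(n), function(i) {
    m <- evaluate_pair(preds[[i]], refs[[i]])
    data.frame(id = ids[i], category = categories[i],
               dice = m$dice, jaccard = m$jaccard,
               precision = m$precision, recall = m$recall,
               asd = m$asd, hd95 = m$hd95, stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- c("dice", "jaccard", "precision", "recall", "asd", "hd95")
  by_category <- stats::aggregate(per_image[metric_cols],
                                  by = list(category = per_image$category),
                                  FUN = mean)
  macro <- colMeans(per_image[metric_cols])
  list(per_image = per_image, by_category = by_category,
       macro = as.list(macro), miou = miou(preds, refs))
}

#' Write a metric report to disk
#'
#' Per-image CSV plus an aggregate JSON keyed by category (mirroring the
#' usual per-category benchmark table layout), including the mIoU definition
#' used.
#' @param report result of [evaluate_masks()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "per_image_metrics.csv")
  utils::write.csv(report$per_image, csv, row.names = FALSE)
  js <- file.path(dir, "aggregate_metrics.json")
  agg <- list(miou_definition = "image-level two-class mean IoU, macro-averaged over images",
              miou = report$miou,
              macro = report$macro,
              by_category = report$by_category)
  jsonlite::write_json(agg, js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv, js))
}
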