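#' Region overlap scores for a mask pair
#'
#' Computes the four standard region metrics between a ground-truth and a
#' predicted binary mask, on pixel sets: IoU (intersection over union),
#' Dice (`2|I| / (|GT| + |PR|)`), Recall (`|I| / |GT|`) and Precision
#' (`|I| / |PR|`). Empty denominators follow the convention: a metric is 1
#' when both masks are empty and 0 when exactly one is.
#'
#' @param gt,pred Binary mask matrices of identical dimensions.
#' @return A one-row tibble with columns `iou`, `dice`, `recall`,
#'   `precision`, all in `[0, 1]`.
#' @export
#' @examples
#' gt <- matrix(0, 4, 4); gt[1:2, 1:2] <- 1
#' region_scores(gt, gt)
region_scores <- function(gt, pred) {
  gt <- as_binary_mask(assert_mask(gt, "gt"))
  pred <- as_binary_mask(assert_mask(pred, "pred"))
  if (!all(dim(gt) == dim(pred))) abort("gt and pred dimensions differ")
  n_gt <- sum(gt); n_pr <- sum(pred)
  n_int <- sum(gt * pred)
  n_uni <- n_gt + n_pr - n_int
  safe <- function(num, den) {
    if (den > 0) num / den else if (n_gt == 0 && n_pr == 0) 1 else 0
  }
  tibble::tibble(
    iou = safe(n_int, n_uni),
    dice = safe(2 * n_int, n_gt + n_pr),
    recall = safe(n_int, n_gt),
    precision = safe(n_int, n_pr)
  )
}

check_prob_pair <- function(pred, gt) {
  if (!is.matrix(pred) || !is.matrix(gt)) abort("pred and gt must be matrices")
  if (!all(dim(pred) == dim(gt))) abort("pred and gt dimensions differ")
  if (anyNA(pred) || any(pred < 0) || any(pred > 1))
    abort("pred must contain probabilities in [0, 1]")
  invisible(TRUE)
}

#' Segmentation losses
#'
#' Soft Dice, Jaccard and binary cross-entropy losses between a predicted
#' probability map and a binary ground-truth mask. The soft intersection is
#' `sum(p * y)`, making the losses differentiable for training; on binary
#' predictions with `smooth = 0` they reduce exactly to `1 - Dice` and
#' `1 - IoU`. The additive smoothing constant (default 1) in numerator and
#' denominator stabilizes near-empty masks. Probabilities are clipped to
#' `[eps, 1 - eps]` in the cross-entropy before taking logarithms.
#'
#' @param pred Probability map (matrix in `[0, 1]`).
#' @param gt Binary ground-truth mask, same dimensions.
#' @param smooth Additive smoothing constant for Dice/Jaccard.
#' @param eps Clipping bound for the cross-entropy logs.
#' @return A scalar loss value.
#' @export
#' @examples
#' y <- matrix(c(1, 0, 1, 0), 2, 2)
#' dice_loss(y, y, smooth = 0)
dice_loss <- function(pred, gt, smooth = 1) {
  check_prob_pair(pred, gt)
  y <- as_binary_mask(gt)
  1 - (2 * sum(pred * y) + smooth) / (sum(pred) + sum(y) + smooth)
}

#' @rdname dice_loss
#' @export
jaccard_loss <- function(pred, gt, smooth = 1) {
  check_prob_pair(pred, gt)
  y <- as_binary_mask(gt)
  inter <- sum(pred * y)
  union <- sum(pred) + sum(y) - inter
  1 - (inter + smooth) / (union + smooth)
}

#' @rdname dice_loss
#' @export
bce_loss <- function(pred, gt, eps = 1e-7) {
  check_prob_pair(pred, gt)
  y <- as_binary_mask(gt)
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Consensus ground truth from multiple annotators
#'
#' Pixel-wise intersection (logical AND) of two or more binary masks: a
#' pixel is foreground in the consensus only if every annotator marked it.
#'
#' @param masks A list of at least two binary mask matrices with equal
#'   dimensions.
#' @return A 0/1 integer matrix.
#' @export
consensus_mask <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    abort("need a list of at least 2 masks")
  masks <- lapply(masks, function(m) as_binary_mask(assert_mask(m)))
  d <- dim(masks[[1L]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1))))
    abort("all masks must share dimensions")
  Reduce(function(a, b) a * b, masks)
}

#' Evaluate a directory-free set of mask pairs
#'
#' Convenience wrapper: per-pair region scores plus a mean and standard
#' deviation summary row, in the layout used for cross-validated
#' segmentation reporting.
#'
#' @param gt_masks,pred_masks Lists of paired binary masks.
#' @param ids Optional identifiers (default sequence numbers).
#' @return A list with `scores` (per-pair tibble) and `summary` (tibble of
#'   mean and sd per metric).
#' @export
evaluate_masks <- function(gt_masks, pred_masks, ids = NULL) {
  if (length(gt_masks) != length(pred_masks)) abort("unpaired mask lists")
  if (length(gt_masks) == 0L) abort("no mask pairs supplied")
  if (is.null(ids)) ids <- sprintf("case_%04d", seq_along(gt_masks))
  scores <- purrr::map2(gt_masks, pred_masks, region_scores) |>
    dplyr::bind_rows() |>
    dplyr::mutate(case_id = ids, .before = 1L)
  summary <- scores |>
    dplyr::summarise(dplyr::across(
      c("iou", "dice", "recall", "precision"),
      list(mean = mean, sd = stats::sd)
    ))
  list(scores = scores, summary = summary)
}
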