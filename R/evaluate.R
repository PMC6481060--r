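# Segmentation evaluation: overlap metrics and the signed area
# difference statistic used to validate automated total-cell-area
# segmentation against a reference (e.g. manual) mask.

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("mask shapes %dx%d and %dx%d do not match",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to overlap
#' perfectly (1).
#'
#' @param a,b [bf_mask()] objects or logical matrices of one shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  pa <- as_mask_pixels(a); pb <- as_mask_pixels(b)
  check_same_shape(pa, pb)
  denom <- sum(pa) + sum(pb)
  if (denom == 0) return(1)
  2 * sum(pa & pb) / denom
}

#' Intersection-over-union (Jaccard index)
#'
#' `|A n B| / |A u B|`; two empty masks give 1. Never exceeds the Dice
#' coefficient.
#'
#' @inheritParams dice
#' @return A number in `[0, 1]`.
#' @export
iou <- function(a, b) {
  pa <- as_mask_pixels(a); pb <- as_mask_pixels(b)
  check_same_shape(pa, pb)
  un <- sum(pa | pb)
  if (un == 0) return(1)
  sum(pa & pb) / un
}

#' Signed area difference in percent
#'
#' `(area(auto) - area(ref)) / area(ref) * 100`, with the reference
#' area taken as 100%. Positive values mean the automated mask is larger
#' than the reference — the typical direction when contrasting debris is
#' picked up that an annotator would ignore.
#'
#' @param auto Automated segmentation mask.
#' @param ref Reference (e.g. manual) mask; must be nonempty.
#' @return Signed percentage.
#' @export
area_difference_percent <- function(auto, ref) {
  pa <- as_mask_pixels(auto); pr <- as_mask_pixels(ref)
  check_same_shape(pa, pr)
  if (sum(pr) == 0)
    stop("reference mask is empty; area difference is undefined")
  (sum(pa) - sum(pr)) / sum(pr) * 100
}

#' Evaluate one automated/reference mask pair
#'
#' @inheritParams area_difference_percent
#' @return One-row data frame with `dice`, `iou`, `area_diff_percent`.
#' @export
evaluate_pair <- function(auto, ref) {
  data.frame(dice = dice(auto, ref), iou = iou(auto, ref),
             area_diff_percent = area_difference_percent(auto, ref))
}

#' Summarize area differences over a batch of mask pairs
#'
#' Computes the mean and sample standard deviation (n-1 denominator) of
#' [area_difference_percent()] over a list of `(auto, ref)` pairs — the
#' summary used to report agreement between automated and manual
#' segmentation.
#'
#' @param pairs List of length-2 lists/pairs `(auto, ref)`.
#' @return Named list with `mean` and `sd` (both in percent) and the
#'   per-pair `differences`.
#' @export
evaluate_batch <- function(pairs) {
  if (!is.list(pairs) || length(pairs) < 2L)
    stop("'pairs' must be a list of at least 2 (auto, ref) pairs")
  d <- vapply(pairs,
              function(p) area_difference_percent(p[[1L]], p[[2L]]),
              numeric(1))
  list(mean = mean(d), sd = stats::sd(d), differences = d)
}
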