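# Dice score and Hausdorff distance with the missing-label conventions:
# a pair where exactly one label is absent scores Dice 0 and an infinite
# HD; a pair where both are absent is undefined and excluded from
# aggregation. Dice is aggregated by the mean, HD by the median.

#' Dice score of two regions
#'
#' `2 |A n B| / (|A| + |B|)` over two binary regions on the same grid.
#' Returns 0 when exactly one region is empty and `NA` (undefined) when
#' both are empty.
#'
#' @param region_a,region_b Logical matrices (or 0/1) of identical shape.
#' @return Numeric in `[0, 1]`, or `NA` when undefined.
#' @export
dice_score <- function(region_a, region_b) {
  if (!all(dim(region_a) == dim(region_b)))
    stop("regions must share the same grid", call. = FALSE)
  a <- sum(region_a != 0)
  b <- sum(region_b != 0)
  if (a + b == 0) return(NA_real_)
  2 * sum(region_a != 0 & region_b != 0) / (a + b)
}

#' Hausdorff distance between two contours
#'
#' Symmetric maximum of the directed minimum Euclidean distances between
#' two finite point sets: `max{ max_a min_b d(a,b), max_b min_a d(b,a) }`.
#' When exactly one contour is absent the distance is `+Inf`; when both
#' are absent it is undefined (`NA`).
#'
#' @param contour_a,contour_b Two-column matrices of point coordinates, or
#'   `NULL` for an absent contour.
#' @return Non-negative distance, `Inf`, or `NA` when undefined.
#' @export
hausdorff_distance <- function(contour_a, contour_b) {
  empty <- function(x) is.null(x) || NROW(x) == 0
  if (empty(contour_a) && empty(contour_b)) return(NA_real_)
  if (empty(contour_a) || empty(contour_b)) return(Inf)
  a <- as.matrix(contour_a); b <- as.matrix(contour_b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

#' Classify a predicted mask against a manual reference
#'
#' Images without a manual reference label are excluded; a nonempty
#' reference with an empty prediction is a missing label; otherwise the
#' prediction is correct when its myocardium Dice reaches `tau` and
#' incorrect below. `tau` is an operational proxy for a visual
#' correctness check and should be reported with results.
#'
#' @param pred,ref Integer label matrices on the same grid.
#' @param tau Myocardium Dice threshold for correctness (default 0.5).
#' @return One of `"correct"`, `"incorrect"`, `"missing"`, `"excluded"`.
#' @export
classify_prediction <- function(pred, ref, tau = 0.5) {
  if (!all(dim(pred) == dim(ref)))
    stop("prediction and reference must share the same grid", call. = FALSE)
  if (all(ref == 0L)) return("excluded")
  if (all(pred == 0L)) return("missing")
  d <- dice_score(pred == 2L, ref == 2L)
  if (!is.na(d) && d >= tau) "correct" else "incorrect"
}

#' Tally prediction classifications as percentages
#'
#' @param statuses Character vector of classifications from
#'   [classify_prediction()].
#' @return Data frame with counts and percentages of correct, incorrect
#'   and missing over the included (non-excluded) images.
#' @export
prediction_status_tally <- function(statuses) {
  inc <- statuses[statuses != "excluded"]
  if (length(inc) == 0) stop("no included images", call. = FALSE)
  lev <- c("correct", "incorrect", "missing")
  cnt <- vapply(lev, function(l) sum(inc == l), integer(1))
  data.frame(status = lev, n = cnt,
             percent = 100 * cnt / length(inc),
             n_included = length(inc), row.names = NULL)
}

#' Pairwise agreement between a predicted and a reference mask
#'
#' Dice is computed on the filled regions (cavity for LV, myocardial ring
#' for MY); HD on the boundary point sets (endocardial contours for LV,
#' epicardial contours for MY) extracted by [mask_to_contours()].
#'
#' @param pred,ref Integer label masks on the same grid.
#' @param hd_units `"px"` (default) or `"mm"`.
#' @param pixel_spacing_mm Pixel spacing used when `hd_units = "mm"`.
#' @return A one-row data frame: `status` (both_present, reference_only,
#'   prediction_only, both_absent), `dice_lv`, `dice_my`, `hd_lv`,
#'   `hd_my`.
#' @export
pairwise_agreement <- function(pred, ref, hd_units = c("px", "mm"),
                               pixel_spacing_mm = 0.4) {
  hd_units <- match.arg(hd_units)
  if (!all(dim(pred) == dim(ref)))
    stop("masks must share the same grid", call. = FALSE)
  pe <- all(pred == 0L); re <- all(ref == 0L)
  status <- if (pe && re) "both_absent" else if (re) "prediction_only"
            else if (pe) "reference_only" else "both_present"
  if (status == "both_absent") {
    return(data.frame(status = status, dice_lv = NA_real_,
                      dice_my = NA_real_, hd_lv = NA_real_,
                      hd_my = NA_real_))
  }
  scale <- if (hd_units == "mm") pixel_spacing_mm else 1
  cp_p <- suppressMessages(mask_to_contours(pred))
  cp_r <- suppressMessages(mask_to_contours(ref))
  data.frame(
    status = status,
    dice_lv = dice_score(pred == 1L, ref == 1L),
    dice_my = dice_score(pred == 2L, ref == 2L),
    hd_lv = hausdorff_distance(cp_p$endo, cp_r$endo) * scale,
    hd_my = hausdorff_distance(cp_p$epi, cp_r$epi) * scale)
}

#' Aggregate per-image agreement rows
#'
#' Dice is aggregated by the mean and HD by the median, over pairs with
#' defined metrics (both-absent pairs are excluded). Infinite HDs
#' participate in the median as `+Inf`; the display cap of 100 (see
#' [cap_hd()]) is for plotting only and never enters the median.
#'
#' @param pairs Data frame of rows from [pairwise_agreement()].
#' @return One-row data frame with `mean_dice_lv`, `mean_dice_my`,
#'   `median_hd_lv`, `median_hd_my` and `n_pairs`.
#' @export
aggregate_agreement <- function(pairs) {
  defined <- pairs$status != "both_absent"
  if (!any(defined)) stop("no pairs with defined metrics", call. = FALSE)
  p <- pairs[defined, , drop = FALSE]
  med <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else stats::median(x)
  }
  data.frame(
    mean_dice_lv = mean(p$dice_lv, na.rm = TRUE),
    mean_dice_my = mean(p$dice_my, na.rm = TRUE),
    median_hd_lv = med(p$hd_lv),
    median_hd_my = med(p$hd_my),
    n_pairs = nrow(p))
}

#' Cap Hausdorff distances for visualisation
#'
#' Maps values greater than `cap` (including infinite values) to `cap`.
#' For plotting only; aggregation always uses the uncapped values.
#'
#' @param x Numeric vector of distances.
#' @param cap Display cap (default 100).
#' @return Capped vector.
#' @export
cap_hd <- function(x, cap = 100) pmin(x, cap)
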