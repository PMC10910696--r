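# Evaluation: pixel confusion counts, F1 / Dice, boundary localization error
# from 24 radial contour samples, and the vertical cup-to-disc ratio.

#' Pixelwise confusion counts
#'
#' @param pred,gt binary matrices of identical shape.
#' @return named integer vector `TP, FP, FN, TN`.
#' @export
confusionCounts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("shape mismatch between prediction and ground truth")
  pred <- pred > 0.5; gt <- gt > 0.5
  c(TP = sum(pred & gt), FP = sum(pred & !gt),
    FN = sum(!pred & gt), TN = sum(!pred & !gt))
}

#' F1 score, precision, recall, and Dice coefficient from confusion counts
#'
#' `F1 = 2PR/(P+R)` and `DC = 2TP/(2TP+FP+FN)`; for binary masks the two
#' coincide. Empty-mask convention: if prediction and ground truth are both
#' empty the score is 1; if exactly one is empty it is 0.
#'
#' @param counts named vector from [confusionCounts()].
#' @return for `f1Score`/`diceScore` a scalar in `[0, 1]`; `precisionRecall`
#'   returns `c(precision, recall)`.
#' @export
f1Score <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fp + fn == 0) return(1)        # both masks empty
  if (tp == 0 && (fp == 0 || fn == 0)) return(0)  # exactly one empty
  pr <- precisionRecall(counts)
  if (sum(pr) == 0) return(0)
  unname(2 * pr[1] * pr[2] / (pr[1] + pr[2]))
}

#' @rdname f1Score
#' @export
diceScore <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fp + fn == 0) return(1)
  unname(2 * tp / (2 * tp + fp + fn))
}

#' @rdname f1Score
#' @export
precisionRecall <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Radial contour samples of a binary mask
#'
#' From a center point, marches rays at `n_rays` equally spaced angles
#' (0, 15, ..., 345 degrees for the default 24) in 0.25-px steps and records
#' the distance to the outermost mask pixel along each ray.
#'
#' @param mask binary matrix with at least one positive pixel.
#' @param n_rays number of rays (default 24).
#' @param center optional `(row, col)` center; defaults to the mask centroid.
#' @return a list of class `ContourRadii` with `center`, `angles` (radians)
#'   and `radii` (pixels).
#' @export
contourRadii <- function(mask, n_rays = 24L, center = NULL) {
  pos <- which(mask > 0.5, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("empty mask has no contour")
  if (is.null(center)) center <- c(mean(pos[, 1]) - 1, mean(pos[, 2]) - 1)
  h <- nrow(mask); w <- ncol(mask)
  angles <- (seq_len(n_rays) - 1L) * 2 * pi / n_rays
  rmax <- sqrt(h^2 + w^2)
  steps <- seq(0, rmax, by = 0.25)
  radii <- vapply(angles, function(th) {
    rr <- round(center[1] + steps * sin(th)) + 1
    cc <- round(center[2] + steps * cos(th)) + 1
    inside <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    hit <- inside & mask[cbind(pmin(pmax(rr, 1), h), pmin(pmax(cc, 1), w))] > 0.5
    if (!any(hit)) 0 else steps[max(which(hit))]
  }, numeric(1))
  structure(list(center = center, angles = angles, radii = radii),
            class = "ContourRadii")
}

#' @export
print.ContourRadii <- function(x, ...) {
  cat(sprintf("ContourRadii: %d rays from (%.1f, %.1f), mean radius %.2f px\n",
              length(x$radii), x$center[1], x$center[2], mean(x$radii)))
  invisible(x)
}

#' Boundary localization error
#'
#' Mean absolute difference between ground-truth and predicted radial
#' boundary distances sampled along the same rays from the same center:
#' `BLE = (1/N) * sum_theta |d_g - d_0|`. Smaller is better; 0 iff the radii
#' are identical. `strict_formula = TRUE` instead evaluates the difference-
#' of-squares radicand `sqrt(d_g^2 - d_0^2)` literally, which is undefined
#' (NaN) wherever the prediction overshoots the ground truth; it is provided
#' for auditability only.
#'
#' @param pred,gt `ContourRadii` objects with the same number of rays
#'   (numeric radii vectors are also accepted).
#' @param strict_formula evaluate the difference-of-squares form (default
#'   `FALSE`).
#' @return mean radial error in pixels.
#' @export
bleError <- function(pred, gt, strict_formula = FALSE) {
  rp <- if (inherits(pred, "ContourRadii")) pred$radii else pred
  rg <- if (inherits(gt, "ContourRadii")) gt$radii else gt
  if (length(rp) != length(rg))
    stop("mismatched number of rays: ", length(rp), " vs ", length(rg))
  if (strict_formula) {
    rad <- rg^2 - rp^2
    rad[rad < 0] <- NaN
    return(mean(sqrt(rad)))
  }
  mean(abs(rg - rp))
}

#' Vertical cup-to-disc ratio
#'
#' Vertical extent (max row - min row + 1) of the cup mask divided by that of
#' the disc mask. Values above roughly 0.4 are associated with glaucoma risk.
#'
#' @param disc_mask binary disc mask (must be non-empty).
#' @param cup_mask binary cup mask; if empty the ratio is 0 with a warning.
#' @return scalar ratio.
#' @export
cupDiscRatio <- function(disc_mask, cup_mask) {
  vext <- function(m) {
    rows <- which(rowSums(m > 0.5) > 0)
    if (length(rows) == 0L) return(0)
    diff(range(rows)) + 1
  }
  vd <- vext(disc_mask)
  if (vd == 0) stop("empty disc mask: CDR undefined")
  vc <- vext(cup_mask)
  if (vc == 0) {
    warning("empty cup mask: CDR reported as 0")
    return(0)
  }
  vc / vd
}

#' Evaluate predicted masks against ground truth
#'
#' Computes precision, recall, F1, Dice and BLE for the disc and the cup,
#' plus the predicted and ground-truth vertical cup-to-disc ratios. Both
#' contours of a structure are sampled from the ground-truth disc centroid
#' so the radii are comparable.
#'
#' @param pred_disc,pred_cup predicted binary masks.
#' @param gt_disc,gt_cup ground-truth binary masks.
#' @param n_rays rays for the boundary localization error.
#' @return a one-row `data.frame` with columns
#'   `disc_precision, disc_recall, disc_f1, disc_dice, disc_ble,
#'    cup_precision, cup_recall, cup_f1, cup_dice, cup_ble, cdr_pred,
#'    cdr_gt`. BLE is `NA` when a predicted structure is empty.
#' @export
evaluateMasks <- function(pred_disc, pred_cup, gt_disc, gt_cup, n_rays = 24L) {
  center <- {
    pos <- which(gt_disc > 0.5, arr.ind = TRUE)
    c(mean(pos[, 1]) - 1, mean(pos[, 2]) - 1)
  }
  one <- function(pred, gt) {
    cc <- confusionCounts(pred, gt)
    pr <- precisionRecall(cc)
    ble <- if (sum(pred) == 0 || sum(gt) == 0) NA_real_ else
      bleError(contourRadii(pred, n_rays, center = center),
               contourRadii(gt, n_rays, center = center))
    c(pr, f1 = f1Score(cc), dice = diceScore(cc), ble = ble)
  }
  d <- one(pred_disc, gt_disc)
  cp <- one(pred_cup, gt_cup)
  cdr_pred <- if (sum(pred_disc) == 0 || sum(pred_cup) == 0) NA_real_ else
    suppressWarnings(cupDiscRatio(pred_disc, pred_cup))
  data.frame(disc_precision = d[["precision"]], disc_recall = d[["recall"]],
             disc_f1 = d[["f1"]], disc_dice = d[["dice"]],
             disc_ble = d[["ble"]],
             cup_precision = cp[["precision"]], cup_recall = cp[["recall"]],
             cup_f1 = cp[["f1"]], cup_dice = cp[["dice"]],
             cup_ble = cp[["ble"]],
             cdr_pred = cdr_pred,
             cdr_gt = suppressWarnings(cupDiscRatio(gt_disc, gt_cup)))
}
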