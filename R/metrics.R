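#' Segmentation evaluation metrics
#'
#' Two-class masks use the breast-ultrasound convention: label 1 is normal
#' tissue, label 2 is tumor. All pixel metrics are defined from the 2x2
#' confusion table with the tumor class as positive: global accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, per-class Jaccard index (IoU)
#' `TP/(TP+FP+FN)`, pixelwise F1 (Dice) `2TP/(2TP+FP+FN)`, and the
#' boundary-F1 score, which matches the predicted and reference region
#' boundaries within a Euclidean pixel tolerance.
#'
#' @name seg_metrics
NULL

check_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  if (length(mask) == 0L) stop(sprintf("`%s` is empty", what), call. = FALSE)
  bad <- !(mask %in% c(1, 2))
  if (any(bad))
    stop(sprintf("`%s` contains labels outside {1, 2}: %s", what,
                 paste(unique(mask[bad])[seq_len(min(3, sum(bad)))], collapse = ", ")),
         call. = FALSE)
  invisible(mask)
}

check_pair <- function(pred, truth) {
  check_mask(pred, "pred"); check_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` dimensions differ", call. = FALSE)
  invisible(NULL)
}

#' Pixel confusion counts for a two-class mask pair
#'
#' Counts pixels with the tumor class (label 2) as positive.
#'
#' @param pred,truth Label matrices with values in `{1, 2}` and equal
#'   dimensions.
#' @return An object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn`, summing to the pixel total.
#' @export
confusion_counts <- function(pred, truth) {
  check_pair(pred, truth)
  structure(
    list(tp = sum(pred == 2 & truth == 2),
         tn = sum(pred == 1 & truth == 1),
         fp = sum(pred == 2 & truth == 1),
         fn = sum(pred == 1 & truth == 2)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (tumor positive): TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# reorient counts so `positive_class` plays the positive role
orient_counts <- function(c, positive_class) {
  if (!positive_class %in% c(1, 2))
    stop("`positive_class` must be 1 or 2", call. = FALSE)
  if (positive_class == 2) c
  else list(tp = c$tn, tn = c$tp, fp = c$fn, fn = c$fp)
}

#' Global accuracy
#'
#' Fraction of correctly classified pixels regardless of class.
#'
#' @param counts A [confusion_counts()] object.
#' @return Fraction in `[0, 1]`.
#' @export
global_accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  (counts$tp + counts$tn) / total
}

#' Per-class Jaccard index (IoU)
#'
#' `TP / (TP + FP + FN)` with the requested class as positive. Returns `NA`
#' when the class is absent from both masks (empty union).
#'
#' @param counts A [confusion_counts()] object.
#' @param positive_class Class label, 1 (normal) or 2 (tumor).
#' @return Fraction in `[0, 1]`, or `NA_real_` for an absent class.
#' @export
class_iou <- function(counts, positive_class = 2) {
  c <- orient_counts(counts, positive_class)
  union <- c$tp + c$fp + c$fn
  if (union == 0) return(NA_real_)
  c$tp / union
}

#' Pixelwise F1 (Dice coefficient)
#'
#' `2 TP / (2 TP + FP + FN)`; algebraically `2 IoU / (1 + IoU)`. Returns
#' `NA` when the class is absent from both masks.
#'
#' @inheritParams class_iou
#' @return Fraction in `[0, 1]`, or `NA_real_` for an absent class.
#' @export
pixel_f1 <- function(counts, positive_class = 2) {
  c <- orient_counts(counts, positive_class)
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) return(NA_real_)
  2 * c$tp / denom
}

#' Boundary pixels of a class region
#'
#' Inner 4-connectivity boundary: a region pixel whose up/down/left/right
#' neighbour lies outside the region, or which sits on the image border.
#'
#' @param mask Label matrix.
#' @param class_id Class whose region boundary is extracted.
#' @return Two-column matrix of (row, col) coordinates.
#' @keywords internal
boundary_pixels <- function(mask, class_id) {
  m <- mask == class_id
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr,        2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  b <- core & !(up & down & left & right)
  which(b, arr.ind = TRUE)
}

# minimum Euclidean distance from each row of `a` to the point set `b`
min_dist_to_set <- function(a, b) {
  if (nrow(a) == 0L) return(numeric(0))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Boundary-F1 score
#'
#' Extracts the 4-connectivity inner boundary of the class region in both
#' masks; boundary precision is the fraction of predicted boundary pixels
#' within `tolerance` (Euclidean distance) of some reference boundary pixel,
#' recall the symmetric quantity, and the score their harmonic mean. When
#' both boundaries are empty the score is undefined (`NA`); when exactly one
#' is empty it is 0.
#'
#' @inheritParams confusion_counts
#' @param positive_class Class whose boundary is scored.
#' @param tolerance Match distance in pixels (>= 0). The conventional
#'   default is 0.75\% of the image diagonal, see [bf_default_tolerance()].
#' @return Fraction in `[0, 1]`, or `NA_real_` when the class is absent
#'   from both masks.
#' @export
boundary_f1 <- function(pred, truth, positive_class = 2,
                        tolerance = bf_default_tolerance(dim(truth))) {
  check_pair(pred, truth)
  if (tolerance < 0) stop("`tolerance` must be >= 0", call. = FALSE)
  bp <- boundary_pixels(pred, positive_class)
  bt <- boundary_pixels(truth, positive_class)
  if (nrow(bp) == 0L && nrow(bt) == 0L) return(NA_real_)
  if (nrow(bp) == 0L || nrow(bt) == 0L) return(0)
  precision <- mean(min_dist_to_set(bp, bt) <= tolerance)
  recall <- mean(min_dist_to_set(bt, bp) <= tolerance)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Default boundary-F1 match tolerance
#'
#' 0.75\% of the image diagonal, rounded up to the nearest pixel — the
#' documented default of the standard semantic-segmentation evaluation
#' routines.
#'
#' @param dims Integer vector `(height, width)`.
#' @return Tolerance in pixels.
#' @export
bf_default_tolerance <- function(dims) {
  ceiling(0.0075 * sqrt(sum(dims[1:2]^2)))
}

#' Evaluate one prediction/reference mask pair
#'
#' Computes global accuracy, per-class IoU and boundary-F1, and their
#' class means. Classes absent from both masks are excluded from the means
#' (reported as `NA` per class).
#'
#' @inheritParams boundary_f1
#' @param tolerance Boundary-F1 match tolerance in pixels.
#' @return An object of class `image_metrics`: list with `global_accuracy`,
#'   `iou_per_class`, `mean_iou`, `bf_per_class`, `mean_bf`.
#' @export
evaluate_image <- function(pred, truth,
                           tolerance = bf_default_tolerance(dim(truth))) {
  counts <- confusion_counts(pred, truth)
  iou <- c(`1` = class_iou(counts, 1), `2` = class_iou(counts, 2))
  bf <- c(`1` = boundary_f1(pred, truth, 1, tolerance),
          `2` = boundary_f1(pred, truth, 2, tolerance))
  structure(
    list(global_accuracy = global_accuracy(counts),
         iou_per_class = iou,
         mean_iou = mean(iou, na.rm = TRUE),
         bf_per_class = bf,
         mean_bf = mean(bf, na.rm = TRUE)),
    class = "image_metrics"
  )
}

#' @export
print.image_metrics <- function(x, ...) {
  cat(sprintf("GA %.4f | mean IoU %.4f | mean BF %.4f\n",
              x$global_accuracy, x$mean_iou, x$mean_bf))
  invisible(x)
}

#' Evaluate a set of mask pairs
#'
#' Global accuracy is accumulated over all pixels of all images. Mean IoU
#' and mean BF average, unweighted over images, the per-image class-averaged
#' values (classes absent from both masks of an image are skipped). An
#' alternative `iou_mode = "accumulated"` pools the confusion counts over
#' the whole set before taking per-class IoU.
#'
#' @param pairs List of `list(pred = , truth = )` mask pairs.
#' @param tolerance Boundary-F1 match tolerance in pixels; by default from
#'   the first image's dimensions.
#' @param iou_mode `"image"` (default: image-then-class averaging) or
#'   `"accumulated"` (dataset-pooled confusion counts).
#' @return An `image_metrics` object describing the set.
#' @export
evaluate_set <- function(pairs, tolerance = NULL,
                         iou_mode = c("image", "accumulated")) {
  iou_mode <- match.arg(iou_mode)
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("`pairs` must be a nonempty list", call. = FALSE)
  if (is.null(tolerance))
    tolerance <- bf_default_tolerance(dim(pairs[[1]]$truth))
  acc <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  per_image <- lapply(pairs, function(p) {
    m <- evaluate_image(p$pred, p$truth, tolerance)
    cc <- confusion_counts(p$pred, p$truth)
    acc$tp <<- acc$tp + cc$tp; acc$tn <<- acc$tn + cc$tn
    acc$fp <<- acc$fp + cc$fp; acc$fn <<- acc$fn + cc$fn
    m
  })
  class(acc) <- "confusion_counts"
  iou_mat <- t(vapply(per_image, `[[`, numeric(2), "iou_per_class"))
  bf_mat <- t(vapply(per_image, `[[`, numeric(2), "bf_per_class"))
  mean_iou <- if (iou_mode == "image") {
    mean(vapply(per_image, `[[`, numeric(1), "mean_iou"), na.rm = TRUE)
  } else {
    mean(c(class_iou(acc, 1), class_iou(acc, 2)), na.rm = TRUE)
  }
  structure(
    list(global_accuracy = global_accuracy(acc),
         iou_per_class = colMeans(iou_mat, na.rm = TRUE),
         mean_iou = mean_iou,
         bf_per_class = colMeans(bf_mat, na.rm = TRUE),
         mean_bf = mean(vapply(per_image, `[[`, numeric(1), "mean_bf"),
                        na.rm = TRUE),
         n_images = length(pairs)),
    class = "image_metrics"
  )
}
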