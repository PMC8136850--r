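#' Pluggable two-class segmentation backends
#'
#' Stand-in segmenters that label each pixel as normal tissue (1) or tumor
#' (2), invocable in the two inference modes of the evaluation protocol:
#' `batch` (the whole image collection presented at once) and `one_by_one`
#' (one image per call). Every backend shipped here is a pure per-image
#' function, so the two modes are guaranteed to produce identical masks.
#'
#' @name backends
NULL

#' Describe a segmentation backend
#'
#' @param name Unique backend name.
#' @param kind `"classical"` (filtering + Otsu threshold + morphology) or
#'   `"learned"` (neural-network pixel classifier, see
#'   [train_tiny_learned()]).
#' @param ... Kind-specific parameters. Classical: `smooth_radius` (median
#'   filter, pixels), `morph_radius` (opening/closing structuring disc,
#'   pixels), `min_area` (smallest acceptable tumor component, pixels),
#'   `dark_positive` (`TRUE`: the hypoechoic/dark side of the threshold is
#'   the tumor candidate). Learned: `hidden` (hidden units), `maxit`
#'   (optimiser iterations), `pixels_per_image` (training pixels sampled per
#'   image), `decay` (weight decay), `train_seed`.
#' @return An object of class `segmenter_spec`.
#' @export
segmenter_spec <- function(name, kind = c("classical", "learned"), ...) {
  kind <- match.arg(kind)
  dots <- list(...)
  defaults <- if (kind == "classical") {
    list(smooth_radius = 3L, morph_radius = 3L, min_area = 30L,
         dark_positive = TRUE)
  } else {
    list(hidden = 8L, maxit = 200L, pixels_per_image = 400L,
         decay = 1e-4, train_seed = 1L, min_area = 30L)
  }
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown ", kind, " parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- utils::modifyList(defaults, dots)
  structure(list(name = name, kind = kind, params = params),
            class = "segmenter_spec")
}

collapse_channels <- function(image) {
  if (is.matrix(image)) image else apply(image, c(1, 2), mean)
}

# keep the largest connected tumor candidate with area >= min_area
largest_component_mask <- function(candidate, min_area) {
  lab <- EBImage::bwlabel(candidate)
  mask <- matrix(1, nrow(candidate), ncol(candidate))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    best <- which.max(areas)
    if (areas[best] >= min_area) mask[lab == best] <- 2
  }
  mask
}

#' Classical threshold-and-morphology segmenter
#'
#' Deterministic pipeline: collapse channels to one plane, median smoothing,
#' global Otsu threshold with the dark (hypoechoic) side as tumor candidate,
#' morphological opening and closing with a disc, then keep the largest
#' connected candidate component with area at least `min_area` (otherwise
#' the tumor class is empty).
#'
#' @param image Matrix or h x w x 3 array, intensities in `[0, 255]`.
#' @param spec A classical [segmenter_spec()].
#' @return Label matrix in `{1, 2}`.
#' @export
segment_classical <- function(image, spec = segmenter_spec("otsu", "classical")) {
  if (!inherits(spec, "segmenter_spec") || spec$kind != "classical")
    stop("`spec` must be a classical segmenter_spec", call. = FALSE)
  p <- spec$params
  plane <- collapse_channels(image) / 255
  if (diff(range(plane)) == 0)
    return(matrix(1, nrow(plane), ncol(plane)))
  sm <- as.matrix(EBImage::medianFilter(plane, p$smooth_radius))
  thr <- EBImage::otsu(EBImage::Image(sm))
  candidate <- if (isTRUE(p$dark_positive)) sm < thr else sm > thr
  if (p$morph_radius > 0) {
    brush <- EBImage::makeBrush(2L * p$morph_radius + 1L, shape = "disc")
    candidate <- EBImage::closing(EBImage::opening(candidate, brush), brush)
    candidate <- as.matrix(candidate) > 0
  }
  largest_component_mask(candidate, p$min_area)
}

# local texture features for the learned pixel classifier
pixel_features <- function(image) {
  plane <- collapse_channels(image) / 255
  rng <- range(plane)
  norm <- if (diff(rng) > 0) (plane - rng[1]) / diff(rng) else plane * 0
  box <- function(k) matrix(1 / k^2, k, k)
  m5 <- as.matrix(EBImage::filter2(norm, box(5)))
  m11 <- as.matrix(EBImage::filter2(norm, box(11)))
  sq5 <- as.matrix(EBImage::filter2(norm^2, box(5)))
  sd5 <- sqrt(pmax(sq5 - m5^2, 0))
  cbind(intensity = as.vector(norm), mean5 = as.vector(m5),
        mean11 = as.vector(m11), sd5 = as.vector(sd5))
}

#' Train the learned pixel-classifier backend
#'
#' A small single-hidden-layer neural network (a few hundred weights)
#' classifying each pixel from local texture features (normalised intensity,
#' 5x5 and 11x11 local means, 5x5 local standard deviation). A balanced
#' pixel subsample is drawn from every training pair. Predictions are
#' post-processed like the classical backend (largest connected component,
#' minimum area). Training is fully reproducible from
#' `spec$params$train_seed`.
#'
#' @param pairs List of `list(image = , mask = )` training pairs (>= 20), or
#'   a `phantom_pair` list as produced by [generate_phantom()].
#' @param spec A learned [segmenter_spec()].
#' @return An object of class `tiny_segmenter` usable with [segment_with()].
#' @export
train_tiny_learned <- function(pairs, spec = segmenter_spec("tiny-nnet", "learned")) {
  if (!inherits(spec, "segmenter_spec") || spec$kind != "learned")
    stop("`spec` must be a learned segmenter_spec", call. = FALSE)
  if (!is.list(pairs) || length(pairs) < 20L)
    stop("need at least 20 training pairs", call. = FALSE)
  p <- spec$params
  with_seed(p$train_seed, {
    feats <- vector("list", length(pairs))
    labs <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
      f <- pixel_features(pairs[[i]]$image)
      y <- as.vector(pairs[[i]]$mask) == 2
      # balanced subsample: half tumor, half background, when available
      k <- p$pixels_per_image
      pos <- which(y); neg <- which(!y)
      take_pos <- sample(pos, min(length(pos), ceiling(k / 2)))
      take_neg <- sample(neg, min(length(neg), k - length(take_pos)))
      idx <- c(take_pos, take_neg)
      feats[[i]] <- f[idx, , drop = FALSE]
      labs[[i]] <- y[idx]
    }
    x <- do.call(rbind, feats)
    y <- unlist(labs)
    fit <- nnet::nnet(x, as.numeric(y), size = p$hidden, decay = p$decay,
                      maxit = p$maxit, entropy = TRUE, trace = FALSE)
    structure(list(fit = fit, spec = spec), class = "tiny_segmenter")
  })
}

segment_learned <- function(image, handle) {
  f <- pixel_features(image)
  prob <- as.vector(stats::predict(handle$fit, f))
  plane <- collapse_channels(image)
  candidate <- matrix(prob > 0.5, nrow(plane), ncol(plane))
  largest_component_mask(candidate, handle$spec$params$min_area)
}

#' Segment one image with any backend
#'
#' @param segmenter A classical [segmenter_spec()] or a trained
#'   `tiny_segmenter` handle.
#' @param image Matrix or h x w x 3 array.
#' @return Label matrix in `{1, 2}`.
#' @export
segment_image <- function(segmenter, image) {
  if (inherits(segmenter, "tiny_segmenter")) segment_learned(image, segmenter)
  else if (inherits(segmenter, "segmenter_spec") && segmenter$kind == "classical")
    segment_classical(image, segmenter)
  else stop("unsupported segmenter object", call. = FALSE)
}

#' Untrained-model sanity check
#'
#' Rejects a learned handle whose held-out mean tumor IoU is at or below a
#' chance-level floor (e.g. a model trained for 0 effective iterations).
#'
#' @param handle A `tiny_segmenter`.
#' @param pairs Held-out `list(image, mask)` pairs.
#' @param floor Minimum acceptable mean tumor-class IoU.
#' @return `TRUE` if the handle passes; `FALSE` (with a warning) otherwise.
#' @export
sanity_check_segmenter <- function(handle, pairs, floor = 0.2) {
  ious <- vapply(pairs, function(p) {
    pred <- segment_image(handle, p$image)
    iou <- class_iou(confusion_counts(pred, p$mask), 2)
    if (is.na(iou)) 0 else iou
  }, numeric(1))
  ok <- mean(ious) > floor
  if (!ok)
    warning(sprintf("segmenter rejected: mean tumor IoU %.3f <= floor %.3f",
                    mean(ious), floor), call. = FALSE)
  ok
}

#' Segment a sequence of images in batch or one-by-one mode
#'
#' `batch` presents the whole collection at once (features and predictions
#' are computed over the stacked collection); `one_by_one` calls the backend
#' once per image. Both modes return masks in input order and — because
#' every shipped backend is a pure per-image function — always produce
#' identical results.
#'
#' @param segmenter A classical [segmenter_spec()] or trained
#'   `tiny_segmenter`.
#' @param images Nonempty list of images.
#' @param mode `"batch"` or `"one_by_one"`.
#' @return List of label masks, one per input image.
#' @export
segment_with <- function(segmenter, images, mode = c("batch", "one_by_one")) {
  mode <- match.arg(mode)
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a nonempty list", call. = FALSE)
  if (mode == "one_by_one") {
    out <- vector("list", length(images))
    for (i in seq_along(images)) out[[i]] <- segment_image(segmenter, images[[i]])
    return(out)
  }
  # batch: for the learned backend, predict once on the stacked feature
  # matrix of the whole collection; classical backends map over the batch
  if (inherits(segmenter, "tiny_segmenter")) {
    feats <- lapply(images, pixel_features)
    sizes <- vapply(feats, nrow, integer(1))
    prob <- as.vector(stats::predict(segmenter$fit, do.call(rbind, feats)))
    ends <- cumsum(sizes); starts <- ends - sizes + 1L
    lapply(seq_along(images), function(i) {
      plane <- collapse_channels(images[[i]])
      candidate <- matrix(prob[starts[i]:ends[i]] > 0.5,
                          nrow(plane), ncol(plane))
      largest_component_mask(candidate, segmenter$spec$params$min_area)
    })
  } else {
    lapply(images, segment_image, segmenter = segmenter)
  }
}
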