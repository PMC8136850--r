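#' Fuzzy intensification operator (FIO) contrast enhancement
#'
#' The FIO scheme enhances the contrast of a grayscale plane in three steps:
#' (1) *fuzzification*: min-max normalisation of intensities into fuzzy
#' memberships, `mu = (I - Min) / (Max - Min)`, with `Min`/`Max` taken over
#' the plane itself; (2) *intensification*: memberships are pushed away from
#' the crossover 0.5 by `mu' = 2 mu^2` for `mu <= 0.5` and
#' `mu' = 1 - 2 (1 - mu)^2` for `mu > 0.5`; (3) *de-fuzzification*: mapping
#' back to the original intensity range, `I' = Min + mu' (Max - Min)`.
#' The operator is an S-curve in membership space: it darkens pixels below
#' the mid-intensity and brightens pixels above it, while the extremes and
#' the exact midpoint are fixed points, so the dynamic range of the plane is
#' preserved.
#'
#' @name fio
NULL

#' Enhancement configuration
#'
#' @param channel_policy How multi-channel images are treated:
#'   `"per_channel"` (default) applies the operator to each channel plane
#'   independently; `"luminance_first"` averages the channels into a single
#'   luminance plane, enhances it, and replicates it back to the input's
#'   channel count.
#' @param iterations Number of intensification passes (>= 1). The classic
#'   operator is applied once by default; iterating sharpens the S-curve
#'   towards a binary map.
#' @param rounding Integer-mode rounding rule: `"nearest"` (half away from
#'   zero) or `"floor"`.
#' @param output_mode `"integer"` returns rounded intensities clamped to the
#'   source plane's `[Min, Max]`; `"real"` returns the unrounded values
#'   (useful for exact comparison against a scalar reference).
#' @return An object of class `enhance_config`.
#' @export
enhance_config <- function(channel_policy = c("per_channel", "luminance_first"),
                           iterations = 1L,
                           rounding = c("nearest", "floor"),
                           output_mode = c("integer", "real")) {
  channel_policy <- match.arg(channel_policy)
  rounding <- match.arg(rounding)
  output_mode <- match.arg(output_mode)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("`iterations` must be a positive integer", call. = FALSE)
  structure(
    list(channel_policy = channel_policy, iterations = iterations,
         rounding = rounding, output_mode = output_mode),
    class = "enhance_config"
  )
}

check_plane <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  if (length(x) == 0L)
    stop(sprintf("`%s` is empty", what), call. = FALSE)
  if (anyNA(x))
    stop(sprintf("`%s` contains missing values", what), call. = FALSE)
  invisible(x)
}

#' Fuzzify a grayscale plane
#'
#' Min-max normalises intensities into fuzzy memberships in `[0, 1]`. `Min`
#' and `Max` are computed over the plane itself, so the darkest pixel maps to
#' membership 0 and the brightest to 1. A constant plane (`Max == Min`) has
#' no contrast to normalise; the all-zero map is returned with attribute
#' `degenerate = TRUE` and a warning.
#'
#' @param image Numeric matrix of intensities on the 8-bit scale `[0, 255]`.
#' @return Membership matrix in `[0, 1]`, with attributes `min_val`,
#'   `max_val` and `degenerate`.
#' @export
#' @examples
#' m <- fuzzify(matrix(c(10, 105, 200, 10), 2, 2))
#' attr(m, "min_val")  # 10
fuzzify <- function(image) {
  check_plane(image)
  mn <- min(image); mx <- max(image)
  if (mx == mn) {
    warning("constant plane (Max == Min): returning degenerate all-zero membership map",
            call. = FALSE)
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
  } else {
    out <- (image - mn) / (mx - mn)
    attr(out, "degenerate") <- FALSE
  }
  attr(out, "min_val") <- mn
  attr(out, "max_val") <- mx
  out
}

#' Apply the intensification operator to a membership map
#'
#' One pass maps `mu <= 0.5` to `2 mu^2` and `mu > 0.5` to
#' `1 - 2 (1 - mu)^2`; both branches agree at the crossover `mu = 0.5` and
#' fix the endpoints 0 and 1. The pass is repeated `iterations` times.
#'
#' @param membership Numeric matrix with all values in `[0, 1]`.
#' @param iterations Number of passes (>= 1).
#' @return Membership matrix of the same shape, values in `[0, 1]`.
#' @export
intensify <- function(membership, iterations = 1L) {
  check_plane(membership, "membership")
  if (min(membership) < 0 || max(membership) > 1)
    stop("membership values must lie in [0, 1]", call. = FALSE)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("`iterations` must be a positive integer", call. = FALSE)
  mu <- membership
  for (k in seq_len(iterations)) {
    lo <- mu <= 0.5
    mu <- ifelse(lo, 2 * mu^2, 1 - 2 * (1 - mu)^2)
  }
  # clip floating residue only; the operator itself stays in [0, 1]
  mu[mu < 0] <- 0; mu[mu > 1] <- 1
  attributes(mu) <- attributes(membership)
  dim(mu) <- dim(membership)
  mu
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' De-fuzzify a membership map back to intensities
#'
#' Inverts fuzzification over the range `[min_val, max_val]`:
#' `I = min_val + mu * (max_val - min_val)`, then, in integer output mode,
#' rounds per the configured rule and clamps to `[min_val, max_val]`.
#'
#' @param membership Numeric matrix with values in `[0, 1]`.
#' @param min_val,max_val Intensity range of the source plane
#'   (`min_val <= max_val`).
#' @param config An [enhance_config()]; only `rounding` and `output_mode`
#'   are consulted.
#' @return Intensity matrix of the same shape.
#' @export
defuzzify <- function(membership, min_val, max_val, config = enhance_config()) {
  check_plane(membership, "membership")
  if (min(membership) < 0 || max(membership) > 1)
    stop("membership values must lie in [0, 1]", call. = FALSE)
  if (min_val > max_val)
    stop("`min_val` must not exceed `max_val`", call. = FALSE)
  out <- min_val + membership * (max_val - min_val)
  if (config$output_mode == "integer") {
    out <- switch(config$rounding,
                  nearest = round_half_away(out),
                  floor = floor(out))
    out[out < min_val] <- min_val
    out[out > max_val] <- max_val
  }
  matrix(out, nrow(membership), ncol(membership))
}

enhance_plane <- function(plane, config) {
  mu <- suppressWarnings(fuzzify(plane))
  if (isTRUE(attr(mu, "degenerate"))) {
    warning("constant plane left unchanged by enhancement", call. = FALSE)
    return(plane)
  }
  mu <- intensify(mu, config$iterations)
  defuzzify(mu, attr(mu, "min_val"), attr(mu, "max_val"), config)
}

#' FIO contrast enhancement of an image
#'
#' Applies fuzzify -> intensify -> de-fuzzify to a 2-D plane or to each plane
#' of a `height x width x channels` array, per the configured channel policy.
#' `Min`/`Max` are always computed per plane per image, never across a batch
#' or across channels. Constant planes are returned unchanged (with a
#' warning): a plane without contrast has nothing to stretch.
#'
#' @param image Numeric matrix or 3-D array with intensities in `[0, 255]`.
#' @param config An [enhance_config()].
#' @return Enhanced image of the same shape and mode as the input.
#' @export
#' @examples
#' img <- matrix(c(0, 64, 128, 255), 2, 2)
#' fio_enhance(img)  # 64 -> 32: below-midpoint pixels darken
fio_enhance <- function(image, config = enhance_config()) {
  if (is.matrix(image)) return(enhance_plane(image, config))
  if (!(is.array(image) && length(dim(image)) == 3L))
    stop("`image` must be a matrix or a 3-D array", call. = FALSE)
  d <- dim(image)
  out <- image
  if (config$channel_policy == "luminance_first") {
    lum <- apply(image, c(1, 2), mean)
    enh <- enhance_plane(lum, config)
    for (k in seq_len(d[3])) out[, , k] <- enh
  } else {
    for (k in seq_len(d[3])) out[, , k] <- enhance_plane(image[, , k], config)
  }
  out
}
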