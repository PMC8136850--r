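#' Image and mask file I/O
#'
#' 8-bit PNG and TIFF readers/writers for grayscale or 3-channel images on
#' the `[0, 255]` integer scale, and label-mask readers that understand the
#' `{1, 2}` pixel convention (1 = normal tissue, 2 = tumor) as well as
#' binary `{0, 255}` / `{0, 1}` masks via an explicit mapping.
#'
#' @name image_io
NULL

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("unsupported image format: .", ext, " (use PNG or TIFF)",
            call. = FALSE)
}

#' Read an 8-bit grayscale or 3-channel image
#'
#' @param path PNG or TIFF file.
#' @return Matrix (single channel) or h x w x 3 array of integers in
#'   `[0, 255]`. An alpha channel, if present, is dropped.
#' @export
read_gray_image <- function(path) {
  x <- switch(img_format(path),
              png = png::readPNG(path),
              tiff = tiff::readTIFF(path))
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  round_half_away(x * 255)
}

#' Write an 8-bit grayscale or 3-channel image
#'
#' @param image Matrix or h x w x 3 array with intensities in `[0, 255]`.
#' @param path Destination PNG or TIFF file.
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  if (min(image) < 0 || max(image) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  x <- image / 255
  switch(img_format(path),
         png = png::writePNG(x, path),
         tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L))
  invisible(path)
}

#' Read a ground-truth label mask
#'
#' Accepts 8-bit grayscale files whose pixel values are literally `{1, 2}`
#' (the convention of the MT_Small_Dataset ground truths), or binary masks
#' via `mapping = "binary"` (0 maps to class 1, any nonzero value to
#' class 2).
#'
#' @param path PNG or TIFF file.
#' @param mapping `"labels"` for literal `{1, 2}` files, `"binary"` for
#'   `{0, 255}` / `{0, 1}` files.
#' @return Label matrix with values in `{1, 2}`.
#' @export
read_label_mask <- function(path, mapping = c("labels", "binary")) {
  mapping <- match.arg(mapping)
  x <- switch(img_format(path),
              png = png::readPNG(path),
              tiff = tiff::readTIFF(path))
  if (length(dim(x)) == 3L) x <- x[, , 1]
  vals <- round_half_away(x * 255)
  mask <- if (mapping == "binary") {
    ifelse(vals > 0, 2, 1)
  } else {
    vals
  }
  bad <- !(mask %in% c(1, 2))
  if (any(bad))
    stop(sprintf("mask %s contains labels outside {1, 2} (e.g. %s); %s",
                 basename(path), mask[which(bad)[1]],
                 "use mapping = \"binary\" for 0/255 masks"),
         call. = FALSE)
  matrix(mask, nrow(x), ncol(x))
}

#' Write a label mask in the `{1, 2}` convention
#'
#' @param mask Label matrix with values in `{1, 2}`.
#' @param path Destination PNG or TIFF file.
#' @return Invisibly, `path`.
#' @export
write_label_mask <- function(mask, path) {
  check_mask(mask)
  write_gray_image(mask, path)
}
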