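#' Synthetic breast-ultrasound phantoms
#'
#' The generator emulates the statistical features of B-mode breast
#' ultrasound that the enhancement/segmentation pipeline interacts with: a
#' speckled background, a single darker (hypoechoic) lesion with an
#' irregular boundary, optional posterior shadowing, log compression, and
#' the 128 x 128 x 3 image / `{1, 2}` mask convention of the
#' MT_Small_Dataset layout. It is a statistical caricature, not an acoustic
#' simulation.
#'
#' @name phantom
NULL

#' Phantom generation parameters
#'
#' @param size Integer `(height, width)`, each >= 32. Default `c(128, 128)`.
#' @param lesion_area_fraction Length-2 numeric range in `(0, 1)` for the
#'   lesion's mask-area fraction. Default `c(0.03, 0.25)`.
#' @param boundary_irregularity Nonnegative amplitude of the smooth radial
#'   perturbation of the lesion outline; 0 gives an exact ellipse. Values
#'   below ~0.5 keep the outline star-shaped (hence connected).
#' @param contrast Lesion/background mean echogenicity ratio in `(0, 1]`;
#'   values < 1 give a hypoechoic (darker) lesion.
#' @param speckle_looks Positive number of looks of the multiplicative
#'   gamma speckle (mean 1, variance `1/looks`); small values give coarse,
#'   harsh speckle.
#' @param shadow_strength Posterior acoustic shadow attenuation in `[0, 1]`;
#'   0 disables the shadow.
#' @param hyperechoic If `TRUE` the lesion is brighter than background
#'   (echogenicity ratio `1/contrast`), for robustness experiments.
#' @param max_retries Resampling budget when a drawn lesion violates the
#'   area-fraction or connectivity constraints.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(size = c(128L, 128L),
                           lesion_area_fraction = c(0.03, 0.25),
                           boundary_irregularity = 0.2,
                           contrast = 0.5,
                           speckle_looks = 4,
                           shadow_strength = 0,
                           hyperechoic = FALSE,
                           max_retries = 100L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stop("`size` must be two integers >= 32", call. = FALSE)
  if (length(lesion_area_fraction) != 2L ||
      any(lesion_area_fraction <= 0) || any(lesion_area_fraction >= 1) ||
      diff(lesion_area_fraction) < 0)
    stop("`lesion_area_fraction` must be an increasing range within (0, 1)",
         call. = FALSE)
  if (boundary_irregularity < 0)
    stop("`boundary_irregularity` must be >= 0", call. = FALSE)
  if (contrast <= 0 || contrast > 1)
    stop("`contrast` must lie in (0, 1]", call. = FALSE)
  if (speckle_looks <= 0) stop("`speckle_looks` must be positive", call. = FALSE)
  if (shadow_strength < 0 || shadow_strength > 1)
    stop("`shadow_strength` must lie in [0, 1]", call. = FALSE)
  structure(
    list(size = size, lesion_area_fraction = lesion_area_fraction,
         boundary_irregularity = boundary_irregularity, contrast = contrast,
         speckle_looks = speckle_looks, shadow_strength = shadow_strength,
         hyperechoic = isTRUE(hyperechoic), max_retries = as.integer(max_retries)),
    class = "phantom_params"
  )
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# smooth periodic radial perturbation, normalised to max |s| = 1
radial_noise <- function(theta, harmonics = 2:5) {
  a <- stats::rnorm(length(harmonics))
  b <- stats::rnorm(length(harmonics))
  s <- rowSums(vapply(seq_along(harmonics), function(i) {
    a[i] * cos(harmonics[i] * theta) + b[i] * sin(harmonics[i] * theta)
  }, numeric(length(theta))))
  m <- max(abs(s))
  if (m == 0) s else s / m
}

draw_lesion_once <- function(params) {
  h <- params$size[1]; w <- params$size[2]
  frac <- stats::runif(1, params$lesion_area_fraction[1],
                       params$lesion_area_fraction[2])
  aspect <- stats::runif(1, 1, 2.2)
  a <- sqrt(frac * h * w * aspect / pi)  # semi-axes in pixels
  b <- a / aspect
  cy <- stats::runif(1, 0.35, 0.65) * h
  cx <- stats::runif(1, 0.35, 0.65) * w
  phi <- stats::runif(1, 0, pi)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  u <- dy * cos(phi) + dx * sin(phi)
  v <- -dy * sin(phi) + dx * cos(phi)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  inside <- if (params$boundary_irregularity > 0) {
    theta <- atan2(v, u)
    # perturbation coefficients are drawn once per lesion
    pert <- radial_noise(as.vector(theta))
    rho <= 1 + params$boundary_irregularity * matrix(pert, h, w)
  } else {
    rho <= 1
  }
  mask <- matrix(1, h, w)
  mask[inside] <- 2
  # generation record, useful for tests against the analytic ellipse
  attr(mask, "axes") <- c(a, b)
  attr(mask, "target_fraction") <- frac
  mask
}

mask_connected <- function(mask) {
  lab <- EBImage::bwlabel(mask == 2)
  max(lab) == 1
}

#' Sample a random lesion ground-truth mask
#'
#' Draws an ellipse with random centre, axes and orientation, radially
#' perturbed by smooth periodic noise scaled by `boundary_irregularity`, and
#' rasterises it to class 2 on a class-1 background. Resamples (up to
#' `max_retries`) until the rasterised area fraction falls inside the
#' configured range and the lesion is a single 4-connected component.
#'
#' @param params A [phantom_params()].
#' @param seed Optional integer seed; the same `(params, seed)` always
#'   yields the identical mask.
#' @return Label matrix with values in `{1, 2}`.
#' @export
sample_lesion_mask <- function(params = phantom_params(), seed = NULL) {
  with_seed(seed, {
    lo <- params$lesion_area_fraction[1]; hi <- params$lesion_area_fraction[2]
    for (i in seq_len(params$max_retries)) {
      mask <- draw_lesion_once(params)
      frac <- mean(mask == 2)
      if (frac >= lo && frac <= hi && mask_connected(mask)) return(mask)
    }
    stop(sprintf(paste0("could not draw a lesion satisfying area fraction ",
                        "[%.3f, %.3f] and single-component connectivity in %d tries"),
                 lo, hi, params$max_retries), call. = FALSE)
  })
}

#' Render a speckled B-mode-like image for a lesion mask
#'
#' Builds an echogenicity map (background 1, lesion `contrast`, softened by
#' a small Gaussian blur), multiplies by mean-1 gamma speckle with shape
#' `speckle_looks`, optionally attenuates a posterior-shadow column band
#' below the lesion by `shadow_strength`, log-compresses, and rescales to
#' 8-bit intensities replicated over three identical channels.
#'
#' @param mask Label matrix from [sample_lesion_mask()].
#' @param params A [phantom_params()].
#' @param seed Optional integer seed for the speckle.
#' @return A list of class `phantom_pair`: `image` (h x w x 3 array of
#'   integers in `[0, 255]`, identical channels), `mask`, and `metadata`.
#' @export
render_phantom <- function(mask, params = phantom_params(), seed = NULL) {
  check_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  with_seed(seed, {
    ratio <- if (params$hyperechoic) 1 / params$contrast else params$contrast
    echo <- matrix(1, h, w)
    echo[mask == 2] <- ratio
    echo <- as.matrix(EBImage::gblur(echo, sigma = 1.2))
    L <- params$speckle_looks
    speckle <- matrix(stats::rgamma(h * w, shape = L, rate = L), h, w)
    img <- echo * speckle
    if (params$shadow_strength > 0) {
      cols_les <- which(colSums(mask == 2) > 0)
      if (length(cols_les)) {
        bottom <- max(which(rowSums(mask == 2) > 0))
        if (bottom < h) {
          att <- 1 - params$shadow_strength
          img[(bottom + 1):h, cols_les] <- img[(bottom + 1):h, cols_les] * att
        }
      }
    }
    img <- log1p(20 * img) / log1p(20)
    rng <- range(img)
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    plane <- round_half_away(img * 255)
    out <- array(0, dim = c(h, w, 3))
    for (k in 1:3) out[, , k] <- plane
    structure(
      list(image = out, mask = mask,
           metadata = list(params = params, seed = seed)),
      class = "phantom_pair"
    )
  })
}

#' Generate one phantom image/mask pair
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed determining both mask and speckle.
#' @return A `phantom_pair` (see [render_phantom()]).
#' @export
generate_phantom <- function(params = phantom_params(), seed = NULL) {
  with_seed(seed, {
    mask <- sample_lesion_mask(params)
    render_phantom(mask, params)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask pairs in the MT_Small_Dataset-like folder layout —
#' `Original_<subset>/` holding 3-channel 8-bit PNG images and
#' `Ground_Truth_<subset>/` holding 8-bit PNG masks in the `{1, 2}` pixel
#' convention — plus a `manifest.csv` of filenames, per-phantom seeds and
#' generator parameters. Per-phantom seeds are derived deterministically
#' from the master seed, so the whole dataset is byte-reproducible.
#'
#' @param n Number of pairs (>= 1).
#' @param params A [phantom_params()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param subset Subset name used in the folder names.
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(n, params = phantom_params(), out_dir,
                             seed = 1L, subset = "Phantom") {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  img_dir <- file.path(out_dir, paste0("Original_", subset))
  msk_dir <- file.path(out_dir, paste0("Ground_Truth_", subset))
  for (d in c(img_dir, msk_dir))
    if (!dir.create(d, recursive = TRUE, showWarnings = FALSE) && !dir.exists(d))
      stop("cannot create output directory: ", d, call. = FALSE)
  seeds <- as.integer(seed) + seq_len(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- generate_phantom(params, seeds[i])
    fname <- sprintf("%s_%04d.png", tolower(subset), i)
    write_gray_image(pair$image, file.path(img_dir, fname))
    write_label_mask(pair$mask, file.path(msk_dir, fname))
    rows[[i]] <- data.frame(
      filename = fname, seed = seeds[i],
      area_fraction = mean(pair$mask == 2),
      contrast = params$contrast, speckle_looks = params$speckle_looks,
      boundary_irregularity = params$boundary_irregularity,
      shadow_strength = params$shadow_strength,
      height = params$size[1], width = params$size[2],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
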