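# Independent scalar oracles and small fixture builders. Oracles are written
# pixel-by-pixel with explicit loops, deliberately sharing no code with the
# vectorized implementations they check.

# --- FIO scalar reference ----------------------------------------------------

fio_oracle <- function(plane, iterations = 1L) {
  mn <- min(plane); mx <- max(plane)
  if (mx == mn) return(plane)
  out <- plane
  for (i in seq_len(nrow(plane))) {
    for (j in seq_len(ncol(plane))) {
      mu <- (plane[i, j] - mn) / (mx - mn)
      for (k in seq_len(iterations)) {
        mu <- if (mu <= 0.5) 2 * mu * mu else 1 - 2 * (1 - mu) * (1 - mu)
      }
      out[i, j] <- mn + mu * (mx - mn)
    }
  }
  out
}

# --- metric brute-force references -------------------------------------------

confusion_oracle <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 2 && t == 2) tp <- tp + 1L
      else if (p == 1 && t == 1) tn <- tn + 1L
      else if (p == 2 && t == 1) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

iou_oracle <- function(pred, truth, cls) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == cls; t <- truth[i, j] == cls
      if (p && t) inter <- inter + 1L
      if (p || t) uni <- uni + 1L
    }
  }
  if (uni == 0L) NA_real_ else inter / uni
}

dice_oracle <- function(pred, truth, cls) {
  inter <- 0L; np <- 0L; nt <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == cls; t <- truth[i, j] == cls
      if (p && t) inter <- inter + 1L
      if (p) np <- np + 1L
      if (t) nt <- nt + 1L
    }
  }
  if (np + nt == 0L) NA_real_ else 2 * inter / (np + nt)
}

boundary_oracle <- function(mask, cls) {
  pts <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] != cls) next
      edge <- i == 1 || i == nr || j == 1 || j == nc
      if (!edge) {
        edge <- mask[i - 1, j] != cls || mask[i + 1, j] != cls ||
          mask[i, j - 1] != cls || mask[i, j + 1] != cls
      }
      if (edge) pts <- rbind(pts, c(i, j))
    }
  }
  if (is.null(pts)) matrix(numeric(0), 0, 2) else pts
}

bf_oracle <- function(pred, truth, cls, tol) {
  bp <- boundary_oracle(pred, cls)
  bt <- boundary_oracle(truth, cls)
  if (nrow(bp) == 0 && nrow(bt) == 0) return(NA_real_)
  if (nrow(bp) == 0 || nrow(bt) == 0) return(0)
  matched <- function(a, b) {
    hits <- 0L
    for (i in seq_len(nrow(a))) {
      ok <- FALSE
      for (j in seq_len(nrow(b))) {
        d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
        if (d <= tol) { ok <- TRUE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits / nrow(a)
  }
  pr <- matched(bp, bt); rc <- matched(bt, bp)
  if (pr + rc == 0) return(0)
  2 * pr * rc / (pr + rc)
}

# --- fixture builders ---------------------------------------------------------

random_plane <- function(h = 8, w = 8) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

random_mask <- function(h, w, p_tumor = NULL) {
  if (is.null(p_tumor)) p_tumor <- runif(1, 0.05, 0.6)
  matrix(ifelse(runif(h * w) < p_tumor, 2, 1), h, w)
}

# hand-drawn 3x3 pair: truth tumor = top row, pred tumor = left column
drawn_pair_3x3 <- function() {
  truth <- matrix(1, 3, 3); truth[1, ] <- 2
  pred <- matrix(1, 3, 3); pred[, 1] <- 2
  list(pred = pred, truth = truth)
}

# noise-free dark disk on bright background, with its ground-truth mask
disk_fixture <- function(h = 128, w = 128, radius = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cy <- if (is.null(seed)) h / 2 else runif(1, 0.35, 0.65) * h
  cx <- if (is.null(seed)) w / 2 else runif(1, 0.35, 0.65) * w
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- (rows - cy)^2 + (cols - cx)^2 <= radius^2
  mask <- matrix(1, h, w); mask[inside] <- 2
  plane <- matrix(160, h, w); plane[inside] <- 60
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- plane
  list(image = img, mask = mask)
}

phantom_pair_list <- function(n, params, seed) {
  lapply(seq_len(n), function(i) {
    p <- generate_phantom(params, seed + i)
    list(image = p$image, mask = p$mask, truth = p$mask)
  })
}
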