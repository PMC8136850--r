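#' Benchmark-style metrics tables
#'
#' A `metrics_table` holds one row per (model, condition) with the three
#' headline percentages — global accuracy, mean IoU, mean BF — the layout
#' used by published breast-ultrasound segmentation benchmarks, where
#' `condition` is "before" or "after" contrast enhancement. Values are kept
#' at full precision; rounding to 2 decimals (half-up) happens only when a
#' table is formatted or written.
#'
#' @name metrics_table
NULL

TABLE_METRICS <- c("global_accuracy", "mean_iou", "mean_bf")

#' Round half-up
#'
#' Decimal rounding with ties going up (away from zero for positives), the
#' convention of the published tables this package reproduces; base
#' `round()` rounds ties to even. A tiny epsilon absorbs binary
#' representation error in values that are exact decimals.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Construct a metrics table
#'
#' @param model Character vector of model/backend names.
#' @param condition Character vector, `"before"` or `"after"` enhancement.
#' @param global_accuracy,mean_iou,mean_bf Numeric percentages in `[0, 100]`.
#' @return A data frame of class `metrics_table`.
#' @export
metrics_table <- function(model, condition, global_accuracy, mean_iou, mean_bf) {
  condition <- as.character(condition)
  if (!all(condition %in% c("before", "after")))
    stop("`condition` must be \"before\" or \"after\"", call. = FALSE)
  vals <- cbind(global_accuracy, mean_iou, mean_bf)
  if (any(vals < 0 | vals > 100, na.rm = TRUE))
    stop("metric percentages must lie in [0, 100]", call. = FALSE)
  out <- data.frame(model = as.character(model), condition = condition,
                    global_accuracy = global_accuracy, mean_iou = mean_iou,
                    mean_bf = mean_bf, stringsAsFactors = FALSE)
  class(out) <- c("metrics_table", "data.frame")
  out
}

table_key <- function(tab) paste(tab$model, tab$condition, sep = "\r")

#' Average metrics tables element-wise and append an average row
#'
#' All tables must share the same (model, condition) row keys. Each cell of
#' the result is the arithmetic mean of that cell across tables, rounded
#' half-up to the report precision (2 decimals, the precision of the
#' published tables); an `"Average"` row per condition is then appended
#' holding the column means over the rounded model rows — i.e. over the
#' values the table actually displays.
#'
#' @param tables List of [metrics_table()] objects.
#' @param digits Decimal places of the report (default 2).
#' @return A `metrics_table` with an `Average` row per condition.
#' @export
aggregate_tables <- function(tables, digits = 2) {
  if (inherits(tables, "metrics_table")) tables <- list(tables)
  if (!is.list(tables) || length(tables) == 0L)
    stop("`tables` must be a nonempty list of metrics tables", call. = FALSE)
  ref <- tables[[1]]
  keys <- table_key(ref)
  for (tab in tables[-1]) {
    if (!setequal(table_key(tab), keys) || nrow(tab) != nrow(ref))
      stop("tables do not share the same (model, condition) row keys",
           call. = FALSE)
  }
  # align each table to the first one's row order, then average cells
  avg <- ref
  for (m in TABLE_METRICS) {
    cols <- vapply(tables, function(tab) {
      tab[[m]][match(keys, table_key(tab))]
    }, numeric(nrow(ref)))
    avg[[m]] <- round_half_up(rowMeans(matrix(cols, nrow = nrow(ref))), digits)
  }
  # average row per condition, over the rounded (displayed) model rows
  for (cond in unique(avg$condition)) {
    rows <- avg[avg$condition == cond & avg$model != "Average", ]
    avg <- rbind(avg, data.frame(
      model = "Average", condition = cond,
      global_accuracy = round_half_up(mean(rows$global_accuracy), digits),
      mean_iou = round_half_up(mean(rows$mean_iou), digits),
      mean_bf = round_half_up(mean(rows$mean_bf), digits),
      stringsAsFactors = FALSE))
  }
  rownames(avg) <- NULL
  class(avg) <- c("metrics_table", "data.frame")
  avg
}

#' @export
print.metrics_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (m in TABLE_METRICS) y[[m]] <- sprintf("%.2f", round_half_up(y[[m]], 2))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Published CNN segmentation benchmarks on breast-ultrasound images
#'
#' Per-model global accuracy, mean IoU and mean boundary-F1 percentages
#' reported for eight CNN segmentation backbones on 200 benign and 200
#' malignant breast-ultrasound images (the MT_Small_Dataset), before and
#' after fuzzy-intensification contrast enhancement, in batch and one-by-one
#' inference modes. These printed values are shipped as package data and
#' serve as inputs to [aggregate_tables()] for reproducing the cross-subset
#' averages.
#'
#' @param subset `"benign"`, `"malignant"`, or `NULL` for all rows.
#' @param mode `"batch"`, `"one_by_one"`, or `NULL` for all rows.
#' @return A data frame with columns `subset`, `mode`, `model`, `condition`,
#'   `global_accuracy`, `mean_iou`, `mean_bf`; with both `subset` and `mode`
#'   given, a [metrics_table()].
#' @export
bus_cnn_benchmarks <- function(subset = NULL, mode = NULL) {
  path <- system.file("extdata", "bus_cnn_benchmarks.csv", package = "fioseg",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(subset)) df <- df[df$subset == match.arg(subset, c("benign", "malignant")), ]
  if (!is.null(mode)) df <- df[df$mode == match.arg(mode, c("batch", "one_by_one")), ]
  if (!is.null(subset) && !is.null(mode)) {
    return(metrics_table(df$model, df$condition, df$global_accuracy,
                         df$mean_iou, df$mean_bf))
  }
  rownames(df) <- NULL
  df
}
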