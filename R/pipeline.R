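#' Experiment orchestration
#'
#' Runs the full evaluation protocol: for each dataset subset, backend and
#' inference mode, segment the raw images (condition "before") and the
#' FIO-enhanced images (condition "after"), score predictions against the
#' ground truth, and assemble per-subset metrics tables plus the
#' cross-subset aggregate in the published benchmark layout.
#'
#' @name pipeline
NULL

#' Experiment configuration
#'
#' @param dataset Either a path to an on-disk dataset in the
#'   `Original_*/Ground_Truth_*` layout, or a list
#'   `list(params = phantom_params(), n = , subsets = )` describing phantom
#'   subsets to generate in memory.
#' @param backends List of segmenters ([segmenter_spec()] or trained
#'   `tiny_segmenter` handles).
#' @param modes Character vector from `c("batch", "one_by_one")`.
#' @param conditions Character vector from `c("before", "after")`.
#' @param bf_tolerance Boundary-F1 tolerance in pixels, or `NULL` for the
#'   image-diagonal default.
#' @param enhance An [enhance_config()] used for condition "after".
#' @param seed Master seed for phantom generation.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset, backends,
                              modes = c("batch", "one_by_one"),
                              conditions = c("before", "after"),
                              bf_tolerance = NULL,
                              enhance = enhance_config(),
                              seed = 1L) {
  if (!all(modes %in% c("batch", "one_by_one")) || length(modes) == 0L)
    stop("`modes` must be a nonempty subset of {batch, one_by_one}", call. = FALSE)
  if (!all(conditions %in% c("before", "after")) || length(conditions) == 0L)
    stop("`conditions` must be a nonempty subset of {before, after}", call. = FALSE)
  if (!is.list(backends) || length(backends) == 0L)
    stop("at least one backend is required", call. = FALSE)
  nm <- vapply(backends, backend_name, character(1))
  if (anyDuplicated(nm)) stop("backend names must be unique", call. = FALSE)
  structure(
    list(dataset = dataset, backends = backends, modes = modes,
         conditions = conditions, bf_tolerance = bf_tolerance,
         enhance = enhance, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

backend_name <- function(b) {
  if (inherits(b, "tiny_segmenter")) b$spec$name else b$name
}

#' Load an on-disk dataset of image/mask pairs
#'
#' Expects the `Original_<subset>/` + `Ground_Truth_<subset>/` folder layout
#' with masks paired to images by filename. Unpaired files are skipped with
#' a warning and listed in the returned load report.
#'
#' @param path Dataset root directory.
#' @param mapping Mask pixel convention, see [read_label_mask()].
#' @return Named list of subsets; each subset is a list of
#'   `list(image, truth, name)` pairs. Attribute `skipped` lists unpaired
#'   files.
#' @export
load_dataset <- function(path, mapping = "labels") {
  img_dirs <- list.dirs(path, recursive = FALSE)
  img_dirs <- img_dirs[grepl("^Original_", basename(img_dirs))]
  if (length(img_dirs) == 0L)
    stop("no Original_* folders under ", path, call. = FALSE)
  skipped <- character(0)
  subsets <- list()
  for (d in img_dirs) {
    subset <- sub("^Original_", "", basename(d))
    gt_dir <- file.path(path, paste0("Ground_Truth_", subset))
    if (!dir.exists(gt_dir))
      stop("missing ground-truth folder for subset ", subset, call. = FALSE)
    imgs <- list.files(d, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    pairs <- list()
    for (f in imgs) {
      gt <- file.path(gt_dir, f)
      if (!file.exists(gt)) {
        warning("no ground truth for ", f, "; skipped", call. = FALSE)
        skipped <- c(skipped, file.path(d, f))
        next
      }
      pairs[[length(pairs) + 1L]] <- list(
        image = read_gray_image(file.path(d, f)),
        truth = read_label_mask(gt, mapping),
        name = f)
    }
    orphan_gt <- setdiff(list.files(gt_dir, pattern = "\\.(png|tif|tiff)$",
                                    ignore.case = TRUE), imgs)
    if (length(orphan_gt)) {
      warning(length(orphan_gt), " ground-truth file(s) without images in ",
              subset, call. = FALSE)
      skipped <- c(skipped, file.path(gt_dir, orphan_gt))
    }
    if (length(pairs)) subsets[[subset]] <- pairs
  }
  if (length(subsets) == 0L) stop("dataset is empty", call. = FALSE)
  attr(subsets, "skipped") <- skipped
  subsets
}

phantom_subsets <- function(ds, seed) {
  subsets <- ds$subsets %||% "Phantom"
  n <- ds$n
  params <- ds$params %||% phantom_params()
  out <- list()
  for (s in seq_along(subsets)) {
    base <- seed + (s - 1L) * (n + 1L)
    out[[subsets[s]]] <- lapply(seq_len(n), function(i) {
      pair <- generate_phantom(params, base + i)
      list(image = pair$image, truth = pair$mask,
           name = sprintf("%s_%04d", tolower(subsets[s]), i))
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full enhancement-and-segmentation experiment
#'
#' For every subset, backend, mode and condition requested, segments the
#' (optionally FIO-enhanced) images, evaluates against the ground truth with
#' [evaluate_set()], and assembles one [metrics_table()] per (subset, mode)
#' plus a cross-subset aggregate per mode via [aggregate_tables()]. All
#' metric values are percentages. Deterministic for a fixed config and
#' master seed.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: list with `tables`
#'   (named `<subset>.<mode>`), `aggregated` (named by mode), and `meta`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  subsets <- if (is.character(config$dataset)) load_dataset(config$dataset)
             else phantom_subsets(config$dataset, config$seed)
  tol <- config$bf_tolerance %||%
    bf_default_tolerance(dim(subsets[[1]][[1]]$truth))
  tables <- list()
  for (subset in names(subsets)) {
    pairs <- subsets[[subset]]
    images <- list(before = lapply(pairs, `[[`, "image"))
    if ("after" %in% config$conditions)
      images$after <- lapply(images$before, fio_enhance, config = config$enhance)
    truths <- lapply(pairs, `[[`, "truth")
    for (mode in config$modes) {
      rows <- list()
      for (b in config$backends) {
        for (cond in config$conditions) {
          preds <- segment_with(b, images[[cond]], mode)
          ev <- evaluate_set(
            Map(function(p, t) list(pred = p, truth = t), preds, truths),
            tolerance = tol)
          rows[[length(rows) + 1L]] <- data.frame(
            model = backend_name(b), condition = cond,
            global_accuracy = 100 * ev$global_accuracy,
            mean_iou = 100 * ev$mean_iou,
            mean_bf = 100 * ev$mean_bf, stringsAsFactors = FALSE)
        }
      }
      tab <- do.call(rbind, rows)
      class(tab) <- c("metrics_table", "data.frame")
      tables[[paste(subset, mode, sep = ".")]] <- tab
    }
  }
  aggregated <- list()
  for (mode in config$modes) {
    aggregated[[mode]] <- aggregate_tables(
      tables[grep(paste0("\\.", mode, "$"), names(tables))])
  }
  structure(
    list(tables = tables, aggregated = aggregated,
         meta = list(seed = config$seed, bf_tolerance = tol,
                     conditions = config$conditions, modes = config$modes,
                     backends = vapply(config$backends, backend_name,
                                       character(1)),
                     n_per_subset = vapply(subsets, length, integer(1)),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "experiment_report"
  )
}

#' Write an experiment report to disk
#'
#' One CSV per table (2-decimal half-up percentages, before/after rows) plus
#' a machine-readable JSON twin of the whole report.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @param path Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  if (length(report$tables) == 0L) stop("empty report", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  all_tabs <- c(report$tables,
                stats::setNames(report$aggregated,
                                paste0("aggregate.", names(report$aggregated))))
  for (nm in names(all_tabs)) {
    tab <- as.data.frame(all_tabs[[nm]])
    for (m in TABLE_METRICS) tab[[m]] <- round_half_up(tab[[m]], 2)
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }
  jf <- file.path(path, "report.json")
  jsonlite::write_json(
    list(tables = lapply(all_tabs, as.data.frame), meta = report$meta),
    jf, auto_unbox = TRUE, digits = NA)
  invisible(c(written, jf))
}
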