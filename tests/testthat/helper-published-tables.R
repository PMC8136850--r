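# Printed cross-subset average tables of the published benchmark (the
# batch-mode and one-by-one-mode averages over the benign and malignant
# per-subset tables shipped in inst/extdata), frozen here as the expected
# output of aggregate_tables().

published_batch_average <- function() {
  metrics_table(
    model = c("FCN-AlexNet", "U-Net", "SegNet-VGG16", "SegNet-VGG19",
              "DeepLabV3+-ResNet18", "DeepLabV3+-ResNet50",
              "DeepLabV3+-MobileNet-V2", "DeepLabV3+-Xception", "Average",
              "FCN-AlexNet", "U-Net", "SegNet-VGG16", "SegNet-VGG19",
              "DeepLabV3+-ResNet18", "DeepLabV3+-ResNet50",
              "DeepLabV3+-MobileNet-V2", "DeepLabV3+-Xception", "Average"),
    condition = rep(c("before", "after"), each = 9),
    global_accuracy = c(85.98, 87.09, 86.32, 86.41, 85.69, 85.27, 86.33,
                        85.58, 86.08,
                        94.64, 94.57, 95.84, 95.85, 95.68, 96.15, 95.29,
                        95.57, 95.45),
    mean_iou = c(49.60, 49.84, 49.79, 49.93, 49.42, 49.07, 49.65, 49.56,
                 49.61,
                 75.41, 74.02, 80.34, 80.29, 80.53, 81.74, 77.54, 79.69,
                 78.70),
    mean_bf = c(42.56, 42.92, 42.42, 42.69, 42.66, 42.59, 42.80, 42.37,
                42.63,
                57.34, 65.86, 69.87, 70.73, 70.62, 71.85, 68.30, 70.04,
                68.08))
}

published_onebyone_average <- function() {
  metrics_table(
    model = c("FCN-AlexNet", "U-Net", "SegNet-VGG16", "SegNet-VGG19",
              "DeepLabV3+-ResNet18", "DeepLabV3+-ResNet50",
              "DeepLabV3+-MobileNet-V2", "DeepLabV3+-Xception", "Average",
              "FCN-AlexNet", "U-Net", "SegNet-VGG16", "SegNet-VGG19",
              "DeepLabV3+-ResNet18", "DeepLabV3+-ResNet50",
              "DeepLabV3+-MobileNet-V2", "DeepLabV3+-Xception", "Average"),
    condition = rep(c("before", "after"), each = 9),
    global_accuracy = c(95.43, 95.34, 96.52, 96.67, 96.79, 96.69, 96.20,
                        95.88, 96.19,
                        94.64, 94.57, 95.83, 95.84, 95.68, 96.15, 95.29,
                        95.57, 95.44),
    mean_iou = c(79.69, 77.98, 83.50, 84.38, 85.48, 85.41, 82.67, 82.39,
                 82.69,
                 75.41, 74.02, 80.31, 80.27, 80.53, 81.74, 77.54, 79.69,
                 78.69),
    mean_bf = c(59.96, 69.72, 72.62, 73.34, 74.14, 73.18, 73.16, 72.84,
                71.12,
                57.34, 65.86, 69.86, 70.75, 70.62, 71.85, 68.30, 70.03,
                68.07))
}

# headline published averages over the 400 images and eight models
abstract_batch_numbers <- function() {
  list(ga_before = 86.08, ga_after = 95.45,
       iou_before = 49.61, iou_after = 78.70,
       bf_before = 42.63, bf_after = 68.08)
}

# compare two metrics tables cell-by-cell after aligning row keys
expect_tables_equal <- function(got, want, tol = 0) {
  key <- function(t) paste(t$model, t$condition)
  expect_setequal(key(got), key(want))
  idx <- match(key(want), key(got))
  for (m in c("global_accuracy", "mean_iou", "mean_bf")) {
    if (tol == 0) expect_equal(got[[m]][idx], want[[m]], tolerance = 1e-12)
    else expect_true(all(abs(got[[m]][idx] - want[[m]]) <= tol + 1e-12))
  }
}
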