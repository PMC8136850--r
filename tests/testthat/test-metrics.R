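test_that("confusion counts match hand counts and enforce the mask contract", {
  truth <- matrix(1, 4, 4); truth[1, 1:3] <- 2; truth[2, 1:2] <- 2  # 5 tumor px
  cc <- confusion_counts(truth, truth)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 5L, tn = 11L, fp = 0L, fn = 0L))

  all_normal <- matrix(1, 4, 4)
  cc2 <- confusion_counts(all_normal, truth)
  expect_equal(cc2$tp, 0L); expect_equal(cc2$fn, 5L); expect_equal(cc2$tn, 11L)

  pair <- drawn_pair_3x3()
  cc3 <- confusion_counts(pair$pred, pair$truth)
  expect_equal(unclass(cc3)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 2L, fn = 2L, tn = 4L))

  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "dimensions")
  expect_error(confusion_counts(matrix(c(1, 7), 1, 2), matrix(1, 1, 2)),
               "outside \\{1, 2\\}")
})

test_that("pixel metrics reproduce hand arithmetic on the drawn grids", {
  pair <- drawn_pair_3x3()
  cc <- confusion_counts(pair$pred, pair$truth)
  expect_equal(global_accuracy(cc), 5 / 9)
  expect_equal(class_iou(cc, 2), 0.2)
  expect_equal(class_iou(cc, 1), 0.5)
  expect_equal(pixel_f1(cc, 2), 1 / 3)  # 2TP/(2TP+FP+FN) = 2/6; = 2*0.2/1.2

  perfect <- confusion_counts(pair$truth, pair$truth)
  expect_equal(global_accuracy(perfect), 1)
  expect_equal(class_iou(perfect, 1), 1); expect_equal(class_iou(perfect, 2), 1)

  wrong <- structure(list(tp = 0, tn = 0, fp = 3, fn = 3),
                     class = "confusion_counts")
  expect_equal(global_accuracy(wrong), 0)

  # absent class -> NA marker
  none <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_true(is.na(class_iou(none, 2)))
  expect_true(is.na(pixel_f1(none, 2)))
})

test_that("boundary-F1 handles identical, shifted and one-sided-empty masks", {
  truth <- matrix(1, 10, 10); truth[3:6, 3:6] <- 2
  expect_equal(boundary_f1(truth, truth, 2, tolerance = 0), 1)

  pred <- matrix(1, 10, 10); pred[3:6, 4:7] <- 2   # shifted right by 1
  expect_equal(boundary_f1(pred, truth, 2, tolerance = 1),
               bf_oracle(pred, truth, 2, 1))

  empty <- matrix(1, 10, 10)
  expect_equal(boundary_f1(empty, truth, 2, tolerance = 2), 0)
  expect_true(is.na(boundary_f1(empty, empty, 2, tolerance = 2)))
  expect_error(boundary_f1(truth, truth, 2, tolerance = -1), ">= 0")
})

test_that("vectorized metrics agree exactly with brute-force oracles", {
  set.seed(41)
  for (rep in 1:150) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    pred <- random_mask(h, w); truth <- random_mask(h, w)
    cc <- confusion_counts(pred, truth)
    oc <- confusion_oracle(pred, truth)
    expect_identical(cc$tp, oc$tp); expect_identical(cc$fp, oc$fp)
    expect_identical(cc$tn, oc$tn); expect_identical(cc$fn, oc$fn)
    for (cls in 1:2) {
      expect_equal(class_iou(cc, cls), iou_oracle(pred, truth, cls))
      expect_equal(pixel_f1(cc, cls), dice_oracle(pred, truth, cls))
      tol <- sample(0:3, 1)
      expect_equal(boundary_f1(pred, truth, cls, tol),
                   bf_oracle(pred, truth, cls, tol))
    }
    # Dice-Jaccard identity
    iou <- class_iou(cc, 2)
    if (!is.na(iou)) expect_equal(pixel_f1(cc, 2), 2 * iou / (1 + iou))
  }
})

test_that("boundary-F1 is non-decreasing in the match tolerance", {
  set.seed(43)
  for (rep in 1:20) {
    pred <- random_mask(12, 12); truth <- random_mask(12, 12)
    vals <- vapply(0:5, function(tol) boundary_f1(pred, truth, 2, tol),
                   numeric(1))
    vals <- vals[!is.na(vals)]
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("relabeling both masks swaps per-class metrics and keeps GA", {
  set.seed(47)
  for (rep in 1:25) {
    pred <- random_mask(9, 9); truth <- random_mask(9, 9)
    sw <- function(m) 3 - m
    cc <- confusion_counts(pred, truth)
    cs <- confusion_counts(sw(pred), sw(truth))
    expect_equal(global_accuracy(cc), global_accuracy(cs))
    expect_equal(class_iou(cc, 2), class_iou(cs, 1))
    expect_equal(pixel_f1(cc, 1), pixel_f1(cs, 2))
    expect_equal(boundary_f1(pred, truth, 2, 1),
                 boundary_f1(sw(pred), sw(truth), 1, 1))
  }
})

test_that("image evaluation fills all fields with class-present averaging", {
  pair <- drawn_pair_3x3()
  m <- evaluate_image(pair$pred, pair$truth, tolerance = 1)
  expect_equal(m$global_accuracy, 5 / 9)
  expect_equal(unname(m$iou_per_class), c(0.5, 0.2))
  expect_equal(m$mean_iou, 0.35)

  perfect <- evaluate_image(pair$truth, pair$truth, tolerance = 1)
  expect_equal(perfect$global_accuracy, 1)
  expect_equal(perfect$mean_iou, 1); expect_equal(perfect$mean_bf, 1)

  miss <- evaluate_image(matrix(1, 3, 3), pair$truth, tolerance = 1)
  expect_equal(unname(miss$iou_per_class["2"]), 0)
  expect_equal(unname(miss$bf_per_class["2"]), 0)
})

test_that("set evaluation pools pixels for GA and averages images for IoU/BF", {
  truth <- matrix(1, 4, 4); truth[2:3, 2:3] <- 2
  perfect <- list(pred = truth, truth = truth)
  swapped <- list(pred = 3 - truth, truth = truth)  # every pixel wrong

  both <- evaluate_set(list(perfect, perfect), tolerance = 1)
  expect_equal(both$global_accuracy, 1)
  expect_equal(both$mean_iou, 1); expect_equal(both$mean_bf, 1)

  half <- evaluate_set(list(perfect, swapped), tolerance = 1)
  expect_equal(half$global_accuracy, 0.5)

  single <- evaluate_set(list(perfect), tolerance = 1)
  one <- evaluate_image(perfect$pred, perfect$truth, tolerance = 1)
  expect_equal(single$global_accuracy, one$global_accuracy)
  expect_equal(single$mean_iou, one$mean_iou)
  expect_equal(single$mean_bf, one$mean_bf)

  expect_error(evaluate_set(list()), "nonempty")

  # accumulated IoU mode pools counts before the class average
  acc <- evaluate_set(list(perfect, swapped), tolerance = 1,
                      iou_mode = "accumulated")
  cc <- confusion_counts(rbind(truth, 3 - truth), rbind(truth, truth))
  expect_equal(acc$mean_iou, mean(c(class_iou(cc, 1), class_iou(cc, 2))))
})

test_that("default boundary tolerance follows the image diagonal", {
  expect_equal(bf_default_tolerance(c(128, 128)), ceiling(0.0075 * sqrt(2) * 128))
  expect_equal(bf_default_tolerance(c(100, 100)), 2)
})
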