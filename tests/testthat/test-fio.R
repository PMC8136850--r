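test_that("fuzzification maps the intensity range onto [0,1] memberships", {
  img <- matrix(c(10, 200, 150, 10), 2, 2)
  mu <- fuzzify(img)
  expect_equal(mu[1, 1], 0)        # minimum pixel -> membership 0
  expect_equal(mu[2, 1], 1)        # maximum pixel -> membership 1
  expect_equal(attr(mu, "min_val"), 10)
  expect_equal(attr(mu, "max_val"), 200)

  full <- fuzzify(matrix(c(0, 64, 255, 128), 2, 2))
  expect_equal(full[2, 1], 64 / 255, tolerance = 1e-12)

  expect_warning(mu0 <- fuzzify(matrix(77, 3, 3)), "constant")
  expect_true(all(mu0 == 0))
  expect_true(attr(mu0, "degenerate"))
  expect_error(fuzzify(matrix(numeric(0), 0, 0)), "empty|matrix")
})

test_that("intensification has the textbook fixed points and branch values", {
  mu <- matrix(c(0, 0.25, 0.5, 0.75, 1, 0.5), 2, 3)
  out <- intensify(mu)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 0.125)    # 2 * 0.25^2
  expect_equal(out[1, 2], 0.5)      # crossover fixed point
  expect_equal(out[2, 2], 0.875)    # 1 - 2 * 0.25^2
  expect_equal(out[1, 3], 1)
  expect_error(intensify(matrix(c(-0.1, 0.5), 1, 2)), "\\[0, 1\\]")
  expect_error(intensify(mu, iterations = 0), "positive")
})

test_that("de-fuzzification inverts fuzzification over the source range", {
  cfg <- enhance_config()
  expect_equal(defuzzify(matrix(0, 1, 1), 10, 200, cfg)[1, 1], 10)
  expect_equal(defuzzify(matrix(1, 1, 1), 10, 200, cfg)[1, 1], 200)
  expect_equal(defuzzify(matrix(0.5, 1, 1), 0, 255, cfg)[1, 1], 128)
  expect_equal(defuzzify(matrix(0.5, 1, 1), 0, 255,
                         enhance_config(rounding = "floor"))[1, 1], 127)
  expect_error(defuzzify(matrix(0.5, 1, 1), 10, 5, cfg), "min_val")

  set.seed(11)
  for (rep in 1:20) {
    img <- random_plane()
    mu <- fuzzify(img)
    back <- defuzzify(mu, attr(mu, "min_val"), attr(mu, "max_val"), cfg)
    expect_identical(back, img + 0)  # exact round trip when intensify is skipped
  }
})

test_that("enhancement matches hand-worked values and degenerate rules", {
  img <- matrix(c(0, 64, 128, 255), 2, 2)
  out <- fio_enhance(img)
  expect_equal(out[2, 1], 32)   # 2*(64/255)^2 * 255 = 32.13 -> 32
  expect_equal(out[1, 1], 0); expect_equal(out[2, 2], 255)

  expect_warning(const <- fio_enhance(matrix(77, 4, 4)), "constant")
  expect_equal(const, matrix(77, 4, 4))

  arr <- array(0, dim = c(4, 4, 3))
  set.seed(3); plane <- random_plane(4, 4)
  for (k in 1:3) arr[, , k] <- plane
  enh <- fio_enhance(arr)
  expect_equal(enh[, , 1], enh[, , 2])
  expect_equal(enh[, , 2], enh[, , 3])
  expect_equal(enh[, , 1], fio_enhance(plane))

  lum <- fio_enhance(arr, enhance_config(channel_policy = "luminance_first"))
  expect_equal(lum[, , 1], lum[, , 3])
})

test_that("enhancement preserves range, fixed points, order and polarity", {
  cfg_real <- enhance_config(output_mode = "real")
  set.seed(21)
  for (rep in 1:60) {
    img <- random_plane()
    mn <- min(img); mx <- max(img)
    out <- fio_enhance(img)
    expect_true(all(out >= mn & out <= mx))
    expect_true(all(out[img == mn] == mn))
    expect_true(all(out[img == mx] == mx))

    real <- fio_enhance(img, cfg_real)
    mid <- (mn + mx) / 2
    expect_true(all(real[img <= mid] <= img[img <= mid] + 1e-9))
    expect_true(all(real[img >= mid] >= img[img >= mid] - 1e-9))

    # order preservation
    o <- order(as.vector(img))
    expect_true(all(diff(as.vector(real)[o]) >= -1e-9))
  }

  # exact midpoint is a fixed point when representable
  img <- matrix(c(10, 110, 210, 60), 2, 2)
  expect_equal(fio_enhance(img)[2, 1], 110)

  # binary {Min, Max} planes are unchanged for any iteration count
  bin <- matrix(sample(c(40, 220), 36, replace = TRUE), 6, 6)
  for (it in c(1, 3, 7)) {
    expect_equal(fio_enhance(bin, enhance_config(iterations = it)), bin)
  }
})

test_that("vectorized enhancement agrees exactly with the scalar reference", {
  cfg <- enhance_config(output_mode = "real")
  set.seed(31)
  for (rep in 1:200) {
    img <- random_plane(8, 8)
    it <- sample(1:3, 1)
    expect_equal(fio_enhance(img, enhance_config(iterations = it,
                                                 output_mode = "real")),
                 fio_oracle(img, it), tolerance = 1e-12)
  }
  expect_equal(fio_enhance(matrix(c(0, 255, 13, 77), 2, 2), cfg),
               fio_oracle(matrix(c(0, 255, 13, 77), 2, 2)), tolerance = 1e-12)
})

test_that("iterating the operator polarizes memberships towards 0/1", {
  mu <- matrix(seq(0.01, 0.99, length.out = 25), 5, 5)
  m1 <- intensify(mu, 1)
  m5 <- intensify(mu, 5)
  lo <- mu < 0.5; hi <- mu > 0.5
  expect_true(all(m5[lo] <= m1[lo]))
  expect_true(all(m5[hi] >= m1[hi]))
  expect_true(all(m5 >= 0 & m5 <= 1))
})
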