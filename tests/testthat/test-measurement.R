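test_that("measure_roi implements (Sa - Sb)/Sb with clamping at zero", {
  f <- make_image_fixture(bg = 100, lesion_max = 110)
  m <- measure_roi(f$image, f$lesion, f$background)
  expect_equal(m$sa, 110)
  expect_equal(m$sb, 100)
  expect_equal(m$cnr, 0.10)

  uniform <- measure_roi(matrix(100, 8, 8),
                         diag(8) == 1, diag(8) != 1)
  expect_equal(uniform$cnr, 0)

  dark <- make_image_fixture(bg = 100, lesion_max = 90)
  dark$image[dark$lesion] <- 90  # whole lesion darker than background
  expect_equal(measure_roi(dark$image, dark$lesion, dark$background)$cnr, 0)
})

test_that("CNR is invariant to intensity rescaling", {
  withr::with_seed(5, {
    for (i in 1:20) {
      img <- matrix(runif(64, 50, 150), 8, 8)
      les <- matrix(FALSE, 8, 8); les[3:5, 3:5] <- TRUE
      cnr <- measure_roi(img, les, !les)$cnr
      c_scale <- runif(1, 0.1, 10)
      expect_equal(measure_roi(img * c_scale, les, !les)$cnr, cnr)
    }
  })
})

test_that("enlarging the lesion ROI never decreases CNR", {
  withr::with_seed(8, {
    for (i in 1:20) {
      img <- matrix(runif(100, 50, 150), 10, 10)
      small <- matrix(FALSE, 10, 10); small[4:6, 4:6] <- TRUE
      big <- small; big[3:7, 3:7] <- TRUE
      bg <- matrix(FALSE, 10, 10); bg[9:10, ] <- TRUE
      expect_gte(measure_roi(img, big, bg)$cnr,
                 measure_roi(img, small, bg)$cnr)
    }
  })
})

test_that("degenerate masks and backgrounds are rejected", {
  f <- make_image_fixture()
  none <- matrix(FALSE, 16, 16)
  expect_error(measure_roi(f$image, none, f$background),
               class = "cesmr_mask_error")
  expect_error(measure_roi(f$image, f$lesion, matrix(FALSE, 8, 8)),
               class = "cesmr_mask_error")
  expect_error(measure_roi(f$image, f$lesion, f$lesion),
               class = "cesmr_mask_error")  # overlapping ROIs
  zero_img <- matrix(0, 16, 16)
  expect_error(measure_roi(zero_img, f$lesion, f$background),
               class = "cesmr_measurement_error")
  expect_error(measure_roi(f$image - 200, f$lesion, f$background),
               class = "cesmr_argument_error")
})

test_that("views are ordered by acquisition time, not view name", {
  m <- order_views(make_measurements(times = c(120, 224),
                                     views = c("CC", "MLO")))
  expect_equal(m$position, c("former", "latter"))
  expect_equal(m$view[1], "CC")
  expect_equal(m$time_gap, c(104, 104))

  rev <- order_views(make_measurements(times = c(200, 90),
                                       views = c("CC", "MLO")))
  expect_equal(rev$view[1], "MLO")

  expect_error(order_views(make_measurements(times = c(100, 100))),
               class = "cesmr_ordering_error")
  expect_error(order_views(make_measurements()[1, ]),
               class = "cesmr_argument_error")
})

test_that("enhancement detection uses a strict threshold", {
  expect_true(detect_enhancement(0.027))
  expect_false(detect_enhancement(0))
  expect_false(detect_enhancement(0.05, threshold = 0.05))
  expect_true(detect_enhancement(0.051, threshold = 0.05))
  expect_error(detect_enhancement(0.1, threshold = -1),
               class = "cesmr_argument_error")
})
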