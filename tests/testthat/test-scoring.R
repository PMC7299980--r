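test_that("RSD follows the two-projection formula with the zeroing rule", {
  expect_equal(compute_rsd(0, 0), 0)
  expect_equal(compute_rsd(0.068, 0.056), -17.6, tolerance = 0.005)
  expect_equal(compute_rsd(0.027, 0.033), 22.2, tolerance = 0.005)
  expect_equal(compute_rsd(0.10, 0.05), -50)
  expect_equal(compute_rsd(0, 0.5), 100)  # capped: rise from nothing
  expect_equal(compute_rsd(0.5, 0), -100)
  expect_error(compute_rsd(-0.1, 0.5), class = "cesmr_argument_error")
})

test_that("pattern classification matches the RSD taxonomy", {
  # reference medians: malignant pair descends, benign pair ascends
  expect_equal(classify_pattern(0.068, 0.056), "descending")  # RSD -17.6
  expect_equal(classify_pattern(0.027, 0.033), "ascending")   # RSD +22.2
  expect_equal(classify_pattern(0, 0), "none")
  expect_equal(classify_pattern(0, 0.01), "ascending")
  # strict inequalities: the +/-10 boundary belongs to steady
  expect_equal(classify_pattern(100, 110), "steady")
  expect_equal(classify_pattern(100, 90), "steady")
  expect_equal(classify_pattern(100, 110.1), "ascending")
  expect_equal(classify_pattern(100, 89.9), "descending")
  # representative RSD magnitudes around the printed group summaries
  expect_equal(classify_pattern(100, 100 - 11.9), "descending")
  expect_equal(classify_pattern(100, 106), "steady")
  expect_equal(classify_pattern(100, 111.4), "ascending")
})

test_that("classification is exhaustive, exclusive and antisymmetric", {
  withr::with_seed(21, {
    cnr1 <- c(0, 0, runif(200, 0, 20))
    cnr2 <- c(0, runif(1, 0.1, 5), runif(200, 0, 20))
    pat <- classify_pattern(cnr1, cnr2)
    expect_true(all(pat %in% c("ascending", "steady", "descending", "none")))
    # swapping the projections maps ascending <-> descending when both
    # values are positive and fixes steady
    both_pos <- cnr1 > 0 & cnr2 > 0
    swapped <- classify_pattern(cnr2[both_pos], cnr1[both_pos])
    mapped <- dplyr::recode(pat[both_pos], ascending = "descending",
                            descending = "ascending")
    # antisymmetry holds away from the asymmetric RSD denominator band:
    # |RSD| <= 10 in one direction guarantees steady both ways only when
    # the reversed ratio also stays inside the band
    rsd_fwd <- compute_rsd(cnr1[both_pos], cnr2[both_pos])
    rsd_rev <- compute_rsd(cnr2[both_pos], cnr1[both_pos])
    clear <- (rsd_fwd > 10 & rsd_rev < -10) |
      (rsd_fwd < -10 & rsd_rev > 10) |
      (abs(rsd_fwd) <= 10 & abs(rsd_rev) <= 10)
    expect_true(all(swapped[clear] == mapped[clear]))
  })
})

test_that("score_lesion assembles the ordered kinetic record", {
  rec <- score_lesion(make_measurements(cnr = c(0.10, 0.05)),
                      metadata = list(lesion_id = "L1"))
  expect_equal(rec$cnr1, 0.10)
  expect_equal(rec$cnr2, 0.05)
  expect_equal(rec$rsd, -50)
  expect_equal(rec$pattern, "descending")
  expect_true(rec$subtraction_detected)
  expect_equal(rec$time_gap, 104)
  expect_equal(rec$lesion_id, "L1")

  # former/latter defined by time: same values, swapped view names
  a <- score_lesion(make_measurements(views = c("CC", "MLO")))
  b <- score_lesion(make_measurements(views = c("MLO", "CC")))
  expect_equal(a[c("cnr1", "cnr2", "rsd", "pattern")],
               b[c("cnr1", "cnr2", "rsd", "pattern")])

  none <- score_lesion(make_measurements(cnr = c(0, 0)))
  expect_equal(none$pattern, "none")
  expect_equal(none$rsd, 0)
  expect_false(none$subtraction_detected)
})

test_that("irregular lesions are flagged for audit", {
  m <- make_measurements(cnr = c(0, 0.05))
  m$sa[1] <- 95  # raw CNR negative, clamped upstream
  rec <- score_lesion(m)
  expect_match(rec$flags, "clamped_cnr")
  expect_match(rec$flags, "one_view_enhancement")
  expect_equal(rec$pattern, "ascending")
  expect_equal(rec$rsd, 100)
})

test_that("score_cohort matches row-wise scoring", {
  cohort <- generate_cohort(cohort_config(seed = 31))
  scored <- score_cohort(cohort)
  expect_equal(scored$rsd, compute_rsd(cohort$cnr1, cohort$cnr2))
  expect_equal(scored$pattern, classify_pattern(cohort$cnr1, cohort$cnr2))
  expect_error(score_cohort(dplyr::select(cohort, -"cnr1")),
               class = "cesmr_schema_error")
})
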