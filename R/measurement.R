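#' Measure lesion CNR from a subtraction image and its ROIs
#'
#' Computes the contrast-to-noise ratio of one projection:
#' `CNR = (Sa - Sb) / Sb`, where `Sa` is the maximum pixel value inside
#' the lesion ROI (robust to lesion heterogeneity, unlike a mean) and `Sb`
#' is the arithmetic mean inside the background ROI, drawn over fatty
#' background away from enhancing tissue. A lesion darker than background
#' is non-enhancement, not negative enhancement, so a negative raw ratio
#' is clamped to zero.
#'
#' @param image Numeric matrix of non-negative intensities (one
#'   subtraction view).
#' @param lesion,background Logical matrices the same shape as `image`,
#'   each with at least one `TRUE` pixel; they must not overlap.
#' @param view Optional view label (e.g. `"CC"`, `"MLO"`).
#' @param time Optional acquisition time in seconds since injection.
#' @return One-row tibble with columns `view`, `time`, `sa`, `sb`, `cnr`.
#' @examples
#' img <- matrix(100, 8, 8); img[4, 4] <- 110
#' les <- matrix(FALSE, 8, 8); les[3:5, 3:5] <- TRUE
#' bg <- !les
#' measure_roi(img, les, bg)
#' @export
measure_roi <- function(image, lesion, background, view = NA_character_,
                        time = NA_real_) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0) {
    abort("`image` must be a non-empty numeric matrix.",
          class = "cesmr_argument_error")
  }
  if (any(image < 0, na.rm = TRUE)) {
    abort("`image` intensities must be non-negative.",
          class = "cesmr_argument_error")
  }
  for (nm in c("lesion", "background")) {
    m <- get(nm)
    if (!is.logical(m) || !identical(dim(m), dim(image))) {
      abort(paste0("`", nm, "` mask must be a logical matrix matching the image shape."),
            class = "cesmr_mask_error")
    }
    if (!any(m)) {
      abort(paste0("`", nm, "` mask has no pixels."), class = "cesmr_mask_error")
    }
  }
  if (any(lesion & background)) {
    abort("Lesion and background ROIs overlap; they must be disjoint.",
          class = "cesmr_mask_error")
  }
  sa <- max(image[lesion])
  sb <- mean(image[background])
  if (sb <= 0) {
    abort("Background mean is zero: CNR is undefined for a degenerate background.",
          class = "cesmr_measurement_error")
  }
  tibble::tibble(view = view, time = as.numeric(time), sa = sa, sb = sb,
                 cnr = max(0, (sa - sb) / sb))
}

#' Order a lesion's two view measurements by acquisition time
#'
#' The kinetic reading compares the former (earlier) and latter (later)
#' projection. Which of CC/MLO comes first varies between exams, so the
#' ordering is by acquisition time, never by view name. Equal timestamps
#' are ambiguous and rejected.
#'
#' @param measurements Two-row tibble of per-view measurements (from
#'   [measure_roi()]) for one lesion, with distinct non-missing `time`s.
#' @return The same tibble ordered former-first, with a `position` column
#'   (`"former"`, `"latter"`) and a `time_gap` column carrying the gap in
#'   seconds between the two acquisitions.
#' @export
order_views <- function(measurements) {
  if (nrow(measurements) != 2L) {
    abort("`measurements` must contain exactly two views of one lesion.",
          class = "cesmr_argument_error")
  }
  if (anyNA(measurements$time) ||
      measurements$time[1] == measurements$time[2]) {
    abort("Acquisition times must be distinct to define former/latter.",
          class = "cesmr_ordering_error")
  }
  out <- dplyr::arrange(measurements, .data$time)
  out$position <- c("former", "latter")
  out$time_gap <- diff(out$time)
  out
}

#' Is a measured view enhancing?
#'
#' A positive finding is an enhancement region stronger than background,
#' i.e. CNR strictly greater than the threshold (default 0).
#'
#' @param cnr Numeric vector of CNR values (any consistent scale).
#' @param threshold Non-negative enhancement threshold; strict inequality.
#' @return Logical vector.
#' @export
detect_enhancement <- function(cnr, threshold = 0) {
  if (threshold < 0) {
    abort("`threshold` must be >= 0.", class = "cesmr_argument_error")
  }
  cnr > threshold
}

#' Measure every view in a phantom set
#'
#' Runs [measure_roi()] over a phantom directory (or an already loaded
#' [read_phantom_set()] result) and returns the per-view measurement
#' table, ready to be written as CSV.
#'
#' @param x Directory containing `manifest.json`, or the list returned by
#'   [read_phantom_set()].
#' @return Tibble with columns `lesion_id`, `view`, `time`, `sa`, `sb`,
#'   `cnr`, one row per view.
#' @export
measure_phantom_set <- function(x) {
  if (is.character(x)) x <- read_phantom_set(x)
  purrr::imap(x, function(views, id) {
    rows <- purrr::map(views, function(v) {
      measure_roi(v$image, v$lesion, v$background, view = v$view,
                  time = v$time)
    })
    dplyr::mutate(dplyr::bind_rows(rows), lesion_id = id, .before = 1)
  }) |>
    dplyr::bind_rows()
}
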