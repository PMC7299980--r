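#' Relative signal difference between the two projections
#'
#' `RSD = 100 * (CNR2 - CNR1) / CNR1`, the percent change in enhancement
#' intensity from the former to the latter projection. A non-enhanced
#' lesion (both CNRs zero) is scored as zero. When enhancement appears
#' only in the latter view (`cnr1 = 0 < cnr2`) the ratio is undefined;
#' such lesions are reported with a +100% cap and classified as ascending
#' by [classify_pattern()].
#'
#' @param cnr1,cnr2 Non-negative CNR values for the former and latter
#'   projection (any consistent scale; RSD is scale-free).
#' @return Numeric vector of RSD values in percent.
#' @examples
#' compute_rsd(0.068, 0.056)  # -17.6: intensity fades between views
#' compute_rsd(0, 0)          # non-enhanced, scored as zero
#' @export
compute_rsd <- function(cnr1, cnr2) {
  if (any(cnr1 < 0, na.rm = TRUE) || any(cnr2 < 0, na.rm = TRUE)) {
    abort("CNR values must be >= 0.", class = "cesmr_argument_error")
  }
  dplyr::case_when(
    cnr1 == 0 & cnr2 == 0 ~ 0,
    cnr1 == 0 & cnr2 > 0 ~ 100,
    TRUE ~ 100 * (cnr2 - cnr1) / cnr1
  )
}

#' Classify the two-timepoint enhancement pattern
#'
#' Four-way kinetic taxonomy over the ordered CNR pair:
#' * `ascending` — RSD strictly above `threshold` (default +10%), a
#'   continuously rising intensity; includes lesions enhancing only in the
#'   latter view.
#' * `steady` — |RSD| at most `threshold` (boundary values inclusive).
#' * `descending` — RSD strictly below `-threshold`, a fading intensity.
#' * `none` — both projections non-enhanced.
#'
#' @param cnr1,cnr2 Non-negative CNR values, former and latter.
#' @param threshold Positive RSD threshold in percent (default 10).
#' @return Character vector with values in
#'   `c("ascending", "steady", "descending", "none")`.
#' @examples
#' classify_pattern(c(0.068, 0.027, 0), c(0.056, 0.033, 0))
#' @export
classify_pattern <- function(cnr1, cnr2, threshold = 10) {
  if (threshold <= 0) {
    abort("`threshold` must be > 0.", class = "cesmr_argument_error")
  }
  rsd <- compute_rsd(cnr1, cnr2)
  dplyr::case_when(
    cnr1 == 0 & cnr2 == 0 ~ "none",
    cnr1 == 0 & cnr2 > 0 ~ "ascending",
    rsd > threshold ~ "ascending",
    rsd < -threshold ~ "descending",
    TRUE ~ "steady"
  )
}

#' Assemble a scored lesion record from its two view measurements
#'
#' Takes the two per-view measurements of one lesion, orders them by
#' acquisition time (via [order_views()] unless already ordered), and
#' fills the kinetic fields: `cnr1` (former), `cnr2` (latter), `rsd`,
#' `pattern`, and `subtraction_detected` (enhancement in either view).
#' Irregularities worth auditing — a clamped negative raw CNR, or
#' enhancement appearing only in the latter view — are recorded in a
#' `flags` column.
#'
#' @param measurements Two-row measurement tibble (see [measure_roi()]).
#' @param metadata Optional named list or one-row data frame of lesion
#'   metadata (id, pathology, receptor status, ...) prepended to the record.
#' @param threshold RSD classification threshold, passed to
#'   [classify_pattern()].
#' @return One-row tibble: metadata columns, then `cnr1`, `cnr2`,
#'   `time_gap`, `rsd`, `pattern`, `subtraction_detected`, `flags`.
#' @export
score_lesion <- function(measurements, metadata = NULL, threshold = 10) {
  if (!("position" %in% names(measurements)) ||
      !identical(measurements$position, c("former", "latter"))) {
    measurements <- order_views(measurements)
  }
  cnr1 <- measurements$cnr[1]
  cnr2 <- measurements$cnr[2]
  flags <- c(
    if (any(measurements$sa < measurements$sb, na.rm = TRUE)) "clamped_cnr",
    if (cnr1 == 0 && cnr2 > 0) "one_view_enhancement")
  rec <- tibble::tibble(
    cnr1 = cnr1, cnr2 = cnr2,
    time_gap = measurements$time_gap[1],
    rsd = compute_rsd(cnr1, cnr2),
    pattern = classify_pattern(cnr1, cnr2, threshold),
    subtraction_detected = any(detect_enhancement(c(cnr1, cnr2))),
    flags = if (length(flags)) paste(flags, collapse = ";") else NA_character_)
  if (!is.null(metadata)) {
    rec <- dplyr::bind_cols(tibble::as_tibble(as.list(metadata)), rec)
  }
  rec
}

#' Score every lesion in a cohort table
#'
#' Vectorised scoring for cohort tables that already carry measured CNR
#' pairs (e.g. from [generate_cohort()]): appends `rsd`, `pattern` and
#' `subtraction_detected` columns.
#'
#' @param cohort Tibble with numeric columns `cnr1`, `cnr2`.
#' @param threshold RSD classification threshold in percent.
#' @return The cohort tibble with the three scoring columns appended.
#' @examples
#' cohort_config(seed = 3) |> generate_cohort() |> score_cohort()
#' @export
score_cohort <- function(cohort, threshold = 10) {
  if (!all(c("cnr1", "cnr2") %in% names(cohort))) {
    abort("`cohort` must have columns `cnr1` and `cnr2`.",
          class = "cesmr_schema_error")
  }
  dplyr::mutate(
    cohort,
    rsd = compute_rsd(.data$cnr1, .data$cnr2),
    pattern = classify_pattern(.data$cnr1, .data$cnr2, threshold),
    subtraction_detected = detect_enhancement(.data$cnr1) |
      detect_enhancement(.data$cnr2))
}
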