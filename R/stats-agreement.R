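#' Cohen's kappa agreement from a k x k contingency table
#'
#' Chance-corrected agreement between two categorical raters or
#' modalities (e.g. CESM enhancement pattern vs DCE-MRI TIC category):
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` the
#' diagonal proportion and expected agreement `pe` from the table margins.
#'
#' @param table Square numeric matrix of counts, rows and columns in the
#'   same category order; total must be >= 1.
#' @return Object of class `cesm_kappa` with elements `table`, `n`,
#'   `observed`, `expected`, `kappa`; see [tidy.cesm_kappa()].
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))
#' @export
cohen_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) {
    abort("`table` must be square (same categories on both axes).",
          class = "cesmr_argument_error")
  }
  if (any(table < 0) || sum(table) < 1) {
    abort("`table` must hold non-negative counts with total >= 1.",
          class = "cesmr_argument_error")
  }
  n <- sum(table)
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  kappa <- if (pe < 1) {
    (po - pe) / (1 - pe)
  } else if (po == 1) {
    # all mass in one cell: agreement is perfect but chance-uncorrectable
    1
  } else {
    abort("Expected agreement is 1 with imperfect observed agreement; kappa undefined.",
          class = "cesmr_argument_error")
  }
  structure(list(table = table, n = n, observed = po, expected = pe,
                 kappa = kappa),
            class = "cesm_kappa")
}

#' @export
print.cesm_kappa <- function(x, ...) {
  cat(sprintf("<cesm_kappa> n = %d, observed agreement %.1f%%, kappa = %.3f\n",
              x$n, 100 * x$observed, x$kappa))
  invisible(x)
}

#' Tidy an agreement result
#'
#' @param x A `cesm_kappa` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `observed`, `expected`, `kappa`.
#' @export
tidy.cesm_kappa <- function(x, ...) {
  tibble::as_tibble(x[c("n", "observed", "expected", "kappa")])
}

#' Test of independence for a contingency table
#'
#' Chi-square test without continuity correction; for a sparse 2 x 2 table
#' (any expected count of 5 or fewer) Fisher's exact test is used instead.
#' Rows or columns with zero margin are dropped with a warning.
#'
#' @param table Numeric matrix of counts with at least two rows and two
#'   columns (after dropping empty margins).
#' @return One-row tibble: `method` (`"chi-squared"` or `"fisher"`),
#'   `statistic` (NA for Fisher), `df` (NA for Fisher), `p_value`.
#' @examples
#' contingency_test(matrix(c(48, 1, 26, 8, 17, 12, 11, 22), nrow = 2))
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("Dropping zero-margin rows/columns from the contingency table.")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("Need at least a 2 x 2 table after dropping empty margins.",
          class = "cesmr_argument_error")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == 2L) && any(expected <= 5)) {
    res <- fisher.test(table)
    return(tibble::tibble(method = "fisher", statistic = NA_real_,
                          df = NA_real_, p_value = res$p.value))
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(method = "chi-squared", statistic = unname(res$statistic),
                 df = unname(res$parameter), p_value = res$p.value)
}

#' Cross-tabulate LE-image vs subtraction-image detection
#'
#' Partitions lesions into the four mutually exclusive detection
#' categories implied by the two modality flags.
#'
#' @param records Tibble with logical columns `le_detected` and
#'   `subtraction_detected`.
#' @return Tibble with columns `category` (`both`, `le_only`,
#'   `subtraction_only`, `neither`) and `n`; the counts sum to
#'   `nrow(records)`.
#' @export
detection_crosstab <- function(records) {
  if (!all(c("le_detected", "subtraction_detected") %in% names(records))) {
    abort("`records` needs logical columns `le_detected` and `subtraction_detected`.",
          class = "cesmr_schema_error")
  }
  le <- records$le_detected
  sub <- records$subtraction_detected
  tibble::tibble(
    category = c("both", "le_only", "subtraction_only", "neither"),
    n = c(sum(le & sub), sum(le & !sub), sum(!le & sub), sum(!le & !sub)))
}
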