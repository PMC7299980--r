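pathology_levels <- c("benign", "non_infiltrating", "infiltrating")
tic_levels <- c("persistent", "plateau", "washout", "none")
pattern_levels <- c("ascending", "steady", "descending", "none")

is_malignant <- function(pathology) pathology != "benign"

#' Load a lesion cohort from CSV
#'
#' Strict schema validation: the file must provide `lesion_id`,
#' `pathology`, `cnr1`, `cnr2`; optional columns (`benign_subtype`, `er`,
#' `pr`, `her2`, `le_detected`, `tic`, and scoring columns) are kept when
#' present. Unknown pathology or TIC labels and negative CNR values are
#' rejected with the offending value named.
#'
#' @param path CSV path (e.g. written by [write_cohort()]).
#' @return A cohort tibble.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such cohort file: ", path), class = "cesmr_io_error")
  }
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("lesion_id", "pathology", "cnr1", "cnr2")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort file is missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "cesmr_schema_error")
  }
  bad <- setdiff(unique(cohort$pathology), pathology_levels)
  if (length(bad)) {
    abort(paste0("Unknown pathology label(s): ",
                 paste(bad, collapse = ", "),
                 ". Expected one of: ",
                 paste(pathology_levels, collapse = ", ")),
          class = "cesmr_schema_error")
  }
  if ("tic" %in% names(cohort)) {
    bad_tic <- setdiff(unique(cohort$tic[!is.na(cohort$tic)]),
                       c(tic_levels, "unknown"))
    if (length(bad_tic)) {
      abort(paste0("Unknown TIC label(s): ", paste(bad_tic, collapse = ", ")),
            class = "cesmr_schema_error")
    }
  }
  if (any(cohort$cnr1 < 0, na.rm = TRUE) || any(cohort$cnr2 < 0, na.rm = TRUE)) {
    abort("CNR columns must be non-negative.", class = "cesmr_schema_error")
  }
  cohort
}

#' Run the full quantitative CESM analysis
#'
#' Orchestrates the analysis over a lesion cohort: per-group CNR summaries
#' with the former-vs-latter signed-rank test and between-group
#' Kruskal-Wallis / pairwise Bonferroni contrasts; CNR1 summaries by
#' receptor status; RSD summaries benign vs malignant; the
#' enhancement-pattern contingency table with its independence test; ROC
#' analyses of CNR1 and CNR2 with the DeLong paired comparison; the
#' LE-vs-subtraction detection cross-tab; and CESM-pattern vs MRI-TIC
#' agreement (Cohen's kappa) for the MRI subset.
#'
#' @param x A [cohort_config()] (the cohort is generated under its seed),
#'   or a cohort tibble from [generate_cohort()] / [load_cohort()].
#' @param threshold RSD classification threshold in percent.
#' @return Object of class `cesm_report`, a list of result tibbles plus
#'   the scored cohort; see [write_report()] for the file layout.
#' @examples
#' report <- run_analysis(cohort_config(seed = 11))
#' report$pattern_table
#' @export
run_analysis <- function(x, threshold = 10) {
  cohort <- if (inherits(x, "cohort_config")) generate_cohort(x) else x
  if (!is.data.frame(cohort)) {
    abort("`x` must be a cohort_config or a cohort data frame.",
          class = "cesmr_argument_error")
  }
  required <- c("pathology", "cnr1", "cnr2")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort is missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "cesmr_schema_error")
  }
  scored <- score_cohort(cohort, threshold = threshold)
  scored$malignant <- is_malignant(scored$pathology)

  present <- intersect(pathology_levels, unique(scored$pathology))
  skipped <- setdiff(pathology_levels, present)
  if (length(skipped)) {
    warn(paste0("Empty pathology group(s) skipped: ",
                paste(skipped, collapse = ", ")))
  }

  # Table-1-style: CNR by group and projection + within-group paired test
  cnr_summary <- scored |>
    tidyr::pivot_longer(c("cnr1", "cnr2"), names_to = "projection",
                        values_to = "cnr") |>
    dplyr::mutate(projection = dplyr::recode(.data$projection,
                                             cnr1 = "former",
                                             cnr2 = "latter")) |>
    dplyr::group_by(.data$pathology, .data$projection) |>
    dplyr::reframe(describe_group(.data$cnr))
  cnr_wilcoxon <- scored |>
    dplyr::group_by(.data$pathology) |>
    dplyr::reframe(wilcoxon_signed_rank(.data$cnr1, .data$cnr2))

  cnr_group_tests <- NULL
  if (length(present) >= 2) {
    kw <- purrr::map(c(cnr1 = "cnr1", cnr2 = "cnr2"), function(col) {
      kruskal_wallis(scored[[col]], scored$pathology)
    })
    pairs <- utils::combn(present, 2, simplify = FALSE)
    pairwise <- purrr::map(c(cnr1 = "cnr1", cnr2 = "cnr2"), function(col) {
      purrr::map(pairs, function(pr) {
        a <- scored[[col]][scored$pathology == pr[1]]
        b <- scored[[col]][scored$pathology == pr[2]]
        mw <- mann_whitney(a, b)
        tibble::tibble(group1 = pr[1], group2 = pr[2], u = mw$u,
                       p_raw = mw$p_value)
      }) |>
        dplyr::bind_rows() |>
        dplyr::mutate(p_adjusted = bonferroni(.data$p_raw, length(pairs)))
    })
    cnr_group_tests <- list(
      kruskal = dplyr::bind_rows(kw, .id = "score"),
      pairwise = dplyr::bind_rows(pairwise, .id = "score"))
  }

  # Table-2-style: CNR1 by receptor status among cancers
  receptor_summary <- NULL
  receptor_cols <- intersect(c("er", "pr", "her2"), names(scored))
  if (length(receptor_cols)) {
    receptor_summary <- purrr::map(
      stats::setNames(receptor_cols, receptor_cols), function(col) {
        sub <- scored[scored$malignant &
                        scored[[col]] %in% c("positive", "negative"), ]
        if (nrow(sub) == 0 || length(unique(sub[[col]])) < 2) return(NULL)
        summ <- sub |>
          dplyr::group_by(status = .data[[col]]) |>
          dplyr::reframe(describe_group(.data$cnr1))
        mw <- mann_whitney(sub$cnr1[sub[[col]] == "positive"],
                           sub$cnr1[sub[[col]] == "negative"])
        dplyr::mutate(summ, p_value = mw$p_value)
      }) |>
      purrr::compact() |>
      dplyr::bind_rows(.id = "receptor")
    if (nrow(receptor_summary) == 0) receptor_summary <- NULL
  }

  # Table-3-style: RSD benign vs malignant
  rsd_summary <- scored |>
    dplyr::group_by(group = ifelse(.data$malignant, "malignant", "benign")) |>
    dplyr::reframe(describe_group(.data$rsd))
  rsd_test <- NULL
  if (length(unique(scored$malignant)) == 2) {
    rsd_test <- mann_whitney(scored$rsd[!scored$malignant],
                             scored$rsd[scored$malignant])
  }

  # Table-4-style: pattern contingency
  pattern_table <- scored |>
    dplyr::group_by(group = ifelse(.data$malignant, "malignant", "benign"),
                    pattern = factor(.data$pattern, pattern_levels)) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    tidyr::complete(pattern = factor(pattern_levels, pattern_levels),
                    fill = list(n = 0L)) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pattern = as.character(.data$pattern))
  pattern_test <- NULL
  counts <- pattern_table |>
    tidyr::pivot_wider(id_cols = "group", names_from = "pattern",
                       values_from = "n")
  if (nrow(counts) == 2) {
    mat <- as.matrix(counts[, pattern_levels])
    pattern_test <- suppressWarnings(contingency_test(mat))
  }

  # ROC block
  roc <- NULL
  if (length(unique(scored$malignant)) == 2) {
    labels <- ifelse(scored$malignant, "malignant", "benign")
    roc <- list(cnr1 = roc_analysis(scored$cnr1, labels),
                cnr2 = roc_analysis(scored$cnr2, labels),
                comparison = compare_auc_paired(scored$cnr1, scored$cnr2,
                                                labels))
  } else {
    warn("Only one class present; ROC block skipped.")
  }

  # Detection cross-tab
  detection <- NULL
  if ("le_detected" %in% names(scored)) {
    detection <- detection_crosstab(scored)
  }

  # CESM vs MRI agreement on the MRI subset. CESM patterns are mapped onto
  # the TIC category space (ascending ~ persistent, steady ~ plateau,
  # descending ~ washout) so both raters share one axis.
  agreement <- NULL
  if ("tic" %in% names(scored)) {
    mri <- scored[!is.na(scored$tic) & scored$tic %in% tic_levels, ]
    if (nrow(mri) > 0) {
      cesm_as_tic <- dplyr::recode(mri$pattern, ascending = "persistent",
                                   steady = "plateau",
                                   descending = "washout", none = "none")
      tab <- table(factor(cesm_as_tic, tic_levels),
                   factor(mri$tic, tic_levels))
      kp <- cohen_kappa(unclass(tab))
      agreement <- list(table = kp$table, summary = tidy(kp),
                        coincidence_pct = 100 * kp$observed)
    }
  }

  structure(
    list(cohort = scored, n = nrow(scored),
         threshold = threshold,
         cnr_summary = cnr_summary, cnr_wilcoxon = cnr_wilcoxon,
         cnr_group_tests = cnr_group_tests,
         receptor_summary = receptor_summary,
         rsd_summary = rsd_summary, rsd_test = rsd_test,
         pattern_table = pattern_table, pattern_test = pattern_test,
         roc = roc, detection = detection, agreement = agreement,
         seed = attr(cohort, "seed")),
    class = "cesm_report")
}

#' @export
print.cesm_report <- function(x, ...) {
  cat(sprintf("<cesm_report> %d lesions (%d benign / %d malignant)\n",
              x$n, sum(!x$cohort$malignant), sum(x$cohort$malignant)))
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC former %.3f vs latter %.3f (DeLong p = %.4g)\n",
                x$roc$cnr1$auc, x$roc$cnr2$auc,
                x$roc$comparison$p_value))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  CESM-MRI coincidence %.1f%%, kappa = %.3f (n = %d)\n",
                x$agreement$coincidence_pct, x$agreement$summary$kappa,
                x$agreement$summary$n))
  }
  invisible(x)
}

# Flattens a report into plain lists/tibbles for the JSON twin; every
# number written to the CSV report also appears here.
report_to_list <- function(report) {
  out <- list(
    n = report$n, threshold = report$threshold, seed = report$seed,
    cnr_summary = report$cnr_summary, cnr_wilcoxon = report$cnr_wilcoxon,
    rsd_summary = report$rsd_summary, pattern_table = report$pattern_table)
  if (!is.null(report$cnr_group_tests)) {
    out$cnr_group_tests <- report$cnr_group_tests
  }
  if (!is.null(report$receptor_summary)) {
    out$receptor_summary <- report$receptor_summary
  }
  if (!is.null(report$rsd_test)) out$rsd_test <- report$rsd_test
  if (!is.null(report$pattern_test)) out$pattern_test <- report$pattern_test
  if (!is.null(report$roc)) {
    out$roc <- list(cnr1 = glance(report$roc$cnr1),
                    cnr2 = glance(report$roc$cnr2),
                    curve_cnr1 = tidy(report$roc$cnr1),
                    curve_cnr2 = tidy(report$roc$cnr2),
                    comparison = report$roc$comparison)
  }
  if (!is.null(report$detection)) out$detection <- report$detection
  if (!is.null(report$agreement)) {
    out$agreement <- list(
      table = as.data.frame.matrix(report$agreement$table),
      summary = report$agreement$summary,
      coincidence_pct = report$agreement$coincidence_pct)
  } else {
    out$agreement <- "not available"
  }
  out
}

#' Write a report bundle to disk
#'
#' Writes each result table as CSV (percent columns printed to one
#' decimal) plus `report.json`, a machine-readable twin holding every
#' number in the rendered tables at full precision, and the scored cohort
#' as `scored_cohort.csv`.
#'
#' @param report A `cesm_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cesm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round1 <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, 1)))
  }
  write1 <- function(df, name, rounded = TRUE) {
    if (is.null(df)) return(invisible(NULL))
    readr::write_csv(if (rounded) round1(df) else df,
                     file.path(dir, name))
  }
  write1(report$cnr_summary, "cnr_summary.csv")
  write1(report$cnr_wilcoxon, "cnr_wilcoxon.csv", rounded = FALSE)
  if (!is.null(report$cnr_group_tests)) {
    write1(report$cnr_group_tests$kruskal, "cnr_kruskal.csv", rounded = FALSE)
    write1(report$cnr_group_tests$pairwise, "cnr_pairwise.csv",
           rounded = FALSE)
  }
  write1(report$receptor_summary, "receptor_summary.csv")
  write1(report$rsd_summary, "rsd_summary.csv")
  write1(report$pattern_table, "pattern_table.csv")
  if (!is.null(report$roc)) {
    roc_tab <- dplyr::bind_rows(
      former = glance(report$roc$cnr1),
      latter = glance(report$roc$cnr2), .id = "projection")
    write1(roc_tab, "roc_summary.csv", rounded = FALSE)
    write1(report$roc$comparison, "roc_comparison.csv", rounded = FALSE)
  }
  write1(report$detection, "detection_crosstab.csv", rounded = FALSE)
  if (!is.null(report$agreement)) {
    agr <- tibble::as_tibble(as.data.frame.matrix(report$agreement$table),
                             rownames = "cesm_pattern")
    write1(agr, "agreement_table.csv", rounded = FALSE)
    write1(report$agreement$summary, "agreement_summary.csv",
           rounded = FALSE)
  }
  write_cohort(report$cohort, file.path(dir, "scored_cohort.csv"))
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Bar chart of enhancement-pattern distributions
#'
#' @param scored Scored cohort tibble (with `pathology` and `pattern`
#'   columns) or a `cesm_report`.
#' @return A ggplot comparing pattern proportions between benign and
#'   malignant lesions.
#' @export
plot_pattern_distribution <- function(scored) {
  if (inherits(scored, "cesm_report")) scored <- scored$cohort
  df <- scored |>
    dplyr::mutate(group = ifelse(is_malignant(.data$pathology),
                                 "malignant", "benign"),
                  pattern = factor(.data$pattern, pattern_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, fill = .data$group)) +
    ggplot2::geom_bar(position = "dodge",
                      ggplot2::aes(y = ggplot2::after_stat(prop),
                                   group = .data$group)) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Enhancement pattern", y = "Within-group share",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
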