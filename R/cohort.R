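#' Configuration for a synthetic CESM cohort
#'
#' Bundles everything the cohort generator needs: group sizes, a
#' [quantile_spec()] per pathology group and projection, the within-lesion
#' coupling between the two projections, receptor-status proportions for
#' the malignant groups, lesion-detectability rates on the low-energy (LE)
#' mammogram, and a per-pattern assignment table for DCE-MRI
#' time-intensity-curve (TIC) categories. The defaults are calibrated to a
#' published 145-lesion cohort: 102 benign, 17 non-infiltrating and 26
#' infiltrating cancers, with the five-point CNR summaries of each group
#' used as the sampling quantiles.
#'
#' @param n_benign,n_non_infiltrating,n_infiltrating Non-negative group sizes.
#' @param cnr_specs Named list with elements `benign`, `non_infiltrating`,
#'   `infiltrating`, each a list of two [quantile_spec()]s named `cnr1` and
#'   `cnr2`.
#' @param dependence Within-lesion CNR1--CNR2 copula blend weight in
#'   `[-1, 1]`; see [sample_cnr_pairs()].
#' @param receptor Named list of proportions: `er_known`, `er_pos`,
#'   `pr_known`, `pr_pos`, `her2_known`, `her2_pos`. Receptor labels are
#'   drawn for malignant lesions only.
#' @param benign_subtypes Named numeric vector of benign-subtype
#'   proportions (must sum to 1).
#' @param le_detection List with elements `benign` and `malignant`, each a
#'   numeric vector `c(enhanced = p, non_enhanced = q)` giving the
#'   probability that the lesion is visible on the LE image conditional on
#'   whether it enhances on the subtraction image.
#' @param tic_table 4 x 4 row-stochastic matrix of TIC probabilities given
#'   the lesion's CESM pattern; rows `ascending`, `steady`, `descending`,
#'   `none`, columns `persistent`, `plateau`, `washout`, `none`.
#' @param n_mri Number of lesions (sampled at random) that also undergo
#'   DCE-MRI and therefore receive a TIC label; the rest are `"unknown"`.
#' @param seed Integer seed for the whole cohort draw.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_benign = 102,
                          n_non_infiltrating = 17,
                          n_infiltrating = 26,
                          cnr_specs = default_cnr_specs(),
                          dependence = 0.8,
                          receptor = list(er_known = 41 / 43, er_pos = 30 / 41,
                                          pr_known = 41 / 43, pr_pos = 24 / 41,
                                          her2_known = 30 / 43, her2_pos = 9 / 30),
                          benign_subtypes = c(fibroadenoma = 53, adenosis = 33,
                                              intraductal_papilloma = 8,
                                              other = 8) / 102,
                          le_detection = list(
                            benign = c(enhanced = 20 / 54, non_enhanced = 8 / 48),
                            malignant = c(enhanced = 27 / 42, non_enhanced = 1)),
                          tic_table = default_tic_table(),
                          n_mri = 28,
                          seed = 1L) {
  sizes <- c(n_benign, n_non_infiltrating, n_infiltrating)
  if (any(sizes < 0) || any(sizes != trunc(sizes))) {
    abort("Group sizes must be non-negative integers.",
          class = "cesmr_config_error")
  }
  if (abs(dependence) > 1) {
    abort("`dependence` must lie in [-1, 1].", class = "cesmr_config_error")
  }
  groups <- c("benign", "non_infiltrating", "infiltrating")
  if (!all(groups %in% names(cnr_specs))) {
    abort("`cnr_specs` needs elements benign, non_infiltrating, infiltrating.",
          class = "cesmr_config_error")
  }
  for (g in groups) {
    if (!inherits(cnr_specs[[g]]$cnr1, "quantile_spec") ||
        !inherits(cnr_specs[[g]]$cnr2, "quantile_spec")) {
      abort(paste0("`cnr_specs$", g, "` needs quantile_spec elements cnr1, cnr2."),
            class = "cesmr_config_error")
    }
  }
  if (abs(sum(benign_subtypes) - 1) > 1e-8) {
    abort("`benign_subtypes` proportions must sum to 1.",
          class = "cesmr_config_error")
  }
  tic_table <- as.matrix(tic_table)
  if (!identical(dim(tic_table), c(4L, 4L)) ||
      any(tic_table < 0) || any(abs(rowSums(tic_table) - 1) > 1e-8)) {
    abort("`tic_table` must be a 4 x 4 row-stochastic matrix.",
          class = "cesmr_config_error")
  }
  probs <- unlist(receptor)
  if (any(probs < 0 | probs > 1)) {
    abort("Receptor proportions must lie in [0, 1].",
          class = "cesmr_config_error")
  }
  if (n_mri < 0 || n_mri > sum(sizes)) {
    abort("`n_mri` must lie between 0 and the cohort size.",
          class = "cesmr_config_error")
  }
  structure(
    list(n_benign = as.integer(n_benign),
         n_non_infiltrating = as.integer(n_non_infiltrating),
         n_infiltrating = as.integer(n_infiltrating),
         cnr_specs = cnr_specs, dependence = dependence,
         receptor = receptor, benign_subtypes = benign_subtypes,
         le_detection = le_detection, tic_table = tic_table,
         n_mri = as.integer(n_mri), seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default per-group CNR quantile specifications
#'
#' Five-point CNR summaries (percent scale) for the two projections of each
#' pathology group, with zero-inflation probabilities equal to the observed
#' non-enhancement fractions: 48/102 for benign lesions and 1/43 for
#' cancers.
#'
#' @return Named list of lists of [quantile_spec()]s.
#' @export
default_cnr_specs <- function() {
  zb <- 48 / 102
  zm <- 1 / 43
  list(
    benign = list(
      cnr1 = quantile_spec(zb, 0, 0, 2.7, 4.8, 10.1),
      cnr2 = quantile_spec(zb, 0, 0, 3.3, 5.2, 13.2)),
    non_infiltrating = list(
      cnr1 = quantile_spec(zm, 0, 5.0, 6.8, 8.1, 11.8),
      cnr2 = quantile_spec(zm, 0, 4.3, 5.6, 8.5, 10.4)),
    infiltrating = list(
      cnr1 = quantile_spec(zm, 1.8, 4.9, 6.8, 9.2, 27.2),
      cnr2 = quantile_spec(zm, 0.6, 4.3, 5.6, 7.5, 26.0))
  )
}

#' Default CESM-pattern to MRI-TIC assignment table
#'
#' Row-stochastic conditional probabilities of each DCE-MRI TIC category
#' given the lesion's CESM enhancement pattern, chosen so that the expected
#' between-modality coincidence rate is roughly two thirds (moderate
#' agreement) under the default cohort mix.
#'
#' @return A 4 x 4 matrix with pattern rows and TIC columns.
#' @export
default_tic_table <- function() {
  m <- matrix(c(0.60, 0.20, 0.10, 0.10,
                0.20, 0.55, 0.15, 0.10,
                0.05, 0.20, 0.65, 0.10,
                0.12, 0.10, 0.08, 0.70),
              nrow = 4, byrow = TRUE,
              dimnames = list(pattern = c("ascending", "steady",
                                          "descending", "none"),
                              tic = c("persistent", "plateau",
                                      "washout", "none")))
  m
}

#' Generate a synthetic lesion cohort
#'
#' Draws one row per lesion: pathology group (with benign subtype),
#' receptor status for malignant lesions, a coupled (CNR1, CNR2) pair from
#' the group's quantile specs, an LE-image detection flag conditional on
#' enhancement, and a TIC label for the MRI subset, assigned from the
#' per-pattern table. The draw is bit-reproducible under the config seed,
#' which is recorded in the `seed` attribute of the result.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `lesion_id`, `pathology`,
#'   `benign_subtype`, `er`, `pr`, `her2`, `cnr1`, `cnr2` (percent scale),
#'   `le_detected`, `tic`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dplyr::count(cohort, pathology)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(benign = config$n_benign,
              non_infiltrating = config$n_non_infiltrating,
              infiltrating = config$n_infiltrating)
  n <- sum(groups)
  empty <- tibble::tibble(
    lesion_id = character(0), pathology = character(0),
    benign_subtype = character(0), er = character(0), pr = character(0),
    her2 = character(0), cnr1 = numeric(0), cnr2 = numeric(0),
    le_detected = logical(0), tic = character(0))
  if (n == 0L) {
    attr(empty, "seed") <- config$seed
    return(empty)
  }
  out <- withr::with_seed(config$seed, {
    pathology <- rep(names(groups), groups)
    pairs <- purrr::map(names(groups), function(g) {
      if (groups[[g]] == 0L) {
        return(tibble::tibble(cnr1 = numeric(0), cnr2 = numeric(0)))
      }
      sp <- config$cnr_specs[[g]]
      sample_pairs_core(sp$cnr1, sp$cnr2, config$dependence, groups[[g]])
    })
    pairs <- dplyr::bind_rows(pairs)
    malignant <- pathology != "benign"

    draw_status <- function(n, p_known, p_pos) {
      known <- runif(n) < p_known
      pos   <- runif(n) < p_pos
      dplyr::case_when(!known ~ "unknown", pos ~ "positive",
                       TRUE ~ "negative")
    }
    er <- pr <- her2 <- rep("unknown", n)
    nm <- sum(malignant)
    if (nm > 0) {
      er[malignant]   <- draw_status(nm, config$receptor$er_known,
                                     config$receptor$er_pos)
      pr[malignant]   <- draw_status(nm, config$receptor$pr_known,
                                     config$receptor$pr_pos)
      her2[malignant] <- draw_status(nm, config$receptor$her2_known,
                                     config$receptor$her2_pos)
    }
    benign_subtype <- rep(NA_character_, n)
    nb <- sum(!malignant)
    if (nb > 0) {
      benign_subtype[!malignant] <- sample(
        names(config$benign_subtypes), nb, replace = TRUE,
        prob = config$benign_subtypes)
    }

    enhanced <- pairs$cnr1 > 0 | pairs$cnr2 > 0
    le_prob <- ifelse(
      malignant,
      ifelse(enhanced, config$le_detection$malignant[["enhanced"]],
             config$le_detection$malignant[["non_enhanced"]]),
      ifelse(enhanced, config$le_detection$benign[["enhanced"]],
             config$le_detection$benign[["non_enhanced"]]))
    le_detected <- runif(n) < le_prob

    pattern <- classify_pattern(pairs$cnr1, pairs$cnr2)
    tic <- rep("unknown", n)
    mri_idx <- sample.int(n, config$n_mri)
    tic[mri_idx] <- vapply(pattern[mri_idx], function(p) {
      sample(colnames(config$tic_table), 1L, prob = config$tic_table[p, ])
    }, character(1))

    tibble::tibble(
      lesion_id = sprintf("L%03d", seq_len(n)),
      pathology = pathology, benign_subtype = benign_subtype,
      er = er, pr = pr, her2 = her2,
      cnr1 = pairs$cnr1, cnr2 = pairs$cnr2,
      le_detected = le_detected, tic = tic)
  })
  attr(out, "seed") <- config$seed
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort tibble from [generate_cohort()] or
#'   [score_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
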