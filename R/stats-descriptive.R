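#' Five-number descriptive summary of a group
#'
#' Mean, median, minimum, maximum and quartiles, the layout used to report
#' CNR and RSD distributions by pathology group. Percentiles use linear
#' interpolation between closest ranks (R's type-7 default), a convention
#' fixed here for reproducibility.
#'
#' @param values Non-empty numeric vector (percent scale for CNR/RSD).
#' @return One-row tibble: `n`, `mean`, `median`, `minimum`, `maximum`,
#'   `q25`, `q75`.
#' @examples
#' describe_group(c(0, 0, 2.7, 4.8, 10.1))
#' @export
describe_group <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("`values` must contain at least one non-missing number.",
          class = "cesmr_argument_error")
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(values), mean = mean(values),
                 median = median(values), minimum = min(values),
                 maximum = max(values), q25 = q[1], q75 = q[2])
}

# Shared guard: completely degenerate samples make rank tests meaningless.
all_identical <- function(...) {
  x <- unlist(list(...))
  length(unique(x[!is.na(x)])) <= 1L
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided rank-sum comparison; exact p-value for small untied samples,
#' tie-corrected normal approximation otherwise (via [stats::wilcox.test()]).
#' If every value in both groups is identical the test is degenerate and
#' `p = 1` is returned with a warning.
#'
#' @param a,b Numeric vectors, one per group (each non-empty).
#' @return One-row tibble with `u` (the U statistic for `a`) and `p_value`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    abort("Both groups need at least one observation.",
          class = "cesmr_argument_error")
  }
  if (all_identical(a, b)) {
    warn("All values identical across groups; returning p = 1.")
    return(tibble::tibble(u = length(a) * length(b) / 2, p_value = 1))
  }
  res <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
  tibble::tibble(u = unname(res$statistic), p_value = res$p.value)
}

#' Kruskal-Wallis test for three or more independent groups
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length as `values`.
#' @return One-row tibble with `h` (the tie-corrected H statistic), `df`
#'   and `p_value`; `p = 1` with a warning if all values are identical.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length.",
          class = "cesmr_argument_error")
  }
  if (all_identical(values)) {
    warn("All values identical across groups; returning p = 1.")
    return(tibble::tibble(h = 0, df = length(unique(groups)) - 1L,
                          p_value = 1))
  }
  res <- kruskal.test(values, factor(groups))
  tibble::tibble(h = unname(res$statistic),
                 df = unname(res$parameter), p_value = res$p.value)
}

#' Wilcoxon signed-rank test for paired observations
#'
#' Compares two related measurements (e.g. former vs latter projection CNR
#' within lesions). Zero differences are dropped, Wilcoxon's original
#' treatment.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return One-row tibble with `v` (signed-rank statistic) and `p_value`;
#'   if no nonzero differences remain, `p = 1` with a warning.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must be paired vectors of equal length.",
          class = "cesmr_argument_error")
  }
  d <- x - y
  if (all(d == 0 | is.na(d))) {
    warn("No nonzero paired differences; returning p = 1.")
    return(tibble::tibble(v = 0, p_value = 1))
  }
  res <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  tibble::tibble(v = unname(res$statistic), p_value = res$p.value)
}

#' Bonferroni adjustment for multiple comparisons
#'
#' Each p-value is multiplied by the number of comparisons `m` and capped
#' at 1, so a thoroughly non-significant pairwise contrast reports exactly
#' `p = 1`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of comparisons (default: `length(p_values)`).
#' @return Adjusted p-values, never smaller than the input, never above 1.
#' @examples
#' bonferroni(c(0.5, 0.0003), m = 3)
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) {
    abort("`m` must be >= 1.", class = "cesmr_argument_error")
  }
  pmin(1, p_values * m)
}
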