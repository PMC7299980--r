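# DeLong structural components for one score vector.
# pos/neg are the scores of diseased / non-diseased subjects; psi is the
# Mann-Whitney kernel (1 if pos > neg, 0.5 if tied, 0 otherwise).
delong_components <- function(pos, neg) {
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Empirical ROC analysis with Youden cut-off
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' disease label, the AUC (identical to the Mann-Whitney statistic
#' `U / (n1 * n0)`), a DeLong-variance 95% Wald confidence interval
#' truncated to `[0, 1]`, and the Youden-optimal cut-off. Candidate
#' cut-offs are midpoints between consecutive distinct scores (plus
#' sentinels), with a subject called positive when its score is strictly
#' above the cut-off; among cut-offs attaining the maximal
#' `J = sensitivity + specificity - 1`, the smallest is chosen (the
#' screening-oriented, sensitivity-favouring rule).
#'
#' @param scores Numeric vector of diagnostic scores (higher = more
#'   suspicious).
#' @param labels Binary labels, same length; values in
#'   `c("benign", "malignant")` or anything coercible with `positive`.
#' @param positive The label value treated as diseased.
#' @return Object of class `cesm_roc`: see [tidy.cesm_roc()] for the
#'   per-threshold curve and [glance.cesm_roc()] for the summary row.
#' @examples
#' roc <- roc_analysis(c(1, 2, 3, 4), c("benign", "benign", "malignant", "malignant"))
#' glance(roc)
#' @export
roc_analysis <- function(scores, labels, positive = "malignant") {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    abort("Both classes must be present to build a ROC curve.",
          class = "cesmr_argument_error")
  }
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  comp <- delong_components(pos, neg)
  auc <- comp$auc
  se <- sqrt(var(comp$v10) / length(pos) + var(comp$v01) / length(neg))
  ci <- pmin(1, pmax(0, auc + qnorm(c(0.025, 0.975)) * se))

  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  sens <- vapply(cand, function(t) mean(pos > t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # candidates ascend, so first = smallest

  structure(
    list(curve = tibble::tibble(threshold = cand, sensitivity = sens,
                                specificity = spec, youden = j),
         auc = auc, auc_se = se, ci_lower = ci[1], ci_upper = ci[2],
         cutoff = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden = j[best],
         n_positive = length(pos), n_negative = length(neg),
         positive = positive),
    class = "cesm_roc")
}

#' @export
print.cesm_roc <- function(x, ...) {
  cat(sprintf("<cesm_roc> AUC = %.3f (95%% CI %.3f-%.3f), n = %d/%d\n",
              x$auc, x$ci_lower, x$ci_upper, x$n_positive, x$n_negative))
  cat(sprintf("  Youden cut-off %.3g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Tidy the per-threshold ROC curve
#'
#' @param x A `cesm_roc` object.
#' @param ... Unused.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
tidy.cesm_roc <- function(x, ...) x$curve

#' One-row ROC summary
#'
#' @param x A `cesm_roc` object.
#' @param ... Unused.
#' @return One-row tibble: `auc`, `auc_se`, `ci_lower`, `ci_upper`,
#'   `cutoff`, `sensitivity`, `specificity`, `youden`, `n_positive`,
#'   `n_negative`.
#' @export
glance.cesm_roc <- function(x, ...) {
  tibble::as_tibble(x[c("auc", "auc_se", "ci_lower", "ci_upper", "cutoff",
                        "sensitivity", "specificity", "youden",
                        "n_positive", "n_negative")])
}

#' Plot an ROC curve
#'
#' @param object A `cesm_roc` object.
#' @param ... Unused.
#' @return A ggplot: ROC curve with the chance diagonal and the Youden
#'   operating point marked.
#' @export
autoplot.cesm_roc <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, 1 - .data$specificity,
                          .data$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, shape = 4, size = 3) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$ci_lower,
                                  object$ci_upper)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects (e.g.
#' former- vs latter-projection CNR) using the DeLong structural
#' components: the paired covariance of the two AUC estimates feeds a
#' normal z test on the AUC difference.
#'
#' @param scores1,scores2 Numeric score vectors on the same subjects.
#' @param labels Binary labels, same length.
#' @param positive The label value treated as diseased.
#' @return One-row tibble: `auc1`, `auc2`, `difference`, `se`, `z`,
#'   `p_value`.
#' @export
compare_auc_paired <- function(scores1, scores2, labels,
                               positive = "malignant") {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels)) {
    abort("Both scores and the labels must cover the same subjects.",
          class = "cesmr_argument_error")
  }
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    abort("Both classes must be present.", class = "cesmr_argument_error")
  }
  c1 <- delong_components(scores1[is_pos], scores1[!is_pos])
  c2 <- delong_components(scores2[is_pos], scores2[!is_pos])
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  diff <- c1$auc - c2$auc
  se <- sqrt(max(0, var_diff))
  if (se == 0) {
    if (diff == 0) {
      p <- 1
      z <- 0
    } else {
      warn("Zero DeLong SE with a nonzero AUC difference; reporting p = 0.")
      p <- 0
      z <- Inf * sign(diff)
    }
  } else {
    z <- diff / se
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc1 = c1$auc, auc2 = c2$auc, difference = diff,
                 se = se, z = z, p_value = p)
}
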