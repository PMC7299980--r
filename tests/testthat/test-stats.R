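test_that("describe_group reports the five-number layout", {
  s <- describe_group(c(0, 0, 2.7, 4.8, 10.1))
  expect_equal(s$n, 5)
  expect_equal(s$median, 2.7)
  expect_equal(s$minimum, 0)
  expect_equal(s$maximum, 10.1)
  flat <- describe_group(c(5, 5, 5))
  expect_true(all(flat[c("mean", "median", "minimum", "maximum",
                         "q25", "q75")] == 5))
  expect_error(describe_group(numeric(0)), class = "cesmr_argument_error")
})

test_that("describe_group recovers a calibrated sampler's quantiles", {
  sp <- quantile_spec(0, 0, 0, 2.7, 4.8, 10.1)
  draws <- sample_cnr_pairs(sp, sp, 0, n = 1000, seed = 6)$cnr1
  s <- describe_group(draws)
  expect_equal(s$median, 2.7, tolerance = 0.2)
  expect_equal(s$q75, 4.8, tolerance = 0.2)
})

test_that("rank tests match their classical references", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 0.1)  # exact: 2/choose(6, 3)

  expect_warning(flat <- mann_whitney(c(2, 2), c(2, 2, 2)),
                 "identical")
  expect_equal(flat$p_value, 1)

  expect_warning(kw <- kruskal_wallis(rep(7, 9), rep(1:3, each = 3)),
                 "identical")
  expect_equal(kw$h, 0)
  expect_equal(kw$p_value, 1)

  x <- c(1.1, 2.3, 0.7, 5.2, 4.4)
  g <- c("a", "a", "b", "b", "c")
  ref <- kruskal.test(x, factor(g))
  expect_equal(kruskal_wallis(x, g)$p_value, ref$p.value)

  w <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(2, 3, 5, 7))
  ref_w <- suppressWarnings(
    wilcox.test(c(1, 2, 3, 4), c(2, 3, 5, 7), paired = TRUE))
  expect_equal(w$p_value, ref_w$p.value)
  expect_warning(z <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "nonzero")
  expect_equal(z$p_value, 1)
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(0.0003, m = 3), 0.0009)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))  # m defaults to length
  expect_equal(bonferroni(0.7, m = 1), 0.7)
  withr::with_seed(2, {
    p <- runif(50)
    adj <- bonferroni(p, m = 7)
    expect_true(all(adj >= p) && all(adj <= 1))
  })
  expect_error(bonferroni(0.5, m = 0), class = "cesmr_argument_error")
})

test_that("ROC analysis handles separable, degenerate and tied scores", {
  r <- roc_analysis(c(1, 2, 3, 4), c("benign", "benign", "malignant",
                                     "malignant"))
  expect_equal(r$auc, 1)
  expect_gt(r$cutoff, 2)
  expect_lt(r$cutoff, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  tied <- roc_analysis(rep(2, 10), rep(c("benign", "malignant"), 5))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_analysis(1:4, rep("benign", 4)),
               class = "cesmr_argument_error")
})

test_that("AUC equals the Mann-Whitney identity and flips under negation", {
  withr::with_seed(14, {
    for (i in 1:200) {
      n1 <- sample(3:12, 1)
      n0 <- sample(3:12, 1)
      scores <- c(rnorm(n1, 1), rnorm(n0))
      if (runif(1) < 0.3) scores <- round(scores)  # induce ties
      labels <- rep(c("malignant", "benign"), c(n1, n0))
      r <- roc_analysis(scores, labels)
      u <- suppressWarnings(
        wilcox.test(scores[labels == "malignant"],
                    scores[labels == "benign"]))$statistic
      expect_equal(r$auc, unname(u) / (n1 * n0))
      expect_equal(roc_analysis(-scores, labels)$auc, 1 - r$auc)
    }
  })
})

test_that("AUC, CI and the paired test agree with pROC's DeLong machinery", {
  withr::with_seed(33, {
    for (i in 1:5) {
      labels <- rep(c("malignant", "benign"), c(20, 30))
      s1 <- rnorm(50, ifelse(labels == "malignant", 1, 0))
      s2 <- s1 + rnorm(50, sd = 0.8)
      r <- roc_analysis(s1, labels)
      ref <- pROC::roc(labels, s1, levels = c("benign", "malignant"),
                       direction = "<", quiet = TRUE)
      expect_equal(r$auc, as.numeric(pROC::auc(ref)))
      ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
      expect_equal(c(r$ci_lower, r$ci_upper), ref_ci[c(1, 3)],
                   tolerance = 1e-8)
      cmp <- compare_auc_paired(s1, s2, labels)
      ref2 <- pROC::roc(labels, s2, levels = c("benign", "malignant"),
                        direction = "<", quiet = TRUE)
      ref_test <- pROC::roc.test(ref, ref2, method = "delong",
                                 paired = TRUE)
      expect_equal(cmp$p_value, ref_test$p.value, tolerance = 1e-8)
    }
  })
})

test_that("paired AUC comparison honours its degenerate contracts", {
  labels <- rep(c("malignant", "benign"), c(5, 5))
  s <- c(6:10, 1:5)
  same <- compare_auc_paired(s, s, labels)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # the scores separate perfectly both ways round, so the paired variance
  # degenerates to zero and the contract reports p = 0 with a warning
  expect_warning(flipped <- compare_auc_paired(s, -s, labels),
                 "Zero DeLong SE")
  expect_equal(flipped$difference, same$auc1 - (1 - same$auc1))
})

test_that("DeLong SE matches a brute-force structural-components oracle", {
  withr::with_seed(40, {
    labels <- rep(c("malignant", "benign"), c(4, 6))
    s1 <- rnorm(10)
    s2 <- rnorm(10)
    cmp <- compare_auc_paired(s1, s2, labels)
    # direct recomputation with explicit loops
    pos <- which(labels == "malignant"); neg <- which(labels == "benign")
    psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
    comps <- function(s) {
      v10 <- vapply(pos, function(i) mean(vapply(neg, function(j)
        psi(s[i], s[j]), numeric(1))), numeric(1))
      v01 <- vapply(neg, function(j) mean(vapply(pos, function(i)
        psi(s[i], s[j]), numeric(1))), numeric(1))
      list(v10 = v10, v01 = v01)
    }
    a <- comps(s1); b <- comps(s2)
    var_diff <- var(a$v10 - b$v10) / length(pos) +
      var(a$v01 - b$v01) / length(neg)
    expect_equal(cmp$se, sqrt(var_diff))
  })
})

test_that("Cohen's kappa matches the hand formula and an external check", {
  expect_equal(tidy(cohen_kappa(diag(c(5, 7, 9))))$kappa, 1)
  expect_equal(tidy(cohen_kappa(matrix(25, 2, 2)))$kappa, 0)
  k <- cohen_kappa(matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$observed, 0.70)
  expect_equal(k$expected, 0.50)
  expect_equal(k$kappa, 0.40)
  # scale invariance
  expect_equal(cohen_kappa(3 * k$table)$kappa, k$kappa)
  withr::with_seed(50, {
    for (i in 1:20) {
      tab <- random_table(sample(2:4, 1))
      expect_equal(cohen_kappa(tab)$kappa,
                   e1071::classAgreement(tab)$kappa)
    }
  })
  expect_error(cohen_kappa(matrix(1:6, 2, 3)),
               class = "cesmr_argument_error")
})

test_that("contingency tests pick chi-square or Fisher appropriately", {
  even <- contingency_test(matrix(c(10, 10, 20, 20), 2))
  expect_equal(even$p_value, 1)

  sparse <- contingency_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sparse$method, "fisher")
  # hypergeometric enumeration: tables as or more extreme than observed
  p_oracle <- sum(dhyper(0:10, 10, 10, 10)[dhyper(0:10, 10, 10, 10) <=
                                             dhyper(10, 10, 10, 10)])
  expect_equal(sparse$p_value, p_oracle)

  big <- contingency_test(matrix(c(48, 1, 26, 8, 17, 12, 11, 22),
                                 nrow = 2))
  expect_equal(big$method, "chi-squared")
  expect_lt(big$p_value, 0.001)

  expect_warning(dropped <- contingency_test(
    rbind(c(5, 2), c(0, 0), c(8, 3))), "zero-margin")
  expect_error(contingency_test(matrix(c(5, 8), 1)),
               class = "cesmr_argument_error")
})

test_that("detection cross-tab partitions lesions exhaustively", {
  none <- detection_crosstab(tibble::tibble(
    le_detected = rep(FALSE, 4), subtraction_detected = rep(FALSE, 4)))
  expect_equal(none$n, c(0, 0, 0, 4))

  one <- detection_crosstab(tibble::tibble(le_detected = TRUE,
                                           subtraction_detected = TRUE))
  expect_equal(one$n[one$category == "both"], 1)

  withr::with_seed(60, {
    records <- tibble::tibble(le_detected = runif(100) < 0.4,
                              subtraction_detected = runif(100) < 0.6)
    ct <- detection_crosstab(records)
    expect_equal(sum(ct$n), 100)
    # inclusion-exclusion against per-modality totals
    expect_equal(ct$n[ct$category == "both"] +
                   ct$n[ct$category == "le_only"],
                 sum(records$le_detected))
    expect_equal(ct$n[ct$category == "both"] +
                   ct$n[ct$category == "subtraction_only"],
                 sum(records$subtraction_detected))
  })
})
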