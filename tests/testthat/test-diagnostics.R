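# Enumeration / brute-force oracles used across these tests.

# All-pairs AUC with ties counted one half (disease = lower CR).
auc_bruteforce <- function(cr_ipd, cr_hc) {
  mean(outer(cr_hc, cr_ipd, function(h, d) (h > d) + 0.5 * (h == d)))
}

# Exact two-sided Mann-Whitney p by enumeration over group assignments,
# computing U by pair counting (independent of the rank-sum implementation).
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b)
    sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  u_obs <- u_of(x, y)
  mu <- n1 * (length(pooled) - n1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(ix)
    u_of(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration.
fisher_enumeration_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Mann-Whitney exact p matches enumeration and the textbook case", {
  m <- nigramap:::mw_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$p_value, 0.1)
  expect_equal(m$statistic, 0)
  expect_equal(mw_enumeration_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(7)
  for (i in 1:25) {
    x <- sample(1:6, sample(3:8, 1), replace = TRUE)  # ties likely
    y <- sample(1:6, sample(3:8, 1), replace = TRUE)
    expect_equal(nigramap:::mw_test(x, y)$p_value, mw_enumeration_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney matches wilcox.test's tie-corrected approximation", {
  set.seed(8)
  for (i in 1:10) {
    x <- round(rnorm(15, 0, 2), 1)
    y <- round(rnorm(12, 0.8, 2), 1)
    got <- nigramap:::mw_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("group comparisons gate on normality and Bonferroni-adjust", {
  set.seed(5)
  n <- 20
  normal_effect <- c(rnorm(n, 0.15, 0.03), rnorm(n, 0.20, 0.03))
  skewed <- c(rexp(n, 20), rexp(n, 8))^2   # strongly non-normal
  tbl <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:(2 * n)),
    group = rep(c("IPD", "HC"), each = n),
    reg_normal = normal_effect,
    reg_skewed = skewed)
  res <- compare_groups(tbl, c("reg_normal", "reg_skewed"))
  expect_equal(res$test[res$region == "reg_normal"], "t-test")
  expect_equal(res$test[res$region == "reg_skewed"], "Mann-Whitney")
  expect_equal(res$p_adjusted, pmin(1, 2 * res$p_raw))
  # mean +/- SD reporting iff the t-test was used
  expect_match(res$summary_ipd[res$region == "reg_normal"], "±")
  expect_match(res$summary_ipd[res$region == "reg_skewed"], "\\(")
  # identical groups: p = 1
  tbl$same <- rep(c(1, 2, 3, 4, 5), 2 * n / 5)
  res2 <- compare_groups(tbl, "same")
  expect_equal(res2$p_raw, 1)
  # degenerate constant regions error
  tbl$const <- 1
  expect_error(compare_groups(tbl, "const"), "constant")
  expect_error(compare_groups(tbl[c(1, 2, 21, 22), ], "reg_normal"),
               "at least 3")
})

test_that("AUC equals the Mann-Whitney pair count and handles edge cases", {
  set.seed(12)
  for (i in 1:30) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- round(rnorm(n1, 0.15, 0.04), 2)
    y <- round(rnorm(n2, 0.19, 0.04), 2)
    tbl <- tibble::tibble(group = rep(c("IPD", "HC"), c(n1, n2)),
                          cr = c(x, y))
    r <- suppressWarnings(roc_analysis(tbl, "cr"))
    expect_equal(r$auc, auc_bruteforce(x, y), tolerance = 1e-13)
    u <- nigramap:::mann_whitney_u(y, x)
    expect_equal(r$auc, u / (n1 * n2), tolerance = 1e-13)
  }
  # perfect separation and identical groups
  tbl <- tibble::tibble(group = rep(c("IPD", "HC"), each = 4),
                        cr = c(1, 2, 3, 4, 5, 6, 7, 8) / 10)
  expect_equal(roc_analysis(tbl, "cr")$auc, 1.0)
  tbl$cr <- rep(c(0.1, 0.2, 0.3, 0.4), 2)
  expect_equal(roc_analysis(tbl, "cr")$auc, 0.5)
  tbl$cr <- 0.2
  expect_warning(r <- roc_analysis(tbl, "cr"), "identical")
  expect_equal(r$auc, 0.5)
})

test_that("DeLong AUC variance and CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(20, 0.15, 0.04)
    y <- rnorm(25, 0.20, 0.04)
    tbl <- tibble::tibble(group = rep(c("IPD", "HC"), c(20, 25)),
                          cr = c(x, y))
    r <- roc_analysis(tbl, "cr")
    pr <- suppressMessages(pROC::roc(tbl$group, tbl$cr,
                                     levels = c("HC", "IPD"),
                                     direction = ">"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$var_auc, pROC::var(pr, method = "delong"),
                 tolerance = 1e-10)
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
    expect_true(all(r$ci >= 0 & r$ci <= 1))
  }
})

test_that("the Youden operating point maximizes J with ties toward specificity", {
  tbl <- tibble::tibble(group = rep(c("IPD", "HC"), each = 5),
                        cr = c(0.10, 0.11, 0.12, 0.20, 0.25,
                               0.18, 0.21, 0.22, 0.23, 0.24))
  r <- roc_analysis(tbl, "cr")
  # brute force over all cuts
  cuts <- sort(unique(tbl$cr))
  sens <- vapply(cuts, function(c) mean(tbl$cr[1:5] <= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(tbl$cr[6:10] > c), numeric(1))
  expect_equal(r$youden, max(sens + spec - 1))
  expect_equal(r$sensitivity + r$specificity - 1, r$youden)
  # tie in J resolved toward the higher-specificity (smaller) threshold
  tbl2 <- tibble::tibble(group = rep(c("IPD", "HC"), each = 2),
                         cr = c(0.1, 0.2, 0.3, 0.4))
  r2 <- roc_analysis(tbl2, "cr")
  expect_lt(r2$threshold, 0.3)
})

test_that("paired ROC comparison matches pROC's DeLong test and a permutation oracle", {
  skip_if_not_installed("pROC")
  set.seed(40)
  n <- 50
  strong <- c(rnorm(n, 0.14, 0.03), rnorm(n, 0.20, 0.03))
  null1 <- rnorm(2 * n, 0.2, 0.03)
  tbl <- tibble::tibble(group = rep(c("IPD", "HC"), each = n),
                        strong = strong, weak = null1)
  cmp <- compare_rocs(tbl, c("strong", "weak"))
  r1 <- suppressMessages(pROC::roc(tbl$group, tbl$strong,
                                   levels = c("HC", "IPD"),
                                   direction = ">"))
  r2 <- suppressMessages(pROC::roc(tbl$group, tbl$weak,
                                   levels = c("HC", "IPD"),
                                   direction = ">"))
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(cmp$pairs$p_raw, ref$p.value, tolerance = 1e-10)
  expect_lt(cmp$pairs$p_adjusted, 0.05)
  # permutation oracle: swap the two markers within random subjects
  obs <- abs(auc_bruteforce(strong[1:n], strong[-(1:n)]) -
               auc_bruteforce(null1[1:n], null1[-(1:n)]))
  perm <- replicate(2000, {
    swap <- runif(2 * n) < 0.5
    a <- ifelse(swap, null1, strong)
    b <- ifelse(swap, strong, null1)
    abs(auc_bruteforce(a[1:n], a[-(1:n)]) -
          auc_bruteforce(b[1:n], b[-(1:n)]))
  })
  p_perm <- (1 + sum(perm >= obs)) / 2001
  expect_lt(p_perm, 0.05)
  # identical score vectors: zero difference, p = 1
  tbl$dup <- tbl$strong
  cmp2 <- compare_rocs(tbl, c("strong", "dup"))
  expect_equal(cmp2$pairs$p_adjusted, 1)
  expect_equal(unname(diag(cmp2$p_matrix)), c(1, 1))
})

test_that("LOOCV refits thresholds per fold and behaves under the null", {
  # perfect separation survives leave-one-out
  tbl <- tibble::tibble(group = rep(c("IPD", "HC"), each = 6),
                        cr = c(seq(0.10, 0.15, length.out = 6),
                               seq(0.20, 0.25, length.out = 6)))
  cv <- loocv(tbl, "cr")
  expect_equal(cv$cv_sensitivity, 1.0)
  expect_equal(cv$cv_specificity, 1.0)
  expect_equal(cv$cv_auc, 1.0)
  # null labels: mean cross-validated J near zero, and below the
  # (optimistically biased) apparent J
  set.seed(99)
  cvj <- apparent_j <- numeric(60)
  for (s in 1:60) {
    vals <- rnorm(20, 0.2, 0.03)
    tbl0 <- tibble::tibble(group = sample(rep(c("IPD", "HC"), each = 10)),
                           cr = vals)
    cv0 <- suppressWarnings(loocv(tbl0, "cr"))
    cvj[s] <- cv0$cv_sensitivity + cv0$cv_specificity - 1
    apparent_j[s] <- suppressWarnings(roc_analysis(tbl0, "cr"))$youden
  }
  expect_lt(abs(mean(cvj)), 0.1)       # ~0 within Monte-Carlo error
  expect_lt(mean(cvj), mean(apparent_j))  # optimism of the apparent J
})

test_that("laterality rule, concordance table and Fisher p follow the definitions", {
  cohort <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:4),
    group = "IPD",
    right_motor_score = c(10, 5, 3, 8),
    left_motor_score = c(7, 4, 9, 8))
  cr <- tibble::tibble(
    subject_id = cohort$subject_id, group = "IPD",
    right_n1 = c(0.20, 0.18, 0.10, 0.15),
    left_n1 = c(0.10, 0.17, 0.20, 0.16))
  lat <- laterality_concordance(cohort, cr)
  t1 <- tidy(lat)
  expect_equal(t1$dominant_side, c("right", "indeterminate", "left",
                                   "indeterminate"))
  expect_equal(t1$higher_cr_side, c("right", "right", "left", "left"))
  expect_equal(t1$concordant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lat$n_determinate, 2)
  expect_equal(sum(lat$table), 2)
  # all indeterminate -> error
  cohort$right_motor_score <- cohort$left_motor_score
  expect_error(laterality_concordance(cohort, cr), "indeterminate")
})

test_that("Fisher exact p equals hypergeometric enumeration on random tables", {
  set.seed(77)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 fisher_enumeration_p(tab), tolerance = 1e-9)
  }
  tab <- matrix(c(8, 1, 2, 9), 2, 2)
  expect_equal(stats::fisher.test(tab)$p.value, fisher_enumeration_p(tab),
               tolerance = 1e-12)
})
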