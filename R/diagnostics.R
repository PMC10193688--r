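# Statistical evaluation of the contrast-ratio biomarkers: normality-gated
# group comparisons with Bonferroni correction, ROC/AUC with DeLong CIs and
# paired comparisons, leave-one-out cross-validated operating points, and
# clinical-laterality concordance.

# Mann-Whitney U of x over y with ties counted 1/2, via midranks.
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Two-sided Mann-Whitney test: exact enumeration of the permutation
# distribution of U (ties included) when both groups have <= `exact_max`
# subjects, otherwise normal approximation with tie correction and
# continuity correction. The two-sided p is the symmetric tail
# P(|U - n1*n2/2| >= |u_obs - n1*n2/2|), which for tie-free data equals the
# classical doubled single tail.
mw_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- mann_whitney_u(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    r <- rank(c(x, y))
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

#' Group comparison of contrast ratios with a normality gate
#'
#' Per region: Shapiro-Wilk on each group at alpha 0.05; if both groups are
#' compatible with normality a two-sided Welch t-test is used, otherwise a
#' two-sided Mann-Whitney U test (exact enumeration up to 8 per group,
#' tie-corrected normal approximation beyond). P-values are
#' Bonferroni-adjusted over the regions compared. Group summaries are
#' mean +/- SD when the t-test was used and median (IQR) otherwise,
#' matching the reporting convention.
#'
#' @param cr_table an `nm_cr_table` (needs `group` plus the region columns).
#' @param regions region columns to compare (default all eight).
#' @return tibble: region, test, statistic, p_raw, p_adjusted, summary_ipd,
#'   summary_hc.
#' @export
compare_groups <- function(cr_table, regions = cr_regions()) {
  ipd <- cr_table[cr_table$group == "IPD", , drop = FALSE]
  hc <- cr_table[cr_table$group == "HC", , drop = FALSE]
  if (nrow(ipd) < 3 || nrow(hc) < 3)
    stop("need at least 3 subjects per group", call. = FALSE)
  m <- length(regions)
  rows <- purrr::map(regions, function(rg) {
    x <- ipd[[rg]]; y <- hc[[rg]]
    if (length(unique(x)) == 1 && length(unique(y)) == 1)
      stop(sprintf("region %s: constant values in both groups", rg),
           call. = FALSE)
    shap_p <- function(v) {
      if (length(unique(v)) == 1) return(0)  # constant: not normal
      stats::shapiro.test(v)$p.value
    }
    normal <- shap_p(x) > 0.05 && shap_p(y) > 0.05
    if (normal) {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      stat <- unname(ht$statistic)
      p <- ht$p.value
      test <- "t-test"
      fmt <- function(v) sprintf("%.6f ± %.6f", mean(v),
                                 stats::sd(v))
    } else {
      ht <- mw_test(x, y)
      stat <- ht$statistic
      p <- ht$p_value
      test <- "Mann-Whitney"
      fmt <- function(v) {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.6f (%.6f–%.6f)", q[2], q[1], q[3])
      }
    }
    tibble::tibble(region = rg, test = test, statistic = stat, p_raw = p,
                   p_adjusted = min(1, m * p),
                   summary_ipd = fmt(x), summary_hc = fmt(y))
  })
  dplyr::bind_rows(rows)
}

# DeLong placement values for one marker. Disease-positive = IPD with the
# fixed "lower CR = disease" direction, so AUC = P(CR_HC > CR_IPD) + ties/2.
delong_placements <- function(cr_ipd, cr_hc) {
  v10 <- vapply(cr_hc, function(h)
    mean((h > cr_ipd) + 0.5 * (h == cr_ipd)), numeric(1))
  v01 <- vapply(cr_ipd, function(d)
    mean((cr_hc > d) + 0.5 * (cr_hc == d)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v01))
}

# Youden-optimal cut for the rule "IPD if CR <= c"; ties in J broken toward
# higher specificity (the smaller cut).
youden_threshold <- function(cr_ipd, cr_hc) {
  v <- sort(unique(c(cr_ipd, cr_hc)))
  cuts <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  sens <- vapply(cuts, function(c) mean(cr_ipd <= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(cr_hc > c), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  k <- best[1]  # smallest cut among maximizers = highest specificity
  list(threshold = cuts[k], sensitivity = sens[k], specificity = spec[k],
       youden = j[k])
}

#' ROC analysis of one contrast-ratio region
#'
#' AUC for the fixed rule "lower CR means disease", computed by the
#' rank/Mann-Whitney method with ties counted one half; DeLong 95%
#' confidence interval (Wald on the AUC scale, clipped to `[0, 1]`); and
#' the Youden-optimal operating point with ties broken toward higher
#' specificity.
#'
#' @param cr_table an `nm_cr_table`.
#' @param region one region column name.
#' @return object of class `nm_roc` with fields `region`, `auc`, `ci`
#'   (length 2), `var_auc`, `threshold`, `sensitivity`, `specificity`,
#'   `youden`, `curve` (tibble of fpr/tpr/threshold), `scores`, `labels`,
#'   `degenerate`.
#' @export
roc_analysis <- function(cr_table, region) {
  x <- cr_table[[region]][cr_table$group == "IPD"]
  y <- cr_table[[region]][cr_table$group == "HC"]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  degenerate <- length(unique(c(x, y))) == 1
  if (degenerate)
    warning(sprintf("region %s: all values identical; AUC = 0.5", region),
            call. = FALSE)
  pl <- delong_placements(x, y)
  auc <- pl$auc
  var_auc <- if (length(pl$v10) > 1 && length(pl$v01) > 1)
    stats::var(pl$v10) / length(pl$v10) +
      stats::var(pl$v01) / length(pl$v01)
  else NA_real_
  half <- 1.959963984540054 * sqrt(max(var_auc, 0))
  ci <- c(max(0, auc - half), min(1, auc + half))
  op <- youden_threshold(x, y)
  cuts <- sort(unique(c(-Inf, c(x, y), Inf)))
  curve <- tibble::tibble(
    threshold = cuts,
    tpr = vapply(cuts, function(c) mean(x <= c), numeric(1)),
    fpr = vapply(cuts, function(c) mean(y <= c), numeric(1)))
  structure(list(region = region, auc = auc, ci = ci, var_auc = var_auc,
                 threshold = op$threshold, sensitivity = op$sensitivity,
                 specificity = op$specificity, youden = op$youden,
                 curve = curve, scores = c(x, y),
                 labels = rep(c("IPD", "HC"), c(length(x), length(y))),
                 direction = "lower CR = disease",
                 degenerate = degenerate),
            class = "nm_roc")
}

#' @export
print.nm_roc <- function(x, ...) {
  cat(sprintf(
    "<nm_roc> %s: AUC %.3f (95%% CI %.3f-%.3f), sens %.1f%%, spec %.1f%% at CR <= %.4f\n",
    x$region, x$auc, x$ci[1], x$ci[2], 100 * x$sensitivity,
    100 * x$specificity, x$threshold))
  invisible(x)
}

#' Pairwise DeLong comparison of region AUCs
#'
#' Paired DeLong test of the AUC difference for every pair of regions
#' (same subjects scored on each region), Bonferroni-adjusted over the
#' number of pairs.
#'
#' @param cr_table an `nm_cr_table`.
#' @param regions region columns to compare (>= 2).
#' @return list of class `nm_roc_comparison`: `p_matrix` (symmetric matrix
#'   of adjusted p), `pairs` tibble (region_a, region_b, auc_a, auc_b, z,
#'   p_raw, p_adjusted), `aucs`.
#' @export
compare_rocs <- function(cr_table, regions = cr_regions()) {
  if (length(regions) < 2) stop("need >= 2 regions", call. = FALSE)
  if (anyNA(cr_table[regions]))
    stop("paired comparison requires all regions scored on all subjects",
         call. = FALSE)
  pls <- lapply(regions, function(rg)
    delong_placements(cr_table[[rg]][cr_table$group == "IPD"],
                      cr_table[[rg]][cr_table$group == "HC"]))
  names(pls) <- regions
  aucs <- vapply(pls, `[[`, numeric(1), "auc")
  nh <- length(pls[[1]]$v10); nd <- length(pls[[1]]$v01)
  pairs <- utils::combn(regions, 2)
  m <- ncol(pairs)
  rows <- purrr::map(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    va <- pls[[a]]; vb <- pls[[b]]
    var_diff <- (stats::var(va$v10) + stats::var(vb$v10) -
                   2 * stats::cov(va$v10, vb$v10)) / nh +
      (stats::var(va$v01) + stats::var(vb$v01) -
         2 * stats::cov(va$v01, vb$v01)) / nd
    d <- va$auc - vb$auc
    if (var_diff <= 1e-16) {
      z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
    } else {
      z <- d / sqrt(var_diff)
    }
    p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
    tibble::tibble(region_a = a, region_b = b, auc_a = va$auc,
                   auc_b = vb$auc, z = z, p_raw = p,
                   p_adjusted = min(1, m * p))
  })
  tab <- dplyr::bind_rows(rows)
  pm <- matrix(NA_real_, length(regions), length(regions),
               dimnames = list(regions, regions))
  diag(pm) <- 1
  for (k in seq_len(m)) {
    pm[pairs[1, k], pairs[2, k]] <- tab$p_adjusted[k]
    pm[pairs[2, k], pairs[1, k]] <- tab$p_adjusted[k]
  }
  structure(list(p_matrix = pm, pairs = tab, aucs = aucs),
            class = "nm_roc_comparison")
}

#' @export
print.nm_roc_comparison <- function(x, ...) {
  cat("<nm_roc_comparison> Bonferroni-adjusted paired DeLong p-values\n")
  print(round(x$p_matrix, 4))
  invisible(x)
}

#' Leave-one-out cross-validated operating point
#'
#' For each held-out subject the Youden threshold is refit on the remaining
#' subjects and applied to the held-out CR; cross-validated sensitivity and
#' specificity are pooled over the held-out classifications. The
#' cross-validated AUC is computed from the pooled held-out scores; since
#' CR scores are not refit per fold, this equals the apparent AUC and is
#' reported for completeness with a note.
#'
#' @param cr_table an `nm_cr_table`.
#' @param region one region column name.
#' @return tibble row of class `nm_loocv`: region, cv_auc, cv_sensitivity,
#'   cv_specificity, n_folds, note.
#' @export
loocv <- function(cr_table, region) {
  grp <- cr_table$group
  if (sum(grp == "IPD") < 2 || sum(grp == "HC") < 2)
    stop("need >= 2 subjects per group", call. = FALSE)
  val <- cr_table[[region]]
  n <- length(val)
  pred_ipd <- logical(n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    xr <- val[-i][grp[-i] == "IPD"]
    yr <- val[-i][grp[-i] == "HC"]
    if (!length(xr) || !length(yr)) {
      skipped[i] <- TRUE
      warning("fold with an empty group skipped", call. = FALSE)
      next
    }
    thr <- youden_threshold(xr, yr)$threshold
    pred_ipd[i] <- val[i] <= thr
  }
  use <- !skipped
  cv_sens <- mean(pred_ipd[use & grp == "IPD"])
  cv_spec <- mean(!pred_ipd[use & grp == "HC"])
  cv_auc <- delong_placements(val[grp == "IPD"], val[grp == "HC"])$auc
  out <- tibble::tibble(
    region = region, cv_auc = cv_auc, cv_sensitivity = cv_sens,
    cv_specificity = cv_spec, n_folds = sum(use),
    note = "cv_auc equals apparent AUC: scores are unchanged by holding out")
  class(out) <- c("nm_loocv", class(out))
  out
}

#' Clinical laterality vs contrast-ratio laterality
#'
#' A patient's dominant symptom side is the side whose per-side motor score
#' exceeds the other by at least two points (otherwise indeterminate).
#' Because nigral degeneration is contralateral to motor symptoms, the
#' dominant side is expected to coincide with the side of the *higher* N1
#' CR. Association is tested with Fisher's exact test on the 2x2 table of
#' dominant side by higher-CR side, indeterminate subjects excluded.
#'
#' @param cohort tibble with `subject_id`, `group`, `right_motor_score`,
#'   `left_motor_score`.
#' @param cr_table an `nm_cr_table` with `right_n1` / `left_n1`.
#' @return list of class `nm_laterality`: `subjects` tibble (per-IPD
#'   subject: dominant_side, higher_cr_side, concordant), `table` (2x2),
#'   `fisher_p`, `n_concordant`, `n_determinate`.
#' @export
laterality_concordance <- function(cohort, cr_table) {
  ipd <- dplyr::inner_join(
    cohort[cohort$group == "IPD",
           c("subject_id", "right_motor_score", "left_motor_score")],
    cr_table[cr_table$group == "IPD",
             c("subject_id", "right_n1", "left_n1")],
    by = "subject_id")
  if (!nrow(ipd)) stop("no IPD subjects", call. = FALSE)
  dom <- with(ipd, dplyr::case_when(
    right_motor_score - left_motor_score >= 2 ~ "right",
    left_motor_score - right_motor_score >= 2 ~ "left",
    TRUE ~ "indeterminate"))
  hi <- with(ipd, dplyr::case_when(
    right_n1 > left_n1 ~ "right",
    left_n1 > right_n1 ~ "left",
    TRUE ~ "indeterminate"))
  subjects <- tibble::tibble(subject_id = ipd$subject_id,
                             dominant_side = dom, higher_cr_side = hi,
                             concordant = dom != "indeterminate" &
                               hi != "indeterminate" & dom == hi)
  det <- dom != "indeterminate" & hi != "indeterminate"
  if (!any(det))
    stop("all subjects indeterminate: laterality test undefined",
         call. = FALSE)
  tab <- table(factor(dom[det], levels = c("right", "left")),
               factor(hi[det], levels = c("right", "left")),
               dnn = c("dominant_side", "higher_cr_side"))
  fisher_p <- stats::fisher.test(tab)$p.value
  structure(list(subjects = subjects, table = tab, fisher_p = fisher_p,
                 n_concordant = sum(subjects$concordant),
                 n_determinate = sum(det)),
            class = "nm_laterality")
}

#' @export
print.nm_laterality <- function(x, ...) {
  cat(sprintf(
    "<nm_laterality> %d/%d determinate patients concordant; Fisher exact p = %.4g\n",
    x$n_concordant, x$n_determinate, x$fisher_p))
  print(x$table)
  invisible(x)
}
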