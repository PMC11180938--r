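pc_test <- function(label, n, estimate, se = NA_real_, statistic = NA_real_,
                    p = NA_real_, method, normality_p = NA_real_,
                    degenerate = FALSE, extra = list()) {
  structure(c(list(label = label, n = n, estimate = estimate, se = se,
                   statistic = statistic, p = p, p_adjusted = NA_real_,
                   method = method, normality_p = normality_p,
                   degenerate = degenerate), extra), class = "pc_test")
}

#' @export
print.pc_test <- function(x, ...) {
  cat(sprintf("%s [%s]: n=%d estimate=%.4g se=%.4g stat=%.4g p=%.4g%s\n",
              x$label, x$method, x$n, x$estimate, x$se, x$statistic, x$p,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' One-sample test of ratios against unity
#'
#' Tests whether connected/unconnected ratios differ from 1. Normality is
#' gated by a Shapiro-Wilk test at `alpha_normality`: normal samples get a
#' one-sample t test against 1, non-normal samples a Wilcoxon signed-rank
#' test against 1 (the one-sample analogue of the rank-based alternative).
#' All p-values are two-tailed.
#'
#' @param ratios numeric vector, n >= 3; NAs dropped.
#' @param mu null value (default 1).
#' @param alpha_normality Shapiro-Wilk gate (default 0.05).
#' @param label estimand label carried into the result.
#' @return a `pc_test` (fields `estimate` = mean ratio, `se`, `statistic`,
#'   `p`, `method`, `normality_p`, `degenerate`).
#' @export
one_sample_vs_unity <- function(ratios, mu = 1, alpha_normality = 0.05,
                                label = "ratio vs 1") {
  x <- ratios[!is.na(ratios)]
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing ratios")
  if (sd(x) == 0) {
    return(pc_test(label, n, mean(x), se = 0,
                   p = if (mean(x) == mu) 1 else NA_real_,
                   method = "degenerate", degenerate = TRUE))
  }
  sw <- shapiro.test(x)
  if (sw$p.value >= alpha_normality) {
    tt <- t.test(x, mu = mu)
    pc_test(label, n, mean(x), se = sd(x) / sqrt(n),
            statistic = unname(tt$statistic), p = tt$p.value,
            method = "t", normality_p = sw$p.value)
  } else {
    wt <- wilcox.test(x, mu = mu, exact = FALSE, correct = TRUE)
    pc_test(label, n, mean(x), se = sd(x) / sqrt(n),
            statistic = unname(wt$statistic), p = wt$p.value,
            method = "wilcoxon", normality_p = sw$p.value)
  }
}

#' Three-group comparison of ratios
#'
#' Omnibus comparison of ratios across diagnostic groups (AD / MCI / CN):
#' one-way ANOVA when the model residuals pass the Shapiro-Wilk gate,
#' Kruskal-Wallis otherwise. Pairwise contrasts are reported as mean
#' difference with a Welch standard error and an uncorrected two-tailed
#' Welch p-value.
#'
#' @param ratios numeric vector.
#' @param groups factor or character, same length.
#' @param alpha_normality Shapiro-Wilk gate on ANOVA residuals.
#' @param label estimand label.
#' @return list with `omnibus` (a `pc_test`) and `pairwise` (data.frame:
#'   `contrast`, `mean_diff`, `se`, `p`).
#' @export
group_compare <- function(ratios, groups, alpha_normality = 0.05,
                          label = "group comparison") {
  keep <- !is.na(ratios) & !is.na(groups)
  x <- ratios[keep]
  gv <- groups[keep]
  # keep the clinical AD / MCI / CN ordering when it applies
  lv <- if (all(unique(as.character(gv)) %in% c("AD", "MCI", "CN")))
    intersect(c("AD", "MCI", "CN"), unique(as.character(gv)))
  else sort(unique(as.character(gv)))
  g <- droplevels(factor(gv, levels = lv))
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "))
    keep2 <- !(g %in% small)
    x <- x[keep2]; g <- droplevels(g[keep2])
  }
  if (nlevels(g) < 2) stop("need at least 2 groups with n >= 2")
  fit <- aov(x ~ g)
  res <- stats::residuals(fit)
  sw <- tryCatch(shapiro.test(res), error = function(e) list(p.value = NA_real_))
  norm_ok <- is.na(sw$p.value) || sw$p.value >= alpha_normality
  if (norm_ok) {
    an <- summary(fit)[[1]]
    omnibus <- pc_test(label, length(x), estimate = NA_real_,
                       statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                       method = "anova", normality_p = sw$p.value)
  } else {
    kw <- kruskal.test(x, g)
    omnibus <- pc_test(label, length(x), estimate = NA_real_,
                       statistic = unname(kw$statistic), p = kw$p.value,
                       method = "kruskal", normality_p = sw$p.value)
  }
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    xa <- x[g == pr[1]]; xb <- x[g == pr[2]]
    md <- mean(xa) - mean(xb)
    se <- sqrt(stats::var(xa) / length(xa) + stats::var(xb) / length(xb))
    p <- if (se > 0) t.test(xa, xb)$p.value else if (md == 0) 1 else NA_real_
    data.frame(contrast = paste(pr[1], "-", pr[2]), mean_diff = md,
               se = se, p = p)
  }))
  list(omnibus = omnibus, pairwise = pw)
}

#' Covariate-adjusted regression of cognition on a ratio
#'
#' Ordinary least squares of a cognitive score on a connected/unconnected
#' ratio, adjusted for age, years of education and WMH volume. Returns the
#' ratio coefficient with its SE and two-tailed p-value. An optional subset
#' restricts the fit (e.g. to the MCI group).
#'
#' @param data data.frame containing the variables.
#' @param score,ratio,age,education,wmh_volume column names.
#' @param subset optional logical vector to restrict rows.
#' @param label estimand label.
#' @return a `pc_test`; `estimate` is the ratio coefficient. Collinear
#'   designs are flagged degenerate with no coefficient.
#' @export
adjusted_regression <- function(data, score = "score", ratio = "ratio",
                                age = "age", education = "education",
                                wmh_volume = "wmh_volume_ml", subset = NULL,
                                label = "score ~ ratio (adjusted)") {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  vars <- c(score, ratio, age, education, wmh_volume)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[vars]), vars]
  n <- nrow(data)
  if (n <= 5) stop("need more observations than predictors + 1")
  f <- stats::reformulate(c(ratio, age, education, wmh_volume), response = score)
  fit <- lm(f, data = data)
  cf <- coef(fit)
  if (any(is.na(cf)) || any(!is.finite(cf))) {
    return(pc_test(label, n, NA_real_, method = "regression",
                   degenerate = TRUE))
  }
  sm <- summary(fit)$coefficients
  if (!ratio %in% rownames(sm) || any(is.nan(sm[, "Std. Error"]))) {
    return(pc_test(label, n, NA_real_, method = "regression",
                   degenerate = TRUE))
  }
  pc_test(label, n, estimate = sm[ratio, "Estimate"],
          se = sm[ratio, "Std. Error"], statistic = sm[ratio, "t value"],
          p = sm[ratio, "Pr(>|t|)"], method = "regression",
          extra = list(fit = fit))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are sorted ascending and
#' `p_adj(i) = min over j >= i of (m/j) * p(j)`, capped at 1, returned in the
#' input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Baseline-anchored standardization of longitudinal measures
#'
#' Standardizes a measure using its baseline mean and SD:
#' `z_baseline = (x - mean_b) / sd_b` and
#' `z_month12 = (x12 - mean_b) / sd_b`. The baseline column of the result
#' therefore has mean 0 and SD 1 by construction, and follow-up values are
#' expressed on the baseline scale.
#'
#' @param baseline,month12 numeric vectors, paired by position.
#' @return data.frame with `z_baseline` and `z_month12`.
#' @export
standardize_longitudinal <- function(baseline, month12) {
  stopifnot(length(baseline) == length(month12))
  if (length(baseline) < 2) stop("need at least 2 subjects")
  mb <- mean(baseline); sb <- sd(baseline)
  if (sb == 0) stop("baseline SD is zero; cannot standardize")
  data.frame(z_baseline = (baseline - mb) / sb,
             z_month12 = (month12 - mb) / sb)
}

#' Assemble paired standardized longitudinal records
#'
#' Applies [standardize_longitudinal()] to the ratio and the MMSE of a
#' paired two-timepoint sample and returns one record per subject.
#'
#' @param ratio_baseline,ratio_month12,mmse_baseline,mmse_month12 numeric
#'   vectors, paired by position.
#' @param subject optional subject ids.
#' @return data.frame with standardized ratio and MMSE at both timepoints.
#' @export
longitudinal_records <- function(ratio_baseline, ratio_month12,
                                 mmse_baseline, mmse_month12,
                                 subject = NULL) {
  zr <- standardize_longitudinal(ratio_baseline, ratio_month12)
  zm <- standardize_longitudinal(mmse_baseline, mmse_month12)
  if (is.null(subject)) subject <- sprintf("sub-%03d", seq_len(nrow(zr)))
  data.frame(subject = subject,
             z_ratio_baseline = zr$z_baseline, z_ratio_month12 = zr$z_month12,
             z_mmse_baseline = zm$z_baseline, z_mmse_month12 = zm$z_month12)
}

#' Paired two-timepoint change test
#'
#' With exactly two timepoints, a repeated-measures ANOVA on time reduces to
#' the paired t test (F = t^2); the change between month 12 and baseline is
#' tested against zero. Unpaired subjects (NA at either timepoint) are
#' dropped with a warning.
#'
#' @param baseline,month12 numeric vectors paired by position, n >= 3 pairs.
#' @param label estimand label.
#' @return a `pc_test`; `estimate` is the mean change (month12 - baseline),
#'   `statistic` the paired t, and `extra$F` its square.
#' @export
paired_change_test <- function(baseline, month12, label = "12-month change") {
  ok <- !is.na(baseline) & !is.na(month12)
  if (any(!ok)) warning("dropping ", sum(!ok), " unpaired subject(s)")
  d <- month12[ok] - baseline[ok]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(d) == 0) {
    return(pc_test(label, n, mean(d), se = 0,
                   p = if (mean(d) == 0) 1 else NA_real_,
                   method = "degenerate", degenerate = TRUE))
  }
  tt <- t.test(d, mu = 0)
  pc_test(label, n, mean(d), se = sd(d) / sqrt(n),
          statistic = unname(tt$statistic), p = tt$p.value,
          method = "paired", extra = list(F = unname(tt$statistic)^2))
}

#' Compare the rate of decline of the ratio versus cognition
#'
#' With two timepoints and complete pairs, the measure-by-time interaction of
#' a random-intercept mixed model equals a paired contrast on the per-subject
#' standardized changes: `d_i = delta z_ratio_i - delta z_mmse_i` tested
#' against 0. Negative mean `d` means the ratio declines faster than MMSE.
#'
#' @param records data.frame from [longitudinal_records()].
#' @param label estimand label.
#' @return a `pc_test`; `estimate` is the mean difference of standardized
#'   changes.
#' @export
slope_comparison <- function(records, label = "ratio vs MMSE slope") {
  d <- (records$z_ratio_month12 - records$z_ratio_baseline) -
    (records$z_mmse_month12 - records$z_mmse_baseline)
  paired_change_test(rep(0, length(d)), d, label = label)
}

#' Cohort-level statistics over a ratio table
#'
#' Runs the cross-sectional analyses over a tidy ratio table: per (parcel,
#' level, metric) family a one-sample test of the averaged ratio against 1,
#' BH-corrected within each analysis x level family, and optionally group
#' comparisons when a subject table with diagnosis is supplied.
#'
#' @param ratio_table data.frame with columns `subject`, `parcel`, `level`,
#'   `metric`, `average` (one row per subject x parcel x level x metric).
#' @param subjects optional subject table with `subject` and `group`.
#' @param bh_family how to group p-values for BH correction: `"analysis_level"`
#'   (default; one family per analysis and connectivity level) or `"all"`.
#' @return list with data.frames `one_sample` and (if groups given)
#'   `group_omnibus`, `group_pairwise`.
#' @export
cohort_stats <- function(ratio_table, subjects = NULL,
                         bh_family = c("analysis_level", "all")) {
  bh_family <- match.arg(bh_family)
  keys <- unique(ratio_table[c("parcel", "level", "metric")])
  one <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    rows <- merge(ratio_table, k)
    x <- rows$average[!is.na(rows$average)]
    if (length(x) < 3) return(NULL)
    tst <- one_sample_vs_unity(x, label = paste(k$parcel, k$level, k$metric))
    data.frame(parcel = k$parcel, level = k$level, metric = k$metric,
               n = tst$n, estimate = tst$estimate, se = tst$se,
               statistic = tst$statistic, p = tst$p, method = tst$method,
               normality_p = tst$normality_p)
  }))
  if (!is.null(one)) {
    fam <- if (bh_family == "all") rep(1, nrow(one)) else one$level
    one$p_adjusted <- stats::ave(one$p, fam, FUN = bh_adjust)
  }
  out <- list(one_sample = one)
  if (!is.null(subjects)) {
    merged <- merge(ratio_table, subjects[c("subject", "group")], by = "subject")
    go <- list(); gp <- list()
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      rows <- merge(merged, k)
      if (sum(!is.na(rows$average)) < 6) next
      gc <- group_compare(rows$average, rows$group,
                          label = paste(k$parcel, k$level, k$metric))
      go[[length(go) + 1]] <- data.frame(
        parcel = k$parcel, level = k$level, metric = k$metric,
        statistic = gc$omnibus$statistic, p = gc$omnibus$p,
        method = gc$omnibus$method)
      gp[[length(gp) + 1]] <- cbind(
        data.frame(parcel = k$parcel, level = k$level, metric = k$metric),
        gc$pairwise)
    }
    out$group_omnibus <- if (length(go)) do.call(rbind, go) else NULL
    out$group_pairwise <- if (length(gp)) do.call(rbind, gp) else NULL
  }
  out
}
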