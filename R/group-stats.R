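# Group-level aggregation and comparisons: mean +/- SEM with n, two-tailed
# Student's t-test / one-way ANOVA, percent differences.  No multiple-testing
# correction is applied (noted in the output metadata).

#' Two-group comparison p-value
#'
#' Two-tailed equal-variance Student's t-test (default, as named) or one-way
#' ANOVA; for two groups the ANOVA p equals the t-test p (F = t^2).  Welch's
#' correction is available by flag.
#'
#' @param values_a,values_b Numeric samples.
#' @param method `"ttest"` or `"anova"`.
#' @param welch Use Welch's unequal-variance t-test.
#' @return Two-tailed p-value.
#' @export
compare_groups <- function(values_a, values_b, method = c("ttest", "anova"),
                           welch = FALSE) {
  method <- match.arg(method)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    fsi_error("need n >= 2 per group", "not_evaluable")
  if (sd(c(values_a, values_b)) == 0) return(1.0)  # identical constant data
  if (method == "ttest") {
    t.test(values_a, values_b, var.equal = !welch)$p.value
  } else {
    df <- data.frame(y = c(values_a, values_b),
                     g = factor(rep(c("a", "b"),
                                    c(length(values_a), length(values_b)))))
    summary(aov(y ~ g, data = df))[[1]][["Pr(>F)"]][1]
  }
}

#' Percent difference of a test mean from a reference mean
#'
#' `100 * (mean_test - mean_ref) / mean_ref`, reported to one decimal.
#'
#' @param mean_ref Reference (e.g. vehicle) mean; must be non-zero.
#' @param mean_test Test (e.g. mk801) mean.
#' @return Percent difference, rounded to one decimal.
#' @export
percent_difference <- function(mean_ref, mean_test) {
  if (!is_scalar_number(mean_ref) || mean_ref == 0)
    fsi_error("percent difference undefined for a zero reference mean",
              "undefined_reference")
  round(100 * (mean_test - mean_ref) / mean_ref, 1)
}

#' Summarize a feature table into a two-group comparison table
#'
#' One row per feature: per-group mean, SEM (SD/sqrt(n)) and n, t-test and
#' ANOVA p-values, and the percent difference of the test group from the
#' reference group.  Cells missing a feature are excluded per-feature, with
#' counts reflected in n.  Single-cell groups have undefined SEM (NA) and
#' are flagged.
#'
#' @param features Feature table: data frame with columns `cell_id`,
#'   `group_label`, `feature`, `value` (and optionally `units`).
#' @param ref_group,test_group Group labels; all rows must belong to one of
#'   them.
#' @return Data frame of class `fsi_group_table`, with attribute
#'   `multiple_testing = "none"`.
#' @export
summarize_groups <- function(features, ref_group = "vehicle",
                             test_group = "mk801") {
  bad <- setdiff(unique(features$group_label), c(ref_group, test_group))
  if (length(bad))
    fsi_error(paste0("unknown group label(s): ", paste(bad, collapse = ", ")),
              "unknown_group")
  feats <- sort(unique(features$feature))
  rows <- lapply(feats, function(f) {
    sub <- features[features$feature == f & is.finite(features$value), ]
    a <- sub$value[sub$group_label == ref_group]
    b <- sub$value[sub$group_label == test_group]
    sem <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
    p_t <- tryCatch(compare_groups(a, b, "ttest"),
                    fsiephys_not_evaluable = function(e) NA_real_)
    p_f <- tryCatch(compare_groups(a, b, "anova"),
                    fsiephys_not_evaluable = function(e) NA_real_)
    units <- if ("units" %in% names(sub) && nrow(sub)) sub$units[1] else ""
    data.frame(
      feature = f, units = units,
      mean_vehicle = mean(a), sem_vehicle = sem(a), n_vehicle = length(a),
      mean_mk801 = mean(b), sem_mk801 = sem(b), n_mk801 = length(b),
      p_ttest = p_t, p_anova = p_f,
      pct_difference = if (length(a) && length(b) && mean(a) != 0)
        percent_difference(mean(a), mean(b)) else NA_real_,
      sem_flagged = length(a) < 2 || length(b) < 2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "multiple_testing") <- "none"
  attr(out, "groups") <- c(ref = ref_group, test = test_group)
  class(out) <- c("fsi_group_table", "data.frame")
  out
}
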