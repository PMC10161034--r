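#' Single-pass 3-sigma outlier exclusion
#'
#' Within each group, records whose value deviates by more than three standard
#' deviations from the group are excluded.  Mean and SD for each candidate are
#' computed leave-one-out (excluding the candidate itself): with the candidate
#' included, the largest attainable z-score in a group of n is
#' `(n - 1) / sqrt(n)`, so small groups could never shed even a gross outlier.
#' All candidates are screened against the original data in a single pass (no
#' iteration after removal).  Groups with fewer than 3 records are returned
#' untouched with a warning.
#'
#' @param records A `data.frame`.
#' @param group_cols Columns defining groups (default `"compartment"`).
#' @param value_col Column screened for outliers (default `"accuracy"`).
#' @return A list with `kept` and `excluded` data frames.
#' @export
exclude_outliers_3sigma <- function(records, group_cols = "compartment",
                                    value_col = "accuracy") {
  if (!value_col %in% names(records))
    stop_adipo("column `%s` not found", value_col)
  key <- if (length(group_cols))
    interaction(records[group_cols], drop = TRUE) else factor(rep(1, nrow(records)))
  drop <- logical(nrow(records))
  for (g in levels(key)) {
    i <- which(key == g)
    if (length(i) < 3L) {
      warning(sprintf("group '%s' has < 3 records; no exclusion applied", g))
      next
    }
    x <- records[[value_col]][i]
    drop[i] <- vapply(seq_along(x), function(j)
      abs(x[j] - mean(x[-j])) > 3 * stats::sd(x[-j]), logical(1))
  }
  list(kept = records[!drop, , drop = FALSE],
       excluded = records[drop, , drop = FALSE])
}

#' Confounder screens: truncation and acquisition-interval effects
#'
#' `truncation_effect_test()` runs, per compartment, a two-sided Mann-Whitney
#' U test of measurement accuracy between FOV-truncated and non-truncated
#' records.  `interval_effect_test()` does the same between records with
#' `days_between < cutoff_days` and `>= cutoff_days` (default 15 days,
#' operationalising "two weeks").
#'
#' @param records Accuracy-record table (see [accuracy_record()]).
#' @param alpha Significance level recorded alongside the result.
#' @return A list per compartment, each with the `mwu_result`, group sizes and
#'   group means.
#' @export
truncation_effect_test <- function(records, alpha = 0.05) {
  stratum_test(records, records$truncated,
               c("truncated", "not_truncated"), alpha)
}

#' @rdname truncation_effect_test
#' @param cutoff_days Interval cutoff in days.
#' @export
interval_effect_test <- function(records, cutoff_days = 15, alpha = 0.05) {
  stratum_test(records, abs(records$days_between) < cutoff_days,
               c("short_interval", "long_interval"), alpha)
}

stratum_test <- function(records, in_a, labels, alpha) {
  out <- list()
  for (comp in sort(unique(records$compartment))) {
    sel <- records$compartment == comp
    a <- records$accuracy[sel & in_a]
    b <- records$accuracy[sel & !in_a]
    if (length(a) == 0L || length(b) == 0L)
      stop_adipo("empty stratum '%s' for compartment %s",
                 labels[if (length(a) == 0L) 1 else 2], comp)
    res <- mann_whitney_u(a, b, sidedness = "two")
    out[[comp]] <- list(
      test = res, compartment = comp, alpha = alpha,
      significant = res$p_value < alpha,
      groups = stats::setNames(
        list(list(n = length(a), mean = mean(a), sd = stats::sd(a)),
             list(n = length(b), mean = mean(b), sd = stats::sd(b))),
        labels))
  }
  out
}

#' Derive the acceptable accuracy for a compartment
#'
#' The acceptable accuracy is the mean accuracy attainable under unavoidable
#' positioning differences, estimated from manual (ground-truth vs
#' ground-truth) records.  Subset rules:
#'
#' * `"short_interval"` - only records with `days_between < cutoff_days`
#'   (used when body-shape drift over longer gaps contaminates accuracy);
#' * `"all_excl_outliers"` - all records after 3-sigma outlier exclusion;
#' * `"auto"` - runs [interval_effect_test()] for the compartment and picks
#'   `"short_interval"` when the interval effect is significant, otherwise
#'   `"all_excl_outliers"`;
#' * `"fixed"` - bypass derivation and use `fixed_value` (e.g. the reference
#'   values 94.5% for SAT and 85.2% for VAT).
#'
#' @param records Accuracy-record table (manual comparisons).
#' @param compartment `"SAT"` or `"VAT"`.
#' @param rule Subset rule, see Details.
#' @param fixed_value Threshold used when `rule = "fixed"`.
#' @param cutoff_days Interval cutoff in days.
#' @param alpha Significance level for the `"auto"` rule.
#' @return An object of class `acceptable_accuracy` with fields `compartment`,
#'   `value` (percent), `rule`, `n`, `excluded` (outlier rows) and
#'   `reference_sample` (the qualifying accuracies; empty for `"fixed"`).
#' @export
derive_acceptable_accuracy <- function(records, compartment,
                                       rule = c("auto", "short_interval",
                                                "all_excl_outliers", "fixed"),
                                       fixed_value = NULL, cutoff_days = 15,
                                       alpha = 0.05) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    check_scalar_number(fixed_value, "fixed_value")
    return(structure(list(compartment = compartment, value = fixed_value,
                          rule = "fixed", n = NA_integer_,
                          excluded = NULL, reference_sample = numeric(0)),
                     class = "acceptable_accuracy"))
  }
  recs <- records[records$compartment == compartment, , drop = FALSE]
  if (nrow(recs) == 0L) stop_adipo("no records for compartment %s", compartment)
  if (rule == "auto") {
    # an empty stratum (all scans short- or long-interval) cannot show an
    # interval effect; fall back to the all-days rule
    it <- tryCatch(interval_effect_test(recs, cutoff_days, alpha)[[compartment]],
                   adipoCT_error = function(e) NULL)
    rule <- if (!is.null(it) && it$significant) "short_interval"
            else "all_excl_outliers"
  }
  excluded <- NULL
  if (rule == "short_interval") {
    sub <- recs[abs(recs$days_between) < cutoff_days, , drop = FALSE]
  } else {
    scr <- exclude_outliers_3sigma(recs)
    sub <- scr$kept
    excluded <- scr$excluded
  }
  if (nrow(sub) == 0L) stop_adipo("qualifying subset is empty")
  structure(list(compartment = compartment, value = mean(sub$accuracy),
                 rule = rule, n = nrow(sub), excluded = excluded,
                 reference_sample = sub$accuracy),
            class = "acceptable_accuracy")
}

#' @export
print.acceptable_accuracy <- function(x, ...) {
  cat(sprintf("Acceptable accuracy [%s]: %.1f%% (rule %s, n = %s)\n",
              x$compartment, x$value, x$rule, x$n))
  invisible(x)
}

#' Dose-binned acceptability tests
#'
#' Splits records into half-open SSDE_5.25 bins `[low, high)` and, per bin,
#' runs a one-sided Mann-Whitney U test of the inferiority alternative "bin
#' accuracy is stochastically lower than the reference accuracy sample".  A
#' large p-value therefore supports acceptability of the bin.  Bins with fewer
#' than `small_n_min` records are flagged; empty bins are skipped with a
#' message.
#'
#' @param records Accuracy-record table for one compartment with an
#'   `ssde_5_25` column.
#' @param reference Numeric vector: the reference accuracy sample (the
#'   qualifying subset behind the acceptable accuracy).
#' @param bin_edges Increasing bin edges in mGy; default
#'   `c(0.35, 0.40, 0.45, 0.50, Inf)`.
#' @param alpha Significance level.
#' @param small_n_min Minimum unflagged bin size.
#' @return A `data.frame` of class `dose_bin_results` with one row per
#'   non-empty bin: `bin_low`, `bin_high`, `n`, `mean`, `sd`, `p_value`,
#'   `small_n`.
#' @export
dose_bin_tests <- function(records, reference,
                           bin_edges = c(0.35, 0.40, 0.45, 0.50, Inf),
                           alpha = 0.05, small_n_min = 6L) {
  if (length(reference) == 0L) stop_adipo("reference sample is empty")
  if (is.unsorted(bin_edges, strictly = TRUE) || length(bin_edges) < 2L)
    stop_adipo("`bin_edges` must be strictly increasing with >= 2 edges")
  rows <- list()
  for (i in seq_len(length(bin_edges) - 1L)) {
    lo <- bin_edges[i]; hi <- bin_edges[i + 1L]
    x <- records$accuracy[records$ssde_5_25 >= lo & records$ssde_5_25 < hi]
    if (length(x) == 0L) {
      message(sprintf("dose bin [%g, %g) is empty; skipped", lo, hi))
      next
    }
    res <- mann_whitney_u(x, reference, sidedness = "one_less")
    rows[[length(rows) + 1L]] <- data.frame(
      bin_low = lo, bin_high = hi, n = length(x),
      mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
      p_value = res$p_value, small_n = length(x) < small_n_min)
  }
  out <- do.call(rbind, rows) %||% data.frame()
  attr(out, "alpha") <- alpha
  class(out) <- c("dose_bin_results", "data.frame")
  out
}

#' Determine the lower dose limit from binned tests
#'
#' The limit is the lowest dose `d` (a bin lower edge) such that every bin at
#' or above `d` has `p >= alpha` (no detectable inferiority to the reference)
#' and at least one of those bins is not small-n flagged (a flagged bin never
#' qualifies alone).  If no fine bin qualifies, the lowest passing fallback
#' level (e.g. coarse-thickness data pooled at/above a dose) is used.  If
#' nothing passes, the limit is `NA` with rationale "no limit within tested
#' range".
#'
#' @param bin_results A [dose_bin_tests()] result (bins in increasing order).
#' @param fallback_levels Optional `data.frame` with columns `dose` (mGy) and
#'   `p_value` (and optionally `label`), in increasing dose order.
#' @param alpha Significance level.
#' @return A list of class `dose_limit` with `limit` (mGy or `NA`), `source`
#'   (`"bins"`, `"fallback"` or `"none"`) and a human-readable `rationale`.
#' @export
determine_dose_limit <- function(bin_results, fallback_levels = NULL,
                                 alpha = 0.05) {
  br <- as.data.frame(bin_results)
  if (nrow(br) && is.unsorted(br$bin_low, strictly = TRUE))
    stop_adipo("bins must be ordered by increasing dose")
  limit <- NA_real_; src <- "none"; why <- "no limit within tested range"
  if (nrow(br)) {
    for (i in seq_len(nrow(br))) {
      above <- br[i:nrow(br), , drop = FALSE]
      if (all(above$p_value >= alpha) && any(!above$small_n)) {
        limit <- br$bin_low[i]; src <- "bins"
        why <- sprintf(
          "all %d bin(s) at/above %g mGy show no inferiority at alpha = %g",
          nrow(above), limit, alpha)
        break
      }
    }
  }
  if (is.na(limit) && !is.null(fallback_levels) && nrow(fallback_levels)) {
    ok <- which(fallback_levels$p_value >= alpha)
    if (length(ok)) {
      i <- ok[which.min(fallback_levels$dose[ok])]
      limit <- fallback_levels$dose[i]; src <- "fallback"
      why <- sprintf(
        "no fine bin qualifies; fallback level %s at %g mGy passes (p = %.3g)",
        fallback_levels$label[i] %||% i, limit, fallback_levels$p_value[i])
    }
  }
  structure(list(limit = limit, source = src, rationale = why, alpha = alpha),
            class = "dose_limit")
}

#' @export
print.dose_limit <- function(x, ...) {
  cat(sprintf("Lower dose limit: %s mGy [%s]\n  %s\n",
              if (is.na(x$limit)) "not determined" else format(x$limit),
              x$source, x$rationale))
  invisible(x)
}
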