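# Diagnostic accuracy against the manual-review reference standard:
# patient-level 2x2 confusion table, sensitivity / specificity / PPV / NPV /
# prevalence, and binomial proportion confidence intervals.
#
# The default interval is the Wilson score interval WITH continuity
# correction at z = 1.96, the method used by the classic online clinical
# calculators against which rule-based phenotyping studies are typically
# reported; the equal-tailed Clopper-Pearson exact interval is available as
# an alternative.

CI_METHODS <- c("wilson_cc", "clopper_pearson")

#' Build a 2x2 confusion table from calls and gold labels
#'
#' @param calls Tibble of failure calls ([classify_cohort()]).
#' @param gold Per-patient reference labels: either a data frame with
#'   `patient_id` and `gold_label` columns, or a list of [patient_record()]
#'   objects carrying `gold_label`. Patients without a label are dropped
#'   with a warning; duplicated patient ids are an error.
#' @return An object of class `confusion_table` with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(calls, gold) {
  if (is.list(gold) && !is.data.frame(gold)) {
    gold <- dplyr::bind_rows(lapply(gold, function(r) {
      tibble(patient_id = r$patient_id, gold_label = r$gold_label)
    }))
  }
  if (anyDuplicated(gold$patient_id)) {
    data_error("duplicate patient ids in gold labels")
  }
  if (anyDuplicated(calls$patient_id)) {
    data_error("duplicate patient ids in calls")
  }
  lab <- gold$gold_label[match(calls$patient_id, gold$patient_id)]
  drop <- is.na(lab)
  if (any(drop)) {
    warn(sprintf("%d call(s) without a gold label dropped from the 2x2 table",
                 sum(drop)))
  }
  pos <- calls$positive[!drop]
  lab <- lab[!drop]
  new_confusion_table(sum(pos & lab), sum(pos & !lab),
                      sum(!pos & lab), sum(!pos & !lab))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative counts.
#' @export
new_confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0)) {
    data_error("confusion counts must be non-negative")
  }
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

new_proportion_ci <- function(estimate, lower, upper, conf_level, method,
                              successes, trials) {
  structure(
    list(estimate = estimate, lower = max(0, lower), upper = min(1, upper),
         conf_level = conf_level, method = method,
         successes = successes, trials = trials),
    class = "proportion_ci"
  )
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.4f (%g%% CI %.4f-%.4f) [%s, %d/%d]\n",
              x$estimate, 100 * x$conf_level, x$lower, x$upper,
              x$method, x$successes, x$trials))
  invisible(x)
}

check_ci_args <- function(successes, trials, conf_level) {
  if (trials < 1) config_error("trials must be at least 1")
  if (successes < 0 || successes > trials) {
    config_error("successes must lie in [0, trials]")
  }
  if (conf_level <= 0 || conf_level >= 1) {
    config_error("conf_level must lie in (0, 1)")
  }
}

#' Wilson score interval with continuity correction
#'
#' Closed-form binomial proportion interval. At the default `conf_level`
#' 0.95 the critical value is fixed at z = 1.96, matching the convention of
#' clinical calculators; other confidence levels use the corresponding
#' normal quantile. Boundary cases: zero successes pin the lower limit at 0
#' and all-successes pin the upper limit at 1.
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param conf_level Confidence level in (0, 1).
#' @param z Critical value; default 1.96 at `conf_level = 0.95`.
#' @return A `proportion_ci` object.
#' @export
wilson_cc_interval <- function(successes, trials, conf_level = 0.95, z = NULL) {
  check_ci_args(successes, trials, conf_level)
  if (is.null(z)) {
    z <- if (conf_level == 0.95) 1.96 else qnorm(1 - (1 - conf_level) / 2)
  }
  n <- trials
  p <- successes / n
  denom <- 2 * (n + z^2)
  lower <- (2 * n * p + z^2 - 1 -
              z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / denom
  upper <- (2 * n * p + z^2 + 1 +
              z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / denom
  if (successes == 0) lower <- 0
  if (successes == trials) upper <- 1
  new_proportion_ci(p, lower, upper, conf_level, "wilson_cc",
                    successes, trials)
}

#' Clopper-Pearson exact interval
#'
#' Equal-tailed exact binomial interval via the beta-quantile closed form
#' (inversion of the binomial distribution function).
#'
#' @inheritParams wilson_cc_interval
#' @return A `proportion_ci` object.
#' @export
clopper_pearson_interval <- function(successes, trials, conf_level = 0.95) {
  check_ci_args(successes, trials, conf_level)
  alpha <- 1 - conf_level
  lower <- if (successes == 0) 0 else
    qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    qbeta(1 - alpha / 2, successes + 1, trials - successes)
  new_proportion_ci(successes / trials, lower, upper, conf_level,
                    "clopper_pearson", successes, trials)
}

# Integer-percent rendering: round half away from zero (92.857 -> 93).
percent_int <- function(p) {
  x <- p * 100
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Render a proportion as an integer percent string
#'
#' Rounds half away from zero, the convention used throughout the package's
#' human-readable reports (0.9286 -> "93%").
#'
#' @param p A proportion (or vector of proportions) in \[0, 1\].
#' @export
render_percent <- function(p) {
  ifelse(is.na(p), NA_character_, paste0(percent_int(p), "%"))
}

#' Accuracy report for a confusion table
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), each with a confidence interval, and prevalence
#' (TP+FN)/n as a point estimate. A metric whose denominator is zero is
#' reported absent (`NULL`) rather than 0 or an error.
#'
#' @param table A `confusion_table`.
#' @param method `"wilson_cc"` (default) or `"clopper_pearson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `accuracy_report`.
#' @export
accuracy_report <- function(table, method = c("wilson_cc", "clopper_pearson"),
                            conf_level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  method <- match.arg(method)
  n <- table$tp + table$fp + table$fn + table$tn
  if (n == 0) data_error("empty confusion table")
  ci_fun <- switch(method,
                   wilson_cc = wilson_cc_interval,
                   clopper_pearson = clopper_pearson_interval)
  metric <- function(s, t) {
    if (t == 0) NULL else ci_fun(s, t, conf_level = conf_level)
  }
  structure(
    list(
      table = table,
      sensitivity = metric(table$tp, table$tp + table$fn),
      specificity = metric(table$tn, table$tn + table$fp),
      ppv = metric(table$tp, table$tp + table$fp),
      npv = metric(table$tn, table$tn + table$fn),
      prevalence = list(estimate = (table$tp + table$fn) / n),
      method = method, conf_level = conf_level, n = n
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  fmt <- function(ci) {
    if (is.null(ci)) return("--")
    sprintf("%s (%g%% CI, %s-%s)", render_percent(ci$estimate),
            100 * x$conf_level, render_percent(ci$lower),
            render_percent(ci$upper))
  }
  cat(sprintf("Accuracy report (n=%d, %s intervals)\n", x$n, x$method))
  cat(sprintf("  TP=%d FP=%d FN=%d TN=%d\n",
              x$table$tp, x$table$fp, x$table$fn, x$table$tn))
  cat(sprintf("  Sensitivity %s\n", fmt(x$sensitivity)))
  cat(sprintf("  Specificity %s\n", fmt(x$specificity)))
  cat(sprintf("  PPV         %s\n", fmt(x$ppv)))
  cat(sprintf("  NPV         %s\n", fmt(x$npv)))
  cat(sprintf("  Prevalence  %.2f\n", x$prevalence$estimate))
  invisible(x)
}

#' Serialize an accuracy report to JSON
#'
#' Layout: `{counts:{tp,fp,fn,tn}, metrics:{sensitivity:{est,lo,hi}, ...,
#' prevalence:{est}}, method, conf_level}`. Absent metrics are omitted.
#'
#' @param report An `accuracy_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
report_json <- function(report, path = NULL) {
  ci_obj <- function(ci) {
    if (is.null(ci)) return(NULL)
    list(est = ci$estimate, lo = ci$lower, hi = ci$upper)
  }
  metrics <- Filter(Negate(is.null), list(
    sensitivity = ci_obj(report$sensitivity),
    specificity = ci_obj(report$specificity),
    ppv = ci_obj(report$ppv),
    npv = ci_obj(report$npv),
    prevalence = list(est = report$prevalence$estimate)
  ))
  obj <- list(
    counts = list(tp = report$table$tp, fp = report$table$fp,
                  fn = report$table$fn, tn = report$table$tn),
    metrics = metrics,
    method = report$method,
    conf_level = report$conf_level
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
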