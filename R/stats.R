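# Diagnostic accuracy: confusion matrices, the seven accuracy statistics
# with 95% CIs, per-symptom PPVs, and the cohort-description tests.

#' Construct a 2x2 confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return Object of class `pc_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("confusion matrix must have total > 0",
                             call. = FALSE)
  structure(as.list(as.integer(counts)) |>
              stats::setNames(c("tp", "fp", "fn", "tn")),
            class = "pc_confusion")
}

#' @export
print.pc_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("flagged", "not flagged"),
                              c("cancer", "no cancer")))
  print(m)
  invisible(x)
}

#' Tally tool evaluations into a confusion matrix
#'
#' Only eligible evaluations contribute; `tp` = flagged with a cancer
#' outcome inside follow-up, `fp` = flagged without, `fn` = unflagged with,
#' `tn` = the remainder.
#'
#' @param evaluations Data frame from [evaluate_cohort()] (one tool only).
#' @return A [confusion_matrix()].
#' @export
confusion_from_evaluations <- function(evaluations) {
  if (nrow(evaluations) == 0) stop("no evaluations supplied", call. = FALSE)
  if (length(unique(evaluations$tool)) > 1) {
    stop("evaluations mix tools: ",
         paste(unique(evaluations$tool), collapse = ", "), call. = FALSE)
  }
  e <- evaluations[evaluations$eligible, , drop = FALSE]
  if (nrow(e) == 0) stop("no eligible evaluations", call. = FALSE)
  confusion_matrix(tp = sum(e$flagged & e$outcome_cancer_12m),
                   fp = sum(e$flagged & !e$outcome_cancer_12m),
                   fn = sum(!e$flagged & e$outcome_cancer_12m),
                   tn = sum(!e$flagged & !e$outcome_cancer_12m))
}

stat_ci <- function(estimate, ci_low, ci_high, method, note = "") {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 method = method, note = note), class = "pc_stat")
}

#' @export
print.pc_stat <- function(x, ...) {
  if (is.na(x$estimate)) {
    cat(sprintf("undefined (%s)\n", x$note))
  } else {
    cat(sprintf("%.4f (95%% CI %.4f to %.4f; %s)\n", x$estimate, x$ci_low,
                x$ci_high, x$method))
  }
  invisible(x)
}

undefined_stat <- function(method, note) {
  stat_ci(NA_real_, NA_real_, NA_real_, method, note)
}

#' Binomial confidence interval for a proportion
#'
#' Default method is the exact Clopper-Pearson interval from beta
#' quantiles; Wilson score and Wald intervals are available for
#' comparison.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default), `"wilson"` or `"wald"`.
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @export
#' @examples
#' binomial_ci(102, 7432) # ~ (0.0112, 0.0166)
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("clopper-pearson", "wilson", "wald")) {
  method <- match.arg(method)
  stopifnot(n > 0, successes >= 0, successes <= n,
            level > 0, level < 1)
  x <- successes
  alpha <- 1 - level
  p <- x / n
  ci <- switch(method,
    "clopper-pearson" = c(
      if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)),
    "wilson" = {
      z <- stats::qnorm(1 - alpha / 2)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(max(0, centre - half), min(1, centre + half))
    },
    "wald" = {
      z <- stats::qnorm(1 - alpha / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half))
    })
  stats::setNames(ci, c("low", "high"))
}

proportion_stat <- function(x, n, method, level = 0.95) {
  if (is.na(n) || n == 0) {
    return(undefined_stat(method, "zero denominator"))
  }
  ci <- binomial_ci(x, n, level, method)
  stat_ci(x / n, ci[["low"]], ci[["high"]], method)
}

#' Diagnostic accuracy statistics from a confusion matrix
#'
#' `ppv` = tp/(tp+fp), `npv` = tn/(tn+fn), `sensitivity` = tp/(tp+fn),
#' `specificity` = tn/(tn+fp), `accuracy` = (tp+tn)/total, each with a 95%
#' binomial CI (Clopper-Pearson by default). A zero denominator yields an
#' undefined-statistic marker, not an error.
#'
#' @param cm A [confusion_matrix()].
#' @param method CI method passed to [binomial_ci()].
#' @param level Confidence level.
#' @return A `pc_stat` (estimate, ci_low, ci_high, method).
#' @export
ppv <- function(cm, method = "clopper-pearson", level = 0.95) {
  proportion_stat(cm$tp, cm$tp + cm$fp, method, level)
}

#' @rdname ppv
#' @export
npv <- function(cm, method = "clopper-pearson", level = 0.95) {
  proportion_stat(cm$tn, cm$tn + cm$fn, method, level)
}

#' @rdname ppv
#' @export
sensitivity <- function(cm, method = "clopper-pearson", level = 0.95) {
  proportion_stat(cm$tp, cm$tp + cm$fn, method, level)
}

#' @rdname ppv
#' @export
specificity <- function(cm, method = "clopper-pearson", level = 0.95) {
  proportion_stat(cm$tn, cm$tn + cm$fp, method, level)
}

#' @rdname ppv
#' @export
accuracy <- function(cm, method = "clopper-pearson", level = 0.95) {
  proportion_stat(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn, method,
                  level)
}

#' Positive and negative likelihood ratios with log-method CIs
#'
#' `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`; the CI uses the standard
#' error on the log scale (`SE(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp -
#' 1/(fp+tn))` and analogously for LR-). Division by zero yields an
#' undefined marker.
#'
#' @param cm A [confusion_matrix()].
#' @param level Confidence level (default 0.95).
#' @return List with `lr_plus` and `lr_minus`, each a `pc_stat`.
#' @export
likelihood_ratios <- function(cm, level = 0.95) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (tp + fn == 0 || tn + fp == 0) {
    und <- undefined_stat("log-method", "empty outcome margin")
    return(list(lr_plus = und, lr_minus = und))
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lr_plus <- if (spec >= 1 || tp == 0) {
    undefined_stat("log-method", "specificity = 1 or no true positives")
  } else {
    est <- sens / (1 - spec)
    se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
    stat_ci(est, est * exp(-z * se), est * exp(z * se), "log-method")
  }
  lr_minus <- if (spec <= 0) {
    undefined_stat("log-method", "specificity = 0")
  } else if (sens >= 1) {
    stat_ci(0, 0, 0, "log-method", "perfect sensitivity")
  } else {
    est <- (1 - sens) / spec
    se <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
    stat_ci(est, est * exp(-z * se), est * exp(z * se), "log-method")
  }
  list(lr_plus = lr_plus, lr_minus = lr_minus)
}

#' Likelihood-ratio point estimates from sensitivity and specificity
#'
#' @param sens,spec Proportions in \[0,1\].
#' @return Named vector `c(lr_plus, lr_minus)`.
#' @export
lr_estimates <- function(sens, spec) {
  c(lr_plus = if (spec < 1) sens / (1 - spec) else NA_real_,
    lr_minus = if (spec > 0) (1 - sens) / spec else NA_real_)
}

#' Positive predictive value of a single sign or symptom
#'
#' Treats "at least one event of this code" as the flag, the first such
#' event as the index date, and a C25 diagnosis within the follow-up
#' window as the outcome.
#'
#' @param timelines List of `pc_timeline` from [build_timelines()].
#' @param symptom_code A canonical symptom code.
#' @param config A [cohort_config()].
#' @param method CI method.
#' @return A `pc_stat`; undefined marker when no patient presents with the
#'   code. The number of presenters is attached as attribute `"n"`, the
#'   outcome count as `"tp"`.
#' @export
per_symptom_ppv <- function(timelines, symptom_code,
                            config = cohort_config(),
                            method = "clopper-pearson") {
  assert_canonical_codes(symptom_code)
  hits <- 0L
  n <- 0L
  for (tl in timelines) {
    d <- tl$events$event_date[tl$events$symptom_code == symptom_code]
    if (length(d) == 0) next
    n <- n + 1L
    if (!is.null(tl$diagnosis)) {
      lag <- as.numeric(tl$diagnosis$date - min(d))
      if (lag >= 0 && lag <= config$followup_window_days) hits <- hits + 1L
    }
  }
  out <- if (n == 0) undefined_stat(method, "no presenters") else
    proportion_stat(hits, n, method)
  attr(out, "n") <- n
  attr(out, "tp") <- hits
  out
}

#' Compare presence proportions between two groups (Pearson chi-square)
#'
#' Builds the 2x2 presence table and applies Pearson's chi-square without
#' continuity correction (configurable), mirroring the usual
#' cohort-description comparison.
#'
#' @param a_present,b_present Logical vectors (presence per patient in
#'   group a / b), or `a_present` may be a 2x2 count matrix with
#'   `b_present` missing.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List `statistic`, `p_value`, `df`; `NA`s with a note for
#'   degenerate tables.
#' @export
compare_proportions <- function(a_present, b_present = NULL,
                                correct = FALSE) {
  tab <- if (is.matrix(a_present)) a_present else {
    stopifnot(length(a_present) > 0, length(b_present) > 0)
    rbind(a = c(yes = sum(a_present), no = sum(!a_present)),
          b = c(yes = sum(b_present), no = sum(!b_present)))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_integer_,
                note = "degenerate table"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), note = "")
}

#' Compare two continuous samples (Mann-Whitney U)
#'
#' Tie-corrected normal approximation of the two-sided Mann-Whitney /
#' Wilcoxon rank-sum test.
#'
#' @param a_values,b_values Non-empty numeric vectors.
#' @return List `statistic` (U for the first sample), `p_value`.
#' @export
compare_distributions <- function(a_values, b_values) {
  stopifnot(length(a_values) > 0, length(b_values) > 0)
  ht <- suppressWarnings(stats::wilcox.test(a_values, b_values,
                                            exact = FALSE, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
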