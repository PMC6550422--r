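# Diagnostic validity statistics: confusion matrices, sensitivity and
# specificity with Wald (default) or Wilson 95% intervals, the positive
# likelihood ratio with the Simel log-method interval, and two-center
# comparisons (Fisher exact or chi-square).

#' Confusion matrix
#'
#' @param tp,fp,fn,tn non-negative cell counts: true positives (gold CEPSB
#'   flagged by the algorithm), false positives, false negatives, true
#'   negatives.
#' @return a `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Cross-tabulate algorithm verdicts against the gold standard
#'
#' @param predictions named logical vector of algorithm verdicts (names =
#'   stay ids), e.g. from [apply_algorithm()].
#' @param gold_labels named logical vector of gold-standard CEPSB labels
#'   over the same stay ids.
#' @return a [confusion_matrix()].
#' @export
confusion <- function(predictions, gold_labels) {
  if (is.null(names(predictions)) || is.null(names(gold_labels))) {
    stop("predictions and gold_labels must be named by stay_id",
         call. = FALSE)
  }
  diff1 <- setdiff(names(predictions), names(gold_labels))
  diff2 <- setdiff(names(gold_labels), names(predictions))
  if (length(diff1) || length(diff2)) {
    stop("stay id mismatch; only in predictions: ",
         paste(diff1, collapse = ", "), "; only in gold: ",
         paste(diff2, collapse = ", "), call. = FALSE)
  }
  gold_labels <- gold_labels[names(predictions)]
  confusion_matrix(tp = sum(predictions & gold_labels),
                   fp = sum(predictions & !gold_labels),
                   fn = sum(!predictions & gold_labels),
                   tn = sum(!predictions & !gold_labels))
}

proportion_ci <- function(x, n, method = c("wald", "wilson"), conf = 0.95) {
  method <- match.arg(method)
  if (n == 0L) stop("undefined proportion: denominator is zero",
                    call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lower <- p - half
    upper <- p + half
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lower <- centre - half
    upper <- centre + half
  }
  list(estimate = p, lower = max(0, lower), upper = min(1, upper))
}

#' Sensitivity, specificity and positive likelihood ratio with 95% CIs
#'
#' `sensitivity_ci()` and `specificity_ci()` return the proportion with a
#' Wald normal-approximation interval clipped to `[0, 1]` (Wilson interval
#' behind `method = "wilson"`). `positive_lr_ci()` returns LR+ =
#' sensitivity / (1 - specificity) with the Simel log-method interval
#' `exp(log(LR) +/- 1.96 * sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)))`.
#' With no false positives the LR+ is infinite; a Haldane-corrected finite
#' estimate (0.5 added to every cell) is reported alongside and the result
#' flagged. With no true positives the LR+ is 0 and its CI undefined.
#'
#' @param cm a [confusion_matrix()].
#' @param method `"wald"` (default) or `"wilson"`.
#' @return list with `estimate`, `lower`, `upper` (and for the LR+ a
#'   `degenerate` flag plus `haldane` estimate when `fp = 0`).
#' @export
sensitivity_ci <- function(cm, method = c("wald", "wilson")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  proportion_ci(cm$tp, cm$tp + cm$fn, method)
}

#' @rdname sensitivity_ci
#' @export
specificity_ci <- function(cm, method = c("wald", "wilson")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  proportion_ci(cm$tn, cm$tn + cm$fp, method)
}

#' @rdname sensitivity_ci
#' @export
positive_lr_ci <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (fp + tn == 0L) stop("no gold negatives: LR+ undefined", call. = FALSE)
  se <- tp / (tp + fn)
  one_minus_sp <- fp / (fp + tn)
  if (tp == 0L) {
    return(list(estimate = 0, lower = NA_real_, upper = NA_real_,
                degenerate = TRUE))
  }
  if (fp == 0L) {
    hal <- ((tp + 0.5) / (tp + fn + 1)) / ((fp + 0.5) / (fp + tn + 1))
    return(list(estimate = Inf, lower = NA_real_, upper = NA_real_,
                haldane = hal, degenerate = TRUE))
  }
  lr <- se / one_minus_sp
  z <- stats::qnorm(0.975)
  se_log <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  list(estimate = lr, lower = exp(log(lr) - z * se_log),
       upper = exp(log(lr) + z * se_log), degenerate = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: the p-value is the sum of the probabilities of
#' all tables with the observed margins whose hypergeometric probability
#' does not exceed that of the observed table (with the usual relative
#' tolerance for ties). This is the convention of the reference
#' implementations for 2x2 tables.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n1 <- a + b
  n2 <- c + d
  k <- a + c
  support <- max(0L, k - n2):min(k, n1)
  probs <- stats::dhyper(support, n1, n2, k)
  p_obs <- stats::dhyper(a, n1, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# chi-square expected cell counts for a 2x2 table
expected_cells_2x2 <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Compare a validity metric between two centers
#'
#' Builds the success/failure 2x2 table of the chosen metric across the two
#' centers (for sensitivity: detected vs missed CEPSB cases; for
#' specificity: correctly cleared vs falsely flagged non-cases) and tests
#' homogeneity with the Fisher exact test when any expected cell count is
#' below 5, otherwise with the chi-square test without continuity
#' correction. Two-sided.
#'
#' @param cm_a,cm_b per-center [confusion_matrix()] objects.
#' @param metric `"sensitivity"` or `"specificity"`.
#' @param test `"auto"` (the expected-cell rule above), or force
#'   `"fisher"` / `"chi2"`.
#' @return list with `p_value`, `test` (`"fisher"` or `"chi2"`) and the
#'   underlying `table`.
#' @export
compare_centers <- function(cm_a, cm_b,
                            metric = c("sensitivity", "specificity"),
                            test = c("auto", "fisher", "chi2")) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  stopifnot(inherits(cm_a, "confusion_matrix"),
            inherits(cm_b, "confusion_matrix"))
  tab <- if (metric == "sensitivity") {
    rbind(A = c(success = cm_a$tp, failure = cm_a$fn),
          B = c(success = cm_b$tp, failure = cm_b$fn))
  } else {
    rbind(A = c(success = cm_a$tn, failure = cm_a$fp),
          B = c(success = cm_b$tn, failure = cm_b$fp))
  }
  if (any(rowSums(tab) == 0L)) {
    stop("degenerate center table for metric ", metric, call. = FALSE)
  }
  if (test == "auto") {
    test <- if (any(expected_cells_2x2(tab) < 5)) "fisher" else "chi2"
  }
  if (test == "fisher") {
    p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  }
  list(p_value = p, test = test, table = tab)
}

#' Full validity report for an algorithm on a cohort
#'
#' Applies the algorithm to the analyzable stays, cross-tabulates against
#' the gold standard and reports sensitivity, specificity and LR+ with 95%
#' confidence intervals plus the number of positive tests (tp + fp).
#'
#' @param cohort a `cepsb_cohort`.
#' @param algorithm a `detection_algorithm`.
#' @param method proportion CI method, `"wald"` or `"wilson"`.
#' @return a `validity_report` list with elements `algorithm`,
#'   `confusion`, `n_positive_tests`, `sensitivity`, `specificity`,
#'   `lr_plus`, `n_excluded`.
#' @export
validity_report <- function(cohort, algorithm, method = "wald") {
  pred <- apply_algorithm(algorithm, cohort)
  gold <- classify_gold(analyzable(cohort))
  names(gold) <- analyzable(cohort)$stay_id
  cm <- confusion(pred, gold)
  report_from_confusion(cm, name = algorithm$name, method = method,
                        n_excluded = length(attr(pred, "excluded")))
}

#' @rdname validity_report
#' @param cm a [confusion_matrix()].
#' @param name algorithm label for the report row.
#' @param n_excluded number of stays excluded for missing records.
#' @export
report_from_confusion <- function(cm, name = "algorithm", method = "wald",
                                  n_excluded = 0L) {
  structure(list(algorithm = name, confusion = cm,
                 n_positive_tests = cm$tp + cm$fp,
                 sensitivity = sensitivity_ci(cm, method),
                 specificity = specificity_ci(cm, method),
                 lr_plus = positive_lr_ci(cm),
                 n_excluded = as.integer(n_excluded)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  fmt <- function(ci, scale = 100) {
    sprintf("%s [%s-%s]", format_half_up(ci$estimate * scale, 1),
            format_half_up(ci$lower * scale, 1),
            format_half_up(ci$upper * scale, 1))
  }
  cat(sprintf("<validity_report> %s\n", x$algorithm))
  cat(sprintf("  positive tests: %d   (tp=%d fp=%d fn=%d tn=%d)\n",
              x$n_positive_tests, x$confusion$tp, x$confusion$fp,
              x$confusion$fn, x$confusion$tn))
  cat(sprintf("  sensitivity %%: %s\n", fmt(x$sensitivity)))
  cat(sprintf("  specificity %%: %s\n", fmt(x$specificity)))
  lr <- x$lr_plus
  if (isTRUE(lr$degenerate)) {
    cat(sprintf("  LR+: %s (degenerate%s)\n", format(lr$estimate),
                if (!is.null(lr$haldane))
                  paste0("; Haldane ", format_half_up(lr$haldane, 1))
                else ""))
  } else {
    cat(sprintf("  LR+: %s [%s-%s]\n", format_half_up(lr$estimate, 1),
                format_half_up(lr$lower, 1), format_half_up(lr$upper, 1)))
  }
  invisible(x)
}

#' Round and format half-up
#'
#' Display rounding used in reports: ties round away from zero (half-up),
#' matching the convention of the printed tables this package reproduces
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `round_half_up()`: numeric; `format_half_up()`: character with
#'   `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @rdname round_half_up
#' @export
format_half_up <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
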