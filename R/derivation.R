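# Data-driven algorithm derivation: screen every code occurring in the
# cohort's discharge records against the gold standard, keep those with a
# statistically significant association and a code-level positive
# likelihood ratio above a threshold, and assemble the kept codes into a
# two-clause algorithm (diagnoses in any position AND procedures).

#' Screen discharge codes against the gold standard
#'
#' For every distinct (code, scope) pair occurring at least `min_count`
#' times among the analyzable stays, builds the 2x2 table of code presence
#' against gold-standard CEPSB status (`a` = present & CEPSB, `b` = present
#' & non-CEPSB, `c` = absent & CEPSB, `d` = absent & non-CEPSB). Diagnosis
#' codes are screened in the any-position scope (main or associated);
#' procedure codes in the procedure scope. Per code it reports the positive
#' likelihood ratio `LR+ = [a/(a+c)] / [b/(b+d)]` — with the
#' Haldane-Anscombe correction (0.5 added to all four cells) when `a = 0`
#' or `b = 0` — and a two-sided association p-value on the uncorrected
#' table (Fisher exact by default; chi-square with Yates correction behind
#' `test = "chi2"`).
#'
#' @param cohort a `cepsb_cohort` with at least one gold-positive and one
#'   gold-negative analyzable stay.
#' @param gold_labels optional named logical vector overriding
#'   [classify_gold()].
#' @param min_count drop codes occurring fewer than this many times.
#' @param test `"fisher"` (default) or `"chi2"`.
#' @return data.frame with columns `code`, `scope`, `a`, `b`, `c`, `d`,
#'   `lr_plus`, `p_value`.
#' @export
screen_codes <- function(cohort, gold_labels = NULL, min_count = 1L,
                         test = c("fisher", "chi2")) {
  test <- match.arg(test)
  cohort <- analyzable(cohort)
  if (is.null(gold_labels)) {
    gold_labels <- classify_gold(cohort)
    names(gold_labels) <- cohort$stay_id
  }
  gold_labels <- gold_labels[cohort$stay_id]
  if (all(gold_labels) || !any(gold_labels)) {
    stop("screening needs both gold-positive and gold-negative stays",
         call. = FALSE)
  }
  n_pos <- sum(gold_labels)
  n_neg <- sum(!gold_labels)

  dx_sets <- mapply(function(m, a) unique(c(if (!is.na(m)) m, a)),
                    cohort$main_dx, cohort$assoc_dx, SIMPLIFY = FALSE)
  proc_sets <- lapply(cohort$procedures, unique)

  tally <- function(sets, scope) {
    all_codes <- unlist(sets, use.names = FALSE)
    if (length(all_codes) == 0L) return(NULL)
    labels <- rep(gold_labels, lengths(sets))
    a <- tapply(labels, all_codes, sum)
    present <- tapply(labels, all_codes, length)
    data.frame(code = names(a), scope = scope,
               a = as.integer(a), b = as.integer(present - a),
               stringsAsFactors = FALSE)
  }
  res <- rbind(tally(dx_sets, "ANY_DX"), tally(proc_sets, "PROCEDURE"))
  if (is.null(res) || nrow(res) == 0L) {
    stop("no codes to screen in this cohort", call. = FALSE)
  }
  res <- res[res$a + res$b >= min_count, , drop = FALSE]
  res$c <- n_pos - res$a
  res$d <- n_neg - res$b

  res$lr_plus <- mapply(code_lr_plus, res$a, res$b, res$c, res$d)
  res$p_value <- mapply(function(a, b, c, d) {
    if (test == "fisher") {
      fisher_exact_2x2(a, b, c, d)
    } else {
      suppressWarnings(
        stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                          correct = TRUE)$p.value)
    }
  }, res$a, res$b, res$c, res$d)
  res <- res[order(-res$lr_plus, res$code), ]
  rownames(res) <- NULL
  res
}

# Code-level LR+ with Haldane-Anscombe 0.5 on all cells when a or b is zero.
code_lr_plus <- function(a, b, c, d) {
  if (a == 0L || b == 0L) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / (a + c)) / (b / (b + d))
}

#' Select screened codes for the derived algorithm
#'
#' A code is kept iff its association p-value is below `alpha` and its
#' LR+ strictly exceeds `lr_threshold`. No multiple-testing correction is
#' applied (the selection rule reproduces a fixed published procedure).
#'
#' @param results data.frame from [screen_codes()].
#' @param alpha significance level (default 0.05).
#' @param lr_threshold LR+ cut-off, strict (default 4).
#' @return list with `dx_codes`, `procedure_codes` (character vectors) and
#'   `results` (the input with a `selected` column added). Warns when a
#'   partition is empty.
#' @export
select_codes <- function(results, alpha = 0.05, lr_threshold = 4) {
  stopifnot(is.data.frame(results),
            all(c("code", "scope", "lr_plus", "p_value") %in% names(results)))
  results$selected <- results$p_value < alpha & results$lr_plus > lr_threshold
  dx <- results$code[results$selected & results$scope == "ANY_DX"]
  proc <- results$code[results$selected & results$scope == "PROCEDURE"]
  if (length(dx) == 0L) warning("no diagnosis codes selected", call. = FALSE)
  if (length(proc) == 0L) warning("no procedure codes selected",
                                  call. = FALSE)
  list(dx_codes = dx, procedure_codes = proc, results = results)
}

#' Assemble the derived two-clause algorithm
#'
#' @param selection result of [select_codes()]; both partitions must be
#'   non-empty.
#' @param admin an [admin_filter()].
#' @param name algorithm label.
#' @return a `detection_algorithm` with one any-position diagnosis clause
#'   and one procedure clause.
#' @export
build_algorithm <- function(selection, admin = admin_filter(),
                            name = "derived") {
  if (length(selection$dx_codes) == 0L ||
      length(selection$procedure_codes) == 0L) {
    stop("cannot build algorithm: empty code partition", call. = FALSE)
  }
  detection_algorithm(
    name = name, admin = admin,
    clauses = list(code_clause("ANY_DX", selection$dx_codes),
                   code_clause("PROCEDURE", selection$procedure_codes))
  )
}

#' Derive an algorithm from a cohort in one step
#'
#' Convenience wrapper: [screen_codes()] then [select_codes()] then
#' [build_algorithm()].
#'
#' @inheritParams screen_codes
#' @inheritParams select_codes
#' @inheritParams build_algorithm
#' @return list with `algorithm` and `screen` (the screening table).
#' @export
derive_algorithm <- function(cohort, alpha = 0.05, lr_threshold = 4,
                             min_count = 1L, admin = admin_filter(),
                             name = "derived", test = "fisher") {
  screen <- screen_codes(cohort, min_count = min_count, test = test)
  sel <- select_codes(screen, alpha = alpha, lr_threshold = lr_threshold)
  list(algorithm = build_algorithm(sel, admin = admin, name = name),
       screen = sel$results)
}
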