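# Coding-error audit: classify false negatives and false positives into the
# error taxonomy by diffing the discharge record against the guideline-ideal
# coding of the gold-standard abstract, then tabulate counts, per-stay
# multiplicities, code-system group shares and per-center comparisons.

ERROR_GROUPS <- c(
  incorrect_principal_dx = "ICD10_MISUSE",
  absent_associated_dx = "ICD10_MISUSE",
  absent_complication_code = "ICD10_MISUSE",
  incorrect_complication_code = "ICD10_MISUSE",
  excess_dx = "ICD10_MISUSE",
  absent_ep_procedure = "CCAM_MISUSE",
  admin_error = "ADMIN",
  uncoded_stay = "UNCODED",
  delivery_code_used = "DELIVERY"
)

#' Code-system group of each error type
#'
#' Fixed mapping of the nine error types into five groups: misuse of ICD-10
#' diagnosis codes, misuse of CCAM procedure codes, administrative-data
#' errors, completely uncoded stays, and use of a delivery code. The two
#' 1-count residual types (uncoded stay, delivery code) are kept outside
#' ICD-10 misuse so the group shares reconcile with instance-level
#' denominators.
#'
#' @param error_type character vector of taxonomy labels.
#' @return character vector of group labels.
#' @export
error_group <- function(error_type) {
  bad <- setdiff(error_type, names(ERROR_GROUPS))
  if (length(bad) > 0L) {
    stop("unknown error type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(ERROR_GROUPS[error_type])
}

#' Classify the coding errors of one misclassified stay
#'
#' Deterministic diff of the stay's discharge record against
#' [ideal_coding()] of its gold abstract, for a stay confirmed as a false
#' negative or false positive of a given algorithm. For a false negative
#' (in taxonomy order): a completely empty record is an uncoded stay; a
#' delivery main diagnosis (O80-O84) is a delivery-code error; a main
#' diagnosis outside the ectopic-pregnancy set is an incorrect principal
#' diagnosis; an empty associated-diagnosis list where codes were expected
#' is an absent associated diagnosis; expected complication codes missing
#' from a non-empty list are an absent (or, when an off-list substitute is
#' present, incorrect) complication code; a missing or
#' non-specifically-substituted EP procedure is an absent EP procedure; an
#' administrative field outside the algorithm's filter is an administrative
#' error. For a false positive, unsupported EP/complication/procedure codes
#' are diagnosis codes used in excess. At most `max_errors` types are
#' reported per stay (taxonomy order), matching the observed maximum
#' multiplicity of two.
#'
#' @param stay one-row `cepsb_cohort`.
#' @param direction `"FN"` or `"FP"`.
#' @param admin the [admin_filter()] of the audited algorithm.
#' @param max_errors per-stay truncation (default 2).
#' @return data.frame with columns `stay_id`, `error_type`, `direction`,
#'   `group` (zero rows when the record matches ideal coding).
#' @export
classify_stay_errors <- function(stay, direction = c("FN", "FP"),
                                 admin = admin_filter(), max_errors = 2L) {
  direction <- match.arg(direction)
  stopifnot(nrow(stay) == 1L)
  main <- stay$main_dx
  assoc <- stay$assoc_dx[[1L]]
  proc <- stay$procedures[[1L]]
  found <- character()

  if (direction == "FN") {
    ideal <- ideal_coding(stay)
    if (is.na(main) && length(assoc) == 0L && length(proc) == 0L) {
      found <- "uncoded_stay"
    } else {
      if (!is.na(main) && grepl("^O8[0-4]", main)) {
        found <- c(found, "delivery_code_used")
      } else if (is.na(main) || !main %in% EP_MAIN_CODES) {
        found <- c(found, "incorrect_principal_dx")
      }
      if (length(assoc) == 0L && length(ideal$assoc) > 0L) {
        found <- c(found, "absent_associated_dx")
      } else {
        expected_comp <- intersect(ideal$assoc, COMPLICATION_CODES)
        present_comp <- intersect(assoc, COMPLICATION_CODES)
        if (length(expected_comp) > 0L && length(present_comp) == 0L) {
          intruder <- length(setdiff(assoc, ideal$assoc)) > 0L
          found <- c(found, if (intruder) "incorrect_complication_code"
                     else "absent_complication_code")
        }
      }
      if (!any(proc %in% EP_PROC_CODES) &&
          any(EP_PROC_CODES %in% ideal$proc)) {
        found <- c(found, "absent_ep_procedure")
      }
      if (!all(admin_pass(admin, stay))) found <- c(found, "admin_error")
    }
  } else {
    ideal <- ideal_coding(stay)
    ideal_dx <- c(if (!is.na(ideal$main)) ideal$main, ideal$assoc)
    stay_dx <- c(if (!is.na(main)) main, assoc)
    unsupported_dx <- setdiff(intersect(stay_dx,
                                        c(EP_MAIN_CODES,
                                          COMPLICATION_CODES)),
                              ideal_dx)
    unsupported_proc <- setdiff(intersect(proc, EP_PROC_CODES), ideal$proc)
    if (length(unsupported_dx) > 0L || length(unsupported_proc) > 0L) {
      found <- "excess_dx"
    }
  }
  found <- found[order(match(found, coding_error_types()))]
  found <- utils::head(found, max_errors)
  if (length(found) == 0L) {
    return(data.frame(stay_id = character(), error_type = character(),
                      direction = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(stay_id = stay$stay_id, error_type = found,
             direction = direction, group = error_group(found),
             stringsAsFactors = FALSE)
}

#' Group shares over error instances
#'
#' @param type_counts named integer vector of per-type error counts (names
#'   from [coding_error_types()]).
#' @return named numeric vector of the five group shares (fractions of
#'   total error instances; they sum to one exactly).
#' @export
group_shares <- function(type_counts) {
  groups <- error_group(names(type_counts))
  total <- sum(type_counts)
  if (total == 0L) {
    return(stats::setNames(rep(0, 5), unique(unname(ERROR_GROUPS))))
  }
  shares <- tapply(as.numeric(type_counts), groups, sum) / total
  out <- stats::setNames(rep(0, 5), unique(unname(ERROR_GROUPS)))
  out[names(shares)] <- shares
  out
}

#' Audit the coding errors behind an algorithm's misclassifications
#'
#' Applies the algorithm, identifies false negatives and false positives
#' against the gold standard, classifies each with
#' [classify_stay_errors()], and tabulates: per-type counts (total and per
#' center, with a two-center comparison p-value per type using the Fisher
#' exact / chi-square rule of [compare_centers()]), per-stay error
#' multiplicities, and group shares over all error instances.
#'
#' @param cohort a `cepsb_cohort`.
#' @param algorithm a `detection_algorithm`.
#' @param max_errors per-stay truncation passed to [classify_stay_errors()].
#' @return a `cepsb_audit` list with `records` (one row per error
#'   instance), `type_table` (per-type totals and per-center counts with
#'   p-values), `multiplicity` (stays with 1 vs 2 errors), `group_shares`,
#'   `n_fn`, `n_fp`.
#' @export
audit <- function(cohort, algorithm, max_errors = 2L) {
  cohort_a <- analyzable(cohort)
  pred <- apply_algorithm(algorithm, cohort_a, check_available = FALSE)
  gold <- classify_gold(cohort_a)
  fn_idx <- which(!pred & gold)
  fp_idx <- which(pred & !gold)

  recs <- list()
  for (i in fn_idx) {
    recs[[length(recs) + 1L]] <-
      classify_stay_errors(cohort_a[i, , drop = FALSE], "FN",
                           admin = algorithm$admin, max_errors = max_errors)
  }
  for (i in fp_idx) {
    recs[[length(recs) + 1L]] <-
      classify_stay_errors(cohort_a[i, , drop = FALSE], "FP",
                           admin = algorithm$admin, max_errors = max_errors)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(stay_id = character(), error_type = character(),
               direction = character(), group = character(),
               stringsAsFactors = FALSE)

  types <- coding_error_types()
  center_of <- stats::setNames(cohort_a$center, cohort_a$stay_id)
  records$center <- unname(center_of[records$stay_id])

  count_by <- function(df) {
    tab <- table(factor(df$error_type, levels = types))
    as.integer(tab)
  }
  misclassified <- unique(c(cohort_a$stay_id[fn_idx],
                            cohort_a$stay_id[fp_idx]))
  mis_center <- table(factor(center_of[misclassified], levels = c("A", "B")))

  type_table <- data.frame(
    error_type = types,
    total = count_by(records),
    center_A = count_by(records[records$center == "A", , drop = FALSE]),
    center_B = count_by(records[records$center == "B", , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  # per-type center comparison: stays of the center's misclassified set
  # with vs without this error type
  type_table$p_value <- vapply(seq_len(nrow(type_table)), function(i) {
    nA <- type_table$center_A[i]; nB <- type_table$center_B[i]
    restA <- as.integer(mis_center[["A"]]) - nA
    restB <- as.integer(mis_center[["B"]]) - nB
    if (nA + nB == 0L || restA < 0L || restB < 0L ||
        (as.integer(mis_center[["A"]]) + as.integer(mis_center[["B"]])) == 0L)
      return(NA_real_)
    tab <- rbind(c(nA, restA), c(nB, restB))
    if (any(expected_cells_2x2(tab) < 5)) {
      fisher_exact_2x2(nA, restA, nB, restB)
    } else {
      stats::chisq.test(tab, correct = FALSE)$p.value
    }
  }, numeric(1))

  per_stay <- table(table(records$stay_id))
  multiplicity <- c(`1` = if ("1" %in% names(per_stay))
    as.integer(per_stay[["1"]]) else 0L,
    `2` = if ("2" %in% names(per_stay)) as.integer(per_stay[["2"]]) else 0L)

  counts <- stats::setNames(type_table$total, type_table$error_type)
  structure(list(records = records[, c("stay_id", "center", "error_type",
                                       "direction", "group")],
                 type_table = type_table,
                 multiplicity = multiplicity,
                 group_shares = group_shares(counts),
                 n_fn = length(fn_idx), n_fp = length(fp_idx)),
            class = "cepsb_audit")
}

#' @export
print.cepsb_audit <- function(x, ...) {
  cat(sprintf("<cepsb_audit> %d FN, %d FP, %d error instance(s)\n",
              x$n_fn, x$n_fp, nrow(x$records)))
  shown <- x$type_table[x$type_table$total > 0, , drop = FALSE]
  if (nrow(shown) > 0L) print(shown, row.names = FALSE)
  sh <- x$group_shares[x$group_shares > 0]
  if (length(sh) > 0L) {
    cat("  group shares: ",
        paste(sprintf("%s %s%%", names(sh), format_half_up(100 * sh, 1)),
              collapse = ", "), "\n")
  }
  invisible(x)
}
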