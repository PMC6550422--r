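# Report rendering: validity and audit tables as data frames, CSV and
# Markdown. Percentages are rounded half-up to one decimal at render time
# only; underlying values keep full precision.

#' Tabulate validity reports
#'
#' One row per algorithm, mirroring the columns of a diagnostic validity
#' table: positive tests, sensitivity [95% CI], specificity [95% CI], LR+
#' [95% CI], false positives, false negatives.
#'
#' @param ... `validity_report` objects (or a single list of them).
#' @param digits display decimals for the formatted columns.
#' @return data.frame with both formatted and full-precision columns.
#' @export
validity_table <- function(..., digits = 1) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "validity_report")) {
    reports <- reports[[1L]]
  }
  rows <- lapply(reports, function(r) {
    stopifnot(inherits(r, "validity_report"))
    fmt_ci <- function(ci, scale) {
      sprintf("%s[%s-%s]", format_half_up(ci$estimate * scale, digits),
              format_half_up(ci$lower * scale, digits),
              format_half_up(ci$upper * scale, digits))
    }
    lr <- r$lr_plus
    lr_fmt <- if (isTRUE(lr$degenerate)) {
      if (is.infinite(lr$estimate))
        sprintf("Inf (Haldane %s)", format_half_up(lr$haldane, digits))
      else "0"
    } else fmt_ci(lr, 1)
    data.frame(
      algorithm = r$algorithm,
      positive_tests = r$n_positive_tests,
      sensitivity = fmt_ci(r$sensitivity, 100),
      specificity = fmt_ci(r$specificity, 100),
      lr_plus = lr_fmt,
      false_positives = r$confusion$fp,
      false_negatives = r$confusion$fn,
      sensitivity_raw = r$sensitivity$estimate,
      specificity_raw = r$specificity$estimate,
      lr_plus_raw = r$lr_plus$estimate,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Render a data.frame as a Markdown table
#'
#' @param df data.frame of character/numeric columns.
#' @return character scalar with the pipe-table text.
#' @export
markdown_table <- function(df) {
  cells <- as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Tabulate an audit
#'
#' @param aud a `cepsb_audit` from [audit()].
#' @param digits display decimals.
#' @return list of two data.frames: `types` (per-type totals, per-center
#'   counts, p-values) and `groups` (share of error instances per
#'   code-system group, in percent).
#' @export
audit_tables <- function(aud, digits = 1) {
  stopifnot(inherits(aud, "cepsb_audit"))
  types <- aud$type_table
  types$p_value <- ifelse(is.na(types$p_value), "",
                          format_half_up(types$p_value, 2))
  groups <- data.frame(
    group = names(aud$group_shares),
    share_pct = format_half_up(100 * aud$group_shares, digits),
    stringsAsFactors = FALSE
  )
  list(types = types, groups = groups)
}
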