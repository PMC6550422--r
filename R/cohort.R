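# Stay-level cohort container and I/O.
#
# A cohort is a data.frame (class "cepsb_cohort") with one row per hospital
# stay, pairing the chart-review abstract (gold standard) with the coded
# discharge record:
#
#   stay_id          opaque unique identifier (character)
#   center           "A" or "B"
#   sex              "F" or "M"
#   age              integer years
#   year             integer
#   unit             admitting unit label (e.g. "gynecology")
#   duration_days    non-negative length of stay
#   main_dx          ICD-10 main diagnosis, NA for an uncoded stay
#   assoc_dx         list-column: character vector of associated ICD-10 codes
#   procedures       list-column: character vector of CCAM procedure codes
#   record_available logical; FALSE = chart missing, stay excluded from analysis
#   ep_histology     ectopic pregnancy confirmed by histology
#   laparoscopy      laparoscopy performed
#   tubal_rupture    tubal wall breach seen at laparoscopy
#   hemoperitoneum_cc aspirated hemoperitoneum volume (cc)
#   active_bleeding  active bleeding observed
#   alternative_dx   final non-CEPSB diagnosis label (see ALTERNATIVE_DX)

COHORT_COLUMNS <- c(
  "stay_id", "center", "sex", "age", "year", "unit", "duration_days",
  "main_dx", "assoc_dx", "procedures", "record_available", "ep_histology",
  "laparoscopy", "tubal_rupture", "hemoperitoneum_cc", "active_bleeding",
  "alternative_dx"
)

ALTERNATIVE_DX <- c("none", "spontaneous_abortion", "ovarian_cyst_rupture",
                    "iup_metrorrhagia", "uncomplicated_ep", "pelvic_infection",
                    "other")

#' Construct a validated stay cohort
#'
#' Validates a data.frame of stay records (see the package vignette for the
#' column schema) and returns it classed as `cepsb_cohort`. Checks code
#' syntax, stay-id uniqueness, and the structural invariants of the record
#' pair: an uncoded stay (missing main diagnosis) carries no associated
#' diagnoses or procedures; the main diagnosis never repeats among the
#' associated diagnoses; histological confirmation requires a positive workup
#' (rupture implies laparoscopy); durations are non-negative.
#'
#' @param df data.frame with the cohort columns; `assoc_dx` and `procedures`
#'   may be ";"-joined strings or list-columns of character vectors.
#' @return a `cepsb_cohort` data.frame.
#' @export
cepsb_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing cohort column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), COHORT_COLUMNS)
  if (length(extra) > 0L) {
    stop("unknown cohort column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  df <- df[COHORT_COLUMNS]
  if (!is.list(df$assoc_dx)) {
    df$assoc_dx <- lapply(as.character(df$assoc_dx), split_codes, "ICD10")
  }
  if (!is.list(df$procedures)) {
    df$procedures <- lapply(as.character(df$procedures), split_codes, "CCAM")
  }
  df$stay_id <- as.character(df$stay_id)
  df$center <- as.character(df$center)
  df$sex <- as.character(df$sex)
  df$unit <- as.character(df$unit)
  df$age <- as.integer(df$age)
  df$year <- as.integer(df$year)
  df$duration_days <- as.numeric(df$duration_days)
  df$main_dx <- as.character(df$main_dx)
  df$main_dx[!is.na(df$main_dx) & !nzchar(df$main_dx)] <- NA_character_
  df$hemoperitoneum_cc <- as.numeric(df$hemoperitoneum_cc)
  for (col in c("record_available", "ep_histology", "laparoscopy",
                "tubal_rupture", "active_bleeding")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df$alternative_dx <- as.character(df$alternative_dx)

  fail_row <- function(cond, msg) {
    if (any(cond)) {
      stop(msg, " (row ", paste(which(cond), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  dup <- duplicated(df$stay_id)
  fail_row(dup, "duplicate stay_id")
  fail_row(!df$sex %in% c("F", "M"), "sex must be 'F' or 'M'")
  fail_row(!df$center %in% c("A", "B"), "center must be 'A' or 'B'")
  fail_row(is.na(df$duration_days) | df$duration_days < 0,
           "duration_days must be >= 0")
  fail_row(!is.na(df$hemoperitoneum_cc) & df$hemoperitoneum_cc < 0,
           "hemoperitoneum_cc must be >= 0")
  fail_row(!df$alternative_dx %in% ALTERNATIVE_DX,
           "unknown alternative_dx label")
  ok_main <- is.na(df$main_dx) | is_valid_code(df$main_dx, "ICD10")
  fail_row(!ok_main, "malformed main_dx ICD-10 code")
  bad_assoc <- !vapply(df$assoc_dx,
                       function(x) all(is_valid_code(x, "ICD10")), logical(1))
  fail_row(bad_assoc, "malformed assoc_dx ICD-10 code")
  bad_proc <- !vapply(df$procedures,
                      function(x) all(is_valid_code(x, "CCAM")), logical(1))
  fail_row(bad_proc, "malformed procedure CCAM code")
  uncoded <- is.na(df$main_dx)
  has_codes <- lengths(df$assoc_dx) > 0L | lengths(df$procedures) > 0L
  fail_row(uncoded & has_codes,
           "uncoded stay (no main_dx) must carry no associated codes")
  main_in_assoc <- as.logical(mapply(function(m, a) !is.na(m) && m %in% a,
                                     df$main_dx, df$assoc_dx))
  fail_row(main_in_assoc, "main_dx repeated among assoc_dx")
  fail_row(df$record_available & df$tubal_rupture & !df$laparoscopy,
           "tubal_rupture requires laparoscopy")

  rownames(df) <- NULL
  class(df) <- c("cepsb_cohort", "data.frame")
  df
}

#' @export
print.cepsb_cohort <- function(x, ...) {
  gold <- classify_gold(x)
  cat(sprintf(
    "<cepsb_cohort> %d stays (%d analyzable, %d gold-positive CEPSB)\n",
    nrow(x), sum(x$record_available), sum(gold, na.rm = TRUE)))
  invisible(x)
}

#' Gold-standard CEPSB classification
#'
#' Applies the chart-review case definition: a complicated ectopic pregnancy
#' with severe bleeding (CEPSB) is an ectopic pregnancy confirmed by
#' histological analysis with at least one of (1) tubal rupture, (2)
#' hemoperitoneum of 500 cc or more (inclusive threshold), or (3) active
#' bleeding. All other clinical situations are non-CEPSB.
#'
#' @param cohort a `cepsb_cohort` (or any data.frame with the gold-standard
#'   columns).
#' @return logical vector, one verdict per stay; `NA` for stays whose medical
#'   record is unavailable (excluded stays, never classified).
#' @export
classify_gold <- function(cohort) {
  verdict <- cohort$ep_histology &
    (cohort$tubal_rupture |
       (!is.na(cohort$hemoperitoneum_cc) & cohort$hemoperitoneum_cc >= 500) |
       cohort$active_bleeding)
  verdict[!cohort$record_available] <- NA
  unname(verdict)
}

# Subset of stays with an available medical record, with a message when any
# are dropped (mirrors the excluded-charts count of a validation study).
analyzable <- function(cohort, quiet = TRUE) {
  dropped <- sum(!cohort$record_available)
  if (dropped > 0L && !quiet) {
    message(dropped, " stay(s) without medical record excluded from analysis")
  }
  out <- cohort[cohort$record_available, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cohort)
  out
}

#' Read and write stay cohorts
#'
#' `read_stays()` reads a cohort from CSV or JSONL (one JSON object per
#' line); `write_stays()` is its inverse. Multi-valued code columns
#' (`assoc_dx`, `procedures`) are ";"-joined in CSV; an empty string means
#' absent. Row order is preserved and a write/read round-trip is the
#' identity on valid cohorts.
#'
#' @param path file path.
#' @param format `"CSV"` or `"JSONL"`; default guessed from the file
#'   extension.
#' @return `read_stays()`: a `cepsb_cohort`.
#' @export
read_stays <- function(path, format = c("auto", "CSV", "JSONL")) {
  format <- guess_format(path, match.arg(format))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "CSV") {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = NULL)
  } else {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    for (col in c("assoc_dx", "procedures")) {
      if (!is.null(df[[col]]) && is.list(df[[col]])) {
        df[[col]] <- vapply(df[[col]],
                            function(x) paste(unlist(x), collapse = ";"),
                            character(1))
      }
    }
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$main_dx[!nzchar(df$main_dx)] <- NA_character_
  cepsb_cohort(df)
}

#' @rdname read_stays
#' @param cohort a `cepsb_cohort`.
#' @export
write_stays <- function(cohort, path, format = c("auto", "CSV", "JSONL")) {
  format <- guess_format(path, match.arg(format))
  flat <- flatten_cohort(cohort)
  if (format == "CSV") {
    utils::write.csv(flat, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    jsonlite::stream_out(flat, con, verbose = FALSE, na = "string")
  }
  invisible(path)
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "JSONL" else "CSV"
}

# One row per stay, list-columns ";"-joined (the on-disk representation).
flatten_cohort <- function(cohort) {
  flat <- as.data.frame(cohort[setdiff(COHORT_COLUMNS,
                                       c("assoc_dx", "procedures"))])
  flat$assoc_dx <- vapply(cohort$assoc_dx, paste, character(1), collapse = ";")
  flat$procedures <- vapply(cohort$procedures, paste, character(1),
                            collapse = ";")
  flat$main_dx[is.na(flat$main_dx)] <- ""
  # full-precision text for doubles so a write/read round-trip is bit-exact
  flat$duration_days <- sprintf("%.17g", flat$duration_days)
  flat$hemoperitoneum_cc <- sprintf("%.17g", flat$hemoperitoneum_cc)
  flat[COHORT_COLUMNS]
}
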