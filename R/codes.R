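# Medical code handling: ICD-10 diagnosis codes and CCAM procedure codes.
#
# Codes are represented as plain normalized character strings (uppercase,
# dot-free); the coding system is carried by context (diagnosis fields hold
# ICD-10, procedure fields hold CCAM). parse_code() is the validating
# constructor; format_icd10() restores the conventional dotted spelling for
# display.

ICD10_REGEX <- "^[A-Z][0-9]{2}[A-Z0-9]?$"
CCAM_REGEX  <- "^[A-Z]{4}[0-9]{3}$"

#' Parse and normalize a medical code
#'
#' Normalizes a diagnosis (ICD-10) or procedure (CCAM) code: upper-cases,
#' strips the optional dot separator of ICD-10 spellings (`"O00.1"` becomes
#' `"O001"`), and validates the syntax of the stated system. ICD-10 codes are
#' one letter, two digits and an optional alphanumeric subcode character;
#' CCAM codes are four letters followed by three digits.
#'
#' @param text character vector of raw code spellings.
#' @param system `"ICD10"` or `"CCAM"`.
#' @return character vector of normalized codes.
#' @examples
#' parse_code("O00.1", "ICD10")   # "O001"
#' parse_code("jjfc001", "CCAM")  # "JJFC001"
#' @export
parse_code <- function(text, system = c("ICD10", "CCAM")) {
  system <- match.arg(system)
  if (length(text) == 0L) return(character())
  if (any(is.na(text) | !nzchar(text))) {
    stop("empty code string for system ", system, call. = FALSE)
  }
  value <- toupper(trimws(text))
  if (system == "ICD10") value <- gsub(".", "", value, fixed = TRUE)
  re <- if (system == "ICD10") ICD10_REGEX else CCAM_REGEX
  bad <- !grepl(re, value)
  if (any(bad)) {
    stop("malformed ", system, " code(s): ",
         paste(sQuote(text[bad]), collapse = ", "), call. = FALSE)
  }
  value
}

#' @rdname parse_code
#' @param value character vector of normalized codes (validated, dot-free).
#' @return `format_icd10()`: the conventional dotted spelling, e.g. `"O00.1"`.
#' @export
format_icd10 <- function(value) {
  ifelse(nchar(value) > 3L,
         paste0(substr(value, 1L, 3L), ".", substring(value, 4L)),
         value)
}

is_valid_code <- function(value, system) {
  re <- if (system == "ICD10") ICD10_REGEX else CCAM_REGEX
  grepl(re, value)
}

# Split a ";"-joined multi-code field into a normalized code vector.
split_codes <- function(text, system) {
  if (is.na(text) || !nzchar(text)) return(character())
  parse_code(strsplit(text, ";", fixed = TRUE)[[1L]], system)
}
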