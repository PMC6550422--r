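# Declarative detection algorithms over coded discharge records.
#
# An algorithm is an administrative filter plus a conjunction of code-set
# clauses; each clause is satisfied when at least one of its codes occurs in
# the scoped field of the record:
#   MAIN_DX   -- the main diagnosis only
#   ASSOC_DX  -- the associated-diagnosis position only
#   ANY_DX    -- main or associated diagnosis
#   PROCEDURE -- the procedure list
#
# Two algorithms ship as built-ins: a guideline-based one requiring an
# ectopic-pregnancy main diagnosis AND a coded complication AND an
# EP-specific procedure, and a practice-based ("pragmatic") one requiring an
# EP-related diagnosis in any position AND a related procedure.

CLAUSE_SCOPES <- c("MAIN_DX", "ASSOC_DX", "ANY_DX", "PROCEDURE")

#' Build a code-set clause
#'
#' @param scope one of `"MAIN_DX"`, `"ASSOC_DX"`, `"ANY_DX"`, `"PROCEDURE"`.
#' @param codes non-empty character vector of codes; ICD-10 for diagnosis
#'   scopes, CCAM for `"PROCEDURE"`. Raw spellings are normalized.
#' @return a `code_clause` list.
#' @export
code_clause <- function(scope, codes) {
  scope <- match.arg(scope, CLAUSE_SCOPES)
  system <- if (scope == "PROCEDURE") "CCAM" else "ICD10"
  codes <- unique(parse_code(codes, system))
  if (length(codes) == 0L) stop("clause needs at least one code", call. = FALSE)
  structure(list(scope = scope, codes = codes), class = "code_clause")
}

#' Build an administrative eligibility filter
#'
#' @param sex required sex code (default `"F"`).
#' @param age_min,age_max inclusive age bounds in years.
#' @param year required discharge year.
#' @param unit required admitting unit label (exact match).
#' @return an `admin_filter` list.
#' @export
admin_filter <- function(sex = "F", age_min = 18L, age_max = 45L,
                         year = 2012L, unit = "gynecology") {
  if (age_min > age_max) stop("age_min > age_max", call. = FALSE)
  structure(list(sex = sex, age_min = as.integer(age_min),
                 age_max = as.integer(age_max), year = as.integer(year),
                 unit = unit),
            class = "admin_filter")
}

#' Assemble a detection algorithm
#'
#' @param name algorithm label used in reports.
#' @param admin an [admin_filter()].
#' @param clauses list of [code_clause()] objects, combined by AND; each
#'   clause is an OR over its codes. At least one clause is required.
#' @return a `detection_algorithm`.
#' @export
detection_algorithm <- function(name, admin, clauses) {
  stopifnot(inherits(admin, "admin_filter"), is.list(clauses))
  if (length(clauses) == 0L) {
    stop("an algorithm needs at least one clause", call. = FALSE)
  }
  ok <- vapply(clauses, inherits, logical(1), "code_clause")
  if (!all(ok)) stop("clauses must be code_clause objects", call. = FALSE)
  structure(list(name = as.character(name), admin = admin,
                 clauses = clauses),
            class = "detection_algorithm")
}

#' @export
print.detection_algorithm <- function(x, ...) {
  cat(sprintf("<detection_algorithm> %s\n", x$name))
  a <- x$admin
  cat(sprintf("  admin: sex=%s, age %d-%d, year %d, unit '%s'\n",
              a$sex, a$age_min, a$age_max, a$year, a$unit))
  for (cl in x$clauses) {
    cat(sprintf("  AND %s in {%s}\n", cl$scope,
                paste(cl$codes, collapse = ", ")))
  }
  invisible(x)
}

#' Built-in detection algorithms
#'
#' `builtin_predefined()` encodes the guideline-based algorithm: female,
#' 18-45 years, 2012, gynecology unit; AND an ectopic-pregnancy main
#' diagnosis (O00.0/O00.1/O00.2/O00.8/O00.9); AND a coded complication among
#' the associated diagnoses (O08.1 haemorrhage, K66.1 hemoperitoneum, Z51.3
#' transfusion, O08.3 shock, O08.6 pelvic-organ damage); AND an EP-specific
#' procedure (JJFA001, JJFC001, JQGA001, JJPC001, JJPA001).
#'
#' `builtin_pragmatic()` encodes the practice-based algorithm: the same
#' administrative filter; AND an EP-related diagnosis in any position
#' (O00.1, O00.8, O00.9, O08.1, O08.3); AND a related procedure (JJFA001,
#' JJFC001, JJPC001, JJJC002, FELF001, FELF004).
#'
#' @param complication_scope scope of the complication clause of the
#'   predefined algorithm. The guideline places complications in the
#'   associated-diagnosis position (the default `"ASSOC_DX"`); `"ANY_DX"`
#'   relaxes the position.
#' @return a `detection_algorithm`.
#' @export
builtin_predefined <- function(complication_scope = c("ASSOC_DX", "ANY_DX")) {
  complication_scope <- match.arg(complication_scope)
  detection_algorithm(
    name = "predefined",
    admin = admin_filter(),
    clauses = list(
      code_clause("MAIN_DX", c("O001", "O000", "O002", "O008", "O009")),
      code_clause(complication_scope,
                  c("O081", "K661", "Z513", "O083", "O086")),
      code_clause("PROCEDURE",
                  c("JJFA001", "JJFC001", "JQGA001", "JJPC001", "JJPA001"))
    )
  )
}

#' @rdname builtin_predefined
#' @export
builtin_pragmatic <- function() {
  detection_algorithm(
    name = "pragmatic",
    admin = admin_filter(),
    clauses = list(
      code_clause("ANY_DX", c("O001", "O008", "O009", "O081", "O083")),
      code_clause("PROCEDURE",
                  c("JJFA001", "JJFC001", "JJPC001", "JJJC002",
                    "FELF001", "FELF004"))
    )
  )
}

# Admin filter pass, vectorized over a cohort data.frame.
admin_pass <- function(admin, cohort) {
  cohort$sex == admin$sex &
    !is.na(cohort$age) & cohort$age >= admin$age_min &
    cohort$age <= admin$age_max &
    cohort$year == admin$year &
    cohort$unit == admin$unit
}

clause_pass_row <- function(clause, main, assoc, proc) {
  field <- switch(clause$scope,
                  MAIN_DX   = if (is.na(main)) character() else main,
                  ASSOC_DX  = assoc,
                  ANY_DX    = c(if (!is.na(main)) main, assoc),
                  PROCEDURE = proc)
  any(clause$codes %in% field)
}

#' Evaluate a detection algorithm on a single stay
#'
#' @param alg a `detection_algorithm`.
#' @param stay a one-row `cepsb_cohort` (or cohort row).
#' @return `TRUE` iff the administrative filter passes and every clause has
#'   at least one matching code in its scope.
#' @export
evaluate <- function(alg, stay) {
  stopifnot(inherits(alg, "detection_algorithm"), nrow(stay) == 1L)
  as.vector(apply_algorithm(alg, stay, check_available = FALSE))
}

#' Apply a detection algorithm to a cohort
#'
#' @param alg a `detection_algorithm`.
#' @param cohort a `cepsb_cohort`.
#' @param check_available when `TRUE` (default) stays without an available
#'   medical record are excluded and reported in the `"excluded"` attribute.
#' @return named logical vector of verdicts (names = `stay_id`).
#' @export
apply_algorithm <- function(alg, cohort, check_available = TRUE) {
  stopifnot(inherits(alg, "detection_algorithm"))
  excluded <- character()
  if (check_available && nrow(cohort) > 0L) {
    excluded <- cohort$stay_id[!cohort$record_available]
    cohort <- analyzable(cohort)
  }
  n <- nrow(cohort)
  if (n == 0L) {
    return(structure(logical(0), names = character(), excluded = excluded))
  }
  verdict <- admin_pass(alg$admin, cohort)
  for (clause in alg$clauses) {
    pass <- mapply(clause_pass_row, list(clause), cohort$main_dx,
                   cohort$assoc_dx, cohort$procedures)
    verdict <- verdict & pass
  }
  structure(as.logical(verdict), names = cohort$stay_id, excluded = excluded)
}

#' Read and write algorithm definition files
#'
#' Algorithms serialize to a small JSON document (name, admin block, clauses
#' as scope + code list). The two built-ins ship as packaged files under
#' `inst/extdata/algorithms/`.
#'
#' @param path JSON file path.
#' @return `read_algorithm()`: a `detection_algorithm`.
#' @export
read_algorithm <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  detection_algorithm(
    name = spec$name,
    admin = admin_filter(sex = spec$admin$sex, age_min = spec$admin$age_min,
                         age_max = spec$admin$age_max, year = spec$admin$year,
                         unit = spec$admin$unit),
    clauses = lapply(seq_len(nrow(spec$clauses)), function(i) {
      code_clause(spec$clauses$scope[i], unlist(spec$clauses$codes[i]))
    })
  )
}

#' @rdname read_algorithm
#' @param alg a `detection_algorithm`.
#' @export
write_algorithm <- function(alg, path) {
  spec <- list(
    name = alg$name,
    admin = unclass(alg$admin),
    clauses = data.frame(
      scope = vapply(alg$clauses, `[[`, character(1), "scope"),
      stringsAsFactors = FALSE
    )
  )
  spec$clauses$codes <- lapply(alg$clauses, `[[`, "codes")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
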