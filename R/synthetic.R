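# Synthetic truth-labelled cohort generation and coding-error injection.
#
# The generator emulates a two-center validation study: fixed per-center stay
# and CEPSB counts (prevalence is configured, not sampled), ages from a
# truncated normal, stay durations from a moment-matched log-normal, and
# discharge records produced by an "ideal coder" that follows the coding
# guidelines exactly. A separate injector then corrupts the records with the
# coding-error taxonomy observed in real discharge data, recording the
# ground truth so downstream audits can be checked against it.

EP_MAIN_CODES <- c("O001", "O000", "O002", "O008", "O009")
COMPLICATION_CODES <- c("O081", "K661", "Z513", "O083", "O086")
EP_PROC_CODES <- c("JJFA001", "JJFC001", "JQGA001", "JJPC001", "JJPA001",
                   "JJJC002")
NONSPECIFIC_SALPINGECTOMY <- "JJFC006"  # total salpingectomy, not EP-specific
TRANSFUSION_PROC <- "FELF004"
WRONG_COMPLICATION_CODE <- "R58"   # haemorrhage NEC: plausible but off-list
NON_EP_GYN_MAIN <- "N938"          # abnormal uterine bleeding, unspecified
DELIVERY_MAIN <- "O800"            # spontaneous vertex delivery
ANAEMIA_CODE <- "D62"              # acute posthaemorrhagic anaemia

#' Coding-error taxonomy
#'
#' The nine coding-error types recognized by the injector and the audit, in
#' their canonical order (the order in which injection draws are made and in
#' which multi-error stays are truncated). The first eight arise on true
#' CEPSB stays and drive false negatives; `excess_dx` arises on non-CEPSB
#' stays and drives false positives.
#'
#' @return character vector of the nine error-type labels.
#' @export
coding_error_types <- function() {
  c("incorrect_principal_dx", "absent_associated_dx",
    "absent_complication_code", "incorrect_complication_code",
    "absent_ep_procedure", "admin_error", "uncoded_stay",
    "delivery_code_used", "excess_dx")
}

#' Cohort generator configuration
#'
#' Defaults reproduce the reference two-center study population: 230 + 140
#' stays, 28 + 24 CEPSB cases, mean age 32.0 (SD 6.6) years truncated to
#' 18-45, mean stay 2.21 (SD 1.7) days, year 2012.
#'
#' @param n_stays_per_center named integer vector `c(A=, B=)` of stays.
#' @param cepsb_per_center named integer vector of gold-positive stays.
#' @param age_mean,age_sd age distribution (years) before truncation.
#' @param duration_mean,duration_sd stay duration moments (days); a
#'   log-normal is moment-matched to these.
#' @param year discharge year stamped on every stay.
#' @param seed RNG seed used by [generate_cohort()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_stays_per_center = c(A = 230L, B = 140L),
                          cepsb_per_center = c(A = 28L, B = 24L),
                          age_mean = 32.0, age_sd = 6.6,
                          duration_mean = 2.21, duration_sd = 1.7,
                          year = 2012L, seed = 20120101L) {
  centers <- c("A", "B")
  n_stays_per_center <- as.integer(n_stays_per_center[centers])
  cepsb_per_center <- as.integer(cepsb_per_center[centers])
  names(n_stays_per_center) <- names(cepsb_per_center) <- centers
  if (any(is.na(n_stays_per_center)) || any(is.na(cepsb_per_center))) {
    stop("per-center counts must be named c(A=, B=)", call. = FALSE)
  }
  if (any(n_stays_per_center < 0L) || any(cepsb_per_center < 0L)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (any(cepsb_per_center > n_stays_per_center)) {
    stop("cepsb_per_center exceeds n_stays_per_center", call. = FALSE)
  }
  stopifnot(age_sd > 0, duration_mean > 0, duration_sd > 0)
  structure(list(n_stays_per_center = n_stays_per_center,
                 cepsb_per_center = cepsb_per_center,
                 age_mean = age_mean, age_sd = age_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 year = as.integer(year), seed = as.integer(seed)),
            class = "cohort_config")
}

# Massive-bleeding stays plausibly transfused; deterministic in the gold
# abstract so the audit can recompute the expectation.
transfusion_indicated <- function(gold) {
  hemo <- gold$hemoperitoneum_cc
  !is.na(hemo) & (hemo >= 1500 |
                    (gold$tubal_rupture & gold$active_bleeding & hemo >= 1000))
}

#' Guideline-perfect coding of a gold-standard abstract
#'
#' Produces the discharge record an ideal coder would write for one stay.
#' For a CEPSB case: an ectopic-pregnancy main diagnosis (tubal O00.1 by
#' default), associated diagnoses carrying one code per observed
#' complication (K66.1 for hemoperitoneum >= 500 cc, O08.1 for active
#' bleeding, O08.6 for tubal rupture, Z51.3 when transfusion is indicated)
#' plus D62 (acute posthaemorrhagic anaemia, present in any severe-bleeding
#' stay), and an EP-specific procedure (plus FELF004 when transfused). For a
#' non-CEPSB stay: codes appropriate to the alternative diagnosis, never the
#' full guideline conjunction.
#'
#' @param gold one-row data.frame (or list) with the gold-standard columns
#'   and `alternative_dx`.
#' @param site site of pregnancy for the main diagnosis of an ectopic case:
#'   `"tubal"`, `"abdominal"`, `"ovarian"`, `"other"`, `"unspecified"`.
#' @param ep_procedure the EP-specific procedure code performed (surgical
#'   CEPSB treatment): JJFA001, JJFC001, JQGA001, JJPC001, JJPA001 or
#'   JJJC002.
#' @return list with elements `main` (character or `NA`), `assoc`, `proc`.
#' @export
ideal_coding <- function(gold, site = "tubal", ep_procedure = "JJFC001") {
  main_by_site <- c(tubal = "O001", abdominal = "O000", ovarian = "O002",
                    other = "O008", unspecified = "O009")
  site <- match.arg(site, names(main_by_site))
  stopifnot(ep_procedure %in% EP_PROC_CODES)
  is_cepsb <- isTRUE(gold$ep_histology &&
                       (gold$tubal_rupture ||
                          (!is.na(gold$hemoperitoneum_cc) &&
                             gold$hemoperitoneum_cc >= 500) ||
                          gold$active_bleeding))
  if (is_cepsb) {
    assoc <- character()
    if (!is.na(gold$hemoperitoneum_cc) && gold$hemoperitoneum_cc >= 500) {
      assoc <- c(assoc, "K661")
    }
    if (isTRUE(gold$active_bleeding)) assoc <- c(assoc, "O081")
    if (isTRUE(gold$tubal_rupture)) assoc <- c(assoc, "O086")
    if (transfusion_indicated(gold)) assoc <- c(assoc, "Z513")
    assoc <- c(assoc, ANAEMIA_CODE)
    proc <- ep_procedure
    if (transfusion_indicated(gold)) proc <- c(proc, TRANSFUSION_PROC)
    return(list(main = unname(main_by_site[site]), assoc = assoc,
                proc = proc))
  }
  alt <- gold$alternative_dx
  if (is.null(alt) || is.na(alt) || alt == "none") alt <- "other"
  switch(alt,
    spontaneous_abortion = list(main = "O034", assoc = character(),
                                proc = "JNJD002"),
    ovarian_cyst_rupture = list(main = "N830", assoc = character(),
                                proc = if (isTRUE(gold$laparoscopy))
                                  "JJNC001" else character()),
    iup_metrorrhagia = list(main = "O200", assoc = character(),
                            proc = character()),
    uncomplicated_ep = list(
      main = unname(main_by_site[site]), assoc = character(),
      proc = if (isTRUE(gold$laparoscopy)) ep_procedure else character()),
    pelvic_infection = list(main = "N709", assoc = character(),
                            proc = character()),
    list(main = "N940", assoc = character(), proc = character())
  )
}

#' Generate a truth-labelled synthetic cohort with error-free coding
#'
#' Deterministic given `cfg$seed`. Per-center stay and CEPSB counts are
#' exact (no sampling noise on prevalence). CEPSB cases are assigned a
#' complication profile (tubal rupture 45%, hemoperitoneum-dominant 30%,
#' active-bleeding-dominant 25%); hemoperitoneum volumes for the
#' hemoperitoneum profile are drawn at or above 500 cc. Discharge records
#' are produced by [ideal_coding()], so the guideline-based algorithm
#' attains sensitivity and specificity 1.0 before error injection.
#'
#' @param cfg a [cohort_config()].
#' @return a `cepsb_cohort` of `sum(cfg$n_stays_per_center)` stays.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  alt_mix <- c(spontaneous_abortion = 0.40, uncomplicated_ep = 0.19,
               ovarian_cyst_rupture = 0.15, iup_metrorrhagia = 0.15,
               pelvic_infection = 0.08, other = 0.03)
  # log-normal moment matching: mean m, sd s  =>  sdlog^2 = log(1+(s/m)^2)
  cv2 <- (cfg$duration_sd / cfg$duration_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(cfg$duration_mean) - sdlog^2 / 2
  p_lo <- stats::pnorm(18, cfg$age_mean, cfg$age_sd)
  p_hi <- stats::pnorm(45, cfg$age_mean, cfg$age_sd)

  rows <- vector("list", sum(cfg$n_stays_per_center))
  k <- 0L
  for (center in c("A", "B")) {
    n <- cfg$n_stays_per_center[[center]]
    n_pos <- cfg$cepsb_per_center[[center]]
    for (i in seq_len(n)) {
      k <- k + 1L
      is_pos <- i <= n_pos
      age <- as.integer(round(stats::qnorm(stats::runif(1, p_lo, p_hi),
                                           cfg$age_mean, cfg$age_sd)))
      duration <- max(0, stats::rlnorm(1, meanlog, sdlog))
      if (is_pos) {
        u <- stats::runif(1)
        if (u < 0.45) {           # rupture profile
          rupture <- TRUE
          hemo <- 300 * exp(stats::rnorm(1, 0, 0.6))
          active <- stats::runif(1) < 0.5
        } else if (u < 0.75) {    # hemoperitoneum profile (>= 500 cc)
          rupture <- FALSE
          hemo <- 500 + stats::rexp(1, rate = 1 / 350)
          active <- stats::runif(1) < 0.3
        } else {                  # active-bleeding profile
          rupture <- FALSE
          hemo <- stats::runif(1, 50, 450)
          active <- TRUE
        }
        ep_proc <- if (rupture) {
          if (stats::runif(1) < 0.7) "JJFC001" else "JJFA001"
        } else {
          if (stats::runif(1) < 0.8) "JJFC001" else "JJPC001"
        }
        gold <- list(ep_histology = TRUE, laparoscopy = TRUE,
                     tubal_rupture = rupture, hemoperitoneum_cc = hemo,
                     active_bleeding = active, alternative_dx = "none")
        hdd <- ideal_coding(gold, ep_procedure = ep_proc)
      } else {
        alt <- names(alt_mix)[findInterval(stats::runif(1),
                                           cumsum(c(0, alt_mix)),
                                           rightmost.closed = TRUE)]
        # surgically managed uncomplicated EPs exist (about a quarter);
        # ruptured cysts reach laparoscopy about half the time
        lap <- switch(alt,
                      uncomplicated_ep = stats::runif(1) < 0.25,
                      ovarian_cyst_rupture = stats::runif(1) < 0.5,
                      {stats::runif(1); FALSE})  # keep draw count fixed
        hemo <- switch(alt,
                       ovarian_cyst_rupture = stats::runif(1, 0, 300),
                       uncomplicated_ep = stats::runif(1, 0, 200),
                       {stats::runif(1); 0})
        gold <- list(ep_histology = alt == "uncomplicated_ep" && lap,
                     laparoscopy = lap, tubal_rupture = FALSE,
                     hemoperitoneum_cc = hemo, active_bleeding = FALSE,
                     alternative_dx = alt)
        hdd <- ideal_coding(gold)
      }
      rows[[k]] <- data.frame(
        stay_id = sprintf("%s%03d", center, i), center = center, sex = "F",
        age = age, year = cfg$year, unit = "gynecology",
        duration_days = duration, main_dx = hdd$main,
        record_available = TRUE, ep_histology = gold$ep_histology,
        laparoscopy = gold$laparoscopy, tubal_rupture = gold$tubal_rupture,
        hemoperitoneum_cc = gold$hemoperitoneum_cc,
        active_bleeding = gold$active_bleeding,
        alternative_dx = gold$alternative_dx,
        stringsAsFactors = FALSE
      )
      rows[[k]]$assoc_dx <- list(hdd$assoc)
      rows[[k]]$procedures <- list(hdd$proc)
    }
  }
  cepsb_cohort(do.call(rbind, rows))
}

#' Coding-error injection model
#'
#' One independent Bernoulli probability per taxonomy member (see
#' [coding_error_types()]); the CEPSB-side types apply to gold-positive
#' stays, `excess_dx` to gold-negative stays. A stay receives at most
#' `max_errors_per_stay` errors (applied and truncated in taxonomy order).
#'
#' @param p_incorrect_principal_dx,p_absent_associated_dx,p_absent_complication_code,p_incorrect_complication_code,p_absent_ep_procedure,p_admin_error,p_uncoded_stay,p_delivery_code,p_excess_dx
#'   per-type probabilities in `[0, 1]`.
#' @param max_errors_per_stay maximum number of injected errors per stay.
#' @return an `error_model` list.
#' @export
error_model <- function(p_incorrect_principal_dx = 0,
                        p_absent_associated_dx = 0,
                        p_absent_complication_code = 0,
                        p_incorrect_complication_code = 0,
                        p_absent_ep_procedure = 0,
                        p_admin_error = 0,
                        p_uncoded_stay = 0,
                        p_delivery_code = 0,
                        p_excess_dx = 0,
                        max_errors_per_stay = 2L) {
  p <- c(incorrect_principal_dx = p_incorrect_principal_dx,
         absent_associated_dx = p_absent_associated_dx,
         absent_complication_code = p_absent_complication_code,
         incorrect_complication_code = p_incorrect_complication_code,
         absent_ep_procedure = p_absent_ep_procedure,
         admin_error = p_admin_error,
         uncoded_stay = p_uncoded_stay,
         delivery_code_used = p_delivery_code,
         excess_dx = p_excess_dx)
  if (any(p < 0 | p > 1)) {
    stop("error probabilities must be in [0, 1]", call. = FALSE)
  }
  if (max_errors_per_stay < 1L) {
    stop("max_errors_per_stay must be >= 1", call. = FALSE)
  }
  structure(list(p = p, max_errors_per_stay = as.integer(max_errors_per_stay)),
            class = "error_model")
}

#' Error model calibrated to the reference study's error tallies
#'
#' Sets each per-type probability to (observed error count) / (size of the
#' eligible stratum): the eight CEPSB-side counts 3, 19, 11, 2, 7, 2, 1, 1
#' over the gold-positive stays (52 by default) and the excess-coding count
#' 3 over the gold-negative stays (318 by default).
#'
#' @param cfg the [cohort_config()] supplying the stratum sizes.
#' @return an `error_model`.
#' @export
calibrate_default_model <- function(cfg = cohort_config()) {
  n_pos <- sum(cfg$cepsb_per_center)
  n_neg <- sum(cfg$n_stays_per_center) - n_pos
  stopifnot(n_pos > 0, n_neg > 0)
  error_model(
    p_incorrect_principal_dx = 3 / n_pos,
    p_absent_associated_dx = 19 / n_pos,
    p_absent_complication_code = 11 / n_pos,
    p_incorrect_complication_code = 2 / n_pos,
    p_absent_ep_procedure = 7 / n_pos,
    p_admin_error = 2 / n_pos,
    p_uncoded_stay = 1 / n_pos,
    p_delivery_code = 1 / n_pos,
    p_excess_dx = 3 / n_neg
  )
}

# Mutation primitives. Each takes the current record state and returns the
# mutated state, or NULL when the mutation would not change the record (a
# masked draw: not applied, not logged).
mutate_record <- function(type, rec, admin_choice) {
  main <- rec$main_dx; assoc <- rec$assoc_dx; proc <- rec$procedures
  switch(type,
    incorrect_principal_dx = {
      if (is.na(main) || !main %in% EP_MAIN_CODES) return(NULL)
      rec$main_dx <- NON_EP_GYN_MAIN
      rec
    },
    absent_associated_dx = {
      if (length(assoc) == 0L) return(NULL)
      rec$assoc_dx <- character()
      rec
    },
    absent_complication_code = {
      if (!any(assoc %in% COMPLICATION_CODES)) return(NULL)
      rec$assoc_dx <- setdiff(assoc, COMPLICATION_CODES)
      rec
    },
    incorrect_complication_code = {
      if (!any(assoc %in% COMPLICATION_CODES)) return(NULL)
      rec$assoc_dx <- c(setdiff(assoc, COMPLICATION_CODES),
                        WRONG_COMPLICATION_CODE)
      rec
    },
    absent_ep_procedure = {
      specific <- intersect(proc, EP_PROC_CODES)
      if (length(specific) == 0L) return(NULL)
      kept <- setdiff(proc, EP_PROC_CODES)
      if ("JJFC001" %in% specific) {
        kept <- c(kept, NONSPECIFIC_SALPINGECTOMY)  # non-specific sibling
      }
      rec$procedures <- kept
      rec
    },
    admin_error = {
      if (admin_choice < 1 / 3) rec$age <- 52L
      else if (admin_choice < 2 / 3) rec$unit <- "emergency"
      else rec$year <- rec$year - 1L
      rec
    },
    uncoded_stay = {
      rec$main_dx <- NA_character_
      rec$assoc_dx <- character()
      rec$procedures <- character()
      rec
    },
    delivery_code_used = {
      if (is.na(main) || !main %in% EP_MAIN_CODES) return(NULL)
      rec$main_dx <- DELIVERY_MAIN
      rec
    },
    excess_dx = {
      rec$main_dx <- "O001"
      rec$assoc_dx <- unique(c(setdiff(assoc, "O001"), "O081"))
      rec$procedures <- unique(c(proc, "JJFC001"))
      rec
    }
  )
}

#' Inject coding errors into an ideally coded cohort
#'
#' Walks the cohort in row order consuming a single seeded random stream
#' (ten draws per stay: one per taxonomy member plus one admin-field
#' selector, so the stream position is independent of what fires). Each
#' applicable error type fires independently with its model probability;
#' mutations are applied in taxonomy order and truncated at
#' `max_errors_per_stay`. A drawn mutation that would not change the record
#' (for example deleting a complication code already removed by an earlier
#' error, or marking an already-mutated stay uncoded) is masked: neither
#' applied nor logged, keeping the error log exactly recoverable by the
#' audit.
#'
#' @param cohort a `cepsb_cohort` with error-free records.
#' @param model an [error_model()].
#' @param seed integer RNG seed.
#' @return list with elements `cohort` (mutated) and `error_log`
#'   (data.frame `stay_id`, `error_type`, ground-truth injections).
#' @export
inject_errors <- function(cohort, model, seed) {
  stopifnot(inherits(model, "error_model"))
  set.seed(as.integer(seed))
  types <- coding_error_types()
  gold <- classify_gold(cohort)
  n <- nrow(cohort)
  draws <- matrix(stats::runif(n * 10L), nrow = n, byrow = TRUE)
  log_id <- character()
  log_type <- character()
  for (i in seq_len(n)) {
    if (is.na(gold[i])) next
    rec <- cohort[i, , drop = FALSE]
    n_applied <- 0L
    touched <- FALSE
    for (t in seq_along(types)) {
      type <- types[t]
      if (n_applied >= model$max_errors_per_stay) break
      applicable <- if (type == "excess_dx") !gold[i] else gold[i]
      if (type == "uncoded_stay" && touched) applicable <- FALSE
      if (!applicable || draws[i, t] >= model$p[[type]]) next
      state <- list(main_dx = rec$main_dx,
                    assoc_dx = rec$assoc_dx[[1L]],
                    procedures = rec$procedures[[1L]],
                    age = rec$age, unit = rec$unit, year = rec$year,
                    sex = rec$sex)
      mutated <- mutate_record(type, state, draws[i, 10L])
      if (is.null(mutated)) next
      rec$main_dx <- mutated$main_dx
      rec$assoc_dx[[1L]] <- mutated$assoc_dx
      rec$procedures[[1L]] <- mutated$procedures
      rec$age <- mutated$age; rec$unit <- mutated$unit
      rec$year <- mutated$year; rec$sex <- mutated$sex
      n_applied <- n_applied + 1L
      touched <- TRUE
      log_id <- c(log_id, rec$stay_id)
      log_type <- c(log_type, type)
    }
    if (touched) {
      cohort$main_dx[i] <- rec$main_dx
      cohort$assoc_dx[[i]] <- rec$assoc_dx[[1L]]
      cohort$procedures[[i]] <- rec$procedures[[1L]]
      cohort$age[i] <- rec$age
      cohort$unit[i] <- rec$unit
      cohort$year[i] <- rec$year
      cohort$sex[i] <- rec$sex
    }
  }
  list(cohort = cohort,
       error_log = data.frame(stay_id = log_id, error_type = log_type,
                              stringsAsFactors = FALSE))
}
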