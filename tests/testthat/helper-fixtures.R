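# Shared fixtures, built in code.

# Minimal valid stay row; override fields as needed.
make_stay <- function(stay_id = "S001", center = "A", sex = "F", age = 30L,
                      year = 2012L, unit = "gynecology", duration_days = 2,
                      main_dx = "O001", assoc_dx = character(),
                      procedures = character(), record_available = TRUE,
                      ep_histology = FALSE, laparoscopy = FALSE,
                      tubal_rupture = FALSE, hemoperitoneum_cc = 0,
                      active_bleeding = FALSE, alternative_dx = "other") {
  df <- data.frame(stay_id = stay_id, center = center, sex = sex, age = age,
                   year = year, unit = unit, duration_days = duration_days,
                   main_dx = main_dx, record_available = record_available,
                   ep_histology = ep_histology, laparoscopy = laparoscopy,
                   tubal_rupture = tubal_rupture,
                   hemoperitoneum_cc = hemoperitoneum_cc,
                   active_bleeding = active_bleeding,
                   alternative_dx = alternative_dx,
                   stringsAsFactors = FALSE)
  df$assoc_dx <- list(assoc_dx)
  df$procedures <- list(procedures)
  df
}

make_cohort <- function(...) {
  cepsb_cohort(do.call(rbind, list(...)))
}

# The three canonical evaluation examples: fully coded CEPSB stay, stay
# missing the complication code, and a completely uncoded stay.
three_stay_cohort <- function() {
  make_cohort(
    make_stay("S1", main_dx = "O001", assoc_dx = "K661",
              procedures = "JJFC001", ep_histology = TRUE,
              laparoscopy = TRUE, hemoperitoneum_cc = 800,
              alternative_dx = "none"),
    make_stay("S2", main_dx = "O001", procedures = "JJFC001",
              ep_histology = TRUE, laparoscopy = TRUE,
              alternative_dx = "uncomplicated_ep"),
    make_stay("S3", main_dx = NA_character_)
  )
}

# Brute-force evaluation oracle: explicit loops over clause/code/field
# membership, written independently of evaluate()'s vectorized path.
oracle_evaluate <- function(alg, stay) {
  a <- alg$admin
  if (!(stay$sex == a$sex && stay$age >= a$age_min && stay$age <= a$age_max &&
        stay$year == a$year && stay$unit == a$unit)) {
    return(FALSE)
  }
  for (clause in alg$clauses) {
    field <- switch(clause$scope,
                    MAIN_DX = if (is.na(stay$main_dx)) character() else
                      stay$main_dx,
                    ASSOC_DX = stay$assoc_dx[[1]],
                    ANY_DX = c(if (!is.na(stay$main_dx)) stay$main_dx,
                               stay$assoc_dx[[1]]),
                    PROCEDURE = stay$procedures[[1]])
    hit <- FALSE
    for (code in clause$codes) {
      for (f in field) if (identical(code, f)) hit <- TRUE
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# Independent two-sided Fisher oracle: enumerate every table with the
# observed margins and sum hypergeometric probabilities computed from
# choose() ratios (no dhyper).
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
  support <- max(0, k - n2):min(k, n1)
  prob <- vapply(support, function(x) {
    choose(n1, x) * choose(n2, k - x) / choose(N, k)
  }, numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Random stay with codes drawn from a pool overlapping the built-ins.
random_stay <- function(id) {
  dx_pool <- c("O001", "O000", "O008", "O081", "K661", "Z513", "O083",
               "N938", "D62", "O200", "R58", "O800")
  proc_pool <- c("JJFC001", "JJFA001", "JJPC001", "JJJC002", "FELF004",
                 "JJFC006", "JNJD002", "JQGA001")
  main <- if (runif(1) < 0.1) NA_character_ else sample(dx_pool, 1)
  assoc <- if (is.na(main)) character() else
    setdiff(sample(dx_pool, min(rpois(1, 1.5), 5L)), main)
  proc <- if (is.na(main)) character() else
    unique(sample(proc_pool, min(rpois(1, 1), 4L)))
  make_stay(id, main_dx = main, assoc_dx = assoc, procedures = proc,
            sex = sample(c("F", "F", "F", "M"), 1),
            age = sample(15:50, 1),
            year = sample(c(2012L, 2012L, 2011L), 1),
            unit = sample(c("gynecology", "gynecology", "emergency"), 1))
}

# Cohort with two planted discriminative codes (one diagnosis, one
# procedure) and exchangeable noise codes, for derivation-recovery tests.
planted_cohort <- function(n_pos = 52, n_neg = 318,
                           p_pos = 0.8, p_neg = 0.05) {
  noise_dx <- c("N938", "D259", "O200", "N830", "K351", "R104")
  noise_proc <- c("JNJD002", "HHFA001", "JJNC001", "ZZQX001")
  rows <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos + n_neg)) {
    pos <- i <= n_pos
    planted_dx <- runif(1) < (if (pos) p_pos else p_neg)
    planted_proc <- runif(1) < (if (pos) p_pos else p_neg)
    assoc <- noise_dx[runif(6) < ifelse(pos, 0.3, 0.2)]
    if (planted_dx) assoc <- c("O001", assoc)
    proc <- noise_proc[runif(4) < ifelse(pos, 0.3, 0.2)]
    if (planted_proc) proc <- c("JJFC001", proc)
    rows[[i]] <- make_stay(sprintf("P%03d", i), main_dx = "N999",
                           assoc_dx = assoc, procedures = proc,
                           ep_histology = pos, laparoscopy = pos,
                           hemoperitoneum_cc = if (pos) 600 else 0,
                           alternative_dx = if (pos) "none" else "other")
  }
  cepsb_cohort(do.call(rbind, rows))
}
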