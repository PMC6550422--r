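# Synthetic cohort generator and coding-error injection.

test_that("generate_cohort hits the configured counts exactly", {
  coh <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(coh), 370L)
  gold <- classify_gold(coh)
  expect_equal(sum(gold), 52L)
  expect_equal(sum(gold & coh$center == "A"), 28L)
  expect_equal(sum(gold & coh$center == "B"), 24L)
  expect_equal(sum(coh$center == "A"), 230L)
  expect_true(all(coh$age >= 18 & coh$age <= 45))
  expect_true(all(coh$duration_days >= 0))
  # hemoperitoneum-profile cases carry >= 500 cc by construction; every
  # gold positive satisfies at least one complication criterion
  pos <- coh[which(gold), ]
  expect_true(all(pos$tubal_rupture | pos$hemoperitoneum_cc >= 500 |
                    pos$active_bleeding))
  # zero-prevalence config
  none <- generate_cohort(cohort_config(cepsb_per_center = c(A = 0, B = 0),
                                        seed = 3))
  expect_equal(sum(classify_gold(none)), 0L)
  # infeasible config rejected
  expect_error(cohort_config(n_stays_per_center = c(A = 10, B = 10),
                             cepsb_per_center = c(A = 11, B = 0)),
               "exceeds")
})

test_that("generation and injection are deterministic given the seed", {
  cfg <- cohort_config(seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  model <- calibrate_default_model(cfg)
  i1 <- inject_errors(c1, model, seed = 7)
  i2 <- inject_errors(c2, model, seed = 7)
  expect_identical(as.data.frame(i1$cohort), as.data.frame(i2$cohort))
  expect_identical(i1$error_log, i2$error_log)
  i3 <- inject_errors(c1, model, seed = 8)
  expect_false(identical(i1$error_log, i3$error_log))
})

test_that("ideal coding writes the guideline conjunction for CEPSB only", {
  # CEPSB with hemoperitoneum 800 cc
  gold <- list(ep_histology = TRUE, laparoscopy = TRUE, tubal_rupture = FALSE,
               hemoperitoneum_cc = 800, active_bleeding = FALSE,
               alternative_dx = "none")
  rec <- ideal_coding(gold)
  expect_identical(rec$main, "O001")
  expect_true("K661" %in% rec$assoc)
  expect_true("JJFC001" %in% rec$proc)
  # uncomplicated EP treated surgically: EP main + procedure, no
  # complication code
  gold2 <- list(ep_histology = TRUE, laparoscopy = TRUE,
                tubal_rupture = FALSE, hemoperitoneum_cc = 100,
                active_bleeding = FALSE, alternative_dx = "uncomplicated_ep")
  rec2 <- ideal_coding(gold2)
  expect_identical(rec2$main, "O001")
  expect_identical(rec2$proc, "JJFC001")
  expect_false(any(rec2$assoc %in% c("O081", "K661", "Z513", "O083", "O086")))
  # ovarian cyst rupture: no ectopic-pregnancy code at all
  gold3 <- list(ep_histology = FALSE, laparoscopy = TRUE,
                tubal_rupture = FALSE, hemoperitoneum_cc = 200,
                active_bleeding = FALSE,
                alternative_dx = "ovarian_cyst_rupture")
  rec3 <- ideal_coding(gold3)
  expect_false(any(grepl("^O00", c(rec3$main, rec3$assoc))))
  # massive hemoperitoneum -> transfusion coding
  gold4 <- modifyList(gold, list(hemoperitoneum_cc = 2000))
  rec4 <- ideal_coding(gold4)
  expect_true("Z513" %in% rec4$assoc)
  expect_true("FELF004" %in% rec4$proc)
})

test_that("null and saturated injection behave as contracted", {
  coh <- generate_cohort(cohort_config(seed = 12))
  zero <- inject_errors(coh, error_model(), seed = 1)
  expect_identical(as.data.frame(zero$cohort), as.data.frame(coh))
  expect_equal(nrow(zero$error_log), 0L)
  sat <- inject_errors(coh, error_model(p_uncoded_stay = 1), seed = 1)
  gold <- classify_gold(coh)
  uncoded <- is.na(sat$cohort$main_dx) &
    lengths(sat$cohort$assoc_dx) == 0L & lengths(sat$cohort$procedures) == 0L
  expect_true(all(uncoded[gold]))       # every CEPSB stay emptied
  expect_false(any(uncoded[!gold]))     # non-CEPSB stays untouched
  expect_error(error_model(p_excess_dx = 1.2), "\\[0, 1\\]")
  expect_error(error_model(max_errors_per_stay = 0), "max_errors")
})

test_that("calibrated model matches printed tallies over eligible strata", {
  model <- calibrate_default_model()
  expect_equal(model$p[["absent_associated_dx"]], 19 / 52)
  expect_equal(model$p[["excess_dx"]], 3 / 318)
  expect_equal(model$p[["incorrect_principal_dx"]], 3 / 52)
  expect_equal(model$p[["absent_complication_code"]], 11 / 52)
  expect_true(all(model$p >= 0 & model$p <= 1))
  expect_identical(model$max_errors_per_stay, 2L)
})

test_that("injected counts match the masking-aware binomial expectation", {
  # Expectation oracle: each type fires Bernoulli(p) independently on its
  # eligible stratum; sequential application masks a draw whose mutation
  # would be a no-op. For the default generator the dominant masking terms
  # are: absent/incorrect complication masked by earlier associated-dx
  # deletions, and uncoded masked by any earlier error. The cap at 2 errors
  # is a smaller correction, so a 3-SD band around the no-cap expectation
  # is used with 40 replicates.
  cfg <- cohort_config(seed = 21)
  coh <- generate_cohort(cfg)
  model <- calibrate_default_model(cfg)
  p <- model$p
  n_pos <- 52; n_neg <- 318
  exp_counts <- c(
    incorrect_principal_dx = n_pos * p[["incorrect_principal_dx"]],
    absent_associated_dx = n_pos * p[["absent_associated_dx"]],
    absent_complication_code = n_pos * p[["absent_complication_code"]] *
      (1 - p[["absent_associated_dx"]]),
    incorrect_complication_code = n_pos *
      p[["incorrect_complication_code"]] *
      (1 - p[["absent_associated_dx"]]) *
      (1 - p[["absent_complication_code"]]),
    absent_ep_procedure = n_pos * p[["absent_ep_procedure"]],
    admin_error = n_pos * p[["admin_error"]],
    uncoded_stay = n_pos * p[["uncoded_stay"]] *
      prod(1 - p[c("incorrect_principal_dx", "absent_associated_dx",
                   "absent_complication_code", "incorrect_complication_code",
                   "absent_ep_procedure", "admin_error")]),
    delivery_code_used = n_pos * p[["delivery_code_used"]] *
      (1 - p[["incorrect_principal_dx"]]),
    excess_dx = n_neg * p[["excess_dx"]]
  )
  n_rep <- 40
  totals <- matrix(0, n_rep, length(exp_counts),
                   dimnames = list(NULL, names(exp_counts)))
  for (r in seq_len(n_rep)) {
    log <- inject_errors(coh, model, seed = 5000 + r)$error_log
    tab <- table(factor(log$error_type, levels = names(exp_counts)))
    totals[r, ] <- as.integer(tab)
  }
  mean_counts <- colMeans(totals)
  # 3 SD of the replicate mean (binomial variance, eligible stratum n)
  n_elig <- c(rep(n_pos, 8), n_neg)
  sd_mean <- sqrt(n_elig * (exp_counts / n_elig) *
                    (1 - exp_counts / n_elig)) / sqrt(n_rep)
  expect_true(all(abs(mean_counts - exp_counts) <=
                    pmax(3 * sd_mean, 0.35)))
  # at most max_errors_per_stay entries per stay
  log <- inject_errors(coh, model, seed = 77)$error_log
  expect_true(all(table(log$stay_id) <= model$max_errors_per_stay))
})

test_that("sensitivity responds monotonically to error pressure", {
  cfg <- cohort_config(n_stays_per_center = c(A = 60, B = 40),
                       cepsb_per_center = c(A = 15, B = 12), seed = 8)
  coh <- generate_cohort(cfg)
  sens <- function(model, seeds) {
    mean(vapply(seeds, function(s) {
      mut <- inject_errors(coh, model, seed = s)$cohort
      pred <- apply_algorithm(builtin_predefined(), mut)
      gold <- classify_gold(mut)
      names(gold) <- mut$stay_id
      cm <- confusion(pred, gold)
      cm$tp / (cm$tp + cm$fn)
    }, numeric(1)))
  }
  seeds <- 1:100
  s0 <- sens(error_model(), seeds)
  expect_equal(s0, 1.0)
  s_lo <- sens(error_model(p_absent_complication_code = 0.2), seeds)
  s_hi <- sens(error_model(p_absent_complication_code = 0.6), seeds)
  expect_true(s_lo < s0)
  expect_true(s_hi < s_lo)
  # specificity non-increasing in excess-coding pressure
  spec <- function(model, seeds) {
    mean(vapply(seeds, function(s) {
      mut <- inject_errors(coh, model, seed = s)$cohort
      pred <- apply_algorithm(builtin_predefined(), mut)
      gold <- classify_gold(mut)
      names(gold) <- mut$stay_id
      cm <- confusion(pred, gold)
      cm$tn / (cm$tn + cm$fp)
    }, numeric(1)))
  }
  sp_lo <- spec(error_model(p_excess_dx = 0.1), 1:40)
  sp_hi <- spec(error_model(p_excess_dx = 0.5), 1:40)
  expect_true(sp_hi < sp_lo)
  expect_true(sp_lo < 1)
})
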