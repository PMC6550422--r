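# Validity statistics: confusion, Wald/Wilson CIs, LR+ log-method CI,
# Fisher exact vs enumeration oracle, center comparisons.

test_that("confusion cross-tabulates and checks id sets", {
  pred <- c(S1 = TRUE, S2 = TRUE, S3 = FALSE, S4 = FALSE)
  gold <- c(S1 = TRUE, S2 = FALSE, S3 = TRUE, S4 = FALSE)
  cm <- confusion(pred, gold)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1L, 1L, 1L, 1L))
  # order independence
  cm2 <- confusion(pred[c(3, 1, 4, 2)], gold)
  expect_identical(unclass(cm2), unclass(cm))
  # all-negative predictions
  cm3 <- confusion(c(S1 = FALSE, S2 = FALSE), c(S1 = TRUE, S2 = FALSE))
  expect_identical(c(cm3$tp, cm3$fp), c(0L, 0L))
  expect_error(confusion(pred, gold[1:3]), "only in predictions.*S4")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("Wald intervals are the textbook construction, clipped", {
  cm <- confusion_matrix(12, 3, 40, 315)
  se <- sensitivity_ci(cm)
  p <- 12 / 52
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 52)
  expect_equal(se$estimate, p)
  expect_equal(se$lower, p - half)
  expect_equal(se$upper, p + half)
  sp <- specificity_ci(cm)
  expect_equal(sp$estimate, 315 / 318)
  expect_equal(sp$upper, 1)   # clipped at 1
  # degenerate Wald at p = 0
  z <- sensitivity_ci(confusion_matrix(0, 0, 5, 10))
  expect_equal(c(z$estimate, z$lower, z$upper), c(0, 0, 0))
  # p = 1 specificity
  o <- specificity_ci(confusion_matrix(1, 0, 1, 10))
  expect_equal(c(o$estimate, o$lower, o$upper), c(1, 1, 1))
  expect_error(sensitivity_ci(confusion_matrix(0, 2, 0, 3)), "denominator")
  # Wilson option differs from Wald and stays inside [0,1]
  w <- sensitivity_ci(cm, method = "wilson")
  expect_false(isTRUE(all.equal(w$lower, se$lower)))
  expect_true(w$lower > 0 && w$upper < 1)
})

test_that("CI width shrinks when all cells are scaled up", {
  cm1 <- confusion_matrix(12, 3, 40, 315)
  cm2 <- confusion_matrix(24, 6, 80, 630)
  w1 <- sensitivity_ci(cm1)
  w2 <- sensitivity_ci(cm2)
  expect_equal(w1$estimate, w2$estimate)
  expect_true((w2$upper - w2$lower) < (w1$upper - w1$lower))
  # LR+ scale invariance of the point estimate
  expect_equal(positive_lr_ci(cm1)$estimate, positive_lr_ci(cm2)$estimate)
})

test_that("LR+ uses the log-method interval and flags degenerate cells", {
  cm <- confusion_matrix(33, 17, 19, 301)
  lr <- positive_lr_ci(cm)
  expect_equal(lr$estimate, (33 / 52) / (17 / 318))
  se_log <- sqrt(1 / 33 - 1 / 52 + 1 / 17 - 1 / 318)
  expect_equal(lr$lower, exp(log(lr$estimate) - qnorm(0.975) * se_log))
  # LR+ > 1 iff sensitivity > 1 - specificity; chance performance
  # (tp = fn, fp = tn) -> 1
  even <- confusion_matrix(10, 30, 10, 30)
  expect_equal(positive_lr_ci(even)$estimate, 1)
  # fp = 0: infinite with Haldane companion
  inf <- positive_lr_ci(confusion_matrix(52, 0, 0, 318))
  expect_true(is.infinite(inf$estimate))
  expect_true(inf$degenerate)
  expect_equal(inf$haldane, (52.5 / 53) / (0.5 / 319))
  # tp = 0: LR+ 0, flagged
  zero <- positive_lr_ci(confusion_matrix(0, 3, 5, 10))
  expect_equal(zero$estimate, 0)
  expect_true(zero$degenerate)
})

test_that("fisher_exact_2x2 equals the enumeration oracle", {
  # exhaustive over all tables with both row margins <= 15
  tables <- list()
  for (n1 in 0:15) {
    for (n2 in 0:15) {
      if (n1 + n2 == 0) next
      for (k in 0:(n1 + n2)) {
        for (a in max(0, k - n2):min(k, n1)) {
          tables[[length(tables) + 1L]] <- c(a, n1 - a, k - a, n2 - (k - a))
        }
      }
    }
  }
  p_impl <- vapply(tables, function(t) fisher_exact_2x2(t[1], t[2], t[3],
                                                        t[4]), numeric(1))
  p_orac <- vapply(tables, function(t) oracle_fisher(t[1], t[2], t[3], t[4]),
                   numeric(1))
  expect_equal(p_impl, p_orac, tolerance = 1e-10)
  # randomized tables with margins up to 30, cross-checked against both the
  # oracle and the reference implementation
  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    k <- sample.int(n1 + n2 + 1, 1) - 1L
    rng <- max(0, k - n2):min(k, n1)
    a <- rng[sample.int(length(rng), 1)]
    b <- n1 - a; c <- k - a; d <- n2 - c
    p <- fisher_exact_2x2(a, b, c, d)
    expect_equal(p, oracle_fisher(a, b, c, d), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(c(a, b, c, d), 2,
                                              byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("compare_centers applies the small-cell rule, two-sided", {
  # center sensitivities 10/28 vs 2/24: all expected cells >= 5, so the
  # auto rule picks chi-square; the Fisher value is available on request
  # and both land at 0.02 when rounded to the printed precision
  cm_a <- confusion_matrix(10, 3, 18, 199)
  cm_b <- confusion_matrix(2, 0, 22, 116)
  res <- compare_centers(cm_a, cm_b, "sensitivity")
  expect_identical(res$test, "chi2")
  expect_true(res$p_value < 0.05)
  resf <- compare_centers(cm_a, cm_b, "sensitivity", test = "fisher")
  expect_equal(resf$p_value, oracle_fisher(10, 18, 2, 22), tolerance = 1e-10)
  expect_equal(round_half_up(resf$p_value, 2), 0.02)
  expect_equal(round_half_up(res$p_value, 2), 0.02)
  # a genuinely sparse table goes to Fisher automatically
  sparse <- compare_centers(confusion_matrix(3, 0, 2, 10),
                            confusion_matrix(1, 0, 4, 10), "sensitivity")
  expect_identical(sparse$test, "fisher")
  # identical matrices -> p = 1
  same <- compare_centers(cm_a, cm_a, "sensitivity")
  expect_equal(same$p_value, 1.0)
  # big balanced table -> chi-square branch without continuity correction
  big_a <- confusion_matrix(40, 10, 40, 200)
  big_b <- confusion_matrix(30, 10, 50, 200)
  res2 <- compare_centers(big_a, big_b, "sensitivity")
  expect_identical(res2$test, "chi2")
  tab <- rbind(c(40, 40), c(30, 50))
  expect_equal(res2$p_value,
               stats::chisq.test(tab, correct = FALSE)$p.value)
  # degenerate metric denominators rejected
  expect_error(compare_centers(confusion_matrix(0, 1, 0, 5), cm_b,
                               "sensitivity"), "degenerate")
})

test_that("validity_report composes counts and metrics", {
  coh <- three_stay_cohort()
  rep <- validity_report(coh, builtin_pragmatic())
  expect_identical(rep$confusion$tp, 1L)
  expect_identical(rep$confusion$fp, 1L)
  expect_identical(rep$n_positive_tests, 2L)
  tab <- validity_table(rep)
  expect_identical(tab$algorithm, "pragmatic")
  expect_match(tab$sensitivity, "^100.0")
  # conservation: cells sum to analyzable stays
  cm <- rep$confusion
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 3L)
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(76.55, 1), 76.6)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(23.076923 * 100 / 100, 1), 23.1)
  expect_identical(format_half_up(7.1541, 1), "7.2")
  expect_identical(format_half_up(99.0566, 1), "99.1")
})
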