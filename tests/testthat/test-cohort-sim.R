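test_that("default cohort has the study's shape and record invariants", {
  cohort <- generate_cohort(cohort_params(), seed = 2)
  v1 <- cohort[cohort$visit == 1, ]
  expect_equal(sum(v1$group == "control"), 18)
  expect_equal(sum(v1$group == "mtbi"), 25)
  expect_equal(sum(cohort$visit == 2), 19)
  expect_false(any(duplicated(cohort[c("subject_id", "visit")])))
  ## every visit-2 record pairs with a visit-1 record
  expect_true(all(cohort$subject_id[cohort$visit == 2] %in%
                    cohort$subject_id[cohort$visit == 1]))
  expect_true(all(is.na(cohort$days_post_injury[cohort$group == "control"])))
  expect_true(all(!is.na(cohort$days_post_injury[cohort$group == "mtbi"])))
  expect_true(all(cohort$scat2 >= 0 & cohort$scat2 <= 100))
  expect_true(all(cohort$gm_volume_cm3 > 0 & cohort$wm_volume_cm3 > 0))
  ## reproducibility
  expect_identical(cohort, generate_cohort(cohort_params(), seed = 2))
})

test_that("zero-SD parameters collapse every subject onto the group means", {
  mom <- cvrkit:::default_moments("full-cohort")
  mom$control_sd <- 0
  mom$mtbi_sd <- 0
  mom$mtbi2_sd <- 0
  p <- cohort_params(moments = mom, n_followup = 0)
  cohort <- generate_cohort(p, seed = 3)
  ctrl <- cohort[cohort$group == "control", ]
  expect_true(all(ctrl$gm_cvr == 0.28))
  expect_true(all(ctrl$scat2 == 91.5))
  tbi <- cohort[cohort$group == "mtbi", ]
  expect_true(all(tbi$wm_cvr == 0.1472))
})

test_that("large samples converge to the generator's own moments and correlations", {
  n <- 5000
  p <- cohort_params(n_control = n, n_mtbi = n, n_followup = 0)
  cohort <- generate_cohort(p, seed = 4)
  mom <- p$moments
  for (g in c("control", "mtbi")) {
    sub <- cohort[cohort$group == g, ]
    mu <- stats::setNames(mom[[paste0(if (g == "control") "control" else "mtbi", "_mean")]],
                          mom$variable)
    sdv <- stats::setNames(mom[[paste0(if (g == "control") "control" else "mtbi", "_sd")]],
                           mom$variable)
    for (v in mom$variable) {
      tol <- max(0.02 * abs(mu[[v]]), 4 * sdv[[v]] / sqrt(n))
      expect_lt(abs(mean(sub[[v]]) - mu[[v]]), tol)
    }
  }
  ## empirical correlations track the post-projection targets within 0.05
  tg <- p$cor_targets_achieved
  for (i in seq_len(nrow(tg))) {
    sub <- cohort[cohort$group == tg$group[i], ]
    r_emp <- cor(sub[[tg$var1[i]]], sub[[tg$var2[i]]])
    expect_lt(abs(r_emp - tg$r_achieved[i]), 0.05)
  }
})

test_that("projection to the nearest correlation matrix preserves signs", {
  p <- cohort_params()
  expect_true(p$projected[["control"]])   # the control SCAT2 star is infeasible raw
  tg <- p$cor_targets_achieved
  expect_true(all(sign(tg$r_achieved) == sign(tg$r)))
  expect_true(all(abs(tg$r_achieved) <= abs(tg$r) + 1e-8))
})

test_that("raw infeasible correlation matrices are refused with a PSD hint", {
  p <- cohort_params(project_psd = FALSE)
  expect_error(generate_cohort(p), class = "cvrkit_error_params_error",
               regexp = "nearPD")
  expect_error(cohort_params(n_followup = 30), class = "cvrkit_error_params_error")
  expect_error(cohort_params(cor_targets = cvrkit:::cor_tbl("control", "scat2", "gm_cvr", 1.2)),
               class = "cvrkit_error_params_error")
})

test_that("demographic summaries reproduce the group composition percentages", {
  cohort <- generate_cohort(cohort_params(), seed = 5)
  demo <- summarize_demographics(cohort)
  demo <- demo[order(demo$group), ]
  expect_equal(demo$n, c(18, 25))
  expect_equal(demo$n_male, c(11, 18))
  expect_equal(demo$male_pct, c(100 * 11 / 18, 72))
  expect_true(is.na(demo$days_post_injury_mean[demo$group == "control"]))
})

test_that("cohort CSV round trip preserves the table", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_params(n_control = 5, n_mtbi = 5,
                                          n_followup = 3), seed = 6)
  f <- file.path(dir, "cohort.csv")
  write_cohort_csv(cohort, f)
  back <- read_cohort_csv(f)
  expect_equal(back$scat2, cohort$scat2)
  expect_equal(back$subject_id, cohort$subject_id)
})
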