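test_that("Mann-Whitney matches the exhaustive-enumeration oracle for all small splits", {
  set.seed(14)
  for (n1 in 1:6) {
    for (n2 in seq_len(8 - n1)) {
      for (rep in 1:3) {
        ## integer draws force ties regularly
        x <- sample(1:5, n1, replace = TRUE)
        y <- sample(1:5, n2, replace = TRUE)
        got <- group_compare(two_groups(x, y), "value")
        oracle <- mw_oracle(x, y)
        expect_equal(got$statistic, oracle$u,
                     info = sprintf("U at n1=%d n2=%d", n1, n2))
        expect_equal(got$p.value, oracle$p,
                     info = sprintf("p at n1=%d n2=%d", n1, n2))
      }
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test away from the enumeration path", {
  set.seed(15)
  x <- rnorm(12); y <- rnorm(15) + 0.5            # no ties, exact distribution
  got <- group_compare(two_groups(x, y), "value")
  w <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(got$statistic, unname(w$statistic))
  expect_equal(got$p.value, w$p.value)

  x <- rnorm(30); y <- rnorm(35) + 0.3            # normal approximation branch
  got <- group_compare(two_groups(x, y), "value")
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p.value, w$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney conventions: separated and identical groups", {
  r <- group_compare(two_groups(c(1, 2, 3), c(4, 5, 6)), "value")
  expect_equal(r$statistic, 0)          # first group loses every pairing
  expect_equal(r$p.value, 0.1)
  expect_match(r$convention, "control")
  r2 <- group_compare(two_groups(c(1, 2, 3), c(1, 2, 3)), "value")
  expect_equal(r2$statistic, 3 * 3 / 2)
  expect_equal(r2$p.value, 1)
  expect_error(group_compare(two_groups(numeric(), 1:3), "value"),
               class = "cvrkit_error_insufficient_data")
})

test_that("paired t matches the closed form and handles degenerate differences", {
  set.seed(16)
  tbl <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:10), 2),
    visit = rep(c(1L, 2L), each = 10),
    value = c(rnorm(10, 50, 5), rnorm(10, 48, 5))
  )
  got <- paired_compare(tbl, "value")
  d <- tbl$value[11:20] - tbl$value[1:10]
  expect_equal(got$statistic, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  expect_equal(got$df, 9)
  expect_equal(got$estimate, mean(d))
  expect_equal(got$p.value, 2 * pt(-abs(got$statistic), 9), tolerance = 1e-12)

  same <- tbl; same$value[11:20] <- same$value[1:10]
  g0 <- paired_compare(same, "value")
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)

  shift <- tbl; shift$value[11:20] <- shift$value[1:10] + 1
  gs <- paired_compare(shift, "value")
  expect_true(gs$degenerate)
  expect_equal(gs$p.value, 0)

  expect_error(paired_compare(tbl[c(1, 11), ][-2, ], "value"),
               class = "cvrkit_error_insufficient_data")
})

test_that("Pearson correlation matches the covariance-ratio closed form", {
  tbl <- tibble::tibble(group = "g", visit = 1L,
                        a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  got <- correlate(tbl, "a", "b")
  expect_equal(got$estimate, 0.6)     # sum of cross products 3 over sqrt(5 * 5)
  expect_equal(got$n, 4)

  ident <- tibble::tibble(group = "g", visit = 1L, a = 1:5, b = 1:5)
  expect_equal(correlate(ident, "a", "b")$estimate, 1)

  expect_error(correlate(tibble::tibble(group = "g", visit = 1, a = c(1, 1, 1),
                                        b = 1:3), "a", "b"),
               class = "cvrkit_error_undefined_correlation")
  expect_error(correlate(ident[1:2, ], "a", "b"),
               class = "cvrkit_error_insufficient_data")
})

test_that("correlation is affine-invariant and antisymmetric under negation", {
  set.seed(17)
  for (i in 1:5) {
    tbl <- tibble::tibble(group = "g", visit = 1L,
                          a = rnorm(20), b = rnorm(20))
    r0 <- correlate(tbl, "a", "b")$estimate
    tbl2 <- dplyr::mutate(tbl, a = 3.2 * a + 7, b = 0.5 * b - 2)
    expect_equal(correlate(tbl2, "a", "b")$estimate, r0, tolerance = 1e-12)
    tbl3 <- dplyr::mutate(tbl, a = -a)
    expect_equal(correlate(tbl3, "a", "b")$estimate, -r0, tolerance = 1e-12)
  }
})

test_that("ANCOVA coefficients equal the normal-equations oracle", {
  set.seed(18)
  n <- 20
  tbl <- tibble::tibble(
    group = rep(c("control", "mtbi"), each = n / 2),
    visit = 1L,
    age_years = runif(n, 20, 70),
    sex = sample(c("M", "F"), n, replace = TRUE),
    scat2 = rnorm(n, 80, 10)
  )
  got <- adjusted_group_effect(tbl, "scat2")
  X <- cbind(1, tbl$group == "mtbi", tbl$age_years, tbl$sex == "M")
  beta <- solve(t(X) %*% X, t(X) %*% tbl$scat2)
  expect_equal(got$estimate[got$term == "group"], beta[2], tolerance = 1e-10)
  expect_equal(got$estimate[got$term == "age_years"], beta[3], tolerance = 1e-10)
  expect_equal(got$estimate[got$term == "sex"], beta[4], tolerance = 1e-10)
})

test_that("a pure group offset is detected and recovered within 2 SE", {
  set.seed(19)
  n <- 40
  tbl <- tibble::tibble(
    group = rep(c("control", "mtbi"), each = n / 2),
    visit = 1L,
    age_years = runif(n, 20, 70),
    sex = sample(c("M", "F"), n, replace = TRUE),
    scat2 = 80 + 8 * (rep(c(0, 1), each = n / 2)) + rnorm(n, sd = 2)
  )
  got <- adjusted_group_effect(tbl, "scat2")
  grp <- got[got$term == "group", ]
  expect_lt(grp$p.value, 0.001)
  expect_lt(abs(grp$estimate - 8), 2 * grp$std.error)
})

test_that("without covariates the adjusted effect reduces to the pooled t-test", {
  set.seed(20)
  tbl <- tibble::tibble(
    group = rep(c("control", "mtbi"), each = 12),
    visit = 1L,
    scat2 = rnorm(24, 80, 6) + rep(c(0, -4), each = 12)
  )
  got <- adjusted_group_effect(tbl, "scat2", covariates = character())
  tt <- t.test(scat2 ~ group, data = tbl, var.equal = TRUE)
  expect_equal(got$p.value[got$term == "group"], tt$p.value, tolerance = 1e-12)
})

test_that("rank-deficient ANCOVA designs raise a design error", {
  tbl <- tibble::tibble(
    group = rep(c("control", "mtbi"), each = 5),
    visit = 1L,
    age_years = 40,                       # constant covariate
    sex = rep("M", 10),
    scat2 = rnorm(10)
  )
  expect_error(adjusted_group_effect(tbl, "scat2"),
               class = "cvrkit_error_design_error")
})

test_that("the normality gate decides and enforces its sample-size range", {
  set.seed(21)
  g <- normality_gate(rnorm(50))
  expect_true(g$decision %in% c("parametric", "nonparametric"))
  expect_equal(g$n, 50)
  ## heavy skew is flagged with high probability
  rej <- mean(replicate(200, normality_gate(rexp(50))$p.value < 0.05))
  expect_gt(rej, 0.5)
  expect_error(normality_gate(c(1, 2)), class = "cvrkit_error_unsupported_n")
  expect_error(normality_gate(rep(1, 10)), class = "cvrkit_error_undefined_w")
})

test_that("the analysis battery produces every section and counts its tests", {
  cohort <- generate_cohort(cohort_params(), seed = 30)
  res <- run_cohort_analyses(cohort)
  expect_setequal(unique(res$section),
                  c("normality", "group", "paired", "correlation", "ancova"))
  expect_true(all(res$p.value >= 0 & res$p.value <= 1, na.rm = TRUE))
  expect_gt(attr(res, "n_tests"), 10)
  expect_identical(attr(res, "multiplicity_correction"), "none")
})
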