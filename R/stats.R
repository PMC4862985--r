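## ---- Mann-Whitney core -----------------------------------------------------

## U statistic for x (first group): #{x > y} + 0.5 * #{x == y},
## computed from midranks so it matches R1 - n1(n1+1)/2
mw_u <- function(ranks, n1) {
  sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

## exact two-sided p by full enumeration over assignments of pooled values
## to group 1 (valid with ties); p = 2 * min(P(U <= u), P(U >= u)), capped
mw_exact_enum <- function(values, n1, u_obs) {
  n <- length(values)
  r <- rank(values)
  combos <- combn(n, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
  min(1, p)
}

mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- mw_u(r, n1)
  ties <- any(duplicated(pooled))
  n <- n1 + n2
  if (choose(n, n1) <= 20000) {
    method <- "mann-whitney exact (enumeration)"
    p <- mw_exact_enum(pooled, n1, u)
  } else if (!ties && n1 * n2 <= 400) {
    method <- "mann-whitney exact"
    p <- min(1, 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2)))
  } else {
    method <- "mann-whitney normal approximation (tie/continuity corrected)"
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(u = u, p = p, method = method, n1 = n1, n2 = n2)
}

#' Two-group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test of `variable` between the two groups, with
#' exact enumeration for small samples (valid under ties), the exact
#' no-ties distribution for moderate samples (`n1 * n2 <= 400`), and a tie-
#' and continuity-corrected normal approximation otherwise. The reported U
#' counts pairs won by the *first* group level (stated in `convention`).
#'
#' @param data Cohort tibble (one row per subject-visit).
#' @param variable Name of the numeric column to compare.
#' @param visit Visit to filter on (`NULL` = all rows).
#' @param group_col Grouping column (two levels; first sorted level is x).
#' @return One-row tibble: `method`, `variable`, `statistic` (U), `p.value`,
#'   `estimate` (difference in group medians, x - y), `n1`, `n2`,
#'   `convention`.
#' @export
group_compare <- function(data, variable, visit = NULL, group_col = "group") {
  if (!is.null(visit)) data <- data[data$visit == visit, , drop = FALSE]
  g <- data[[group_col]]
  lev <- if (is.factor(g)) levels(g) else sort(unique(g))
  if (length(lev) != 2L) {
    cvr_abort("`group_compare()` needs exactly two groups.", "insufficient_data")
  }
  v <- data[[variable]]
  x <- v[g == lev[1] & !is.na(v)]
  y <- v[g == lev[2] & !is.na(v)]
  if (!length(x) || !length(y)) {
    cvr_abort(sprintf("Empty group when comparing `%s`.", variable),
              "insufficient_data")
  }
  mw <- mann_whitney(x, y)
  tibble::tibble(
    method = mw$method, variable = variable,
    statistic = mw$u, p.value = mw$p,
    estimate = median(x) - median(y),
    n1 = mw$n1, n2 = mw$n2,
    convention = sprintf("U for group '%s'", lev[1])
  )
}

#' Paired comparison across visits (paired t-test)
#'
#' Two-sided paired t-test on visit-2 minus visit-1 differences for subjects
#' with both visits. Zero-variance nonzero-mean differences are reported as
#' the degenerate limit (p -> 0) with `degenerate = TRUE` rather than an
#' error, so batch reports never stall on constant shifts.
#'
#' @param data Cohort tibble with `subject_id` and `visit` columns.
#' @param variable Numeric column to compare.
#' @param visits Length-2 vector of the visit labels to pair (later minus
#'   earlier).
#' @return One-row tibble: `method`, `variable`, `statistic` (t), `df`,
#'   `p.value`, `estimate` (mean difference), `n`, `degenerate`.
#' @export
paired_compare <- function(data, variable, visits = c(1L, 2L)) {
  d1 <- data[data$visit == visits[1], c("subject_id", variable)]
  d2 <- data[data$visit == visits[2], c("subject_id", variable)]
  names(d1)[2] <- "v1"; names(d2)[2] <- "v2"
  pairs <- dplyr::inner_join(d1, d2, by = "subject_id")
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  n <- nrow(pairs)
  if (n < 2L) {
    cvr_abort(sprintf("Need >= 2 complete pairs for `%s`.", variable),
              "insufficient_data")
  }
  d <- pairs$v2 - pairs$v1
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(method = "paired t", variable = variable,
                            statistic = 0, df = n - 1, p.value = 1,
                            estimate = 0, n = n, degenerate = FALSE))
    }
    return(tibble::tibble(method = "paired t", variable = variable,
                          statistic = sign(mean(d)) * Inf, df = n - 1,
                          p.value = 0, estimate = mean(d), n = n,
                          degenerate = TRUE))
  }
  tt <- t.test(pairs$v2, pairs$v1, paired = TRUE)
  tibble::tibble(method = "paired t", variable = variable,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, estimate = unname(tt$estimate),
                 n = n, degenerate = FALSE)
}

#' Pearson correlation between two cohort variables
#'
#' Pearson product-moment correlation with a two-sided p-value from the t
#' transform, after pairwise-complete deletion and optional group/visit
#' filtering.
#'
#' @param data Cohort tibble.
#' @param x,y Names of the two numeric columns.
#' @param group Optional group filter value.
#' @param visit Optional visit filter value.
#' @return One-row tibble: `method`, `x`, `y`, `estimate` (r), `statistic`
#'   (t), `p.value`, `n`, plus the filters applied.
#' @export
correlate <- function(data, x, y, group = NULL, visit = NULL) {
  if (!is.null(group)) data <- data[data$group %in% group, , drop = FALSE]
  if (!is.null(visit)) data <- data[data$visit %in% visit, , drop = FALSE]
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) {
    cvr_abort(sprintf("Need >= 3 complete pairs to correlate %s and %s.", x, y),
              "insufficient_data")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    cvr_abort(sprintf("Correlation between %s and %s is undefined: zero variance.",
                      x, y), "undefined_correlation")
  }
  ct <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(method = "pearson", x = x, y = y,
                 estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value, n = n,
                 group = if (is.null(group)) NA_character_ else paste(group, collapse = "+"),
                 visit = if (is.null(visit)) NA_integer_ else as.integer(visit[1]))
}

#' Covariate-adjusted group effect (additive ANCOVA)
#'
#' Fits the additive linear model `response ~ group + covariates` by least
#' squares and reports type-II partial F statistics per term (for an
#' additive model these are the drop-one F tests). Sex enters as a factor
#' (two-level 0/1 indicator).
#'
#' @param data Cohort tibble.
#' @param response Name of the response column (e.g. `"scat2"`).
#' @param covariates Character vector of covariate columns
#'   (default `c("age_years", "sex")`).
#' @param group_col Grouping column.
#' @param visit Visit filter (default 1).
#' @return A tibble with one row per model term: `method`, `response`,
#'   `term`, `df`, `statistic` (partial F), `p.value`, `n`.
#' @export
adjusted_group_effect <- function(data, response, covariates = c("age_years", "sex"),
                                  group_col = "group", visit = 1L) {
  if (!is.null(visit)) data <- data[data$visit == visit, , drop = FALSE]
  cols <- c(response, group_col, covariates)
  df <- data[cols]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df[[group_col]] <- factor(df[[group_col]])
  if ("sex" %in% names(df)) df$sex <- factor(df$sex)
  if (nlevels(df[[group_col]]) < 2L || min(table(df[[group_col]])) < 2L) {
    cvr_abort("Need >= 2 subjects in each group.", "insufficient_data")
  }
  for (cv in covariates) {
    if (length(unique(df[[cv]])) < 2L) {
      cvr_abort(sprintf("Covariate `%s` is constant: rank-deficient design.", cv),
                "design_error")
    }
  }
  fml <- stats::reformulate(c(group_col, covariates), response = response)
  fit <- lm(fml, data = df)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    cvr_abort("Rank-deficient design: collinear or constant terms.", "design_error")
  }
  dr <- drop1(fit, scope = fml, test = "F")
  terms <- rownames(dr)[-1]
  ## coefficient and SE for single-df terms (NA for multi-level factors)
  asg <- attr(stats::model.matrix(fit), "assign")
  sm <- summary(fit)$coefficients
  est <- se <- rep(NA_real_, length(terms))
  for (i in seq_along(terms)) {
    cols <- which(asg == i)
    if (length(cols) == 1L) {
      est[i] <- sm[cols, 1]
      se[i] <- sm[cols, 2]
    }
  }
  tibble::tibble(
    method = "ancova type-II partial F", response = response,
    term = terms, df = dr$Df[-1],
    statistic = dr$`F value`[-1], p.value = dr$`Pr(>F)`[-1],
    estimate = est, std.error = se, n = nrow(df)
  )
}

#' Shapiro-Wilk normality gate
#'
#' Tests normality and returns the decision used to pick the comparison
#' family downstream: `"parametric"` iff `p >= alpha`.
#'
#' @param values Numeric vector (3 to 5000 non-missing values).
#' @param alpha Gate level (default 0.05).
#' @return One-row tibble: `method`, `statistic` (W), `p.value`, `n`,
#'   `decision`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    cvr_abort("Shapiro-Wilk supports 3 <= n <= 5000.", "unsupported_n")
  }
  if (sd(values) == 0) {
    cvr_abort("Shapiro-Wilk W is undefined for constant input.", "undefined_w")
  }
  sw <- shapiro.test(values)
  tibble::tibble(method = "shapiro-wilk", statistic = unname(sw$statistic),
                 p.value = sw$p.value, n = n,
                 decision = ifelse(sw$p.value >= alpha, "parametric", "nonparametric"))
}

## ---- analysis battery ------------------------------------------------------

#' Demographic summary of a cohort table
#'
#' Per-group counts and the percentages derived from them (visit 1): N,
#' males with percentage, age mean/SD, and days post-injury mean/SD where
#' recorded.
#'
#' @param cohort Cohort tibble.
#' @return A tibble, one row per group.
#' @export
summarize_demographics <- function(cohort) {
  cohort |>
    dplyr::filter(.data$visit == 1) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_male = sum(.data$sex == "M"),
      male_pct = 100 * sum(.data$sex == "M") / dplyr::n(),
      age_mean = mean(.data$age_years),
      age_sd = sd(.data$age_years),
      days_post_injury_mean = mean(.data$days_post_injury),
      days_post_injury_sd = sd(.data$days_post_injury),
      .groups = "drop"
    )
}

## run one battery entry; degenerate inputs yield an NA row instead of
## aborting the whole report
safe_stat <- function(expr, method, ...) {
  tryCatch(expr, cvrkit_error = function(e) {
    tibble::tibble(method = paste0(method, " (not computable)"),
                   statistic = NA_real_, p.value = NA_real_, ...,
                   note = conditionMessage(e))
  })
}

#' Run the full cohort statistical battery
#'
#' Reproduces a standard observational-study analysis on a cohort table:
#' (1) per-group Shapiro-Wilk normality gates for each imaging/symptom
#' variable at visit 1, choosing Welch t (both groups parametric) or
#' Mann-Whitney for the group comparison; (2) paired t-tests across visits
#' within the follow-up subjects; (3) Pearson correlations of SCAT2 with
#' tissue CVR indexes per group, SCAT2 with GM volume per group, WM CVR with
#' WM volume in the patient group, and age with SCAT2 per group; (4) an
#' additive ANCOVA of SCAT2 on group, age and sex. No multiple-testing
#' correction is applied; the number of tests run is recorded in the
#' `n_tests` attribute.
#'
#' @param cohort Cohort tibble (as from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param alpha Normality-gate level.
#' @param variables Variables entered into group and paired comparisons.
#' @return A tibble of stacked test results with a `section` column
#'   (`normality`, `group`, `paired`, `correlation`, `ancova`).
#' @export
run_cohort_analyses <- function(cohort,
                                alpha = 0.05,
                                variables = c("sss", "scat2", "wm_cvr", "gm_cvr",
                                              "brain_cvr", "wm_volume_cm3",
                                              "gm_volume_cm3")) {
  groups <- sort(unique(cohort$group[cohort$visit == 1]))
  res <- list()

  ## normality gates + group comparisons at visit 1
  for (v in variables) {
    gates <- purrr::map_dfr(groups, function(g) {
      vals <- cohort[[v]][cohort$group == g & cohort$visit == 1]
      gate <- tryCatch(normality_gate(vals, alpha),
                       cvrkit_error = function(e) {
                         tibble::tibble(method = "shapiro-wilk", statistic = NA_real_,
                                        p.value = NA_real_, n = length(vals),
                                        decision = "nonparametric")
                       })
      dplyr::mutate(gate, section = "normality", variable = v, group = g)
    })
    res[[length(res) + 1L]] <- gates
    parametric <- all(gates$decision == "parametric")
    cmp <- safe_stat({
      if (parametric) {
        x <- cohort[[v]][cohort$group == groups[1] & cohort$visit == 1]
        y <- cohort[[v]][cohort$group == groups[2] & cohort$visit == 1]
        tt <- t.test(x, y)
        tibble::tibble(method = "welch t", variable = v,
                       statistic = unname(tt$statistic), p.value = tt$p.value,
                       estimate = mean(x) - mean(y),
                       n1 = length(x), n2 = length(y),
                       convention = sprintf("t for group '%s' minus '%s'",
                                            groups[1], groups[2]))
      } else {
        group_compare(cohort, v, visit = 1)
      }
    }, "group comparison", variable = v)
    res[[length(res) + 1L]] <- dplyr::mutate(cmp, section = "group")
  }

  ## paired comparisons across visits (follow-up subjects)
  if (any(cohort$visit == 2)) {
    for (v in setdiff(variables, "sss")) {
      res[[length(res) + 1L]] <- dplyr::mutate(
        safe_stat(paired_compare(cohort[cohort$group == "mtbi", ], v),
                  "paired t", variable = v),
        section = "paired")
    }
  }

  ## correlation battery
  corr_specs <- list(
    list(x = "scat2", y = "wm_cvr"), list(x = "scat2", y = "gm_cvr"),
    list(x = "scat2", y = "brain_cvr"), list(x = "scat2", y = "gm_volume_cm3"),
    list(x = "age_years", y = "scat2")
  )
  for (g in groups) {
    for (sp in corr_specs) {
      res[[length(res) + 1L]] <- dplyr::mutate(
        safe_stat(correlate(cohort, sp$x, sp$y, group = g, visit = 1),
                  "pearson", x = sp$x, y = sp$y, group = g),
        section = "correlation")
    }
  }
  if ("mtbi" %in% groups) {
    res[[length(res) + 1L]] <- dplyr::mutate(
      safe_stat(correlate(cohort, "wm_cvr", "wm_volume_cm3",
                          group = "mtbi", visit = 1),
                "pearson", x = "wm_cvr", y = "wm_volume_cm3", group = "mtbi"),
      section = "correlation")
  }

  ## covariate-adjusted group effect on symptoms
  res[[length(res) + 1L]] <- dplyr::mutate(
    safe_stat(adjusted_group_effect(cohort, "scat2"),
              "ancova", response = "scat2"),
    section = "ancova")

  out <- dplyr::bind_rows(res)
  out <- dplyr::relocate(out, "section")
  attr(out, "n_tests") <- sum(!is.na(out$p.value) & out$section != "normality")
  attr(out, "multiplicity_correction") <- "none"
  out
}
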