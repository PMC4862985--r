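## variables drawn jointly from the per-group Gaussian copula, fixed order
COHORT_VARS <- c("age_years", "scat2", "sss", "wm_cvr", "gm_cvr", "brain_cvr",
                 "wm_volume_cm3", "gm_volume_cm3", "petco2_min", "petco2_max")

cor_tbl <- function(group, var1, var2, r) {
  tibble::tibble(group = group, var1 = var1, var2 = var2, r = r)
}

default_cor_targets <- function() {
  dplyr::bind_rows(
    cor_tbl("control", "scat2", c("wm_cvr", "gm_cvr", "brain_cvr", "gm_volume_cm3"),
            c(-0.59, -0.56, -0.58, 0.29)),
    cor_tbl("control", "age_years", "scat2", -0.60),
    cor_tbl("mtbi", "scat2", c("gm_cvr", "brain_cvr", "gm_volume_cm3"),
            c(0.40, 0.40, 0.52)),
    cor_tbl("mtbi", "wm_cvr", "wm_volume_cm3", -0.46),
    cor_tbl("mtbi", "age_years", "scat2", -0.62)
  )
}

default_moments <- function(mtbi_variant) {
  m <- tibble::tribble(
    ~variable,          ~control_mean, ~control_sd, ~mtbi_mean, ~mtbi_sd, ~mtbi2_mean, ~mtbi2_sd,
    "age_years",        38.7,  12.6,  42.7,   16.3,   NA,     NA,
    "scat2",            91.5,   5.7,  72.76,  10.9,   77.8,   14.22,
    "sss",               5.28, 10.2,  35.72,  24.8,   35.72,  24.8,
    "wm_cvr",            0.160, 0.04,  0.1472, 0.05,   0.1468, 0.04,
    "gm_cvr",            0.28,  0.06,  0.26,   0.091,  0.25,   0.074,
    "brain_cvr",         0.215, 0.04,  0.20,   0.072,  0.20,   0.05,
    "wm_volume_cm3",   417.1,  47.2, 413.83,  48.8,  410.97,  53.9,
    "gm_volume_cm3",   375.2,  40.8, 365.14,  47.4,  351.4,   42.3,
    "petco2_min",       34.94,  3.36, 34.63,   5.03,  34.63,   5.03,
    "petco2_max",       44.0,   4.04, 44.70,   3.67,  44.70,   3.67
  )
  ## the two readings of the mTBI visit-1 column (full cohort vs the n=19
  ## follow-up subset) carry identical printed moments, so the variants
  ## differ only in labelling; both are exposed for transparency
  attr(m, "mtbi_variant") <- mtbi_variant
  m
}

build_cor_matrix <- function(targets, group) {
  k <- length(COHORT_VARS)
  R <- diag(k)
  dimnames(R) <- list(COHORT_VARS, COHORT_VARS)
  tg <- targets[targets$group == group, , drop = FALSE]
  for (i in seq_len(nrow(tg))) {
    R[tg$var1[i], tg$var2[i]] <- R[tg$var2[i], tg$var1[i]] <- tg$r[i]
  }
  R
}

is_psd <- function(R, tol = 1e-8) {
  min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

#' Parameters for the synthetic cohort generator
#'
#' Defaults encode a two-group mTBI/control observational study: group sizes
#' 18 controls and 25 mTBI with 19 mTBI follow-ups; per-group means and SDs
#' for symptom scores (SCAT2, SSS), tissue CVR indexes, tissue volumes,
#' demographics, and achieved PetCO2 extremes; and a per-group target
#' correlation structure (negative SCAT2-CVR correlation in controls,
#' positive in mTBI, positive SCAT2-GM-volume and negative WM-CVR-WM-volume
#' correlation in mTBI, negative age-SCAT2 everywhere). Correlations not
#' specified are 0. Completed matrices that are not positive semi-definite
#' are projected to the nearest correlation matrix (the star of strong SCAT2
#' correlations in controls is infeasible as written), and the projected
#' matrix becomes the generator's target; set `project_psd = FALSE` to keep
#' the raw matrix and let [generate_cohort()] refuse it.
#'
#' @param n_control,n_mtbi,n_followup Group sizes; follow-up subjects are a
#'   random subset of the mTBI group.
#' @param male_fraction Named per-group fractions of male subjects; exact
#'   male counts are `round(n * fraction)` (11/18 controls and 18/25 mTBI at
#'   the default sizes).
#' @param moments Tibble of per-variable means/SDs (see
#'   `cvrkit:::default_moments`); `mtbi2_*` columns are visit-2 mTBI moments.
#' @param cor_targets Tibble `group, var1, var2, r` of target correlations.
#' @param test_retest Named per-variable visit-1/visit-2 latent correlations.
#'   Anatomical volumes default to 0.95 (volumes are highly reproducible;
#'   this also reproduces the observed power of the paired GM-volume
#'   decline), functional CVR indexes and scores to 0.7, PetCO2 to 0.5.
#' @param mtbi_variant Labelling of the mTBI visit-1 column: `"full-cohort"`
#'   or `"followup-subset"` (identical moments; kept as named variants).
#' @param project_psd Project infeasible correlation matrices to the nearest
#'   correlation matrix at construction (default `TRUE`).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_params` object; `$cor_matrix` holds the per-group
#'   target matrices actually used, `$cor_targets_achieved` the originally
#'   requested pairs with their post-projection values.
#' @export
cohort_params <- function(n_control = 18, n_mtbi = 25, n_followup = 19,
                          male_fraction = c(control = 11 / 18, mtbi = 18 / 25),
                          moments = NULL,
                          cor_targets = default_cor_targets(),
                          test_retest = NULL,
                          mtbi_variant = c("full-cohort", "followup-subset"),
                          project_psd = TRUE,
                          seed = 1L) {
  mtbi_variant <- match.arg(mtbi_variant)
  n_control <- check_count(n_control, "n_control", min = 2L)
  n_mtbi <- check_count(n_mtbi, "n_mtbi", min = 2L)
  n_followup <- check_count(n_followup, "n_followup", min = 0L)
  if (n_followup > n_mtbi) {
    cvr_abort("`n_followup` cannot exceed `n_mtbi`.", "params_error")
  }
  moments <- moments %||% default_moments(mtbi_variant)
  if (any(c(moments$control_sd, moments$mtbi_sd) < 0, na.rm = TRUE)) {
    cvr_abort("SDs must be >= 0.", "params_error")
  }
  if (any(abs(cor_targets$r) >= 1)) {
    cvr_abort("Target correlations must have |r| < 1.", "params_error")
  }
  bad <- setdiff(c(cor_targets$var1, cor_targets$var2), COHORT_VARS)
  if (length(bad)) {
    cvr_abort(sprintf("Unknown correlation variables: %s.", paste(bad, collapse = ", ")),
              "params_error")
  }
  test_retest <- modifyList(
    list(scat2 = 0.7, sss = 0.7, wm_cvr = 0.7, gm_cvr = 0.7, brain_cvr = 0.7,
         wm_volume_cm3 = 0.95, gm_volume_cm3 = 0.95,
         petco2_min = 0.5, petco2_max = 0.5),
    as.list(test_retest %||% list())
  )

  cor_matrix <- list()
  projected <- c(control = FALSE, mtbi = FALSE)
  for (g in c("control", "mtbi")) {
    R <- build_cor_matrix(cor_targets, g)
    if (!is_psd(R)) {
      if (project_psd) {
        R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
        dimnames(R) <- list(COHORT_VARS, COHORT_VARS)
        projected[g] <- TRUE
      }
    }
    cor_matrix[[g]] <- R
  }
  achieved <- cor_targets
  achieved$r_achieved <- purrr::map_dbl(seq_len(nrow(achieved)), function(i) {
    cor_matrix[[achieved$group[i]]][achieved$var1[i], achieved$var2[i]]
  })

  structure(
    list(n_control = n_control, n_mtbi = n_mtbi, n_followup = n_followup,
         male_fraction = male_fraction, moments = moments,
         cor_targets = cor_targets, cor_matrix = cor_matrix,
         cor_targets_achieved = achieved, projected = projected,
         test_retest = test_retest, mtbi_variant = mtbi_variant,
         days_visit1 = c(mean = 63.5, sd = 42),
         days_visit2 = c(mean = 180, sd = 38),
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

## draw n rows from the latent Gaussian with correlation R (columns = vars)
draw_latent <- function(n, R) {
  L <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(rnorm(n * ncol(R)), n, ncol(R)) %*% L
  colnames(Z) <- colnames(R)
  Z
}

latent_to_values <- function(Z, means, sds) {
  X <- sweep(sweep(Z, 2, sds[colnames(Z)], `*`), 2, means[colnames(Z)], `+`)
  tibble::as_tibble(X)
}

#' Generate a synthetic subject cohort
#'
#' Subjects are drawn from a per-group Gaussian copula (latent multivariate
#' normal mapped to the requested marginal means and SDs) so the cohort
#' reproduces the configured correlation structure in expectation. Sex is
#' assigned by exact per-group male counts (shuffled). Visit-2 records for a
#' random subset of mTBI subjects are generated as correlated innovations on
#' the visit-1 latents (per-variable test-retest correlations) with visit-2
#' marginal moments, so paired comparisons behave realistically. SCAT2 is
#' clamped to [0, 100] and volumes to positive values; SSS is left Gaussian.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A tibble, one row per subject-visit, with columns `subject_id`,
#'   `group`, `visit`, `age_years`, `sex`, `days_post_injury`, `scat2`,
#'   `sss`, `wm_cvr`, `gm_cvr`, `brain_cvr`, `wm_volume_cm3`,
#'   `gm_volume_cm3`, `petco2_min`, `petco2_max`.
#' @examples
#' cohort <- generate_cohort(cohort_params(), seed = 7)
#' dplyr::count(cohort, group, visit)
#' @export
generate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  for (g in c("control", "mtbi")) {
    if (!is_psd(params$cor_matrix[[g]])) {
      cvr_abort(
        sprintf(paste0("Target correlation matrix for group `%s` is not positive ",
                       "semi-definite; project it first, e.g. ",
                       "as.matrix(Matrix::nearPD(R, corr = TRUE)$mat) or rebuild ",
                       "cohort_params() with project_psd = TRUE."), g),
        "params_error"
      )
    }
  }
  set.seed(seed %||% params$seed)
  mom <- params$moments
  get_mom <- function(prefix) {
    stats::setNames(mom[[paste0(prefix, "_mean")]], mom$variable)
  }
  get_sd <- function(prefix) {
    stats::setNames(mom[[paste0(prefix, "_sd")]], mom$variable)
  }

  make_group <- function(g, n, id_prefix) {
    Z <- draw_latent(n, params$cor_matrix[[g]])
    X <- latent_to_values(Z, get_mom(if (g == "control") "control" else "mtbi"),
                          get_sd(if (g == "control") "control" else "mtbi"))
    n_male <- round(n * unname(params$male_fraction[[g]]))
    sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    days <- if (g == "mtbi") {
      pmax(1, rnorm(n, params$days_visit1["mean"], params$days_visit1["sd"]))
    } else rep(NA_real_, n)
    rec <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("%s%02d", id_prefix, seq_len(n)),
                     group = g, visit = 1L, sex = sex,
                     days_post_injury = days),
      X
    )
    list(records = rec, Z = Z)
  }

  ctrl <- make_group("control", params$n_control, "C")
  tbi <- make_group("mtbi", params$n_mtbi, "T")

  records <- dplyr::bind_rows(ctrl$records, tbi$records)

  if (params$n_followup > 0) {
    idx <- sort(sample(params$n_mtbi, params$n_followup))
    rho <- unlist(params$test_retest)[COHORT_VARS[-1]]  # age handled directly
    E <- draw_latent(params$n_followup, params$cor_matrix$mtbi)
    Z1 <- tbi$Z[idx, , drop = FALSE]
    Z2 <- Z1
    for (v in names(rho)) {
      Z2[, v] <- rho[[v]] * Z1[, v] + sqrt(1 - rho[[v]]^2) * E[, v]
    }
    means2 <- get_mom("mtbi2"); sds2 <- get_sd("mtbi2")
    ## variables without stated visit-2 moments keep their visit-1 moments
    m1 <- get_mom("mtbi"); s1 <- get_sd("mtbi")
    means2[is.na(means2)] <- m1[is.na(means2)]
    sds2[is.na(sds2)] <- s1[is.na(sds2)]
    X2 <- latent_to_values(Z2, means2, sds2)
    v1 <- tbi$records[idx, ]
    delta_days <- (params$days_visit2["mean"] - params$days_visit1["mean"]) / 365.25
    rec2 <- dplyr::bind_cols(
      tibble::tibble(subject_id = v1$subject_id, group = "mtbi", visit = 2L,
                     sex = v1$sex,
                     days_post_injury = pmax(
                       v1$days_post_injury + 1,
                       rnorm(params$n_followup, params$days_visit2["mean"],
                             params$days_visit2["sd"]))),
      X2
    )
    rec2$age_years <- v1$age_years + delta_days
    records <- dplyr::bind_rows(records, rec2)
  }

  records$scat2 <- pmin(100, pmax(0, records$scat2))
  records$wm_volume_cm3 <- pmax(1e-6, records$wm_volume_cm3)
  records$gm_volume_cm3 <- pmax(1e-6, records$gm_volume_cm3)
  out <- records[, c("subject_id", "group", "visit", "age_years", "sex",
                     "days_post_injury", "scat2", "sss", "wm_cvr", "gm_cvr",
                     "brain_cvr", "wm_volume_cm3", "gm_volume_cm3",
                     "petco2_min", "petco2_max")]
  structure(out, params = params, class = c("cvr_cohort", class(out)))
}

#' Read / write a cohort table as CSV
#'
#' One row per subject-visit with the documented column set of
#' [generate_cohort()].
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort_csv()` returns a tibble; the writer returns the path
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "visit", "scat2")
  if (!all(need %in% names(df))) {
    cvr_abort(sprintf("Cohort CSV must include columns %s.",
                      paste(need, collapse = ", ")), "invalid_argument")
  }
  tibble::as_tibble(df)
}
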