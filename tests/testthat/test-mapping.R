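test_that("an exactly linear voxel is recovered to machine precision", {
  reg <- default_regressor(120)
  x <- regressor_values(reg)
  base_idx <- which(x == 35)
  for (c_true in c(0.28, 0.16, -0.1, 2.5)) {
    for (s0 in c(1, 500, 1e4)) {
      ts <- s0 * (1 + c_true / 100 * (x - 35))
      fit <- fit_voxel(ts, reg, baseline_volumes = base_idx)
      expect_equal(fit$slope_pct_per_mmHg, c_true, tolerance = 1e-12)
      expect_equal(abs(fit$rvalue), 1, tolerance = 1e-12)
      expect_equal(sign(fit$rvalue), sign(c_true))
    }
  }
})

test_that("negating the response negates slope and r; constants are degenerate", {
  reg <- default_regressor(80)
  set.seed(3)
  ts <- 700 + 2 * regressor_values(reg) + rnorm(80, sd = 5)
  f1 <- fit_voxel(ts, reg)
  f2 <- fit_voxel(2 * mean(ts) - ts, reg)   # reflect around the mean
  expect_equal(f2$slope_pct_per_mmHg, -f1$slope_pct_per_mmHg, tolerance = 1e-10)
  expect_equal(f2$rvalue, -f1$rvalue, tolerance = 1e-10)

  fc <- fit_voxel(rep(500, 80), reg)
  expect_equal(fc$slope_pct_per_mmHg, 0)
  expect_equal(fc$rvalue, 0)
  expect_true(fc$degenerate && fc$valid)

  expect_error(fit_voxel(ts, rep(40, 80)), class = "cvrkit_error_invalid_argument")
})

test_that("map slopes and r equal the closed-form OLS oracle on every voxel", {
  bold <- random_bold(c(6, 6, 4), n_t = 60, seed = 21)
  reg <- default_regressor(60)
  x <- regressor_values(reg)
  base_idx <- which(x == 35)
  map <- compute_cvr_map(bold, reg, qc = qc_spec(n_discard = 0),
                         baseline_mmHg = 35)
  for (v in seq_len(prod(dim(bold$data)[1:3]))) {
    idx <- arrayInd(v, dim(bold$data)[1:3])
    ts <- bold$data[idx[1], idx[2], idx[3], ]
    oracle <- ols_oracle(ts, x, base_idx)
    expect_equal(map$slope[idx], unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(map$rvalue[idx], unname(oracle["r"]), tolerance = 1e-10)
  }
  expect_true(all(abs(map$rvalue) <= 1))
})

test_that("slope is invariant to a positive gain on the whole series", {
  bold <- random_bold(c(4, 4, 3), n_t = 60, seed = 5)
  reg <- default_regressor(60)
  m1 <- compute_cvr_map(bold, reg, qc = qc_spec(n_discard = 0))
  bold2 <- bold
  bold2$data <- bold$data * 7.5
  m2 <- compute_cvr_map(bold2, reg, qc = qc_spec(n_discard = 0))
  expect_equal(m2$slope, m1$slope, tolerance = 1e-10)
  expect_equal(m2$rvalue, m1$rvalue, tolerance = 1e-12)
})

test_that("noise propagates into slope spread as the OLS standard error predicts", {
  reg <- default_regressor(252)
  x <- regressor_values(reg)
  n_vox <- 600
  s0 <- 1000
  sigma <- 12
  set.seed(77)
  dims <- c(10, 10, 6)
  arr <- array(s0 + rnorm(prod(dims) * 252, sd = sigma), c(dims, 252))
  bold <- bold_image(arr, c(3.6, 3.6, 3), 2)
  map <- compute_cvr_map(bold, reg, qc = qc_spec(n_discard = 0),
                         baseline_mmHg = 35)
  emp_sd <- sd(map$slope[map$valid])
  ## sd of the percent slope: 100/S0 * sigma / sqrt(Sxx)
  pred_sd <- 100 / s0 * sigma / sqrt(sum((x - mean(x))^2))
  expect_gt(sum(map$valid), 500)
  expect_lt(abs(emp_sd - pred_sd) / pred_sd, 0.2)
})

test_that("censoring volumes equals fitting the pre-shortened series", {
  reg <- default_regressor(100)
  set.seed(9)
  ts <- 800 + 1.5 * regressor_values(reg) + rnorm(100, sd = 10)
  drop <- c(10, 11, 50, 83)
  arr <- array(ts, c(1, 1, 1, 100))
  out <- apply_qc(bold_image(arr, c(1, 1, 1), 2), reg,
                  qc_spec(n_discard = 0, censor_volumes = drop), min_remaining = 10)
  f_censored <- fit_voxel(out$bold$data[1, 1, 1, ], out$regressor)
  f_manual <- fit_voxel(ts[-drop], regressor_values(reg)[-drop])
  expect_equal(f_censored$slope_pct_per_mmHg, f_manual$slope_pct_per_mmHg)
  expect_equal(f_censored$rvalue, f_manual$rvalue)
})

test_that("mask handling: empty masks fit nothing, grid mismatches error", {
  bold <- random_bold(c(4, 4, 3), n_t = 60)
  reg <- default_regressor(60)
  m_empty <- compute_cvr_map(bold, reg, qc = qc_spec(n_discard = 0),
                             mask = array(FALSE, c(4, 4, 3)))
  expect_false(any(m_empty$valid))
  expect_true(all(is.na(m_empty$slope)))

  expect_error(compute_cvr_map(bold, reg, mask = array(TRUE, c(5, 5, 3))),
               class = "cvrkit_error_grid_mismatch")
})

test_that("lag search recovers a known hemodynamic delay", {
  reg <- default_regressor(150)
  x <- regressor_values(reg)
  lag_true <- 2L
  x_lag <- x[pmin(pmax(seq_along(x) - lag_true, 1L), length(x))]
  dims <- c(4, 4, 3)
  set.seed(12)
  arr <- array(0, c(dims, 150))
  for (v in seq_len(prod(dims))) {
    idx <- arrayInd(v, dims)
    arr[idx[1], idx[2], idx[3], ] <- 1000 * (1 + 0.25 / 100 * (x_lag - 35)) +
      rnorm(150, sd = 1)
  }
  bold <- bold_image(arr, c(3.6, 3.6, 3), 2)
  map <- compute_cvr_map(bold, reg, qc = qc_spec(n_discard = 0),
                         baseline_mmHg = 35, lag_search = TRUE, max_lag = 5)
  expect_equal(map$qc_report$lag_volumes, lag_true)
  expect_equal(mean(map$slope[map$valid]), 0.25, tolerance = 0.01)
})
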