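test_that("simulated traces are reproducible and hit scheduled plateaus", {
  p <- hypercapnia_protocol()
  t1 <- simulate_capnograph(p, noise_sd_mmHg = 0.5, seed = 42)
  t2 <- simulate_capnograph(p, noise_sd_mmHg = 0.5, seed = 42)
  expect_identical(t1, t2)

  ## noiseless flat protocol at 40 mmHg: every plateau maximum is 40
  flat <- hypercapnia_protocol(baseline_mmHg = 40, step_mmHg = 0)
  tr <- simulate_capnograph(flat, noise_sd_mmHg = 0)
  expect_equal(max(tr$pco2_mmHg), 40)
  expect_true(all(attr(tr, "plateau_mmHg") == 40))

  ## noiseless default protocol: plateau levels span baseline..baseline+10
  tr <- simulate_capnograph(p, noise_sd_mmHg = 0)
  expect_setequal(unique(attr(tr, "plateau_mmHg")), c(35, 45))
})

test_that("end-tidal detection recovers generator plateau values exactly", {
  p <- hypercapnia_protocol()
  tr <- simulate_capnograph(p, noise_sd_mmHg = 0, breath_rate_per_min = 15)
  et <- detect_end_tidal(tr)
  ## oracle: per-breath argmax over the generator's own breath windows
  plateau <- attr(tr, "plateau_mmHg")
  starts <- attr(tr, "breath_start_s")
  period <- attr(tr, "breath_period_s")
  oracle <- vapply(seq_along(starts), function(k) {
    sel <- tr$time_s >= starts[k] & tr$time_s < starts[k] + period
    max(tr$pco2_mmHg[sel])
  }, numeric(1))
  expect_equal(oracle, plateau)              # generator sanity
  expect_equal(nrow(et), length(plateau))
  expect_equal(et$petco2_mmHg, plateau)      # machine-precision recovery
  expect_true(all(diff(et$breath_time_s) >= 2))
  ## detected range brackets the protocol span
  expect_equal(range(et$petco2_mmHg), c(35, 45))
})

test_that("breathless traces raise a detection failure", {
  flatline <- tibble::tibble(time_s = seq(0, 30, 0.1), pco2_mmHg = 40)
  expect_error(detect_end_tidal(flatline), class = "cvrkit_error_detection_failure")
  ## a single breath is not enough to build a series
  one <- simulate_capnograph(hypercapnia_protocol(), duration_s = 4.5,
                             noise_sd_mmHg = 0)
  expect_error(detect_end_tidal(one), class = "cvrkit_error_detection_failure")
})

test_that("TR resampling is exact for constant and affine end-tidal series", {
  const <- tibble::tibble(breath_time_s = seq(0, 100, 4), petco2_mmHg = 40)
  reg <- resample_to_tr(const, tr_s = 2, n_volumes = 50)
  expect_true(all(reg$petco2_mmHg == 40))

  ## midpoint of a linear segment: (0, 30) to (100, 40) gives 35 at t = 50
  two <- tibble::tibble(breath_time_s = c(0, 100), petco2_mmHg = c(30, 40))
  reg <- resample_to_tr(two, tr_s = 4, n_volumes = 25)
  expect_equal(reg$petco2_mmHg[reg$time_s == 50], 35)

  ## affine series reproduced exactly at interior volumes, flat at the edges
  et <- tibble::tibble(breath_time_s = seq(2, 198, 4))
  et$petco2_mmHg <- 38 + 0.02 * et$breath_time_s
  reg <- resample_to_tr(et, tr_s = 2, n_volumes = 100)
  interior <- reg$time_s >= min(et$breath_time_s) & reg$time_s <= max(et$breath_time_s)
  expect_equal(reg$petco2_mmHg[interior], 38 + 0.02 * reg$time_s[interior])
  expect_true(all(reg$petco2_mmHg[!interior] %in%
                    c(et$petco2_mmHg[1], et$petco2_mmHg[nrow(et)])))

  expect_error(resample_to_tr(const[1, ], 2, 10),
               class = "cvrkit_error_invalid_argument")
})

test_that("capno-to-regressor round trip reproduces the schedule away from steps", {
  p <- hypercapnia_protocol()
  sched <- build_protocol_waveform(p, tr_s = 2, n_volumes = 255)
  trace <- simulate_capnograph(p, noise_sd_mmHg = 0)
  reg <- resample_to_tr(detect_end_tidal(trace), tr_s = 2, n_volumes = 255)
  ## exclude volumes within two breath periods of a block transition, where
  ## breath-wise sampling and linear interpolation smooth the square step
  edges <- c(60, 105, 195, 325)
  away <- vapply(sched$time_s, function(t) min(abs(t - edges)) > 8, logical(1))
  expect_equal(reg$petco2_mmHg[away], sched$petco2_mmHg[away], tolerance = 1e-8)
})

test_that("trace and regressor CSV round trips preserve values", {
  dir <- withr::local_tempdir()
  p <- hypercapnia_protocol()
  trace <- simulate_capnograph(p, noise_sd_mmHg = 0.3, seed = 5)
  f <- file.path(dir, "capno.csv")
  write_capno_csv(trace, f)
  back <- read_capno_csv(f)
  expect_equal(back$pco2_mmHg, trace$pco2_mmHg)

  reg <- build_protocol_waveform(p, 2, 100)
  g <- file.path(dir, "petco2.csv")
  write_regressor_csv(reg, g)
  reg2 <- read_regressor_csv(g)
  expect_equal(reg2$petco2_mmHg, reg$petco2_mmHg)
  expect_equal(attr(reg2, "tr_s"), 2)
})
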