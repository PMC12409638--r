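# Preprocessing operators and pipeline composition.

test_that("normalize_oh is an identity at unit reference and scale-invariant", {
  w <- default_axis()
  y <- rep(1, 3101) + 0.5 * exp(-0.5 * ((w - 980) / 5)^2)
  s <- raman_spectrum(w, y) # I(3299) = 1 (flat away from 980)
  out <- normalize_oh(s, 3299)
  expect_equal(out$intensity, s$intensity, tolerance = 1e-12)

  s5 <- s; s5$intensity <- 5 * s$intensity
  expect_equal(normalize_oh(s5, 3299)$intensity, out$intensity,
               tolerance = 1e-12)

  neg <- s; neg$intensity <- s$intensity - 2
  expect_error(normalize_oh(neg, 3299), "reference intensity")
  expect_error(normalize_oh(s, 3299.5), "not on axis")
})

test_that("normalize_oh equalises noiseless spectra across exposure times", {
  cfg <- noiseless_config()
  a <- generate_spectrum(c(ams = 0.3, tris = 1.1), 175, cfg)
  b <- generate_spectrum(c(ams = 0.3, tris = 1.1), 625, cfg) # below clipping
  na <- normalize_oh(a, 3299)
  nb <- normalize_oh(b, 3299)
  expect_lt(max(abs(na$intensity - nb$intensity)), 1e-6)
})

test_that("savgol_smooth reproduces quadratics and matches the local LS oracle", {
  x <- 1:200
  y <- 2 * x^2 + 3 * x + 1
  s <- raman_spectrum(x, y)
  sm <- savgol_smooth(s, 11, 2)
  expect_lt(max(abs(sm$intensity - y)), 1e-9 * max(abs(y)))

  yr <- withr::with_seed(3, rnorm(50))
  sr <- raman_spectrum(1:50, yr)
  expect_lt(max(abs(savgol_smooth(sr, 11, 2)$intensity[1, ] -
                      sg_local_ls_oracle(yr, 11, 2))), 1e-9)

  noisy <- withr::with_seed(4, raman_spectrum(1:500, rnorm(500)))
  expect_lt(stats::var(savgol_smooth(noisy, 11, 2)$intensity[1, ]),
            stats::var(noisy$intensity[1, ]))

  expect_error(savgol_smooth(s, 10, 2), "odd")
  expect_error(savgol_smooth(s, 3, 4), "odd|polyorder")
})

test_that("per-segment smoothing rejects segments shorter than the window", {
  s <- raman_spectrum(c(1:6, 100:160), rnorm(67))
  expect_error(savgol_smooth(s, 11, 2, per_segment = TRUE), "segment")
  expect_silent(savgol_smooth(s, 5, 2, per_segment = TRUE))
})

test_that("precrop removes intervals and tracks segments on the 1/cm grid", {
  s <- raman_spectrum(default_axis(), rnorm(3101))
  p1 <- precrop(s, c(920, 1030))
  expect_length(p1$wavenumber, 3101 - 111)
  expect_equal(p1$segments, cbind(lo = c(200, 1031), hi = c(919, 3300)))

  p2 <- precrop(s, c(920, 1200))
  expect_equal(p2$segments, cbind(lo = c(200, 1201), hi = c(919, 3300)))

  expect_equal(precrop(s, list())$intensity, s$intensity)
  expect_error(precrop(s, c(0, 5000)), "entire axis")
})

test_that("crop retains exactly the requested grid points", {
  s <- raman_spectrum(default_axis(), rnorm(3101))
  expect_length(crop(s, c(1331, 1349))$wavenumber, 19)
  expect_length(crop(s, list(c(427, 471), c(1103, 1115)))$wavenumber, 45 + 13)
  expect_length(crop(s, 980)$wavenumber, 1)
  expect_error(crop(s, c(5000, 6000)), "no wavenumbers")
})

test_that("crop and precrop with disjoint regions commute", {
  s <- raman_spectrum(default_axis(), rnorm(3101))
  a <- crop(precrop(s, c(920, 1030)), c(1203, 1349))
  b <- precrop(crop(s, c(1203, 1349)), c(920, 1030))
  expect_equal(a$wavenumber, b$wavenumber)
  expect_equal(a$intensity, b$intensity)
})

test_that("scaler fits on training statistics and applies linearly", {
  set <- toy_set(n = 8, p = 40)
  st <- fit_scaler(set)
  scaled <- apply_scaler(set, st)
  expect_lt(max(abs(colMeans(scaled$intensity))), 1e-12)
  expect_equal(apply(scaled$intensity, 2, sd), rep(1, 40), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(fit_scaler(subset_spectra(set, 1)), "at least 2")
  const <- set; const$intensity[, 5] <- 3
  expect_error(fit_scaler(const), "zero variance")

  shifted <- set; shifted$intensity <- set$intensity + 2
  d <- apply_scaler(shifted, st)$intensity - scaled$intensity
  expect_equal(d, matrix(2, 8, 40) %*% diag(1 / st$sd), tolerance = 1e-10)
})

test_that("pipeline configs validate parameters", {
  expect_error(pipeline_config("x", "AMS", sg_window = 10, baseline_lambda = 1,
                               crop_include = c(1, 2)), "odd")
  expect_error(pipeline_config("x", "AMS", baseline_lambda = -1,
                               crop_include = c(1, 2)), "positive")
  expect_error(pipeline_config("x", "AMS", baseline_lambda = 1,
                               baseline_diff_order = 4, crop_include = c(1, 2)),
               "2 or 3")
  cfgs <- builtin_pipelines()
  expect_setequal(names(cfgs),
                  c("LR_AMS", "PLS_AMS", "PLS_VIP4_AMS", "PLS_VIP2_AMS",
                    "PLS_P1_C1_VLP", "PLS_P1_C2_VLP", "PLS_P2_C1_VLP",
                    "PLS_P2_C2_VLP"))
  expect_equal(cfgs$PLS_AMS$baseline_lambda, 6e7)
  expect_equal(cfgs$PLS_P2_C2_VLP$baseline_lambda, 1e9)
  expect_equal(cfgs$PLS_P2_C2_VLP$baseline_diff_order, 3L)
  expect_equal(cfgs$PLS_P1_C1_VLP$baseline_diff_order, 2L)
  expect_error(builtin_pipelines("NOPE"), "unknown pipeline")
})

test_that("run_pipeline applies the configured steps in order with provenance", {
  cfg <- noiseless_config()
  cal <- generate_stock_series("AMS", c(0.2, 0.8), reps = 50, exposure_ms = 175,
                               config = cfg, seed = 1)
  out <- run_pipeline(cal, builtin_pipelines("PLS_AMS"))
  expect_equal(n_spectra(out), 2)
  expect_length(out$wavenumber, 2311) # [340, 2650] on the 1/cm grid
  steps <- provenance(out)
  expect_length(steps, 5)
  expect_match(steps[1], "^average")
  expect_match(steps[2], "^normalize")
  expect_match(steps[3], "^baseline")
  expect_match(steps[4], "^savgol")
  expect_match(steps[5], "^crop")

  vlp <- generate_stock_series("VLP", c(0.5, 1.5), reps = 50, exposure_ms = 1250,
                               config = cfg, seed = 2)
  outv <- run_pipeline(vlp, builtin_pipelines("PLS_P2_C2_VLP"))
  expect_length(outv$wavenumber, 19)
  expect_match(provenance(outv)[2], "^precrop")

  # rerunning is bit-identical
  out2 <- run_pipeline(cal, builtin_pipelines("PLS_AMS"))
  expect_identical(out$intensity, out2$intensity)
})

test_that("pipeline errors are annotated with the failing step", {
  cfg <- noiseless_config()
  cal <- generate_stock_series("AMS", c(0.2, 0.8), reps = 2, exposure_ms = 175,
                               config = cfg, seed = 1)
  bad <- builtin_pipelines("PLS_AMS")
  bad$average_n <- 2L
  bad$crop_include <- matrix(c(5000, 6000), 1,
                             dimnames = list(NULL, c("lo", "hi")))
  expect_error(run_pipeline(cal, bad), "step crop")
})
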