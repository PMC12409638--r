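# Synthetic spectrum generator and process simulator.

test_that("blank spectra are deterministic and linear in exposure and concentration", {
  cfg <- noiseless_config()
  blank1 <- generate_spectrum(c(ams = 0), 175, cfg)
  blank2 <- generate_spectrum(c(ams = 0), 175, cfg)
  expect_identical(blank1$intensity, blank2$intensity)
  expect_true(all(blank1$intensity >= 0))

  # doubling exposure doubles intensities exactly (no clipping, no noise)
  a <- generate_spectrum(c(ams = 0.3, vlp = 1, tris = 1), 175, cfg)
  b <- generate_spectrum(c(ams = 0.3, vlp = 1, tris = 1), 350, cfg)
  expect_equal(2 * a$intensity, b$intensity, tolerance = 1e-14)

  # linearity in each concentration
  s0 <- generate_spectrum(c(ams = 0), 175, cfg)
  s1 <- generate_spectrum(c(ams = 0.2), 175, cfg)
  s2 <- generate_spectrum(c(ams = 0.4), 175, cfg)
  expect_equal(s2$intensity - s1$intensity, s1$intensity - s0$intensity,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(generate_spectrum(c(ams = -1), 175, cfg), "negative concentration")
})

test_that("oversaturated 980 band shows the split peak only at long exposure", {
  cfg <- noiseless_config()
  hot <- generate_spectrum(c(ams = 0.6), 1250, cfg)
  w <- hot$wavenumber
  band <- which(w >= 950 & w <= 1010)
  y <- hot$intensity[1, band]
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  expect_gte(sum(is_max), 2) # two flank maxima
  mx <- range(which(is_max))
  expect_lt(min(y[mx[1]:mx[2]]), max(y)) # interior minimum between them

  cold <- generate_spectrum(c(ams = 0.6), 175, cfg)
  yc <- cold$intensity[1, band]
  is_max_c <- c(FALSE, yc[2:(n - 1)] >= yc[1:(n - 2)] & yc[2:(n - 1)] >= yc[3:n], FALSE)
  expect_equal(sum(is_max_c), 1) # unimodal
})

test_that("stock series have the expected layout and are seed-reproducible", {
  cfg <- generator_config()
  s <- generate_stock_series("AMS", seq(0, 1.1, length.out = 12), reps = 5,
                             exposure_ms = 175, config = cfg, seed = 5)
  expect_equal(n_spectra(s), 60)
  expect_length(s$reference, 60)
  expect_equal(unique(s$reference), seq(0, 1.1, length.out = 12))
  expect_equal(s$analyte, "AMS")

  s2 <- generate_stock_series("AMS", seq(0, 1.1, length.out = 12), reps = 5,
                              exposure_ms = 175, config = cfg, seed = 5)
  expect_identical(s$intensity, s2$intensity)
  expect_error(generate_stock_series("AMS", c(0.5), reps = 0, exposure_ms = 175,
                                     config = cfg, seed = 1), "reps")
})

test_that("VLP stock spectra carry residual sulfate plus level-scaled protein bands", {
  cfg <- noiseless_config()
  s <- generate_stock_series("VLP", c(0.5, 2), reps = 1, exposure_ms = 1250,
                             config = cfg, seed = 6)
  w <- s$wavenumber
  i980 <- which(w == 980); i950 <- which(w == 950)
  i1341 <- which(w == 1341); ibg <- which(w == 2900)
  # both levels show the sulfate band (residual AMS); its height above the
  # local background is level-independent
  h1 <- s$intensity[1, i980] - s$intensity[1, i950]
  h2 <- s$intensity[2, i980] - s$intensity[2, i950]
  expect_gt(h1, 1000)
  expect_equal(h1, h2, tolerance = 0.02)
  # protein band scales with the level
  p1 <- s$intensity[1, i1341] - s$intensity[1, ibg]
  p2 <- s$intensity[2, i1341] - s$intensity[2, ibg]
  expect_gt(p2 / p1, 2.5) # 2.0 vs 0.5 g/L, plus level-independent Tris share
})

test_that("the rho=1 cascade follows the closed form with peak c0/e at one DV", {
  tr <- simulate_cff_process(c0_ams = 1.1, rho = 1, dv_max = 7, uf_factor = 1)
  expect_lt(max(abs(tr$c_ams - 1.1 * tr$dv * exp(-tr$dv))), 1e-8)
  expect_equal(tr$dv[which.max(tr$c_ams)], 1, tolerance = 0.03)
  expect_equal(max(tr$c_ams), 1.1 / exp(1), tolerance = 1e-6)
})

test_that("c0 = 0 gives an identically zero precipitant trace", {
  tr <- simulate_cff_process(c0_ams = 0, rho = 0.5, dv_max = 5, uf_factor = 1)
  expect_true(all(tr$c_ams == 0))
})

test_that("the default stage ratio puts the stage-2 peak near 1.6 DV, bounded by c0", {
  tr <- simulate_cff_process(c0_ams = 1.1, rho = 0.35, dv_max = 7)
  vstar <- -log(0.35) / (1 - 0.35)
  expect_equal(tr$dv[which.max(tr$c_ams)], vstar, tolerance = 0.05)
  expect_gte(min(tr$c_ams), 0)
  expect_lte(max(tr$c_ams), 1.1)
  # rise-then-fall: increasing before the peak, decreasing after (DF phase)
  df <- tr[tr$phase == "DF", ]
  ipk <- which.max(df$c_ams)
  expect_true(all(diff(df$c_ams[1:ipk]) >= 0))
  expect_true(all(diff(df$c_ams[ipk:nrow(df)]) <= 1e-12))
})

test_that("ultrafiltration concentrates VLP by the volume ratio and holds AMS", {
  tr <- simulate_cff_process(c0_ams = 1.1, vlp_total = 2, rho = 0.35,
                             dv_max = 7, uf_factor = 2.5)
  df_end <- max(which(tr$phase == "DF"))
  expect_true(all(diff(tr$volume[tr$phase == "UF"]) < 0))
  expect_equal(tr$c_vlp[nrow(tr)], tr$c_vlp[df_end] * 2.5, tolerance = 1e-9)
  expect_equal(tr$c_ams[nrow(tr)], tr$c_ams[df_end])
  expect_error(simulate_cff_process(dv_max = 0.5), "dv_max")
  expect_error(simulate_cff_process(rho = 0), "rho")
})

test_that("process spectra counting, determinism and sampling windows", {
  cfg <- generator_config()
  tr <- simulate_cff_process(dv_max = 3, uf_factor = 1)
  ps <- generate_process_spectra(tr, "continuous", 1250, cfg, reps = 2,
                                 dv_step = 0.1, seed = 7)
  expect_equal(n_spectra(ps), 30 * 2) # 3 DV at 0.1 steps, 2 recordings each
  ps2 <- generate_process_spectra(tr, "continuous", 1250, cfg, reps = 2,
                                  dv_step = 0.1, seed = 7)
  expect_identical(ps$intensity, ps2$intensity)

  semi <- generate_process_spectra(tr, "semi_continuous", c(175, 1250), cfg,
                                   reps = 2, dv_step = 0.1, seed = 7)
  dvs <- unique(semi$meta$dv)
  pts <- c(0.5, 1, 2, 3)
  expect_true(all(vapply(dvs, function(v) any(abs(v - pts) <= 0.15), logical(1))))
  expect_setequal(unique(semi$meta$exposure_ms), c(175, 1250))

  expect_error(generate_process_spectra(tr, "continuous", 1250, cfg, reps = 2,
                                        defective_window = c(2, 9), seed = 1),
               "defective_window")
})

test_that("injected defective blocks are detected at the injected DV range", {
  cfg <- generator_config()
  tr <- simulate_cff_process(dv_max = 7)
  ps <- generate_process_spectra(tr, "continuous", 1250, cfg, reps = 2,
                                 dv_step = 0.1, defective_window = c(3.0, 4.1),
                                 seed = 8)
  blocks <- average_block(ps, 2)
  d <- detect_defective(blocks, window = 31, k = 6)
  flagged <- blocks$meta$dv[d$defective]
  expect_gt(length(flagged), 5)
  expect_true(all(flagged >= 3.0 - 1e-9 & flagged <= 4.1 + 1e-9))
})

test_that("fouling injection biases VLP predictions upward over the run", {
  cfg <- noiseless_config()
  cal <- generate_stock_series("VLP", seq(0, 2.2, length.out = 8), reps = 2,
                               exposure_ms = 1250, config = cfg, seed = 9)
  cfg_p <- builtin_pipelines("PLS_P2_C2_VLP"); cfg_p$average_n <- 2L
  pre <- run_pipeline(cal, cfg_p)
  m <- nipals_pls_fit(intensity_matrix(pre), pre$reference, 2)

  tr <- simulate_cff_process(dv_max = 6, uf_factor = 1)
  ps <- generate_process_spectra(tr, "continuous", 1250, cfg, reps = 2,
                                 dv_step = 0.5, fouling = TRUE, seed = 10)
  pre_p <- run_pipeline(ps, cfg_p)
  bias <- predict(m, pre_p) - pre_p$meta$c_vlp_true
  # bias grows with DV as protein accumulates on the probe
  expect_gt(cor(pre_p$meta$dv, bias), 0.8)
  expect_gt(bias[length(bias)], bias[1] + 0.3)
})
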