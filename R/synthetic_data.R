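# Synthetic Raman data generator.
#
# Emulates the statistical structure of the instrument data the analysis
# assumes: stock-solution calibration series for AMS (0-1.1 M along a
# wash/re-dissolution buffer mixing gradient) and VLP (0-2.2 g/L with
# residual AMS), and on-line spectra from the second membrane stage of a
# dual-stage cross-flow filtration with rise-then-fall AMS, accumulating
# VLP, exposure-time intensity scaling, concentration-dependent baseline
# drift, detector clipping with the split-peak fold-back artifact, probe
# fouling, and injectable defective spectra.
#
# Band positions follow the published assignments (sulfate 451/618/980/1106,
# ammonium 1420, phenylalanine 1004, tyrosine 1206, backbone/Tris 1249,
# backbone+tryptophan 1341, amide I 1660, water OH ~3250 cm^-1); widths and
# amplitudes are generator parameters.  The sulfate amplitudes are set so
# the 980 cm^-1 band reaches the detector full scale at ~0.2 M AMS and
# 1250 ms exposure, and the protein:sulfate amplitude ratio is << 1,
# reproducing the sensor's sensitivity asymmetry.

#' Default Raman band library
#'
#' One row per band: `component`, driving `analyte` (`ams`, `vlp`, `tris`,
#' `water`), `center` (cm^-1), `width` (Gaussian sigma or Lorentzian gamma,
#' cm^-1), `shape`, and `amplitude` in counts per concentration unit
#' (mol/L, g/L, or dimensionless for buffer/water) per ms exposure.
#'
#' @return a `data.frame`.
#' @export
band_library <- function() {
  data.frame(
    component = c("sulfate", "sulfate", "sulfate", "sulfate", "ammonium",
                  "phe", "tyr", "backbone", "trp_backbone", "amide1",
                  "tris", "tris", "water_oh", "water_bend"),
    analyte = c("ams", "ams", "ams", "ams", "ams",
                "vlp", "vlp", "vlp", "vlp", "vlp",
                "tris", "tris", "water", "water"),
    center = c(451, 618, 980, 1106, 1420,
               1004, 1206, 1249, 1341, 1660,
               1249, 1060, 3250, 1640),
    width = c(7, 7, 5, 12, 25,
              5, 8, 12, 9, 18,
              11, 15, 110, 40),
    shape = "gaussian",
    # the 980 amplitude puts the band apex (including dark signal and
    # concentration-dependent drift) at the detector full scale for a
    # 0.2 M AMS solution at 1250 ms exposure: the saturation onset
    amplitude = c(30, 24, 214, 30, 8,
                  2.0, 1.6, 2.2, 3.0, 2.4,
                  6, 3, 40, 3))
}

#' Generator configuration
#'
#' @param band_library band table, see [band_library()].
#' @param baseline_offset named vector: broad-background amplitude in counts
#'   per concentration unit per ms for `ams` and `vlp` (the
#'   concentration-dependent baseline drift).
#' @param dark_per_ms flat dark-signal level, counts per ms.
#' @param noise_sigma_frac additive Gaussian noise sigma per recording, as a
#'   fraction of the detector full scale (default 0.3 %).
#' @param clip_level detector full scale in counts (16-bit default).
#' @param saturation_fold_k fold-back factor of the clipping model in
#'   \[0, 1\]; intensities above full scale L are folded to
#'   L - k (I - L), floored at `fold_floor_frac` x L, producing the
#'   split-peak artifact.
#' @param fold_floor_frac floor of the fold-back, as a fraction of L.
#' @param fouling_rate protein-signal growth on the probe, in g/L-equivalent
#'   per diafiltration volume, when fouling is injected.
#' @param vlp_residual_ams residual AMS in VLP stock solutions, mol/L.
#' @param wash_ams AMS concentration of the wash buffer (mol/L); the
#'   buffer-mixing fraction of a sample is its AMS concentration divided by
#'   this value.
#' @param buffer_beta relative change of the buffer (Tris) Raman response
#'   between re-dissolution buffer (fraction 0) and wash buffer (fraction 1).
#' @param buffer_jitter_sd per-level preparation variability of the
#'   buffer-mixing fraction (second latent concentration source of the
#'   calibration series).
#' @param defect_offset_frac amplitude of the broad baseline shift of
#'   defective spectra, as a fraction of the full scale.
#' @return a `generator_config`.
#' @export
generator_config <- function(band_library = ramancff::band_library(),
                             baseline_offset = c(ams = 10, vlp = 6),
                             dark_per_ms = 8,
                             noise_sigma_frac = 0.003,
                             clip_level = 65535,
                             saturation_fold_k = 0.15,
                             fold_floor_frac = 0.8,
                             fouling_rate = 0.15,
                             vlp_residual_ams = 0.1,
                             wash_ams = 1.1,
                             buffer_beta = 0.3,
                             buffer_jitter_sd = 0.02,
                             defect_offset_frac = 0.3) {
  stopifnot(noise_sigma_frac >= 0, clip_level > 0,
            saturation_fold_k >= 0, saturation_fold_k <= 1)
  structure(list(band_library = band_library,
                 baseline_offset = baseline_offset,
                 dark_per_ms = dark_per_ms,
                 noise_sigma_frac = noise_sigma_frac,
                 clip_level = clip_level,
                 saturation_fold_k = saturation_fold_k,
                 fold_floor_frac = fold_floor_frac,
                 fouling_rate = fouling_rate,
                 vlp_residual_ams = vlp_residual_ams,
                 wash_ams = wash_ams,
                 buffer_beta = buffer_beta,
                 buffer_jitter_sd = buffer_jitter_sd,
                 defect_offset_frac = defect_offset_frac),
            class = "generator_config")
}

# broad, slowly varying background shape of the concentration-dependent
# drift; tapers smoothly to exactly zero above 2600 cm^-1 so the OH
# normalization reference region stays interference-free
drift_shape <- function(w) {
  s <- exp(-0.5 * ((w - 500) / 700)^2)
  taper <- ifelse(w <= 2400, 1,
                  ifelse(w >= 2600, 0, 0.5 * (1 + cos(pi * (w - 2400) / 200))))
  s * taper
}

band_profile <- function(w, center, width, shape) {
  if (shape == "lorentzian") {
    width^2 / ((w - center)^2 + width^2)
  } else {
    exp(-0.5 * ((w - center) / width)^2)
  }
}

# noise-free signal in counts per ms on the given axis
spectrum_signal <- function(composition, config, wavenumber = default_axis()) {
  comp <- c(ams = 0, vlp = 0, tris = 0, water = 1)
  comp[names(composition)] <- as.numeric(composition)
  if (any(comp < 0)) stop("negative concentration in composition")
  sig <- rep(config$dark_per_ms, length(wavenumber))
  bl <- config$band_library
  for (i in seq_len(nrow(bl))) {
    conc <- comp[[bl$analyte[i]]]
    if (conc == 0 || bl$amplitude[i] == 0) next
    sig <- sig + conc * bl$amplitude[i] *
      band_profile(wavenumber, bl$center[i], bl$width[i], bl$shape[i])
  }
  drift <- comp[["ams"]] * config$baseline_offset[["ams"]] +
    comp[["vlp"]] * config$baseline_offset[["vlp"]]
  if (drift != 0) sig <- sig + drift * drift_shape(wavenumber)
  sig
}

# detector model: fold-back clipping producing the split-peak artifact
apply_detector <- function(x, config) {
  L <- config$clip_level
  over <- x > L
  if (any(over)) {
    folded <- L - config$saturation_fold_k * (x[over] - L)
    x[over] <- pmax(folded, config$fold_floor_frac * L)
  }
  pmin(pmax(x, 0), L)
}

#' Generate a single synthetic spectrum
#'
#' Builds I(nu) = t_exp (sum of concentration-weighted bands + drift +
#' water) + Gaussian read noise, then applies the detector model (fold-back
#' clipping at the full scale).  Intensities are exactly linear in every
#' concentration and in exposure time as long as no value exceeds the full
#' scale and noise is off.
#'
#' @param composition named concentrations: `ams` (mol/L), `vlp` (g/L),
#'   `tris` (relative buffer level), `water` (defaults to 1).
#' @param exposure_ms exposure time in ms.
#' @param config a [generator_config()].
#' @param seed optional RNG seed for the noise draw.
#' @param sample_id,acquisition_mode,dv metadata for the spectrum.
#' @return a one-spectrum [raman_set].
#' @export
generate_spectrum <- function(composition, exposure_ms, config = generator_config(),
                              seed = NULL, sample_id = "SYN0001",
                              acquisition_mode = "offline", dv = NA_real_) {
  w <- default_axis()
  sig <- spectrum_signal(composition, config, w) * exposure_ms
  noise_sd <- config$noise_sigma_frac * config$clip_level
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, stats::rnorm(length(w), 0, noise_sd))
  }
  y <- apply_detector(sig, config)
  raman_set(w, matrix(y, nrow = 1L),
            meta = data.frame(sample_id = sample_id, exposure_ms = exposure_ms,
                              dv = dv, acquisition_mode = acquisition_mode,
                              flag = ""))
}

#' Generate a stock-solution calibration series
#'
#' AMS series: concentration levels along the wash/re-dissolution buffer
#' mixing gradient; the buffer-mixing fraction of each level is its nominal
#' value (level / wash concentration) plus a per-level preparation jitter,
#' so the series carries exactly two latent concentration sources (AMS
#' level and buffer composition).  VLP series: dilution levels with a fixed
#' residual AMS background.  Each level is recorded `reps` times with fresh
#' noise; reference values are attached.
#'
#' @param analyte `"AMS"` or `"VLP"`.
#' @param levels concentration levels (mol/L for AMS within 0--1.1,
#'   g/L for VLP within 0--2.2).
#' @param reps recordings per level (>= 1).
#' @param exposure_ms exposure time in ms.
#' @param config a [generator_config()].
#' @param seed RNG seed; the same seed reproduces the set bit-identically.
#' @return a [raman_set] of `length(levels) * reps` spectra with reference
#'   values, ordered level-by-level.
#' @export
generate_stock_series <- function(analyte = c("AMS", "VLP"), levels, reps = 50L,
                                  exposure_ms, config = generator_config(),
                                  seed = 1L) {
  analyte <- match.arg(analyte)
  if (reps < 1L) stop("reps must be >= 1")
  if (any(levels < 0)) stop("negative concentration levels")
  w <- default_axis()
  n <- length(levels) * reps
  noise_sd <- config$noise_sigma_frac * config$clip_level

  with_seed(seed, {
    jitter <- if (analyte == "AMS" && config$buffer_jitter_sd > 0) {
      stats::rnorm(length(levels), 0, config$buffer_jitter_sd)
    } else rep(0, length(levels))
    intens <- matrix(0, n, length(w))
    row <- 1L
    for (li in seq_along(levels)) {
      compo <- if (analyte == "AMS") {
        f <- min(max(levels[li] / config$wash_ams + jitter[li], 0), 1)
        c(ams = levels[li], tris = 1 + config$buffer_beta * f)
      } else {
        c(vlp = levels[li], ams = config$vlp_residual_ams, tris = 1)
      }
      base <- spectrum_signal(compo, config, w) * exposure_ms
      for (r in seq_len(reps)) {
        y <- base
        if (noise_sd > 0) y <- y + stats::rnorm(length(w), 0, noise_sd)
        intens[row, ] <- apply_detector(y, config)
        row <- row + 1L
      }
    }
    meta <- data.frame(
      sample_id = sprintf("%s_L%02d_R%02d", analyte,
                          rep(seq_along(levels), each = reps),
                          rep(seq_len(reps), length(levels))),
      exposure_ms = exposure_ms, dv = NA_real_,
      acquisition_mode = "offline", flag = "")
    raman_set(w, intens, meta = meta,
              reference = rep(levels, each = reps), analyte = analyte)
  })
}

## ---- process simulation ----------------------------------------------------

#' Simulate the dual-stage diafiltration / ultrafiltration process
#'
#' Constant-volume diafiltration washes the precipitant out of the first
#' membrane stage, `C1(v) = c0 exp(-v)` with v the diafiltration volume.
#' The second stage receives the first stage's permeate, giving the linear
#' cascade `dC2/dv = rho (C1 - C2)` with `rho` the stage-1 : stage-2 volume
#' ratio; for `rho = 1` the closed form is `C2(v) = c0 v exp(-v)` (peak
#' c0/e at v = 1).  VLP re-dissolution in stage 1 is a logistic function of
#' `C1` falling below the re-dissolution threshold; dissolved VLP passes the
#' first membrane, transfers with the permeate and is fully retained in
#' stage 2.  An optional ultrafiltration phase then reduces the stage-2
#' volume, concentrating the retained VLP while the membrane-permeant AMS
#' concentration stays level.
#'
#' @param c0_ams initial (wash-buffer) AMS concentration, mol/L.
#' @param vlp_total total re-dissolvable VLP in stage-1-volume-equivalent
#'   concentration units, g/L.
#' @param rho stage volume ratio (> 0).  The stage-2 concentration peaks at
#'   `v = -log(rho) / (1 - rho)`; the default 0.35 puts the peak near
#'   1.6 DV.
#' @param dv_max diafiltration volumes processed (>= 1).
#' @param uf_factor volume reduction factor of the ultrafiltration phase
#'   (25 mL -> 10 mL gives 2.5); `1` skips the phase.
#' @param dt output grid step in DV.
#' @param redissolve_threshold AMS concentration (mol/L) below which the
#'   precipitate re-dissolves.
#' @param redissolve_width logistic width of the re-dissolution transition,
#'   mol/L.
#' @param volume_df stage-2 retentate volume during diafiltration, mL.
#' @return a `process_trace`: data.frame with `dv`, `c_ams`, `c_vlp`,
#'   `phase` (`"DF"`/`"UF"`) and `volume` (mL).
#' @export
simulate_cff_process <- function(c0_ams = 1.1, vlp_total = 2, rho = 0.35,
                                 dv_max = 7, uf_factor = 2.5, dt = 0.02,
                                 redissolve_threshold = 0.6,
                                 redissolve_width = 0.08,
                                 volume_df = 25) {
  if (rho <= 0) stop("rho must be positive")
  if (dv_max < 1) stop("dv_max must be >= 1")
  if (dt <= 0) stop("dt must be positive")

  c1 <- function(v) c0_ams * exp(-v)
  frac_released <- function(v) {
    1 / (1 + exp((c1(v) - redissolve_threshold) / redissolve_width))
  }
  deriv <- function(v, state, parms) {
    C1 <- c1(v)
    dF <- frac_released(v) * (1 - frac_released(v)) * C1 / redissolve_width
    list(c(C2 = rho * (C1 - state[["C2"]]),
           P1 = vlp_total * dF - state[["P1"]],
           V2 = rho * state[["P1"]]))
  }
  grid <- seq(0, dv_max, by = dt)
  if (grid[length(grid)] < dv_max) grid <- c(grid, dv_max)
  sol <- deSolve::ode(y = c(C2 = 0, P1 = 0, V2 = 0), times = grid,
                      func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  trace <- data.frame(dv = sol[, "time"],
                      c_ams = pmax(sol[, "C2"], 0),
                      c_vlp = pmax(sol[, "V2"], 0),
                      phase = "DF", volume = volume_df)

  if (uf_factor > 1) {
    uf_dv <- 0.5  # nominal additional loop time of the UF phase, in DV units
    n_uf <- max(2L, ceiling(uf_dv / dt))
    dv_uf <- dv_max + seq_len(n_uf) / n_uf * uf_dv
    vol_uf <- volume_df + (volume_df / uf_factor - volume_df) * seq_len(n_uf) / n_uf
    last <- trace[nrow(trace), ]
    trace <- rbind(trace, data.frame(dv = dv_uf, c_ams = last$c_ams,
                                     c_vlp = last$c_vlp * volume_df / vol_uf,
                                     phase = "UF", volume = vol_uf))
  }
  structure(trace, class = c("process_trace", "data.frame"))
}

#' Generate on-line process spectra from a simulated trace
#'
#' Emits one block of `reps` recordings per `dv_step` along the trace.
#' Continuous mode covers the whole trace; semi-continuous mode only
#' records in windows around the sampling points (0.5 DV, every full DV,
#' and the ultrafiltration phase), and alternates exposure times when two
#' are given.  Optional injections: probe fouling (protein-band signal
#' growing linearly with DV, without changing the true concentrations) and
#' a defective window (spectra with an immense broad baseline shift).
#' Ground-truth concentrations are carried in the metadata columns
#' `c_ams_true` / `c_vlp_true`.
#'
#' @param trace a `process_trace` from [simulate_cff_process()].
#' @param mode `"continuous"` or `"semi_continuous"`.
#' @param exposure_ms one exposure time, or two for alternating
#'   semi-continuous acquisition.
#' @param config a [generator_config()].
#' @param reps recordings per block (averaged downstream).
#' @param dv_step block spacing in DV.
#' @param fouling inject probe fouling?
#' @param defective_window optional `c(lo, hi)` DV interval of defective
#'   spectra; must lie inside the trace.
#' @param sampling_halfwidth half-width (DV) of the semi-continuous
#'   recording windows.
#' @param seed RNG seed.
#' @return a raw [raman_set] of `reps` recordings per retained block,
#'   time-ordered.
#' @export
generate_process_spectra <- function(trace, mode = c("continuous", "semi_continuous"),
                                     exposure_ms, config = generator_config(),
                                     reps = 50L, dv_step = 0.1,
                                     fouling = FALSE, defective_window = NULL,
                                     sampling_halfwidth = 0.15, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "process_trace"))
  if (reps < 1L) stop("reps must be >= 1")
  dv_end <- max(trace$dv)
  centers <- seq(dv_step, dv_end + 1e-9, by = dv_step)
  if (!is.null(defective_window)) {
    if (defective_window[1L] < min(trace$dv) || defective_window[2L] > dv_end) {
      stop("defective_window outside the trace's DV range")
    }
  }
  c_ams <- stats::approx(trace$dv, trace$c_ams, centers, rule = 2)$y
  c_vlp <- stats::approx(trace$dv, trace$c_vlp, centers, rule = 2)$y
  df_max <- max(trace$dv[trace$phase == "DF"])
  is_uf <- centers > df_max + 1e-9

  if (mode == "semi_continuous") {
    pts <- c(0.5, seq_len(floor(df_max)))
    in_window <- vapply(centers, function(v) {
      any(abs(v - pts) <= sampling_halfwidth)
    }, logical(1)) | is_uf
    keep <- which(in_window)
  } else {
    keep <- seq_along(centers)
  }
  if (length(keep) == 0L) stop("no recording blocks selected")

  w <- default_axis()
  noise_sd <- config$noise_sigma_frac * config$clip_level

  with_seed(seed, {
    n <- length(keep) * reps
    intens <- matrix(0, n, length(w))
    meta_rows <- vector("list", length(keep))
    row <- 1L
    for (bi in seq_along(keep)) {
      i <- keep[bi]
      t_exp <- if (mode == "semi_continuous" && length(exposure_ms) == 2L) {
        exposure_ms[(bi - 1L) %% 2L + 1L]
      } else exposure_ms[1L]
      vlp_eff <- c_vlp[i] + if (fouling) config$fouling_rate * centers[i] else 0
      f <- min(max(c_ams[i] / config$wash_ams, 0), 1)
      base <- spectrum_signal(c(ams = c_ams[i], vlp = vlp_eff,
                                tris = 1 + config$buffer_beta * f),
                              config, w) * t_exp
      if (!is.null(defective_window) &&
          centers[i] >= defective_window[1L] && centers[i] <= defective_window[2L]) {
        base <- base + config$defect_offset_frac * config$clip_level *
          exp(-0.5 * ((w - 900) / 500)^2)
      }
      for (r in seq_len(reps)) {
        y <- base
        if (noise_sd > 0) y <- y + stats::rnorm(length(w), 0, noise_sd)
        intens[row, ] <- apply_detector(y, config)
        row <- row + 1L
      }
      meta_rows[[bi]] <- data.frame(
        sample_id = sprintf("P_%06.3fDV_R%02d", centers[i], seq_len(reps)),
        exposure_ms = t_exp, dv = centers[i],
        acquisition_mode = mode, flag = "",
        c_ams_true = c_ams[i], c_vlp_true = c_vlp[i],
        phase = if (is_uf[i]) "UF" else "DF")
    }
    raman_set(w, intens, meta = do.call(rbind, meta_rows))
  })
}
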