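# Reusable preprocessing operators and attribute-specific pipelines.
#
# A pipeline is an ordered recipe: average -> normalize (OH band) ->
# pre-crop -> baseline (asPLS) -> smooth (Savitzky-Golay) -> crop -> scale.
# AMS pipelines normalize on the water OH band so models transfer across
# exposure times; VLP pipelines instead pre-crop the dominant sulfate region
# before baseline correction, which is what makes the protein-region
# baseline tractable.

#' Create a preprocessing pipeline configuration
#'
#' One configuration per model, holding every preprocessing parameter plus
#' the model recipe (linear regression at one wavenumber, full PLS, or
#' VIP-refined PLS).  The shipped configurations are available through
#' [builtin_pipelines()].
#'
#' @param name configuration name.
#' @param analyte `"AMS"` or `"VLP"`.
#' @param average_n block size for spectrum averaging (50 recordings).
#' @param normalize_wavenumber OH-band reference wavenumber in cm^-1
#'   (3299 for AMS pipelines) or `NULL` to skip normalization.
#' @param precrop_exclude intervals (cm^-1) removed before baseline
#'   correction, or `NULL`.
#' @param baseline_lambda Whittaker smoothness penalty \eqn{\lambda}.
#' @param baseline_diff_order difference order d (2 or 3).
#' @param baseline_tol asPLS convergence tolerance.
#' @param sg_window Savitzky-Golay window (odd, > `sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial degree.
#' @param crop_include intervals (cm^-1) retained for modeling; a single
#'   wavenumber is allowed.
#' @param scale_unit_variance scale retained wavenumbers to unit variance
#'   using training statistics?
#' @param model_type `"linear"`, `"pls"` or `"pls_vip"`.
#' @param lr_wavenumber regression wavenumber for `model_type = "linear"`.
#' @param pls_components fixed component count, or `NULL` to select by
#'   cross-validation.
#' @param cv_range candidate latent-variable counts for cross-validation.
#' @param vip_threshold,vip_min_width,vip_merge_gap VIP interval-selection
#'   parameters (see [select_vip_intervals()]).
#' @param vip_exclude intervals whose VIP-selected regions are discarded
#'   during refinement (used to avoid the saturation-prone sulfate band).
#' @param vip_keep number of VIP intervals kept (by descending mean VIP
#'   score); `Inf` keeps all.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(name, analyte = c("AMS", "VLP"),
                            average_n = 50L,
                            normalize_wavenumber = NULL,
                            precrop_exclude = NULL,
                            baseline_lambda, baseline_diff_order = 2L,
                            baseline_tol = 1e-3,
                            sg_window = 11L, sg_polyorder = 2L,
                            crop_include,
                            scale_unit_variance = FALSE,
                            model_type = c("pls", "linear", "pls_vip"),
                            lr_wavenumber = NULL,
                            pls_components = NULL,
                            cv_range = 2:10,
                            vip_threshold = 1, vip_min_width = 5L,
                            vip_merge_gap = 5,
                            vip_exclude = NULL, vip_keep = Inf) {
  analyte <- match.arg(analyte)
  model_type <- match.arg(model_type)
  if (sg_window %% 2L != 1L || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder")
  }
  if (baseline_lambda <= 0 || baseline_tol <= 0) {
    stop("baseline_lambda and baseline_tol must be positive")
  }
  if (!baseline_diff_order %in% c(2L, 3L)) {
    stop("baseline_diff_order must be 2 or 3")
  }
  if (model_type == "linear" && is.null(lr_wavenumber)) {
    stop("linear model needs lr_wavenumber")
  }
  structure(list(
    name = name, analyte = analyte, average_n = as.integer(average_n),
    normalize_wavenumber = normalize_wavenumber,
    precrop_exclude = if (!is.null(precrop_exclude)) as_intervals(precrop_exclude),
    baseline_lambda = baseline_lambda,
    baseline_diff_order = as.integer(baseline_diff_order),
    baseline_tol = baseline_tol,
    sg_window = as.integer(sg_window), sg_polyorder = as.integer(sg_polyorder),
    crop_include = as_intervals(crop_include),
    scale_unit_variance = isTRUE(scale_unit_variance),
    model_type = model_type, lr_wavenumber = lr_wavenumber,
    pls_components = pls_components, cv_range = cv_range,
    vip_threshold = vip_threshold, vip_min_width = as.integer(vip_min_width),
    vip_merge_gap = vip_merge_gap,
    vip_exclude = if (!is.null(vip_exclude)) as_intervals(vip_exclude),
    vip_keep = vip_keep), class = "pipeline_config")
}

#' Built-in preprocessing/model configurations
#'
#' The eight shipped pipelines: four AMS models (linear regression at
#' 980 cm^-1, full-spectrum PLS over 340--2650 cm^-1, and two VIP-refined
#' PLS models) and four VLP models combining pre-cropping intervals
#' P1 = \[920, 1030\] / P2 = \[920, 1200\] with cropping intervals
#' C1 = \[1203, 1349\] / C2 = \[1331, 1349\].
#'
#' AMS pipelines use \eqn{\lambda = 6 \times 10^7} with a second-order
#' difference penalty and tolerance 1e-3; VLP pipelines use
#' \eqn{\lambda = 1 \times 10^9} with tolerance 1e-4 (P1 rows with d = 2,
#' P2 rows with d = 3).  A Whittaker penalty below 1 would leave spectra
#' unsmoothed, so the sub-unity lambda notation sometimes seen for these
#' settings is read as the corresponding power of ten.
#'
#' For the VIP-refined models the shipped `crop_include` intervals are the
#' published ones; [run_calibration()] re-derives them from the data via VIP
#' scores.  `PLS_VIP2_AMS` additionally discards VIP intervals overlapping
#' the saturation-prone 920--1030 cm^-1 sulfate region and keeps the two
#' strongest remaining intervals, which is what makes it robust to detector
#' oversaturation at long exposure times.
#'
#' @param name optional single configuration name to return.
#' @return a named list of [pipeline_config] objects, or one configuration
#'   if `name` is given.
#' @export
builtin_pipelines <- function(name = NULL) {
  ams <- function(...) pipeline_config(analyte = "AMS",
                                       normalize_wavenumber = 3299,
                                       baseline_lambda = 6e7,
                                       baseline_diff_order = 2L,
                                       baseline_tol = 1e-3, ...)
  vlp <- function(...) pipeline_config(analyte = "VLP",
                                       baseline_lambda = 1e9,
                                       baseline_tol = 1e-4, ...)
  cfgs <- list(
    LR_AMS = ams(name = "LR_AMS", crop_include = 980,
                 model_type = "linear", lr_wavenumber = 980),
    PLS_AMS = ams(name = "PLS_AMS", crop_include = c(340, 2650),
                  model_type = "pls"),
    PLS_VIP4_AMS = ams(name = "PLS_VIP4_AMS",
                       crop_include = list(c(427, 471), c(600, 634),
                                           c(960, 999), c(1103, 1115)),
                       scale_unit_variance = TRUE, model_type = "pls_vip"),
    PLS_VIP2_AMS = ams(name = "PLS_VIP2_AMS",
                       crop_include = list(c(427, 471), c(1103, 1115)),
                       scale_unit_variance = TRUE, model_type = "pls_vip",
                       vip_exclude = c(920, 1030), vip_keep = 2),
    PLS_P1_C1_VLP = vlp(name = "PLS_P1_C1_VLP",
                        precrop_exclude = c(920, 1030),
                        baseline_diff_order = 2L,
                        crop_include = c(1203, 1349)),
    PLS_P1_C2_VLP = vlp(name = "PLS_P1_C2_VLP",
                        precrop_exclude = c(920, 1030),
                        baseline_diff_order = 2L,
                        crop_include = c(1331, 1349)),
    PLS_P2_C1_VLP = vlp(name = "PLS_P2_C1_VLP",
                        precrop_exclude = c(920, 1200),
                        baseline_diff_order = 3L,
                        crop_include = c(1203, 1349)),
    PLS_P2_C2_VLP = vlp(name = "PLS_P2_C2_VLP",
                        precrop_exclude = c(920, 1200),
                        baseline_diff_order = 3L,
                        crop_include = c(1331, 1349)))
  if (is.null(name)) return(cfgs)
  if (!name %in% names(cfgs)) {
    stop("unknown pipeline '", name, "'; available: ",
         paste(names(cfgs), collapse = ", "))
  }
  cfgs[[name]]
}

## ---- operators -------------------------------------------------------------

#' OH-band normalization
#'
#' Divides every spectrum by its intensity at the water OH stretch reference
#' wavenumber, making spectra dimensionless and invariant to exposure time
#' and turbidity.  By default the reference intensity is the mean over a
#' 5-point window (reference +/- 2 cm^-1) for robustness to single-channel
#' noise; `strict_single_point = TRUE` uses the single channel.
#'
#' @param set a [raman_set] (raw intensities).
#' @param wavenumber reference wavenumber in cm^-1 (default 3299).
#' @param window half-width of the averaging window in grid points.
#' @param strict_single_point use only the reference channel?
#' @return the normalized [raman_set]; the reference intensity is 1 at the
#'   reference point (window mean).
#' @export
normalize_oh <- function(set, wavenumber = 3299, window = 2L,
                         strict_single_point = FALSE) {
  stopifnot(inherits(set, "raman_set"))
  idx <- which(set$wavenumber == wavenumber)
  if (length(idx) != 1L) stop("reference wavenumber ", wavenumber, " not on axis")
  cols <- if (strict_single_point) idx else {
    intersect(seq_along(set$wavenumber), (idx - window):(idx + window))
  }
  ref <- rowMeans(set$intensity[, cols, drop = FALSE])
  if (any(ref <= 0)) {
    stop("non-positive reference intensity for spectra ",
         paste(which(ref <= 0), collapse = ", "), ": normalization undefined")
  }
  if (any(grepl("saturated", set$meta$flag))) {
    stop("saturated-flagged spectra in set: OH normalization undefined")
  }
  out <- set
  out$intensity <- set$intensity / ref
  add_provenance(out, sprintf("normalize_oh(%g%s)", wavenumber,
                              if (strict_single_point) ", single-point" else ""))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing.  By default the spectrum is
#' treated as one concatenated vector even across pre-cropping gaps
#' (spliced), matching the downstream baseline treatment; with
#' `per_segment = TRUE` each contiguous axis segment is filtered on its own.
#' Edges are handled by refitting the polynomial on the first/last window
#' (no wraparound); edge regions are typically discarded by later cropping.
#'
#' @param set a [raman_set].
#' @param window odd window length (default 11).
#' @param polyorder polynomial degree (default 2).
#' @param per_segment filter each contiguous segment separately?
#' @return the smoothed [raman_set].
#' @export
savgol_smooth <- function(set, window = 11L, polyorder = 2L,
                          per_segment = FALSE) {
  stopifnot(inherits(set, "raman_set"))
  if (window %% 2L != 1L || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  smooth_one <- function(y) signal::sgolayfilt(y, p = polyorder, n = window)
  out <- set
  if (!per_segment) {
    if (length(set$wavenumber) < window) stop("axis shorter than window")
    out$intensity <- t(apply(set$intensity, 1L, smooth_one))
  } else {
    seg <- set$segments
    pieces <- lapply(seq_len(nrow(seg)), function(i) {
      cols <- which(set$wavenumber >= seg[i, 1L] & set$wavenumber <= seg[i, 2L])
      if (length(cols) < window) {
        stop(sprintf("segment [%g, %g] has %d points, shorter than window %d",
                     seg[i, 1L], seg[i, 2L], length(cols), window))
      }
      t(apply(set$intensity[, cols, drop = FALSE], 1L, smooth_one))
    })
    out$intensity <- do.call(cbind, pieces)
  }
  add_provenance(out, sprintf("savgol(window=%d, polyorder=%d%s)", window,
                              polyorder, if (per_segment) ", per-segment" else ""))
}

#' Pre-crop: remove interior wavenumber intervals
#'
#' Removes all wavenumbers inside the (inclusive) exclusion intervals and
#' records the resulting contiguous segments.  Downstream baseline
#' correction and smoothing operate on the spliced remainder.
#'
#' @param set a [raman_set].
#' @param exclude intervals (cm^-1) to remove; an empty list is the identity.
#' @return the pre-cropped [raman_set].
#' @export
precrop <- function(set, exclude) {
  stopifnot(inherits(set, "raman_set"))
  m <- as_intervals(exclude)
  if (nrow(m) == 0L) return(set)
  keep <- !in_intervals(set$wavenumber, m)
  if (!any(keep)) stop("pre-cropping would remove the entire axis")
  out <- subset_axis(set, keep)
  add_provenance(out, sprintf("precrop(exclude=%s)", format_intervals(m)))
}

#' Crop: retain wavenumber intervals
#'
#' Keeps only wavenumbers inside the union of the (inclusive) intervals;
#' order is preserved.  A single wavenumber is allowed.
#'
#' @param set a [raman_set].
#' @param include intervals (cm^-1) or a single wavenumber to retain.
#' @return the cropped [raman_set].
#' @export
crop <- function(set, include) {
  stopifnot(inherits(set, "raman_set"))
  m <- as_intervals(include)
  if (nrow(m) == 0L) stop("no cropping intervals given")
  keep <- in_intervals(set$wavenumber, m)
  if (!any(keep)) stop("cropping retains no wavenumbers")
  out <- subset_axis(set, keep)
  add_provenance(out, sprintf("crop(include=%s)", format_intervals(m)))
}

subset_axis <- function(set, keep) {
  out <- set
  out$wavenumber <- set$wavenumber[keep]
  out$intensity <- set$intensity[, keep, drop = FALSE]
  out$segments <- axis_segments(out$wavenumber,
                                spacing = min(diff(set$wavenumber)))
  out
}

format_intervals <- function(m) {
  paste(apply(as_intervals(m), 1L, function(iv) {
    if (iv[1L] == iv[2L]) sprintf("%g", iv[1L]) else sprintf("[%g,%g]", iv[1L], iv[2L])
  }), collapse = ",")
}

#' Fit a unit-variance scaler on training spectra
#'
#' Learns per-wavenumber mean and standard deviation from the training set.
#'
#' @param trainset a [raman_set] with at least two spectra.
#' @return a `scaler_state` with `wavenumber`, `mean` and `sd`.
#' @export
fit_scaler <- function(trainset) {
  stopifnot(inherits(trainset, "raman_set"))
  if (n_spectra(trainset) < 2L) stop("need at least 2 training spectra to fit a scaler")
  mu <- colMeans(trainset$intensity)
  sdv <- apply(trainset$intensity, 2L, stats::sd)
  bad <- which(sdv <= 0)
  if (length(bad)) {
    stop("zero variance at wavenumbers: ",
         paste(trainset$wavenumber[utils::head(bad, 10L)], collapse = ", "))
  }
  structure(list(wavenumber = trainset$wavenumber, mean = mu, sd = sdv),
            class = "scaler_state")
}

#' Apply a fitted scaler
#'
#' Centers and scales each retained wavenumber with the training statistics
#' only: (I - mean) / sd.
#'
#' @param set a [raman_set] on the scaler's axis.
#' @param state a `scaler_state` from [fit_scaler()].
#' @return the scaled [raman_set].
#' @export
apply_scaler <- function(set, state) {
  stopifnot(inherits(set, "raman_set"), inherits(state, "scaler_state"))
  if (length(set$wavenumber) != length(state$wavenumber) ||
      any(set$wavenumber != state$wavenumber)) {
    stop("axis mismatch between set and scaler state")
  }
  out <- set
  out$intensity <- sweep(sweep(set$intensity, 2L, state$mean), 2L, state$sd, "/")
  add_provenance(out, "scale(unit variance)")
}

## ---- pipeline runner -------------------------------------------------------

#' Run a preprocessing pipeline
#'
#' Applies, in order: block averaging (if `config$average_n > 1`), OH-band
#' normalization (if configured), pre-cropping (if configured), asPLS
#' baseline subtraction, Savitzky-Golay smoothing, cropping, and
#' unit-variance scaling (if configured).  The applied steps are recorded in
#' the output provenance ([provenance()]).
#'
#' @param set a raw [raman_set].
#' @param config a [pipeline_config].
#' @param baseline_fn baseline operation; [aspls_baseline()] by default.
#' @param scaler optional pre-fitted `scaler_state`.  For a scaling pipeline,
#'   omit it on training data (the scaler is fitted and attached as the
#'   `"scaler"` attribute) and pass the training scaler for test/process
#'   data.
#' @return the preprocessed [raman_set].
#' @export
run_pipeline <- function(set, config, baseline_fn = aspls_baseline,
                         scaler = NULL) {
  stopifnot(inherits(set, "raman_set"), inherits(config, "pipeline_config"))
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline '%s', step %s: %s", config$name, what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  x <- set
  if (config$average_n > 1L) {
    x <- step("average", average_block(x, config$average_n))
  }
  if (!is.null(config$normalize_wavenumber)) {
    x <- step("normalize", normalize_oh(x, config$normalize_wavenumber))
  }
  if (!is.null(config$precrop_exclude) && nrow(config$precrop_exclude) > 0L) {
    x <- step("precrop", precrop(x, config$precrop_exclude))
  }
  x <- step("baseline", {
    corrected <- t(apply(x$intensity, 1L, function(y) {
      y - baseline_fn(y, lam = config$baseline_lambda,
                      diff_order = config$baseline_diff_order,
                      tol = config$baseline_tol)$baseline
    }))
    x$intensity <- corrected
    add_provenance(x, sprintf("baseline(aspls, lambda=%g, d=%d, tol=%g)",
                              config$baseline_lambda, config$baseline_diff_order,
                              config$baseline_tol))
  })
  x <- step("smooth", savgol_smooth(x, config$sg_window, config$sg_polyorder))
  x <- step("crop", crop(x, config$crop_include))
  if (config$scale_unit_variance) {
    x <- step("scale", {
      if (is.null(scaler)) scaler <- fit_scaler(x)
      out <- apply_scaler(x, scaler)
      attr(out, "scaler") <- scaler
      out
    })
  }
  x
}
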