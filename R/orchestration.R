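# End-to-end runs: calibration (pipeline + model + test evaluation),
# transfer of calibrated models to process spectra with QC-gated flags, and
# summary reports.  Every run returns a manifest sufficient to reproduce it.

#' Calibrate a model on stock-solution spectra
#'
#' Runs the configured preprocessing pipeline on the calibration set, fits
#' the configured model and evaluates it on the test set:
#' * `model_type = "linear"`: ordinary least squares at the configured
#'   wavenumber;
#' * `model_type = "pls"`: NIPALS PLS1 with the component count selected by
#'   80/20 cross-validation (unless fixed in the config);
#' * `model_type = "pls_vip"`: a full-spectrum PLS model (340--2650 cm^-1)
#'   is fitted first, VIP scores are computed and intervals re-derived from
#'   the data, optionally filtered (`vip_exclude`, `vip_keep`); the final
#'   pipeline then crops to the derived intervals and the PLS model is
#'   refitted (cross-validation re-run) on the refined variables.
#'
#' Calibration is performed on stock-solution data only; the test set is an
#' independent series (for AMS recorded at a different exposure time, which
#' the OH normalization makes admissible).
#'
#' @param calib_set raw calibration [raman_set] with reference values.
#' @param test_set raw test [raman_set] with reference values.
#' @param config a [pipeline_config] or a built-in configuration name.
#' @param seed seed for the cross-validation split.
#' @return a `calibration_run`: list with `model` (carrying the effective
#'   pipeline and scaler as attributes), `report` (test [metrics()]),
#'   `cv_table`, `vip` (for VIP configs), and `manifest`.
#' @export
run_calibration <- function(calib_set, test_set, config, seed = 1L) {
  if (is.character(config)) config <- builtin_pipelines(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(calib_set$reference)) stop("calibration set has no reference values")

  vip_result <- NULL
  effective <- config

  if (config$model_type == "pls_vip") {
    # stage 1: full-spectrum model for VIP-based interval derivation
    full_cfg <- config
    full_cfg$crop_include <- as_intervals(c(340, 2650))
    full_cfg$scale_unit_variance <- FALSE
    pre_full <- run_pipeline(calib_set, full_cfg)
    cv_full <- cv_select_components(intensity_matrix(pre_full), pre_full$reference,
                                    a_range = config$cv_range, seed = seed)
    fit_full <- nipals_pls_fit(intensity_matrix(pre_full), pre_full$reference,
                               cv_full$ncomp)
    vip_result <- select_vip_intervals(vip_scores(fit_full),
                                       threshold = config$vip_threshold,
                                       min_width = config$vip_min_width,
                                       merge_gap = config$vip_merge_gap)
    iv <- vip_result$intervals
    if (!is.null(config$vip_exclude) && nrow(iv) > 0L) {
      overlaps <- vapply(seq_len(nrow(iv)), function(i) {
        any(iv[i, 1L] <= config$vip_exclude[, 2L] &
              iv[i, 2L] >= config$vip_exclude[, 1L])
      }, logical(1))
      iv <- iv[!overlaps, , drop = FALSE]
    }
    if (is.finite(config$vip_keep) && nrow(iv) > config$vip_keep) {
      strength <- vapply(seq_len(nrow(iv)), function(i) {
        wn <- as.numeric(names(vip_result$scores))
        mean(vip_result$scores[wn >= iv[i, 1L] & wn <= iv[i, 2L]])
      }, numeric(1))
      iv <- iv[order(strength, decreasing = TRUE)[seq_len(config$vip_keep)], ,
               drop = FALSE]
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
    }
    if (nrow(iv) == 0L) stop("VIP refinement selected no intervals")
    effective$crop_include <- iv
  }

  pre_cal <- run_pipeline(calib_set, effective)
  scaler <- attr(pre_cal, "scaler")
  pre_test <- run_pipeline(test_set, effective, scaler = scaler)

  cv_table <- NULL
  if (effective$model_type == "linear") {
    model <- fit_linear(pre_cal, effective$lr_wavenumber)
  } else {
    X <- intensity_matrix(pre_cal)
    ncomp <- effective$pls_components
    if (is.null(ncomp)) {
      cv <- cv_select_components(X, pre_cal$reference,
                                 a_range = effective$cv_range, seed = seed)
      ncomp <- cv$ncomp
      cv_table <- cv$cv_table
    }
    model <- nipals_pls_fit(X, pre_cal$reference, ncomp)
  }
  attr(model, "pipeline") <- effective
  attr(model, "scaler") <- scaler
  attr(model, "train_exposure_ms") <- unique(calib_set$meta$exposure_ms)

  report <- metrics(stats::predict(model, pre_test), pre_test$reference)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_name = config$name,
    analyte = config$analyte,
    seed = seed,
    n_calib = n_spectra(calib_set), n_test = n_spectra(test_set),
    steps = provenance(pre_cal),
    vip_threshold = if (!is.null(vip_result)) vip_result$threshold,
    vip_intervals = if (!is.null(vip_result)) effective$crop_include,
    selected_components = if (inherits(model, "pls_model")) model$n_components,
    model_md5 = object_md5(model),
    r_version = as.character(getRversion()))

  structure(list(model = model, report = report, cv_table = cv_table,
                 vip = vip_result, manifest = manifest),
            class = "calibration_run")
}

#' @export
#' @method print calibration_run
print.calibration_run <- function(x, ...) {
  cat(sprintf("<calibration_run> %s (%s)\n", x$manifest$config_name,
              x$manifest$analyte))
  print(x$report)
  invisible(x)
}

#' Transfer calibrated models to process spectra
#'
#' For each model: the raw process series is block-averaged (the model's
#' configured averaging), QC flags are computed on the raw averaged
#' spectra, the model's preprocessing pipeline (with its stored scaler) is
#' applied, and one prediction per block is emitted together with its QC
#' flag.  A prediction is flagged `saturated` only when the model's
#' retained wavenumbers intersect the detected saturated interval, so
#' models restricted to unsaturated VIP intervals keep reporting through
#' band oversaturation.  Models without OH normalization (the VLP models)
#' require process data at their calibration exposure time.
#'
#' @param models a single model or list of models from [run_calibration()].
#' @param process_set raw, time-ordered process [raman_set] carrying `dv`
#'   metadata.
#' @param qc list of QC parameters: `clip_level`, `band`, `window`, `k`
#'   (see [qc_report()]).
#' @return a `transfer_run`: list with `predictions` (data.frame: `dv`,
#'   `model_name`, `prediction`, `unit`, `flag`), `qc` (the block-level QC
#'   report) and `manifest`.
#' @export
run_transfer <- function(models, process_set,
                         qc = list(clip_level = 65535, band = c(900, 1060),
                                   window = 31L, k = 6)) {
  if (!is.list(models) || inherits(models, c("lr_model", "pls_model"))) {
    models <- list(models)
  }
  stopifnot(inherits(process_set, "raman_set"))
  if (all(is.na(process_set$meta$dv))) stop("process spectra carry no dv metadata")

  preds <- list()
  qc_block <- NULL
  for (m in models) {
    cfg <- attr(m, "pipeline")
    if (is.null(cfg)) stop("model has no stored pipeline configuration")
    if (is.null(cfg$normalize_wavenumber)) {
      train_exp <- attr(m, "train_exposure_ms")
      got <- unique(process_set$meta$exposure_ms)
      if (!all(got %in% train_exp)) {
        stop(sprintf("model '%s' has no exposure normalization: process data at %s ms cannot be used with a calibration at %s ms",
                     cfg$name, paste(got, collapse = "/"),
                     paste(train_exp, collapse = "/")))
      }
    }
    raw_avg <- if (cfg$average_n > 1L) average_block(process_set, cfg$average_n)
               else process_set
    qcr <- qc_report(raw_avg, clip_level = qc$clip_level %||% 65535,
                     band = qc$band %||% c(900, 1060),
                     window = qc$window %||% 31L, k = qc$k %||% 6,
                     min_dev = qc$min_dev %||% 0.02)
    if (is.null(qc_block)) qc_block <- qcr

    pre <- run_pipeline(process_set, cfg, scaler = attr(m, "scaler"))
    p <- stats::predict(m, pre)

    retained <- if (inherits(m, "pls_model")) m$retained_wavenumbers else m$wavenumber
    sat_hits <- !is.na(qcr$sat_lo) &
      vapply(seq_len(nrow(qcr)), function(i) {
        !is.na(qcr$sat_lo[i]) &&
          any(retained >= qcr$sat_lo[i] - 20 & retained <= qcr$sat_hi[i] + 20)
      }, logical(1))
    flag <- ifelse(sat_hits & grepl("defective", qcr$flag), "saturated;defective",
                   ifelse(sat_hits, "saturated",
                          ifelse(grepl("defective", qcr$flag), "defective", "ok")))
    preds[[length(preds) + 1L]] <- data.frame(
      dv = pre$meta$dv, model_name = cfg$name, prediction = p,
      unit = if (cfg$analyte == "AMS") "mol/L" else "g/L", flag = flag)
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$model_name, predictions$dv), ]
  rownames(predictions) <- NULL

  structure(list(predictions = predictions, qc = qc_block,
                 manifest = list(
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   models = vapply(models, function(m) attr(m, "pipeline")$name,
                                   character(1)),
                   model_md5 = vapply(models, object_md5, character(1)),
                   n_process = n_spectra(process_set),
                   qc_params = qc)),
            class = "transfer_run")
}

#' Summarise transferred predictions
#'
#' Computes per-model RMSE and R-squared against ground truth (interpolated
#' at each prediction's DV), restricted to unflagged rows by default, plus
#' flag counts.  Without ground truth only the flag summary is returned.
#'
#' @param transfer a `transfer_run` or its `predictions` data.frame.
#' @param ground_truth optional data.frame with `dv` and `c_ams` and/or
#'   `c_vlp` columns (a `process_trace` works).
#' @param include_flagged include flagged rows in the error metrics?
#' @return a `transfer_report`: list with `metrics` (per-model data.frame)
#'   and `flag_counts`.
#' @export
report <- function(transfer, ground_truth = NULL, include_flagged = FALSE) {
  preds <- if (inherits(transfer, "transfer_run")) transfer$predictions else transfer
  flag_counts <- as.data.frame(table(model = preds$model_name, flag = preds$flag))
  flag_counts <- flag_counts[flag_counts$Freq > 0L, ]
  rownames(flag_counts) <- NULL

  met <- NULL
  if (!is.null(ground_truth)) {
    met <- do.call(rbind, lapply(split(preds, preds$model_name), function(d) {
      truth_col <- if (d$unit[1L] == "mol/L") "c_ams" else "c_vlp"
      if (is.null(ground_truth[[truth_col]])) {
        return(NULL)
      }
      if (!include_flagged) d <- d[d$flag == "ok", , drop = FALSE]
      if (nrow(d) < 2L) return(NULL)
      truth <- stats::approx(ground_truth$dv, ground_truth[[truth_col]],
                             d$dv, rule = 2)$y
      fr <- metrics(d$prediction, truth)
      data.frame(model_name = d$model_name[1L], n = fr$n_test,
                 rmse = fr$rmse, r2 = fr$r2)
    }))
    rownames(met) <- NULL
  }
  structure(list(metrics = met, flag_counts = flag_counts),
            class = "transfer_report")
}

#' @export
#' @method print transfer_report
print.transfer_report <- function(x, ...) {
  cat("<transfer_report>\n")
  if (!is.null(x$metrics)) {
    cat("metrics on unflagged predictions:\n")
    print(x$metrics)
  }
  cat("flag counts:\n")
  print(x$flag_counts)
  invisible(x)
}
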