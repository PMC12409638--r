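# Regression layer: single-wavenumber linear regression, NIPALS PLS1 with
# cross-validated latent-variable selection, VIP scores with interval
# selection, and error metrics.

#' Extract the preprocessed intensity matrix of a set
#'
#' @param set a [raman_set].
#' @return numeric matrix (spectra x wavenumbers) with wavenumbers as
#'   column names.
#' @export
intensity_matrix <- function(set) {
  X <- set$intensity
  colnames(X) <- as.character(set$wavenumber)
  X
}

#' Single-wavenumber linear regression
#'
#' Ordinary least squares of the reference concentration on the preprocessed
#' intensity at one wavenumber (980 cm^-1 for the AMS model, where the
#' sulfate band peaks).
#'
#' @param trainset a preprocessed [raman_set] with reference values.
#' @param wavenumber regression wavenumber in cm^-1 (must be retained).
#' @return an `lr_model` with `wavenumber`, `slope` and `intercept`.
#' @export
fit_linear <- function(trainset, wavenumber) {
  stopifnot(inherits(trainset, "raman_set"))
  if (is.null(trainset$reference)) stop("training set has no reference values")
  idx <- which(trainset$wavenumber == wavenumber)
  if (length(idx) != 1L) stop("wavenumber ", wavenumber, " not retained in set")
  x <- trainset$intensity[, idx]
  y <- trainset$reference
  if (length(unique(y)) < 2L) stop("need at least 2 distinct reference values")
  if (stats::sd(x) == 0) stop("constant intensities at ", wavenumber, " cm-1")
  slope <- stats::cov(x, y) / stats::var(x)
  structure(list(wavenumber = wavenumber, slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 analyte = trainset$analyte),
            class = "lr_model")
}

#' @export
predict.lr_model <- function(object, newdata, ...) {
  set <- newdata
  stopifnot(inherits(set, "raman_set"))
  idx <- which(set$wavenumber == object$wavenumber)
  if (length(idx) != 1L) {
    stop("model wavenumber ", object$wavenumber, " not present in set (axis mismatch)")
  }
  as.numeric(object$intercept + object$slope * set$intensity[, idx])
}

#' NIPALS PLS1 regression
#'
#' Mean-centered single-response partial least squares fitted by the NIPALS
#' algorithm: for each component the weight vector w is the normalised
#' covariance direction X'y, scores t = Xw, loadings p = X't / t't and
#' q = y't / t't, after which X and y are deflated.  The regression
#' coefficient vector is b = W (P'W)^{-1} q.
#'
#' @param X numeric matrix (n samples x p wavenumbers), column names are
#'   wavenumbers.
#' @param y numeric response vector of length n.
#' @param ncomp number of latent variables A.
#' @return a `pls_model` with weights `W`, loadings `P`, y-loadings `q`,
#'   coefficient vector `b`, centering terms, per-component score sums of
#'   squares, and a `truncated` flag when A exceeded the effective rank.
#' @export
nipals_pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 samples")
  if (length(y) != n) stop("length of y must match rows of X")
  if (stats::sd(y) == 0) stop("zero-variance response")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1")
  a_max <- min(n - 1L, p)
  truncated <- FALSE
  if (ncomp > a_max) {
    warning("ncomp truncated from ", ncomp, " to ", a_max, " (rank limit)")
    ncomp <- a_max
    truncated <- TRUE
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  x_scale_ref <- max(sqrt(colSums(Xc^2)), 1e-300)

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp); tt <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * x_scale_ref * max(abs(yc), 1e-300) || !is.finite(nw) || nw == 0) {
      truncated <- TRUE
      break
    }
    w <- w / nw
    t_a <- as.numeric(Xc %*% w)
    tt_a <- sum(t_a^2)
    if (tt_a <= 0) { truncated <- TRUE; break }
    p_a <- as.numeric(crossprod(Xc, t_a)) / tt_a
    q_a <- sum(yc * t_a) / tt_a
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a; tt[a] <- tt_a
    a_used <- a
  }
  if (a_used == 0L) stop("no usable PLS component (X'y vanishes)")
  idx <- seq_len(a_used)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]; q <- q[idx]; tt <- tt[idx]
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  retained <- if (is.null(colnames(X))) {
    seq_len(p)
  } else suppressWarnings(as.numeric(colnames(X)))

  structure(list(n_components = a_used, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, b = b, score_ss = tt, scores = Tm,
                 retained_wavenumbers = retained,
                 truncated = truncated),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "raman_set")) {
    set <- newdata
    if (length(set$wavenumber) != length(object$retained_wavenumbers) ||
        any(set$wavenumber != object$retained_wavenumbers)) {
      stop("axis mismatch with model's retained wavenumbers")
    }
    set$intensity
  } else as.matrix(newdata)
  if (ncol(X) != length(object$b)) stop("axis mismatch with model's retained wavenumbers")
  as.numeric(sweep(X, 2L, object$x_mean) %*% object$b + object$y_mean)
}

#' Cross-validated selection of the PLS component count
#'
#' Splits the samples once into training (80 %) and validation (20 %,
#' rounded up, at least 3 samples), fits PLS models over the candidate
#' component counts on the training split and evaluates the validation
#' RMSE.  The default parsimony rule returns the smallest component count
#' whose validation RMSE is within 5 % of the minimum; `rule = "argmin"`
#' returns the plain minimiser.
#'
#' @param X sample x wavenumber matrix.
#' @param y response vector.
#' @param a_range candidate component counts (default 2:10).
#' @param split_fraction training fraction of the random split.
#' @param seed mandatory seed for the split.
#' @param rule `"parsimony"` or `"argmin"`.
#' @param parsimony_tol relative RMSE margin of the parsimony rule.
#' @return list with `ncomp` (selected count) and `cv_table`
#'   (data.frame of component count vs validation RMSE).
#' @export
cv_select_components <- function(X, y, a_range = 2:10, split_fraction = 0.8,
                                 seed, rule = c("parsimony", "argmin"),
                                 parsimony_tol = 0.05) {
  rule <- match.arg(rule)
  if (length(a_range) == 0L) stop("empty component range")
  a_range <- sort(unique(as.integer(a_range)))
  X <- as.matrix(X)
  n <- nrow(X)
  n_val <- max(3L, ceiling((1 - split_fraction) * n))
  if (n - n_val < 3L) stop("too few samples for an 80/20 split with >= 3 validation samples")
  val <- with_seed(seed, sort(sample.int(n, n_val)))
  tr <- setdiff(seq_len(n), val)

  a_max <- min(max(a_range), length(tr) - 1L, ncol(X))
  fit <- nipals_pls_fit(X[tr, , drop = FALSE], y[tr], a_max)
  rmse <- vapply(a_range, function(a) {
    a_eff <- min(a, fit$n_components)
    b_a <- as.numeric(fit$W[, 1:a_eff, drop = FALSE] %*%
                        solve(crossprod(fit$P[, 1:a_eff, drop = FALSE],
                                        fit$W[, 1:a_eff, drop = FALSE]),
                              fit$q[1:a_eff]))
    pred <- sweep(X[val, , drop = FALSE], 2L, fit$x_mean) %*% b_a + fit$y_mean
    sqrt(mean((pred - y[val])^2))
  }, numeric(1))
  cv_table <- data.frame(ncomp = a_range, rmse_val = rmse)
  # absolute floor treats validation errors at numerical noise as ties, so
  # exactly-fitting models still resolve to the smallest component count
  tie_floor <- 1e-8 * stats::sd(y)
  ncomp <- if (rule == "argmin") {
    a_range[which.min(rmse)]
  } else {
    min(a_range[rmse <= (1 + parsimony_tol) * min(rmse) + tie_floor])
  }
  list(ncomp = ncomp, cv_table = cv_table, validation_idx = val)
}

#' VIP scores of a fitted PLS model
#'
#' Variable importance in projection:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a = q_a^2 t_a' t_a} is the response variance explained by
#' component a.  The scores satisfy \eqn{\sum_j VIP_j^2 = p}.
#'
#' @param model a `pls_model`.
#' @return a `vip_result` with per-wavenumber `scores` (named by
#'   wavenumber), and empty `threshold`/`intervals` until
#'   [select_vip_intervals()] is applied.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$W
  p <- nrow(W)
  wn2 <- colSums(W^2)
  if (any(wn2 <= 0)) stop("degenerate weight vector (zero norm)")
  ssy <- model$q^2 * model$score_ss
  scores <- sqrt(p * as.numeric(sweep(W^2, 2L, wn2, "/") %*% ssy) / sum(ssy))
  names(scores) <- as.character(model$retained_wavenumbers)
  structure(list(scores = scores, threshold = NA_real_, intervals = NULL),
            class = "vip_result")
}

#' Select wavenumber intervals from VIP scores
#'
#' Groups wavenumbers with VIP >= threshold into contiguous runs on the
#' instrument grid, merges runs separated by at most `merge_gap` cm^-1, and
#' drops runs narrower than `min_width` points.  Intervals are inclusive.
#' An empty selection is allowed and flagged with a warning.
#'
#' @param vip a `vip_result` from [vip_scores()].
#' @param threshold VIP threshold (default 1, the greater-than-one
#'   convention).
#' @param min_width minimum run width in grid points.
#' @param merge_gap maximum gap bridged when merging runs, in cm^-1.
#' @return the `vip_result` with `threshold` and `intervals` (matrix with
#'   columns lo, hi) filled in.
#' @export
select_vip_intervals <- function(vip, threshold = 1, min_width = 5L,
                                 merge_gap = 5) {
  stopifnot(inherits(vip, "vip_result"))
  w <- as.numeric(names(vip$scores))
  sel <- w[vip$scores >= threshold]
  vip$threshold <- threshold
  if (length(sel) == 0L) {
    warning("no wavenumbers reach the VIP threshold ", threshold)
    vip$intervals <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("lo", "hi")))
    return(vip)
  }
  spacing <- if (length(w) > 1L) min(diff(w)) else 1
  runs <- axis_segments(sel, spacing = spacing)
  # merge runs separated by <= merge_gap cm^-1
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1L]) {
    if (runs[i, 1L] - merged[nrow(merged), 2L] <= merge_gap) {
      merged[nrow(merged), 2L] <- runs[i, 2L]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  widths <- vapply(seq_len(nrow(merged)), function(i) {
    sum(w >= merged[i, 1L] & w <= merged[i, 2L])
  }, integer(1))
  vip$intervals <- merged[widths >= min_width, , drop = FALSE]
  colnames(vip$intervals) <- c("lo", "hi")
  if (nrow(vip$intervals) == 0L) warning("all VIP runs narrower than min_width")
  vip
}

#' Prediction error metrics
#'
#' RMSE and coefficient of determination of predictions against reference
#' values.  R-squared is computed about the reference mean and reported as
#' `NA` when the reference has zero variance.
#'
#' @param pred predicted concentrations.
#' @param ref reference concentrations (same length, >= 2).
#' @return a `fit_report` with `rmse`, `r2`, `n_test` and `predictions`.
#' @export
metrics <- function(pred, ref) {
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref)) stop("pred and ref must have equal length")
  if (length(ref) < 2L) stop("need at least 2 observations")
  rmse <- sqrt(mean((pred - ref)^2))
  ss_tot <- sum((ref - mean(ref))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero reference variance: R2 undefined")
    NA_real_
  } else 1 - sum((pred - ref)^2) / ss_tot
  structure(list(rmse = rmse, r2 = r2, n_test = length(ref), predictions = pred),
            class = "fit_report")
}

#' @export
#' @method print fit_report
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> n = %d, RMSE = %.4g, R2 = %s\n", x$n_test, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}

## ---- model serialization ---------------------------------------------------

#' Write a calibration model to JSON
#'
#' Serializes an `lr_model` or `pls_model` together with its pipeline
#' configuration and scaler state (stored as attributes by
#' [run_calibration()]) into a versioned JSON document.
#'
#' @param model a fitted model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(format_version = "1.0",
                  class = class(model)[1L],
                  model = unclass(model),
                  pipeline = if (!is.null(attr(model, "pipeline"))) {
                    unclass(attr(model, "pipeline"))
                  },
                  scaler = if (!is.null(attr(model, "scaler"))) {
                    unclass(attr(model, "scaler"))
                  },
                  train_exposure_ms = attr(model, "train_exposure_ms"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path file written by [write_model()].
#' @return the model with its `"pipeline"` and `"scaler"` attributes
#'   restored.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format_version, "1.0")) {
    stop("unsupported model format version: ", payload$format_version)
  }
  m <- payload$model
  if (payload$class == "pls_model") {
    for (fld in c("W", "P", "scores")) m[[fld]] <- as.matrix(m[[fld]])
  }
  model <- structure(m, class = payload$class)
  if (!is.null(payload$pipeline)) {
    cfg <- payload$pipeline
    for (fld in c("precrop_exclude", "crop_include", "vip_exclude")) {
      if (!is.null(cfg[[fld]])) cfg[[fld]] <- as_intervals(cfg[[fld]])
    }
    attr(model, "pipeline") <- structure(cfg, class = "pipeline_config")
  }
  if (!is.null(payload$scaler)) {
    attr(model, "scaler") <- structure(payload$scaler, class = "scaler_state")
  }
  if (!is.null(payload$train_exposure_ms)) {
    attr(model, "train_exposure_ms") <- payload$train_exposure_ms
  }
  model
}
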