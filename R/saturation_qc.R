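# Quality control: detector oversaturation (clipping / split peak) and
# defective-spectrum detection.
#
# Oversaturation of a strong band (the 980 cm^-1 sulfate band at long
# exposure times) shows up either as a run of points pinned at the detector
# full scale or as the characteristic "split peak": two flank maxima with an
# interior minimum where the true apex exceeded the full scale.  Defective
# spectra exhibit gross baseline shifts unrelated to composition and are
# detected as outliers of the total intensity relative to their temporal
# neighbourhood.  QC only flags; flagged spectra are never corrected or
# dropped.

#' Detect detector oversaturation in a band
#'
#' Operates on raw (pre-normalization) intensities.  A spectrum is flagged
#' `saturated` when, within `band`, either (a) at least `min_run`
#' consecutive points lie within `rel_tol` of `clip_level`, or (b) the band
#' shows two local maxima of comparable height (each within 10 % of the
#' band maximum, as both flanks of a folded band pin near the clip level)
#' with an interior minimum whose depth exceeds `dip_frac` of the band
#' amplitude (the split-peak signature).  Spectra whose band maximum stays
#' below 0.9 x `clip_level` are never flagged.  The thresholds are
#' heuristics calibrated on the synthetic generator and are all exposed as
#' arguments.
#'
#' @param set a raw [raman_set].
#' @param clip_level detector full scale in counts (default 65535, 16-bit).
#' @param band inclusive wavenumber interval to inspect (default
#'   `c(900, 1060)`, around the sulfate band).
#' @param rel_tol relative closeness to the clip level for rule (a).
#' @param min_run minimum run length for rule (a).
#' @param dip_frac minimum interior dip depth, as a fraction of the band
#'   amplitude, for rule (b).
#' @return a `data.frame` (one row per spectrum): `sample_id`, `dv`,
#'   `saturated`, `sat_lo`, `sat_hi` (affected interval in cm^-1, `NA` when
#'   unflagged).
#' @export
detect_saturation <- function(set, clip_level = 65535, band = c(900, 1060),
                              rel_tol = 0.005, min_run = 3L, dip_frac = 0.05) {
  stopifnot(inherits(set, "raman_set"))
  cols <- which(set$wavenumber >= band[1L] & set$wavenumber <= band[2L])
  if (length(cols) < 3L) stop("band outside axis (or too narrow)")
  w <- set$wavenumber[cols]

  one <- function(y) {
    out <- list(saturated = FALSE, lo = NA_real_, hi = NA_real_)
    if (max(y) < 0.9 * clip_level) return(out)
    near <- abs(y - clip_level) <= rel_tol * clip_level
    r <- rle(near)
    if (any(r$values & r$lengths >= min_run)) {
      ends <- cumsum(r$lengths)
      i <- which(r$values & r$lengths >= min_run)[1L]
      out$saturated <- TRUE
      out$lo <- w[ends[i] - r$lengths[i] + 1L]
      out$hi <- w[ends[i]]
      return(out)
    }
    # split peak: two highest local maxima with a deep-enough interior minimum
    n <- length(y)
    is_max <- c(FALSE, y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n], FALSE)
    peaks <- which(is_max)
    if (length(peaks) >= 2L) {
      ord <- peaks[order(y[peaks], decreasing = TRUE)]
      amp <- max(y) - min(y)
      for (i in seq_len(min(length(ord), 4L) - 1L)) {
        for (j in (i + 1L):min(length(ord), 4L)) {
          a <- min(ord[i], ord[j]); b <- max(ord[i], ord[j])
          if (b - a < 2L) next
          if (min(y[a], y[b]) < 0.9 * max(y)) next # flank maxima comparable
          dip <- min(y[a], y[b]) - min(y[(a + 1L):(b - 1L)])
          if (dip >= dip_frac * amp) {
            out$saturated <- TRUE
            out$lo <- w[a]; out$hi <- w[b]
            return(out)
          }
        }
      }
    }
    out
  }

  res <- lapply(seq_len(n_spectra(set)), function(i) one(set$intensity[i, cols]))
  data.frame(sample_id = set$meta$sample_id,
             dv = set$meta$dv,
             saturated = vapply(res, `[[`, logical(1), "saturated"),
             sat_lo = vapply(res, `[[`, numeric(1), "lo"),
             sat_hi = vapply(res, `[[`, numeric(1), "hi"))
}

#' Detect defective spectra in a time-ordered series
#'
#' Computes each spectrum's total intensity, normalizes by the series
#' median (so the score is invariant to global rescaling), and scores each
#' spectrum by its absolute deviation from the rolling median of `window`
#' neighbours divided by the rolling median absolute deviation (MAD).
#' Spectra are flagged defective when the score exceeds `k` and the
#' deviation itself exceeds `min_dev` (a defective spectrum is a gross
#' baseline shift; the absolute floor keeps sub-percent trend curvature
#' from being flagged purely because the local noise scale is small).
#'
#' @param set a time-ordered [raman_set] with at least 5 spectra.
#' @param window rolling window length (forced odd; must not exceed the
#'   number of spectra).  For a persistent defect the window must span the
#'   defect run, or the rolling median is itself contaminated.
#' @param k flagging threshold on the robust score.
#' @param min_dev minimum absolute deviation of the median-normalized total
#'   intensity (fraction of the series median) for a flag.
#' @return a `data.frame` (one row per spectrum): `sample_id`, `dv`,
#'   `defective`, `defect_score`.
#' @export
detect_defective <- function(set, window = 15L, k = 6, min_dev = 0.02) {
  stopifnot(inherits(set, "raman_set"))
  n <- n_spectra(set)
  if (n < 5L) stop("need at least 5 spectra")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window) stop("fewer spectra (", n, ") than window ", window)
  if (k <= 0) stop("k must be positive")

  total <- rowSums(set$intensity)
  tnorm <- total / stats::median(total)
  rmed <- stats::runmed(tnorm, window, endrule = "median")
  dev <- abs(tnorm - rmed)
  # robust scale: rolling MAD of the median-subtracted series, so a smooth
  # process trend (which the rolling median tracks) does not inflate it
  h <- (window - 1L) %/% 2L
  rmad <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    stats::median(dev[idx])
  }, numeric(1))
  # guard: exactly reproduced neighbourhoods give 0/0 -> score 0
  score <- ifelse(dev == 0, 0, dev / pmax(rmad, .Machine$double.eps))
  data.frame(sample_id = set$meta$sample_id,
             dv = set$meta$dv,
             defective = score > k & dev > min_dev,
             defect_score = score)
}

#' Combined QC report for a process series
#'
#' Runs [detect_saturation()] and [detect_defective()] on a raw
#' (block-averaged) process series and merges the results.
#'
#' @param set a raw [raman_set], time-ordered.
#' @param clip_level detector full scale in counts.
#' @param band saturation inspection band (cm^-1).
#' @param window,k defective-spectrum parameters; the default window of 31
#'   blocks is sized so that a defect persisting for about one
#'   diafiltration volume (at 0.1 DV block spacing) still deviates from its
#'   rolling median.
#' @return a `data.frame` with columns `sample_id`, `dv`, `flag`
#'   (`"ok"`, `"saturated"`, `"defective"` or `"saturated;defective"`),
#'   `defect_score`, `sat_lo`, `sat_hi`.
#' @export
qc_report <- function(set, clip_level = 65535, band = c(900, 1060),
                      window = 31L, k = 6, min_dev = 0.02) {
  sat <- detect_saturation(set, clip_level = clip_level, band = band)
  def <- detect_defective(set, window = window, k = k, min_dev = min_dev)
  flag <- ifelse(sat$saturated & def$defective, "saturated;defective",
                 ifelse(sat$saturated, "saturated",
                        ifelse(def$defective, "defective", "ok")))
  data.frame(sample_id = sat$sample_id, dv = sat$dv, flag = flag,
             defect_score = def$defect_score,
             sat_lo = sat$sat_lo, sat_hi = sat$sat_hi)
}
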