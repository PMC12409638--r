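# Spectrum containers and on-disk table formats.
#
# A `raman_set` holds an ordered collection of spectra that share one
# wavenumber axis: the axis (strictly increasing, cm^-1), an n x p intensity
# matrix (one row per spectrum, detector counts), per-spectrum acquisition
# metadata, and optionally a vector of reference concentrations used for
# calibration.  Interior gaps introduced by pre-cropping are tracked as
# contiguous axis segments.

#' Default instrument wavenumber axis
#'
#' The full acquisition grid: 200 to 3300 cm^-1 at 1 cm^-1 spacing
#' (3101 points).
#'
#' @return numeric vector of wavenumbers in cm^-1.
#' @export
default_axis <- function() seq(200, 3300, by = 1)

# contiguous segments of a (sub)grid: splits wherever the spacing exceeds
# 1.5x the instrument grid spacing
axis_segments <- function(w, spacing = NULL) {
  if (length(w) == 0L) return(matrix(numeric(0), ncol = 2L))
  spacing <- spacing %||% if (length(w) > 1L) min(diff(w)) else 1
  brk <- which(diff(w) > 1.5 * spacing)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(w))
  cbind(lo = w[starts], hi = w[ends])
}

#' Construct a spectrum set
#'
#' @param wavenumber strictly increasing numeric axis (cm^-1).
#' @param intensity numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns; a single spectrum may be given as a plain vector.
#' @param meta optional `data.frame` with one row per spectrum; recognised
#'   columns are `sample_id`, `exposure_ms`, `dv`, `acquisition_mode` and
#'   `flag`.  Missing columns are filled with defaults (175 ms exposure,
#'   offline acquisition, empty flag).
#' @param reference optional non-negative numeric vector of reference
#'   concentrations, one per spectrum (mol/L for AMS, g/L for VLP).
#' @param analyte one of `"none"`, `"AMS"`, `"VLP"`.
#' @return an object of class `raman_set`.
#' @export
raman_set <- function(wavenumber, intensity, meta = NULL, reference = NULL,
                      analyte = c("none", "AMS", "VLP")) {
  analyte <- match.arg(analyte)
  wavenumber <- as.numeric(wavenumber)
  if (is.null(dim(intensity))) intensity <- matrix(intensity, nrow = 1L)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  n <- nrow(intensity)

  if (length(wavenumber) < 1L) stop("empty wavenumber axis")
  if (any(!is.finite(wavenumber))) stop("non-finite wavenumber values")
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly increasing (duplicated or unordered values)")
  }
  if (ncol(intensity) != length(wavenumber)) {
    stop(sprintf("intensity has %d columns but axis has %d points",
                 ncol(intensity), length(wavenumber)))
  }
  if (any(!is.finite(intensity))) stop("non-finite intensity values")

  meta <- as.data.frame(meta %||% data.frame(row.names = seq_len(n)))
  if (nrow(meta) == 0L && n > 0L) meta <- data.frame(row.names = seq_len(n))
  if (nrow(meta) != n) stop("meta must have one row per spectrum")
  if (is.null(meta$sample_id)) meta$sample_id <- sprintf("S%04d", seq_len(n))
  if (is.null(meta$exposure_ms)) meta$exposure_ms <- 175
  if (is.null(meta$dv)) meta$dv <- NA_real_
  if (is.null(meta$acquisition_mode)) meta$acquisition_mode <- "offline"
  if (is.null(meta$flag)) meta$flag <- ""
  std <- c("sample_id", "exposure_ms", "dv", "acquisition_mode", "flag")
  meta <- meta[, c(std, setdiff(names(meta), std)), drop = FALSE]
  rownames(meta) <- NULL
  if (any(!is.finite(meta$exposure_ms)) || any(meta$exposure_ms <= 0)) {
    stop("exposure_ms must be positive")
  }
  if (!all(meta$acquisition_mode %in% c("offline", "semi_continuous", "continuous"))) {
    stop("acquisition_mode must be offline, semi_continuous or continuous")
  }

  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != n) stop("reference must have one value per spectrum")
    if (any(!is.finite(reference)) || any(reference < 0)) {
      stop("reference values must be finite and non-negative")
    }
  }

  structure(
    list(wavenumber = wavenumber, intensity = intensity, meta = meta,
         reference = reference, analyte = analyte,
         segments = axis_segments(wavenumber)),
    class = "raman_set")
}

#' Construct a single spectrum
#'
#' Convenience wrapper returning a one-spectrum [raman_set].
#'
#' @param wavenumber numeric axis (cm^-1).
#' @param intensity numeric intensity vector.
#' @param exposure_ms exposure time in milliseconds (> 0).
#' @param ... further metadata columns (`sample_id`, `dv`,
#'   `acquisition_mode`).
#' @return a [raman_set] with one spectrum.
#' @export
raman_spectrum <- function(wavenumber, intensity, exposure_ms = 175, ...) {
  meta <- data.frame(exposure_ms = exposure_ms, ...)
  raman_set(wavenumber, matrix(intensity, nrow = 1L), meta = meta)
}

#' @export
#' @method print raman_set
print.raman_set <- function(x, ...) {
  seg <- x$segments
  cat(sprintf("<raman_set> %d spectra x %d wavenumbers [%g, %g] cm-1 (%d segment%s)\n",
              nrow(x$intensity), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber),
              nrow(seg), if (nrow(seg) == 1L) "" else "s"))
  cat(sprintf("  analyte: %s; reference: %s; exposure(s): %s ms\n",
              x$analyte, if (is.null(x$reference)) "none" else "attached",
              paste(unique(x$meta$exposure_ms), collapse = "/")))
  prov <- provenance(x)
  if (length(prov)) cat("  provenance:", paste(prov, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set a [raman_set].
#' @return integer count.
#' @export
n_spectra <- function(set) nrow(set$intensity)

#' Subset spectra of a set
#'
#' @param set a [raman_set].
#' @param i row (spectrum) indices.
#' @return a [raman_set] with the selected spectra, preserving provenance.
#' @export
subset_spectra <- function(set, i) {
  out <- raman_set(set$wavenumber, set$intensity[i, , drop = FALSE],
                   meta = set$meta[i, , drop = FALSE],
                   reference = if (!is.null(set$reference)) set$reference[i],
                   analyte = set$analyte)
  attr(out, "provenance") <- provenance(set)
  out
}

## ---- on-disk formats -------------------------------------------------------

meta_path_for <- function(path) sub("\\.csv$", "", path) |> paste0(".meta.csv")

#' Write a spectrum set to a text table
#'
#' `csv_wide` writes a numeric matrix with the wavenumber axis in the first
#' column (`wavenumber_cm-1`) and one column per spectrum, plus a companion
#' `<name>.meta.csv` carrying per-spectrum metadata and reference values.
#' `jcamp_dx` writes a single-spectrum JCAMP-DX file with `(XY..XY)` data.
#' Numeric values are written with 15 significant digits, so a
#' write/read round trip reproduces the set to text precision.
#'
#' @param set a non-empty [raman_set].
#' @param path output file path.
#' @param dialect `"csv_wide"` or `"jcamp_dx"`.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(set, path, dialect = c("csv_wide", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "raman_set"))
  if (n_spectra(set) == 0L) stop("cannot write an empty spectrum set")

  if (dialect == "jcamp_dx") {
    if (n_spectra(set) != 1L) {
      stop("jcamp_dx stores one spectrum per file; got ", n_spectra(set))
    }
    return(invisible(write_jcamp(set, path)))
  }

  ids <- make.unique(set$meta$sample_id)
  tab <- data.table::as.data.table(
    c(list(`wavenumber_cm-1` = set$wavenumber),
      stats::setNames(lapply(seq_len(n_spectra(set)),
                             function(i) set$intensity[i, ]), ids)))
  data.table::fwrite(tab, path)

  meta <- data.frame(
    spectrum_id = ids,
    exposure_time_ms = set$meta$exposure_ms,
    dv = set$meta$dv,
    sample_id = set$meta$sample_id,
    acquisition_mode = set$meta$acquisition_mode,
    reference_value = if (is.null(set$reference)) NA_real_ else set$reference,
    reference_unit = switch(set$analyte, AMS = "mol/L", VLP = "g/L", ""))
  data.table::fwrite(meta, meta_path_for(path))
  invisible(path)
}

#' Read a spectrum set from a text table
#'
#' Counterpart of [write_spectrum_table()].  For `csv_wide` the companion
#' `<name>.meta.csv` is read when present; otherwise default metadata are
#' filled in.
#'
#' @param path input file path.
#' @param dialect `"csv_wide"` or `"jcamp_dx"`.
#' @return a [raman_set].
#' @export
read_spectrum_table <- function(path, dialect = c("csv_wide", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "jcamp_dx") return(read_jcamp(path))

  tab <- data.table::fread(path, header = TRUE)
  if (ncol(tab) < 2L) stop("csv_wide table needs a wavenumber column plus spectra: ", path)
  if (names(tab)[1L] != "wavenumber_cm-1") {
    stop("first column must be 'wavenumber_cm-1', found '", names(tab)[1L], "'")
  }
  w <- as.numeric(tab[[1L]])
  if (anyDuplicated(w)) {
    stop("duplicated wavenumber row at line ",
         which(duplicated(w))[1L] + 1L, " of ", path)
  }
  if (any(diff(w) <= 0)) stop("non-monotone wavenumber axis in ", path)
  intens <- t(as.matrix(tab[, -1L, drop = FALSE]))
  if (any(!is.finite(intens))) {
    bad <- which(!is.finite(intens), arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed value in column '%s', row %d of %s",
                 rownames(intens)[bad[1L]], bad[2L] + 1L, path))
  }

  mp <- meta_path_for(path)
  meta <- NULL; reference <- NULL; analyte <- "none"
  if (file.exists(mp)) {
    md <- data.table::fread(mp, header = TRUE)
    if (nrow(md) != nrow(intens)) stop("metadata rows do not match spectrum columns")
    meta <- data.frame(sample_id = as.character(md$sample_id),
                       exposure_ms = as.numeric(md$exposure_time_ms),
                       dv = as.numeric(md$dv),
                       acquisition_mode = as.character(md$acquisition_mode),
                       flag = "")
    if (!all(is.na(md$reference_value))) {
      reference <- as.numeric(md$reference_value)
      analyte <- switch(as.character(md$reference_unit[1L]),
                        `mol/L` = "AMS", `g/L` = "VLP", "none")
    }
  }
  raman_set(w, intens, meta = meta, reference = reference, analyte = analyte)
}

write_jcamp <- function(set, path) {
  w <- set$wavenumber
  y <- set$intensity[1L, ]
  hdr <- c(
    "##TITLE=Raman spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##FIRSTX=%.15g", w[1L]),
    sprintf("##LASTX=%.15g", w[length(w)]),
    sprintf("##NPOINTS=%d", length(w)),
    sprintf("##$EXPOSURETIMEMS=%.15g", set$meta$exposure_ms[1L]),
    sprintf("##$SAMPLEID=%s", set$meta$sample_id[1L]),
    sprintf("##$ACQUISITIONMODE=%s", set$meta$acquisition_mode[1L]),
    if (!is.na(set$meta$dv[1L])) sprintf("##$DV=%.15g", set$meta$dv[1L]),
    "##XYDATA=(XY..XY)")
  body <- sprintf("%.15g, %.15g", w, y)
  writeLines(c(hdr, body, "##END="), path)
  path
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  istart <- grep("^##XYDATA=", lines)
  if (length(istart) != 1L) stop("no ##XYDATA block in ", path)
  iend <- grep("^##END=", lines)
  iend <- if (length(iend)) iend[1L] else length(lines) + 1L
  body <- lines[(istart + 1L):(iend - 1L)]
  parts <- strsplit(body, ",")
  if (any(lengths(parts) != 2L)) {
    stop("malformed XYDATA pair at line ", istart + which(lengths(parts) != 2L)[1L])
  }
  xy <- matrix(as.numeric(trimws(unlist(parts))), ncol = 2L, byrow = TRUE)
  grab <- function(key, default) {
    ln <- grep(paste0("^##\\$", key, "="), lines, value = TRUE)
    if (length(ln)) sub(paste0("^##\\$", key, "="), "", ln[1L]) else default
  }
  meta <- data.frame(
    sample_id = grab("SAMPLEID", "S0001"),
    exposure_ms = as.numeric(grab("EXPOSURETIMEMS", "175")),
    dv = as.numeric(grab("DV", NA)),
    acquisition_mode = grab("ACQUISITIONMODE", "offline"),
    flag = "")
  raman_set(xy[, 1L], matrix(xy[, 2L], nrow = 1L), meta = meta)
}

## ---- block averaging -------------------------------------------------------

#' Average consecutive blocks of spectra
#'
#' Pointwise arithmetic mean of each block of `n` consecutive spectra,
#' mirroring the instrument practice of averaging 50 recordings before
#' preprocessing.  A trailing partial block is dropped so every output
#' spectrum carries the same noise level.  Metadata are taken from the first
#' spectrum of each block except `dv`, which becomes the block mean; attached
#' reference values are likewise block-averaged.
#'
#' @param set a non-empty [raman_set].
#' @param n positive integer block size.
#' @return a [raman_set] of `floor(n_spectra(set) / n)` averaged spectra.
#' @export
average_block <- function(set, n) {
  stopifnot(inherits(set, "raman_set"))
  if (n_spectra(set) == 0L) stop("empty spectrum set")
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n)) {
    stop("block size n must be a positive integer")
  }
  n <- as.integer(n)
  nb <- n_spectra(set) %/% n
  if (nb == 0L) stop("fewer spectra (", n_spectra(set), ") than block size ", n)
  keep <- seq_len(nb * n)
  grp <- rep(seq_len(nb), each = n)
  avg <- rowsum(set$intensity[keep, , drop = FALSE], grp, reorder = TRUE) / n
  first <- seq(1L, by = n, length.out = nb)
  meta <- set$meta[first, , drop = FALSE]
  meta$dv <- as.numeric(tapply(set$meta$dv[keep], grp, mean))
  out <- raman_set(set$wavenumber, avg, meta = meta,
                   reference = if (!is.null(set$reference)) {
                     as.numeric(tapply(set$reference[keep], grp, mean))
                   },
                   analyte = set$analyte)
  attr(out, "provenance") <- provenance(set)
  add_provenance(out, sprintf("average(n=%d)", n))
}
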