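# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls do not perturb user-level
#' reproducibility.  A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# normalise an interval specification into a 2-column matrix [lo, hi];
# accepts a single number (degenerate interval), c(lo, hi), a list of such,
# or a matrix with two columns.  All intervals are inclusive, in cm^-1.
as_intervals <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("lo", "hi"))))
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    m <- x
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(iv) {
      iv <- as.numeric(iv)
      if (length(iv) == 1L) iv <- c(iv, iv)
      if (length(iv) != 2L) stop("interval must have one or two endpoints")
      iv
    }))
  } else {
    iv <- as.numeric(x)
    if (length(iv) == 1L) iv <- c(iv, iv)
    if (length(iv) != 2L) stop("interval must have one or two endpoints")
    m <- matrix(iv, ncol = 2L)
  }
  if (any(m[, 1L] > m[, 2L])) stop("interval lower bound exceeds upper bound")
  colnames(m) <- c("lo", "hi")
  m
}

# logical vector: which wavenumbers lie inside the union of intervals
# (inclusive of both endpoints)
in_intervals <- function(w, intervals) {
  m <- as_intervals(intervals)
  inside <- rep(FALSE, length(w))
  for (i in seq_len(nrow(m))) {
    inside <- inside | (w >= m[i, 1L] & w <= m[i, 2L])
  }
  inside
}

# append a provenance entry to a spectrum set
add_provenance <- function(set, step) {
  attr(set, "provenance") <- c(attr(set, "provenance"), step)
  set
}

#' Processing provenance of a spectrum set
#'
#' @param set a [raman_set].
#' @return character vector of applied step descriptions, in order.
#' @export
provenance <- function(set) attr(set, "provenance") %||% character(0)

# md5 of an R object via its serialized bytes (used for run manifests)
object_md5 <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}
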