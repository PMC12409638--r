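# Independent oracles and small fixture builders shared across tests.
# Each oracle is a direct, unoptimised construction kept deliberately
# separate from the implementation path it checks.

# Savitzky-Golay by explicit per-point local least squares: centered window
# at interior points, first/last full window refit at the edges (evaluated
# at the point's position inside the window).
sg_local_ls_oracle <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= h) {
      idx <- 1:window; pos <- i
    } else if (i > n - h) {
      idx <- (n - window + 1L):n; pos <- i - (n - window)
    } else {
      idx <- (i - h):(i + h); pos <- h + 1L
    }
    x <- seq_along(idx) - pos
    fit <- stats::lm.fit(outer(x, 0:polyorder, `^`), y[idx])
    out[i] <- fit$coefficients[1L]
  }
  out
}

# dense normal-equation Whittaker solve
dense_whittaker_oracle <- function(y, w, lam, d) {
  n <- length(y)
  D <- diff(diag(n), differences = d)
  as.numeric(solve(diag(w) + lam * t(D) %*% D, w * y))
}

# PLS1 via the Krylov-space construction (Helland): the A-component PLS
# coefficient vector solves a least-squares problem restricted to the
# Krylov basis {s, Ss, ..., S^{A-1} s} with s = X'y, S = X'X.
pls1_krylov_oracle <- function(X, y, A) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  S <- crossprod(Xc)
  K <- matrix(0, ncol(X), A)
  K[, 1L] <- s
  if (A > 1L) for (a in 2:A) K[, a] <- S %*% K[, a - 1L]
  K <- qr.Q(qr(K)) # orthonormalise for conditioning; same span
  b <- K %*% solve(crossprod(K, S %*% K), crossprod(K, s))
  list(b = as.numeric(b),
       predict = function(Xnew) {
         as.numeric(sweep(Xnew, 2L, colMeans(X)) %*% b + mean(y))
       })
}

# small spectrum set on an arbitrary axis
toy_set <- function(n = 3, p = 60, seed = 1, axis = seq_len(p) + 99) {
  withr::with_seed(seed, {
    raman_set(axis, matrix(stats::rnorm(n * p, mean = 10), nrow = n),
              meta = data.frame(exposure_ms = rep(175, n)))
  })
}

# noiseless generator config (no read noise, no preparation jitter)
noiseless_config <- function(...) {
  generator_config(noise_sigma_frac = 0, buffer_jitter_sd = 0, ...)
}
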