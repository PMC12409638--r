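# Regression layer: linear model, NIPALS PLS1, CV selection, VIP, metrics.

make_xy <- function(n = 20, p = 10, seed = 21) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- as.character(seq_len(p) + 400)
    y <- rnorm(n)
    list(X = X, y = y)
  })
}

test_that("fit_linear recovers an exact line and validates input", {
  s <- raman_set(c(979, 980, 981), rbind(c(0, 0, 0), c(1, 1, 1)),
                 reference = c(0, 1.1), analyte = "AMS")
  m <- fit_linear(s, 980)
  expect_equal(m$slope, 1.1)
  expect_equal(m$intercept, 0)
  expect_equal(predict(m, s), c(0, 1.1))

  const <- raman_set(c(980), matrix(c(2, 2), 2), reference = c(0, 1))
  expect_error(fit_linear(const, 980), "constant")
  expect_error(fit_linear(s, 985), "not retained")
  noref <- raman_set(c(980), matrix(1:2, 2))
  expect_error(fit_linear(noref, 980), "no reference")
})

test_that("linear model prediction errors on axis mismatch", {
  s <- raman_set(c(979, 980, 981), rbind(c(0, 0.5, 0), c(1, 2, 1)),
                 reference = c(0, 1), analyte = "AMS")
  m <- fit_linear(s, 980)
  cropped <- crop(s, c(979, 979))
  expect_error(predict(m, cropped), "axis mismatch")
})

test_that("NIPALS PLS1 fits exactly when y lies in a rank-2 column space", {
  withr::with_seed(22, {
    basis <- matrix(rnorm(5 * 2), 5, 2)
    load <- matrix(rnorm(2 * 3), 2, 3)
    X <- basis %*% load
    colnames(X) <- c("a", "b", "c")
    y <- basis %*% c(1, -2) + 3
    m <- nipals_pls_fit(X, as.numeric(y), 2)
    expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  })
})

test_that("NIPALS matches the independent Krylov PLS1 oracle", {
  d <- make_xy()
  m <- nipals_pls_fit(d$X, d$y, 3)
  oracle <- pls1_krylov_oracle(d$X, d$y, 3)
  expect_lt(max(abs(predict(m, d$X) - oracle$predict(d$X))), 1e-8)
  # also on new data
  d2 <- make_xy(seed = 23)
  expect_lt(max(abs(predict(m, d2$X) - oracle$predict(d2$X))), 1e-8)
})

test_that("NIPALS scores are orthogonal and b reproduces training fits", {
  d <- make_xy(n = 15, p = 30)
  m <- nipals_pls_fit(d$X, d$y, 5)
  G <- crossprod(m$scores)
  off <- abs(G - diag(diag(G)))
  expect_lt(max(off) / max(diag(G)), 1e-8)
  fitted <- sweep(d$X, 2, m$x_mean) %*% m$b + m$y_mean
  resid <- d$y - as.numeric(fitted)
  # residual y is orthogonal to extracted scores
  expect_lt(max(abs(crossprod(m$scores, resid))) / sqrt(sum(d$y^2)), 1e-8)
})

test_that("full-rank PLS1 reproduces ordinary least squares", {
  d <- make_xy(n = 20, p = 5)
  m <- nipals_pls_fit(d$X, d$y, 5)
  ols <- stats::lm.fit(cbind(1, d$X), d$y)
  expect_lt(max(abs(predict(m, d$X) - ols$fitted.values)), 1e-8)
})

test_that("PLS1 guards degenerate inputs", {
  d <- make_xy()
  expect_error(nipals_pls_fit(d$X, rep(1, 20), 2), "zero-variance")
  expect_error(nipals_pls_fit(d$X[1:2, ], d$y[1:2], 1), "at least 3")
  expect_warning(nipals_pls_fit(d$X, d$y, 50), "truncated")
})

test_that("prediction is invariant to spectrum ordering", {
  d <- make_xy(n = 12, p = 8)
  m <- nipals_pls_fit(d$X, d$y, 3)
  perm <- c(5, 1, 12, 3, 7)
  expect_equal(predict(m, d$X[perm, ]), predict(m, d$X)[perm])
})

test_that("CV component selection is deterministic and applies the parsimony floor", {
  withr::with_seed(31, {
    # two latent concentration sources generate X; y is an exact (or noisy)
    # function of them, so two components suffice
    n <- 30; p <- 40
    t1 <- rnorm(n); t2 <- rnorm(n)
    X <- tcrossprod(t1, rnorm(p)) + tcrossprod(t2, rnorm(p)) +
      0.001 * matrix(rnorm(n * p), n, p)
    colnames(X) <- as.character(seq_len(p))
    y_exact <- 3 * t1 - t2
    y_noisy <- y_exact + rnorm(n, sd = 0.05 * sd(y_exact))
  })
  exact <- cv_select_components(X, y_exact, a_range = 2:10, seed = 11)
  expect_equal(exact$ncomp, 2) # parsimony floor of the searched range
  a <- cv_select_components(X, y_noisy, a_range = 2:10, seed = 11)
  b <- cv_select_components(X, y_noisy, a_range = 2:10, seed = 11)
  expect_identical(a, b)
  expect_equal(a$ncomp, 2)
  expect_equal(nrow(a$cv_table), 9)
  expect_error(cv_select_components(X, y, a_range = integer(0), seed = 1),
               "empty")
  expect_error(cv_select_components(X[1:4, ], y[1:4], seed = 1), "80/20")
})

test_that("VIP scores satisfy the normalization identity and closed forms", {
  d <- make_xy(n = 25, p = 12, seed = 41)
  m <- nipals_pls_fit(d$X, d$y, 4)
  v <- vip_scores(m)
  expect_equal(sum(v$scores^2), 12, tolerance = 1e-9)

  m1 <- nipals_pls_fit(d$X, d$y, 1)
  v1 <- vip_scores(m1)
  expect_equal(as.numeric(v1$scores),
               sqrt(12) * abs(m1$W[, 1]) / sqrt(sum(m1$W[, 1]^2)),
               tolerance = 1e-12)

  # a constant (zero-weight) variable gets VIP exactly 0
  X0 <- cbind(d$X, 5)
  colnames(X0) <- c(colnames(d$X), "999")
  m0 <- nipals_pls_fit(X0, d$y, 2)
  expect_equal(vip_scores(m0)$scores[["999"]], 0)
})

test_that("VIP interval selection groups, merges and filters runs", {
  w <- 100:199
  scores <- rep(0.2, 100)
  names(scores) <- w
  scores[11:25] <- 2    # run 110..124
  scores[30:34] <- 2    # run 129..133 (merged: gap 5 cm-1)
  scores[61:63] <- 2    # short isolated run (dropped: width 3)
  v <- structure(list(scores = scores, threshold = NA, intervals = NULL),
                 class = "vip_result")
  out <- select_vip_intervals(v, threshold = 1, min_width = 5, merge_gap = 5)
  expect_equal(out$intervals, cbind(lo = 110, hi = 133))

  none <- v; none$scores[] <- 0.1
  expect_warning(out0 <- select_vip_intervals(none, threshold = 1), "threshold")
  expect_equal(nrow(out0$intervals), 0)

  all_in <- v; all_in$scores[] <- 3
  outa <- select_vip_intervals(all_in, threshold = 1)
  expect_equal(outa$intervals, cbind(lo = 100, hi = 199))
})

test_that("metrics computes RMSE and R2 with hand-checked values", {
  r <- metrics(c(1, 2, 4), c(1, 2, 4))
  expect_equal(r$rmse, 0)
  expect_equal(r$r2, 1)

  ref <- c(1, 2, 4)
  r2 <- metrics(rep(mean(ref), 3), ref)
  expect_equal(r2$r2, 0)

  r3 <- metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r3$rmse, sqrt(1 / 3))
  expect_equal(r3$r2, 1 - 1 / (14 / 3))

  expect_warning(rz <- metrics(c(1, 2), c(3, 3)), "zero reference variance")
  expect_true(is.na(rz$r2))
  expect_error(metrics(1:3, 1:4), "equal length")
})

test_that("models serialize to JSON and back", {
  d <- make_xy(n = 15, p = 6, seed = 51)
  m <- nipals_pls_fit(d$X, d$y, 3)
  attr(m, "pipeline") <- builtin_pipelines("PLS_AMS")
  attr(m, "train_exposure_ms") <- 175
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model(m, path)
  back <- read_model(path)
  expect_s3_class(back, "pls_model")
  expect_equal(back$b, m$b, tolerance = 1e-12)
  expect_equal(predict(back, d$X), predict(m, d$X), tolerance = 1e-10)
  expect_equal(attr(back, "pipeline")$name, "PLS_AMS")
  expect_equal(attr(back, "train_exposure_ms"), 175)

  s <- raman_set(c(979, 980, 981), rbind(c(0, 0, 0), c(1, 1, 1)),
                 reference = c(0, 1.1), analyte = "AMS")
  lr <- fit_linear(s, 980)
  path2 <- file.path(withr::local_tempdir(), "lr.json")
  write_model(lr, path2)
  lr2 <- read_model(path2)
  expect_equal(predict(lr2, s), predict(lr, s))
})
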