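test_that("KPSS statistic matches a reference implementation and calls trends", {
  # frozen oracle values: statsmodels kpss() on the same series at the same
  # Bartlett lag (2) gives 0.5532402293810215 (level) and
  # 0.5267681877969551 (trend)
  set.seed(42)
  x <- cumsum(rnorm(100))
  lv <- kpss_test(x, "level")
  tr <- kpss_test(x, "trend")
  expect_equal(lv$statistic, 0.5532402293810215, tolerance = 1e-9)
  expect_equal(tr$statistic, 0.5267681877969551, tolerance = 1e-9)
  expect_lt(lv$p_value, 0.05)
  # i.i.d. noise is stationary
  set.seed(10)
  expect_gt(kpss_test(rnorm(23), "level")$p_value, 0.05)
  expect_error(kpss_test(rnorm(5)), "too short")
})

test_that("kpss_check first-differences non-stationary responses", {
  set.seed(42)
  rw <- cumsum(rnorm(100))
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  ck <- kpss_check(rw, X)
  expect_true(ck$differenced)
  expect_length(ck$y, 99)
  expect_equal(dim(ck$X), c(99L, 2L))
  expect_gt(ck$retest[["level"]], 0.01)
  set.seed(10)
  ck2 <- kpss_check(rnorm(30))
  expect_false(ck2$differenced)
})

test_that("best subsets equals independent enumeration and closed forms", {
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 2 * X[, 3] + rnorm(n)
  bs <- best_subsets(y, X, max_size = 3)
  # independent oracle: lm over every pair
  pairs <- utils::combn(colnames(X), 2, simplify = FALSE)
  rss_pairs <- vapply(pairs, function(s)
    sum(resid(lm(y ~ X[, s[1]] + X[, s[2]]))^2), numeric(1))
  expect_equal(bs$rss[bs$size == 2], min(rss_pairs), tolerance = 1e-10)
  expect_equal(sort(strsplit(bs$covariates[2], ",")[[1]]),
               sort(pairs[[which.min(rss_pairs)]]))
  # perfect fit: y exactly equals one covariate
  bs0 <- best_subsets(X[, 3], X, max_size = 2)
  expect_equal(attr(bs0, "subsets")[[1]], "x3")
  expect_lt(bs0$rss[1], 1e-20)
  # orthonormal design: winners are the largest-|correlation| covariates
  Q <- qr.Q(qr(matrix(rnorm(n * 5), n, 5)))
  colnames(Q) <- paste0("q", 1:5)
  yq <- Q %*% c(3, -2, 1, 0.5, 0.1) + rnorm(n, 0, 0.01)
  bq <- best_subsets(as.vector(yq), Q, max_size = 3)
  ranked <- colnames(Q)[order(-abs(cor(yq, Q)))]
  for (s in 1:3) {
    expect_setequal(attr(bq, "subsets")[[s]], ranked[1:s])
  }
})

test_that("ARIMA evaluation finds white-noise and AR(1) error structures", {
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  y <- 1 + 2 * X[, 1] + rnorm(n, 0, 0.5)
  cand <- arima_evaluate(y, X, p_max = 2, q_max = 2)
  expect_equal(cand$order, c(0, 0, 0))
  expect_gt(cand$ljung_box_p, 0.05)
  ci <- cand$coefficients["x1", ]
  expect_true(ci[["lower95"]] < 2 && ci[["upper95"]] > 2)
  # AR(1) errors, long series
  set.seed(16)
  n <- 200
  X2 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  y2 <- 2 * X2[, 1] + as.vector(arima.sim(list(ar = 0.8), n))
  cand2 <- arima_evaluate(y2, X2, p_max = 2, q_max = 2)
  expect_gte(cand2$order[1], 1)
})

test_that("intercept-only AICc matches the closed-form Gaussian value", {
  set.seed(17)
  y <- rnorm(25)
  cand <- arima_evaluate(y, matrix(nrow = 25, ncol = 0),
                         p_max = 0, d_max = 0, q_max = 0)
  n <- 25; K <- 2                      # mean + sigma2
  sig2 <- mean((y - mean(y))^2)
  ll <- -n / 2 * (log(2 * pi * sig2) + 1)
  expect_equal(cand$aicc, -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1),
               tolerance = 1e-6)
})

test_that("top-model selection enforces significance and white residuals", {
  set.seed(18)
  n <- 24
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 1.5 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.4)
  bs <- best_subsets(y, X, max_size = 4)
  cands <- lapply(attr(bs, "subsets"), function(s)
    arima_evaluate(y, X[, s, drop = FALSE], p_max = 1, q_max = 1))
  sel <- select_top_model(cands)
  expect_s3_class(sel, "arima_candidate")
  expect_true(all(c("x1", "x2") %in% sel$covariates))
  # every covariate CI excludes zero
  ci <- sel$coefficients[sel$covariates, , drop = FALSE]
  expect_true(all(ci[, "lower95"] > 0 | ci[, "upper95"] < 0))
  # single passing candidate comes back unchanged
  expect_identical(select_top_model(list(sel)), sel)
  # nested tie-break prefers the smaller model when the extra term is null
  extra_wins <- 0
  for (r in 1:20) {
    yy <- 1.5 * X[, 1] + rnorm(n, 0, 0.4)
    c1 <- arima_evaluate(yy, X[, "x1", drop = FALSE],
                         p_max = 0, d_max = 0, q_max = 0)
    c2 <- arima_evaluate(yy, X[, c("x1", "x3")],
                         p_max = 0, d_max = 0, q_max = 0)
    pick <- select_top_model(list(c1, c2))
    if (!is.null(pick) && length(pick$covariates) == 2) {
      extra_wins <- extra_wins + 1
    }
  }
  expect_lt(extra_wins, 10)   # smaller model selected in most replicates
})

test_that("with pure-noise covariates, apparent fit is spurious and CV exposes it", {
  # 12 noise covariates, n = 23: best-subsets selection makes coefficients
  # of the per-size winners look significant far more often than the
  # nominal rate, so a "valid" model is frequently found; its apparent
  # (in-sample) adjusted R2 is inflated while the cross-validated R2 stays
  # low. The empirical no-valid-model rate is reported.
  set.seed(19)
  n <- 23
  none <- 0
  n_sim <- 60
  adj <- c(); cvr <- c()
  for (r in seq_len(n_sim)) {
    X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("v", 1:12)))
    y <- rnorm(n)
    bs <- best_subsets(y, X, max_size = 5)
    cands <- lapply(attr(bs, "subsets"), function(s)
      arima_evaluate(y, X[, s, drop = FALSE],
                     p_max = 0, d_max = 0, q_max = 0))
    sel <- select_top_model(cands)
    if (is.null(sel)) {
      none <- none + 1
    } else {
      adj <- c(adj, finalize_ols(sel)$adj_r2)
      cvr <- c(cvr, repeated_cv(sel, seed = r)$cv_r2)
    }
  }
  message(sprintf("no-valid-model rate on pure noise: %d/%d", none, n_sim))
  expect_gt(none, 0)                      # the filter does reject some runs
  expect_gt(median(adj), 0.2)             # in-sample fit looks real...
  expect_lt(median(cvr), 0.35)            # ...but does not cross-validate
  expect_gt(median(adj) - median(cvr), 0.1)
})

test_that("OLS finalization reports adjusted R2 with scale-invariant results", {
  set.seed(20)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 3 * X[, 1] + X[, 2] + rnorm(n, 0, 0.5)
  cand <- arima_evaluate(y, X, p_max = 0, d_max = 0, q_max = 0)
  fin <- finalize_ols(cand)
  expect_true(all(c("fitted", "residual", "std_residual", "leverage",
                    "qq_theoretical") %in% names(fin$diagnostics)))
  # affine rescaling of covariates leaves adj R2 unchanged
  X2 <- X
  X2[, 1] <- 100 * X2[, 1] - 7
  cand2 <- arima_evaluate(y, X2, p_max = 0, d_max = 0, q_max = 0)
  expect_equal(finalize_ols(cand2)$adj_r2, fin$adj_r2, tolerance = 1e-10)
  # perfect fit
  candp <- arima_evaluate(2 * X[, 1], X[, "x1", drop = FALSE],
                          p_max = 0, d_max = 0, q_max = 0)
  expect_equal(candp$order, c(0, 0, 0))
  expect_equal(suppressWarnings(finalize_ols(candp)$adj_r2), 1,
               tolerance = 1e-8)
  # independent response, large n: adj R2 near zero
  set.seed(21)
  Xi <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("x1", "x2")))
  candi <- arima_evaluate(rnorm(200), Xi, p_max = 0, d_max = 0, q_max = 0)
  expect_lt(abs(finalize_ols(candi)$adj_r2), 0.05)
  expect_error(finalize_ols(structure(list(order = c(1, 0, 0)),
                                      class = "arima_candidate")),
               "0,0,0|applicable")
})

test_that("repeated cross-validation reproduces its closed-form anchors", {
  n <- 25
  x <- seq_len(n) / n
  X <- cbind(x1 = x)
  cand <- arima_evaluate(x, X, p_max = 0, d_max = 0, q_max = 0)
  cv <- repeated_cv(cand, seed = 3)
  expect_equal(cv$cv_r2, 1, tolerance = 1e-10)        # y = x exactly
  expect_length(cv$per_repeat, 5)
  expect_equal(sum(cv$per_fold$n_test), 5 * n)
  # independent response: CV R2 near zero
  set.seed(22)
  Xi <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("x1", "x2")))
  candi <- arima_evaluate(rnorm(n), Xi, p_max = 0, d_max = 0, q_max = 0)
  expect_lt(repeated_cv(candi, seed = 4)$cv_r2, 0.35)
  # determinism under seed
  expect_equal(repeated_cv(cand, seed = 9)$cv_r2,
               repeated_cv(cand, seed = 9)$cv_r2)
})

test_that("prediction intervals have the textbook shape and back-transform", {
  set.seed(23)
  n <- 30
  X <- cbind(x1 = rnorm(n))
  y <- 1 + 2 * X[, 1] + rnorm(n, 0, 0.6)
  cand <- arima_evaluate(y, X, p_max = 0, d_max = 0, q_max = 0)
  nd <- data.frame(year = 1:5,
                   x1 = c(mean(X[, 1]), -2, -1, 1.5, 2.5))
  pr <- predict_intervals(cand, nd)
  widths <- pr$upper95 - pr$lower95
  expect_equal(which.min(widths), 1L)    # narrowest at the covariate mean
  expect_true(all(pr$lower95 <= pr$point & pr$point <= pr$upper95))
  # matches the closed-form lm prediction interval
  fit <- lm(y ~ x1, data.frame(y = y, x1 = X[, 1]))
  ref <- predict(fit, nd, interval = "prediction")
  expect_equal(pr$point, unname(ref[, "fit"]), tolerance = 1e-10)
  expect_equal(pr$lower95, unname(ref[, "lwr"]), tolerance = 1e-10)
  # zero residual variance: degenerate interval
  candp <- arima_evaluate(2 * X[, 1], X, p_max = 0, d_max = 0, q_max = 0)
  prp <- predict_intervals(candp, data.frame(x1 = 0.3))
  expect_equal(prp$lower95, prp$point, tolerance = 1e-6)
  expect_equal(prp$upper95, prp$point, tolerance = 1e-6)
  # monotone back-transform preserves ordering
  bt <- predict_intervals(cand, nd,
                          back_transform = list(centre = -4.8, scale = 0.5))
  expect_true(all(bt$lower95 < bt$point & bt$point < bt$upper95))
  expect_true(all(bt$point > 0 & bt$point < 1))
  # missing covariate rows are skipped with a warning
  expect_warning(pm <- predict_intervals(cand,
                                         data.frame(year = 1:2,
                                                    x1 = c(0.1, NA))),
                 "skipping")
  expect_equal(nrow(pm), 1)
})
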