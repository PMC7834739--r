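#' KPSS stationarity test
#'
#' Kwiatkowski-Phillips-Schmidt-Shin test with null hypothesis of level or
#' trend stationarity. The long-run variance uses a Bartlett window with
#' the usual short truncation lag, and the p-value is interpolated from the
#' standard asymptotic critical-value table (clamped to [0.01, 0.1] at the
#' table edges).
#'
#' @param x numeric series (NA dropped).
#' @param type "level" or "trend" stationarity.
#' @param lshort use the short truncation lag trunc(3 sqrt(n)/13) (default)
#'   rather than trunc(10 sqrt(n)/14).
#' @return list with `statistic`, `p_value`, `lag`.
#' @export
kpss_test <- function(x, type = c("level", "trend"), lshort = TRUE) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  n <- length(x)
  assert_that(n >= 10, "kpss_test: series too short (need >= 10)")
  t_idx <- seq_len(n)
  e <- if (type == "level") x - mean(x) else stats::lm.fit(cbind(1, t_idx), x)$residuals
  S <- cumsum(e)
  eta <- sum(S^2) / n^2
  L <- if (lshort) trunc(3 * sqrt(n) / 13) else trunc(10 * sqrt(n) / 14)
  s2 <- sum(e^2) / n
  if (L > 0) {
    for (l in seq_len(L)) {
      s2 <- s2 + 2 * (1 - l / (L + 1)) * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  stat <- eta / s2
  tbl <- if (type == "level") c(0.347, 0.463, 0.574, 0.739) else
    c(0.119, 0.146, 0.176, 0.216)
  pv <- c(0.10, 0.05, 0.025, 0.01)
  p <- stats::approx(tbl, pv, stat, rule = 2)$y
  list(statistic = stat, p_value = p, lag = L, type = type)
}

#' Stationarity screen with first-differencing
#'
#' Runs the KPSS test for both trend and level stationarity on the
#' response. If either p-value is below `alpha`, the response and all
#' covariates are first-differenced and the response is retested. P-values
#' just under the threshold (within `slack`) are accepted with a warning,
#' mirroring the tolerance for near-stationarity (residual autocorrelation
#' is re-checked later by the ARIMA stage anyway).
#'
#' @param y response vector (ordered by year).
#' @param X covariate matrix aligned with `y` (optional).
#' @param alpha significance threshold, default 0.05.
#' @param slack near-threshold tolerance, default 0.005.
#' @return list with `trend_p`, `level_p`, `differenced` (flag), the
#'   (possibly differenced) `y` and `X`, and the retest p-values when
#'   differencing was applied.
#' @export
kpss_check <- function(y, X = NULL, alpha = 0.05, slack = 0.005) {
  tr <- kpss_test(y, "trend")
  lv <- kpss_test(y, "level")
  ps <- c(trend = tr$p_value, level = lv$p_value)
  near <- ps < alpha & ps >= alpha - slack
  if (any(near)) {
    warning("kpss_check: p-value(s) close to ", alpha, " (",
            paste(names(ps)[near], collapse = ", "),
            "); accepted as near-stationary")
  }
  differenced <- any(ps < alpha - slack)
  out <- list(trend_p = tr$p_value, level_p = lv$p_value,
              differenced = differenced, y = y, X = X)
  if (differenced) {
    out$y <- diff(y)
    if (!is.null(X)) out$X <- apply(X, 2, diff)
    tr2 <- kpss_test(out$y, "trend")
    lv2 <- kpss_test(out$y, "level")
    out$retest <- c(trend = tr2$p_value, level = lv2$p_value)
  }
  out
}

#' Exhaustive best-subsets regression
#'
#' Enumerates every covariate subset of size 1..`max_size` and returns the
#' minimum-RSS subset per size (OLS, intercept always included).
#'
#' @param y response vector.
#' @param X covariate matrix with named columns; rows aligned with `y`.
#'   Rows with any missing value are dropped (complete cases).
#' @param max_size largest subset size, default 5.
#' @return data.frame with one row per size: `size`, `covariates`
#'   (comma-separated), `rss`; attribute `subsets` holds the name vectors.
#' @export
best_subsets <- function(y, X, max_size = 5) {
  X <- as.matrix(X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  max_size <- min(max_size, ncol(X))
  assert_that(n >= max_size + 2, "best_subsets: too few complete cases")
  best <- vector("list", max_size)
  rss_best <- rep(Inf, max_size)
  for (size in seq_len(max_size)) {
    combos <- utils::combn(colnames(X), size, simplify = FALSE)
    for (s in combos) {
      Xs <- cbind(1, X[, s, drop = FALSE])
      q <- qr(Xs)
      if (q$rank < ncol(Xs)) {
        warning("best_subsets: rank-deficient subset skipped: ",
                paste(s, collapse = "+"))
        next
      }
      rss <- sum(qr.resid(q, y)^2)
      if (rss < rss_best[size]) {
        rss_best[size] <- rss
        best[[size]] <- s
      }
    }
  }
  keep <- is.finite(rss_best)
  out <- data.frame(
    size = seq_len(max_size)[keep],
    covariates = vapply(best[keep], paste, "", collapse = ","),
    rss = rss_best[keep]
  )
  attr(out, "subsets") <- best[keep]
  out
}

#' Evaluate a covariate subset under regression with ARMA errors
#'
#' Grid-searches ARIMA orders (p, q in 0..3, d in 0..1, no seasonal terms)
#' for a regression of `y` on the subset, fit by maximum likelihood; the
#' order minimizing AICc wins. Returns coefficient estimates with 95%
#' confidence intervals and the Ljung-Box residual-autocorrelation p-value.
#'
#' @param y response vector.
#' @param X_subset covariate matrix (the candidate subset), columns named.
#' @param p_max,d_max,q_max grid bounds.
#' @return object of class `arima_candidate`: `covariates`, `order`,
#'   `aicc`, `coefficients` (estimate, se, lower95, upper95), `ljung_box_p`,
#'   the fitted `arima` object, and the data used.
#' @export
arima_evaluate <- function(y, X_subset, p_max = 3, d_max = 1, q_max = 3) {
  X_subset <- as.matrix(X_subset)
  cc <- stats::complete.cases(y, X_subset)
  y <- y[cc]; X <- X_subset[cc, , drop = FALSE]
  xreg <- if (ncol(X) > 0) X else NULL   # intercept-only model allowed
  n <- length(y)
  # a (near-)perfect linear fit breaks the ARMA likelihood (zero residual
  # variance); such subsets are returned as exact OLS candidates directly
  ols0 <- stats::lm.fit(cbind(intercept = 1, X), y)
  if (sum(ols0$residuals^2) <= 1e-10 * max(sum((y - mean(y))^2), 1e-300)) {
    return(degenerate_candidate(y, X, ols0))
  }
  best <- NULL
  for (d in 0:d_max) for (p in 0:p_max) for (q in 0:q_max) {
    k_par <- p + q + ncol(X) + (if (d == 0) 1 else 0) + 1  # + intercept, sigma2
    n_eff <- n - d
    if (n_eff <= k_par + 1) next
    fit <- withCallingHandlers(
      tryCatch(
        stats::arima(y, order = c(p, d, q), xreg = xreg, method = "ML",
                     include.mean = (d == 0)),
        error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fit) || !is.finite(fit$loglik) ||
        any(!is.finite(diag(fit$var.coef))) ||
        any(diag(fit$var.coef) < 0)) next
    a <- aicc(fit$loglik, k_par, n_eff)
    if (is.null(best) || a < best$aicc) {
      best <- list(fit = fit, order = c(p, d, q), aicc = a, n_eff = n_eff)
    }
  }
  if (is.null(best)) stop("arima_evaluate: no ARIMA order converged")
  fit <- best$fit
  cf <- fit$coef
  se <- sqrt(pmax(diag(fit$var.coef), 0))
  ci <- cbind(estimate = cf, se = se,
              lower95 = cf - stats::qnorm(0.975) * se,
              upper95 = cf + stats::qnorm(0.975) * se)
  res <- stats::residuals(fit)
  fitdf <- best$order[1] + best$order[3]
  lag <- max(fitdf + 1, min(10, floor(length(res) / 2)))
  lb <- stats::Box.test(res, lag = lag, type = "Ljung-Box", fitdf = fitdf)
  structure(list(
    covariates = colnames(X),
    order = best$order,
    aicc = best$aicc,
    coefficients = ci,
    ljung_box_p = unname(lb$p.value),
    fit = fit,
    y = y, X = X
  ), class = "arima_candidate")
}

#' @export
print.arima_candidate <- function(x, ...) {
  cat(sprintf("Regression with ARMA errors: %s | order (%s) AICc %.2f LB p %.3f\n",
              paste(x$covariates, collapse = " + "),
              paste(x$order, collapse = ","), x$aicc, x$ljung_box_p))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Candidate for an (effectively) perfect linear fit, where the ARMA
# likelihood degenerates: exact OLS solution, order (0,0,0), residuals
# treated as white (zero) noise.
degenerate_candidate <- function(y, X, ols) {
  cf <- ols$coefficients
  ci <- cbind(estimate = cf, se = 0, lower95 = cf, upper95 = cf)
  structure(list(
    covariates = colnames(X),
    order = c(0, 0, 0),
    aicc = -Inf,
    coefficients = ci,
    ljung_box_p = 1,
    fit = NULL,
    y = y, X = X
  ), class = "arima_candidate")
}

# Covariate rows of the coefficient table (excludes intercept and ARMA
# terms).
candidate_covariate_ci <- function(candidate) {
  candidate$coefficients[rownames(candidate$coefficients) %in%
                           candidate$covariates, , drop = FALSE]
}

#' Select the overall top model among ARIMA-evaluated candidates
#'
#' A valid candidate must have every covariate 95% CI excluding zero and a
#' Ljung-Box residual p-value above 0.05. Among valid candidates the lowest
#' AICc wins; when the two best are within 2 AICc units, are nested, and
#' both have order (0,0,0), an OLS F-test (ANOVA) breaks the tie (a
#' significant test favours the larger model).
#'
#' @param candidates list of `arima_candidate` objects.
#' @param lb_alpha Ljung-Box threshold, default 0.05.
#' @return the selected candidate, or NULL if none passes the criteria.
#' @export
select_top_model <- function(candidates, lb_alpha = 0.05) {
  assert_that(length(candidates) >= 1, "select_top_model: no candidates")
  ok <- vapply(candidates, function(cand) {
    ci <- candidate_covariate_ci(cand)
    all(ci[, "lower95"] > 0 | ci[, "upper95"] < 0) &&
      cand$ljung_box_p > lb_alpha
  }, logical(1))
  valid <- candidates[ok]
  if (length(valid) == 0L) return(NULL)
  aiccs <- vapply(valid, function(cand) cand$aicc, numeric(1))
  ord <- order(aiccs)
  top <- valid[[ord[1]]]
  if (length(valid) >= 2) {
    second <- valid[[ord[2]]]
    nested <- all(top$covariates %in% second$covariates) ||
      all(second$covariates %in% top$covariates)
    both_ols <- all(top$order == 0) && all(second$order == 0)
    if (abs(top$aicc - second$aicc) <= 2 && nested && both_ols) {
      small <- if (length(top$covariates) <= length(second$covariates)) top else second
      large <- if (length(top$covariates) > length(second$covariates)) top else second
      cc <- stats::complete.cases(large$y, large$X)
      df <- data.frame(y = large$y[cc], large$X[cc, , drop = FALSE])
      f_small <- stats::lm(stats::reformulate(small$covariates, "y"), df)
      f_large <- stats::lm(stats::reformulate(large$covariates, "y"), df)
      pv <- stats::anova(f_small, f_large)[2, "Pr(>F)"]
      top <- if (is.finite(pv) && pv < 0.05) large else small
    }
  }
  top
}

#' OLS finalization of a (0,0,0) candidate
#'
#' Refits the selected model by ordinary least squares and reports the
#' adjusted R-squared, the overall F-test p-value, and diagnostic tables
#' (residuals vs fitted, QQ quantiles, leverage).
#'
#' @param candidate an `arima_candidate` with order (0,0,0).
#' @return list with `adj_r2`, `p_value`, `fit` (the `lm`), and
#'   `diagnostics` (data.frame: fitted, residual, std_residual, leverage,
#'   qq_theoretical).
#' @export
finalize_ols <- function(candidate) {
  assert_that(all(candidate$order == 0),
              "finalize_ols: only applicable to ARIMA order (0,0,0)")
  df <- data.frame(y = candidate$y, candidate$X)
  fit <- stats::lm(stats::reformulate(candidate$covariates, "y"), df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_value <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  std_res <- stats::rstandard(fit)
  diag_tab <- data.frame(
    fitted = stats::fitted(fit),
    residual = stats::residuals(fit),
    std_residual = std_res,
    leverage = stats::hatvalues(fit),
    qq_theoretical = stats::qnorm(stats::ppoints(length(std_res)))[order(order(std_res))]
  )
  list(adj_r2 = sm$adj.r.squared, p_value = unname(p_value), fit = fit,
       diagnostics = diag_tab)
}

#' Repeated k-fold cross-validation of a candidate model
#'
#' Years are randomly partitioned into folds; the model (OLS on the
#' selected covariates) is refit on the training folds and predicts the
#' held-out fold. The CV R-squared is the squared Pearson correlation
#' between pooled out-of-fold predictions and observations, averaged over
#' repeats.
#'
#' @param candidate an `arima_candidate` (its covariates and data are
#'   used).
#' @param repeats number of repeats, default 5.
#' @param folds number of folds, default 5.
#' @param seed RNG seed for fold assignment.
#' @return list with `cv_r2` (mean over repeats), `per_repeat`,
#'   `per_fold` data.frame.
#' @export
repeated_cv <- function(candidate, repeats = 5, folds = 5, seed = NULL) {
  y <- candidate$y
  X <- as.matrix(candidate$X)
  n <- length(y)
  assert_that(n >= folds, "repeated_cv: fewer observations than folds")
  per_repeat <- numeric(repeats)
  rows <- list()
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      repeat {
        fold_id <- sample(rep_len(seq_len(folds), n))
        if (min(tabulate(fold_id, folds)) >= 2 || n < 2 * folds) break
      }
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        test <- fold_id == f
        df_tr <- data.frame(y = y[!test], X[!test, , drop = FALSE])
        fit <- stats::lm(stats::reformulate(candidate$covariates, "y"), df_tr)
        pred[test] <- stats::predict(fit,
                                     newdata = as.data.frame(X[test, , drop = FALSE]))
        rows[[length(rows) + 1L]] <- data.frame(repeat_ = r, fold = f,
                                                n_test = sum(test))
      }
      per_repeat[r] <- stats::cor(y, pred)^2
    }
  })
  list(cv_r2 = mean(per_repeat), per_repeat = per_repeat,
       per_fold = do.call(rbind, rows))
}

#' Predictions with 95% prediction intervals
#'
#' Point predictions and prediction intervals (parameter plus residual
#' variance) for new covariate values, optionally back-transformed to
#' survival units through the scaled-logit constants. Rows of
#' `new_covariates` with a missing covariate are skipped with a warning.
#' Models whose selected ARIMA order is not (0,0,0) are predicted from
#' their regression component by OLS, with a warning.
#'
#' @param candidate an `arima_candidate`.
#' @param new_covariates data.frame of covariate values; a `year` column,
#'   if present, is carried through.
#' @param level interval coverage, default 0.95.
#' @param back_transform optional list with `centre` and `scale`; when
#'   given, point and interval are mapped through
#'   [back_transform_survival()] (monotone, so ordering is preserved).
#' @return data.frame with `year` (if supplied), `point`, `lower95`,
#'   `upper95`.
#' @export
predict_intervals <- function(candidate, new_covariates, level = 0.95,
                              back_transform = NULL) {
  if (!all(candidate$order == 0)) {
    warning("predict_intervals: non-(0,0,0) order; intervals use the OLS regression component")
  }
  nd <- as.data.frame(new_covariates)
  year <- nd$year
  nd <- nd[, candidate$covariates, drop = FALSE]
  ok <- stats::complete.cases(nd)
  if (any(!ok)) {
    warning("predict_intervals: skipping ", sum(!ok),
            " row(s) with missing covariates")
  }
  df <- data.frame(y = candidate$y, candidate$X)
  fit <- stats::lm(stats::reformulate(candidate$covariates, "y"), df)
  pr <- stats::predict(fit, newdata = nd[ok, , drop = FALSE],
                       interval = "prediction", level = level)
  out <- data.frame(point = pr[, "fit"], lower95 = pr[, "lwr"],
                    upper95 = pr[, "upr"])
  if (!is.null(year)) out <- cbind(year = year[ok], out)
  if (!is.null(back_transform)) {
    for (cl in c("point", "lower95", "upper95")) {
      out[[cl]] <- back_transform_survival(out[[cl]],
                                           back_transform$centre,
                                           back_transform$scale)
    }
  }
  rownames(out) <- NULL
  out
}

#' Run the full staged regression protocol
#'
#' The five-step ladder: (1) KPSS stationarity screen with
#' first-differencing; (2) exhaustive best-subsets regression for subset
#' sizes 1..`max_size`; (3) ARIMA-order evaluation of each top subset by
#' AICc/MLE; (4) top-model selection (all covariates significant, white
#' residuals, lowest AICc); (5) OLS finalization when the selected order is
#' (0,0,0). Optionally follows with repeated cross-validation.
#'
#' @param y named response vector (names = years) or plain vector.
#' @param X covariate matrix (rows aligned with `y`, columns named).
#' @param max_size largest subset size, default 5.
#' @param cv run 5x5 repeated cross-validation on the selected model.
#' @param seed RNG seed (cross-validation folds).
#' @return object of class `regression_ladder`: `kpss`, `subsets`,
#'   `candidates`, `selected` (NULL if nothing passes), `ols`
#'   (adj R2/p/diagnostics, when applicable), `cv`.
#' @export
regression_ladder <- function(y, X, max_size = 5, cv = TRUE, seed = NULL) {
  X <- as.matrix(X)
  ks <- kpss_check(y, X)
  y2 <- ks$y; X2 <- ks$X
  bs <- best_subsets(y2, X2, max_size = max_size)
  cands <- lapply(attr(bs, "subsets"), function(s)
    arima_evaluate(y2, X2[, s, drop = FALSE]))
  sel <- select_top_model(cands)
  ols <- NULL
  cvr <- NULL
  if (!is.null(sel)) {
    if (all(sel$order == 0)) ols <- finalize_ols(sel)
    if (cv) cvr <- repeated_cv(sel, seed = seed)
  }
  structure(list(kpss = ks, subsets = bs, candidates = cands,
                 selected = sel, ols = ols, cv = cvr),
            class = "regression_ladder")
}

#' @export
print.regression_ladder <- function(x, ...) {
  cat(sprintf("KPSS p (trend, level): %.3g, %.3g%s\n",
              x$kpss$trend_p, x$kpss$level_p,
              if (x$kpss$differenced) " [first-differenced]" else ""))
  if (is.null(x$selected)) {
    cat("No valid model (no candidate passed the selection criteria)\n")
    return(invisible(x))
  }
  print(x$selected)
  if (!is.null(x$ols)) {
    cat(sprintf("OLS: adj R2 %.3f, p %.3g\n", x$ols$adj_r2, x$ols$p_value))
  }
  if (!is.null(x$cv)) cat(sprintf("CV R2 (5x5): %.3f\n", x$cv$cv_r2))
  invisible(x)
}
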