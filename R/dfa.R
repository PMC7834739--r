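#' Dynamic factor analysis by EM
#'
#' Fits the DFA state-space model
#' \deqn{x_t = x_{t-1} + w_t, \quad w_t \sim N(0, I_k)}
#' \deqn{y_t = Z x_t + v_t, \quad v_t \sim N(0, R)}
#' by maximum likelihood using an EM algorithm with an exact Kalman
#' filter/smoother E-step and closed-form conditional M-steps for the
#' loadings `Z` (zeros above the diagonal in the first k rows, for
#' identifiability) and the structured observation variance `R`. Missing
#' observations are handled exactly, both in the filter (and hence the
#' likelihood) and in the M-step sufficient statistics. The latent trends
#' have unit-variance innovations and a fixed diffuse initial state
#' (x0 = 0, V0 = 5 I), so all scale information lives in `Z` and `R`.
#'
#' @param y numeric matrix, one row per series (m x T); NA = missing. Rows
#'   should be named.
#' @param k number of latent trends, 1 <= k <= m-1.
#' @param r_structure one of "diagonal_equal", "diagonal_unequal",
#'   "equalvarcov", "unconstrained".
#' @param em_tol convergence tolerance on the relative log-likelihood
#'   change.
#' @param max_iter maximum EM iterations.
#' @param seed seed for random restarts (ignored when `restarts = 0`; the
#'   base initialization is deterministic, SVD-based).
#' @param restarts number of additional randomly perturbed starts; the best
#'   log-likelihood wins.
#' @param zscore centre and scale each series before fitting (default TRUE;
#'   conventional for DFA on mixed anomaly series and required for loading
#'   comparability).
#' @param v0 diffuse prior variance on the initial state.
#' @return an object of class `dfa_fit`: loadings `Z` (m x k), smoothed
#'   trends `x` (k x T), `R`, `logLik`, `n_params`, `n_obs`, `aicc`,
#'   `converged`, `iterations`, `logLik_trace`, plus the (z-scored) data.
#' @export
fit_dfa <- function(y, k, r_structure = c("diagonal_equal",
                                          "diagonal_unequal",
                                          "equalvarcov", "unconstrained"),
                    em_tol = 1e-6, max_iter = 5000, seed = NULL,
                    restarts = 0, zscore = TRUE, v0 = 5) {
  r_structure <- match.arg(r_structure)
  y <- as.matrix(y)
  m <- nrow(y); TT <- ncol(y)
  assert_that(k >= 1 && k <= m, "fit_dfa: need 1 <= k <= m")
  assert_that(TT >= 4, "fit_dfa: need T >= 4")
  assert_that(all(rowSums(!is.na(y)) >= 2),
              "fit_dfa: every series needs >= 2 observations")
  if (zscore) {
    mu <- rowMeans(y, na.rm = TRUE)
    sdv <- apply(y, 1, stats::sd, na.rm = TRUE)
    assert_that(all(sdv > 0), "fit_dfa: zero-variance series")
    y <- (y - mu) / sdv
  }

  fits <- vector("list", restarts + 1L)
  fits[[1]] <- dfa_em(y, k, r_structure, em_tol, max_iter, v0,
                      init_seed = NULL)
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      fits[[r + 1L]] <- dfa_em(y, k, r_structure, em_tol, max_iter, v0,
                               init_seed = if (is.null(seed)) r else
                                 derive_seed(seed, paste0("restart", r)))
    }
  }
  best <- fits[[which.max(vapply(fits, function(f) f$logLik, numeric(1)))]]

  rownames(best$Z) <- rownames(y)
  colnames(best$x) <- colnames(y)
  n_obs <- sum(!is.na(y))
  n_params <- dfa_n_params(m, k, r_structure)
  best$aicc <- aicc(best$logLik, n_params, n_obs)
  best$n_params <- n_params
  best$n_obs <- n_obs
  best$k <- k
  best$r_structure <- r_structure
  best$y <- y
  best <- dfa_sign_convention(best)
  class(best) <- "dfa_fit"
  best
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("DFA fit: %d series, %d trend(s), R = %s\n",
              nrow(x$Z), x$k, x$r_structure))
  cat(sprintf("  logLik %.2f  AICc %.2f  (%d params, %d obs)%s\n",
              x$logLik, x$aicc, x$n_params, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

# Parameter count: free loadings (upper triangle of first k rows fixed at
# zero) plus variance parameters by structure.
dfa_n_params <- function(m, k, r_structure) {
  zfree <- m * k - k * (k - 1) / 2
  rpar <- switch(r_structure,
                 diagonal_equal = 1L,
                 diagonal_unequal = m,
                 equalvarcov = 2L,
                 unconstrained = m * (m + 1) / 2)
  as.integer(zfree + rpar)
}

# Logical mask of free elements of Z (TRUE = estimated).
dfa_free_mask <- function(m, k) {
  f <- matrix(TRUE, m, k)
  for (i in seq_len(min(k, m))) {
    if (i < k) f[i, (i + 1):k] <- FALSE
  }
  f
}

dfa_em <- function(y, k, r_structure, em_tol, max_iter, v0, init_seed) {
  m <- nrow(y); TT <- ncol(y)
  free <- dfa_free_mask(m, k)

  # Deterministic SVD-based start (NAs as zeros on the z-scored data),
  # optionally perturbed for random restarts.
  y0 <- y; y0[is.na(y0)] <- 0
  sv <- svd(y0, nu = k, nv = 0)
  Z <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] / sqrt(TT), k, k)
  if (!is.null(init_seed)) {
    Z <- Z + with_seed(init_seed, matrix(stats::rnorm(m * k, 0, 0.5), m, k))
  }
  Z[!free] <- 0
  R <- project_R(diag(pmax(0.5 * apply(y, 1, stats::var, na.rm = TRUE), 0.05),
                      m, m), r_structure)

  logLik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- dfa_estep(y, Z, R, v0)
    trace <- c(trace, e$logLik)
    if (is.finite(logLik) &&
        (e$logLik - logLik) < em_tol * (abs(logLik) + em_tol)) {
      logLik <- e$logLik
      converged <- TRUE
      break
    }
    logLik <- e$logLik
    if (iter >= max_iter) break
    # M-step (ECM): Z given R, then R given new Z.
    Z <- update_Z(e$S_xx, e$S_yx, R, free)
    Se <- e$S_yy - e$S_yx %*% t(Z) - Z %*% t(e$S_yx) +
      Z %*% e$S_xx %*% t(Z)
    R <- project_R((Se + t(Se)) / (2 * TT), r_structure)
  }
  list(Z = Z, x = e$xs, x_var = e$Ps, R = R, logLik = logLik,
       converged = converged, iterations = iter, logLik_trace = trace)
}

# Kalman filter + RTS smoother E-step with exact missing-data handling.
# Returns smoothed states, the log-likelihood, and the complete-data
# sufficient statistics S_xx, S_yx, S_yy (sums over t of E[x x'], E[y x'],
# E[y y'] given all observed data).
dfa_estep <- function(y, Z, R, v0) {
  m <- nrow(y); TT <- ncol(y); k <- ncol(Z)
  Ik <- diag(1, k)
  xp <- matrix(0, k, TT); Pp <- array(0, c(k, k, TT))   # predicted
  xf <- matrix(0, k, TT); Pf <- array(0, c(k, k, TT))   # filtered
  logLik <- 0
  x_prev <- rep(0, k)
  P_prev <- diag(v0, k)                                  # V0 at t = 0
  for (t in seq_len(TT)) {
    xpt <- x_prev
    Ppt <- P_prev + Ik
    obs <- which(!is.na(y[, t]))
    if (length(obs) > 0) {
      Zo <- Z[obs, , drop = FALSE]
      Roo <- R[obs, obs, drop = FALSE]
      S <- Zo %*% Ppt %*% t(Zo) + Roo
      S <- (S + t(S)) / 2
      cS <- chol(S)
      e <- y[obs, t] - Zo %*% xpt
      Sinv_e <- backsolve(cS, forwardsolve(t(cS), e))
      logLik <- logLik - 0.5 * (length(obs) * log(2 * pi) +
                                  2 * sum(log(diag(cS))) + sum(e * Sinv_e))
      K <- Ppt %*% t(Zo) %*% chol2inv(cS)
      xft <- xpt + K %*% e
      Pft <- (Ik - K %*% Zo) %*% Ppt
      Pft <- (Pft + t(Pft)) / 2
    } else {
      xft <- xpt
      Pft <- Ppt
    }
    xp[, t] <- xpt; Pp[, , t] <- Ppt
    xf[, t] <- xft; Pf[, , t] <- Pft
    x_prev <- xft; P_prev <- Pft
  }
  # RTS smoother
  xs <- matrix(0, k, TT); Ps <- array(0, c(k, k, TT))
  xs[, TT] <- xf[, TT]; Ps[, , TT] <- Pf[, , TT]
  if (TT > 1) {
    for (t in (TT - 1):1) {
      J <- Pf[, , t] %*% solve(Pp[, , t + 1])
      xs[, t] <- xf[, t] + J %*% (xs[, t + 1] - xp[, t + 1])
      Pst <- Pf[, , t] + J %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(J)
      Ps[, , t] <- (Pst + t(Pst)) / 2
    }
  }
  # Sufficient statistics, imputing the conditional moments of missing y.
  S_xx <- matrix(0, k, k)
  S_yx <- matrix(0, m, k)
  S_yy <- matrix(0, m, m)
  for (t in seq_len(TT)) {
    Ext <- xs[, t]
    Exx <- Ps[, , t] + tcrossprod(Ext)
    S_xx <- S_xx + Exx
    obs <- which(!is.na(y[, t]))
    mis <- which(is.na(y[, t]))
    Ey <- numeric(m)
    Eyx <- matrix(0, m, ncol(Z))
    Eyy <- matrix(0, m, m)
    if (length(obs) > 0) {
      yo <- y[obs, t]
      Ey[obs] <- yo
      Eyx[obs, ] <- outer(yo, Ext)
      Eyy[obs, obs] <- outer(yo, yo)
    }
    if (length(mis) > 0) {
      Zm <- Z[mis, , drop = FALSE]
      if (length(obs) > 0) {
        Zo <- Z[obs, , drop = FALSE]
        A <- R[mis, obs, drop = FALSE] %*% solve(R[obs, obs, drop = FALSE])
        W <- Zm - A %*% Zo
        Eym <- as.vector(W %*% Ext + A %*% y[obs, t])
        Cm <- R[mis, mis, drop = FALSE] - A %*% R[obs, mis, drop = FALSE]
        Eymx <- W %*% Exx + outer(as.vector(A %*% y[obs, t]), Ext)
        Vym <- W %*% Ps[, , t] %*% t(W) + Cm
        Eymym <- Vym + outer(Eym, Eym)
        Eymyo <- outer(Eym, y[obs, t])
        Ey[mis] <- Eym
        Eyx[mis, ] <- Eymx
        Eyy[mis, mis] <- Eymym
        Eyy[mis, obs] <- Eymyo
        Eyy[obs, mis] <- t(Eymyo)
      } else {
        Eym <- as.vector(Zm %*% Ext)
        Eymx <- Zm %*% Exx
        Vym <- Zm %*% Ps[, , t] %*% t(Zm) + R[mis, mis, drop = FALSE]
        Ey[mis] <- Eym
        Eyx[mis, ] <- Eymx
        Eyy[mis, mis] <- Vym + outer(Eym, Eym)
      }
    }
    S_yx <- S_yx + Eyx
    S_yy <- S_yy + Eyy
  }
  list(xs = xs, Ps = Ps, logLik = logLik,
       S_xx = S_xx, S_yx = S_yx, S_yy = S_yy)
}

# Constrained GLS update of Z: vec(Z) = D theta over the free elements,
# weighting by R^{-1} (needed because the zero constraints couple rows when
# R is non-diagonal).
update_Z <- function(S_xx, S_yx, R, free) {
  m <- nrow(free); k <- ncol(free)
  Rinv <- solve(R)
  Amat <- kronecker(S_xx, Rinv)
  bvec <- as.vector(Rinv %*% S_yx)
  idx <- which(as.vector(free))
  theta <- solve(Amat[idx, idx, drop = FALSE], bvec[idx])
  Z <- matrix(0, m, k)
  Z[idx] <- theta
  Z
}

# Constrained MLE projection of the (expected) residual covariance onto the
# requested structure. For equalvarcov the compound-symmetry MLE follows
# from the fixed eigenbasis (1-vector and its complement).
project_R <- function(Sbar, r_structure) {
  m <- nrow(Sbar)
  switch(r_structure,
         diagonal_equal = diag(mean(diag(Sbar)), m, m),
         diagonal_unequal = diag(diag(Sbar), m, m),
         unconstrained = (Sbar + t(Sbar)) / 2,
         equalvarcov = {
           s1 <- sum(Sbar) / m            # 1'S1/m, eigenvalue v+(m-1)c
           s2 <- (sum(diag(Sbar)) - s1) / (m - 1)
           lam1 <- max(s1, 1e-10)
           lam2 <- max(s2, 1e-10)
           cc <- (lam1 - lam2) / m
           v <- lam2 + cc
           matrix(cc, m, m) + diag(v - cc, m, m)
         })
}

# Sign convention: per trend, the largest-|loading| entry is positive.
dfa_sign_convention <- function(fit) {
  for (j in seq_len(ncol(fit$Z))) {
    i <- which.max(abs(fit$Z[, j]))
    if (fit$Z[i, j] < 0) {
      fit$Z[, j] <- -fit$Z[, j]
      fit$x[j, ] <- -fit$x[j, ]   # smoother variances are sign-invariant
    }
  }
  fit
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1), with n the number of
#' non-missing data points.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param n_params number of estimated parameters K.
#' @param n_obs number of (non-missing) observations n.
#' @return the AICc value.
#' @export
aicc <- function(log_likelihood, n_params, n_obs) {
  assert_that(n_obs > n_params + 1, "aicc: need n_obs > n_params + 1")
  -2 * log_likelihood + 2 * n_params +
    2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}

#' Akaike weights from AICc values
#'
#' @param aicc_values numeric vector of AICc values for a candidate set.
#' @return vector of weights summing to one.
#' @export
akaike_weights <- function(aicc_values) {
  assert_that(length(aicc_values) >= 1, "akaike_weights: empty input")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Varimax rotation of a DFA solution
#'
#' Rotates the loadings to maximize the varimax criterion and applies the
#' inverse (transpose) rotation to the trends, so the fitted values Z x are
#' unchanged. The per-trend sign convention (largest-|loading| positive) is
#' re-applied after rotation.
#'
#' @param model a `dfa_fit`.
#' @return list with `rotation` (orthogonal k x k), `loadings` (m x k) and
#'   `trends` (k x T).
#' @export
varimax_rotate <- function(model) {
  Z <- model$Z; x <- model$x
  k <- ncol(Z)
  if (k == 1) {
    H <- diag(1, 1)
  } else {
    H <- stats::varimax(Z, normalize = FALSE)$rotmat
  }
  Zr <- Z %*% H
  xr <- t(H) %*% x
  colnames(xr) <- colnames(x)
  for (j in seq_len(k)) {
    i <- which.max(abs(Zr[, j]))
    if (Zr[i, j] < 0) {
      Zr[, j] <- -Zr[, j]
      xr[j, ] <- -xr[j, ]
      H[, j] <- -H[, j]
    }
  }
  rownames(Zr) <- rownames(model$Z)
  list(rotation = H, loadings = Zr, trends = xr)
}

#' Search DFA models over trend counts and variance structures
#'
#' Fits every combination of k (default 1..m-1) and observation-variance
#' structure, then ranks by AICc with Akaike weights and cumulative weights.
#'
#' @param data wide year-by-variable matrix or data.frame (as produced by
#'   [anomalies_wide()]); rows are years, columns series. NA = missing.
#' @param k_range integer vector of trend counts (default 1:(m-1)).
#' @param structures character vector of structures to try (default all 4).
#' @param ... passed to [fit_dfa()] (tolerances, restarts, seed, ...).
#' @return object of class `dfa_search`: a ranking data.frame (`table`) and
#'   the fitted models (`fits`, in table order). Non-converged fits are
#'   retained and flagged.
#' @export
dfa_model_search <- function(data, k_range = NULL,
                             structures = c("diagonal_equal",
                                            "diagonal_unequal",
                                            "equalvarcov", "unconstrained"),
                             ...) {
  y <- t(as.matrix(data))      # series in rows
  m <- nrow(y)
  k_range <- k_range %||% seq_len(m - 1)
  grid <- expand.grid(k = k_range, structure = structures,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_dfa(y, k = grid$k[i], r_structure = grid$structure[i],
                         ...)
  }
  tab <- data.frame(
    structure = grid$structure,
    k = grid$k,
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$akaike_weight <- akaike_weights(tab$aicc)
  tab$cumulative_weight <- cumsum(tab$akaike_weight)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "dfa_search")
}

#' @export
print.dfa_search <- function(x, n = 10, ...) {
  cat(sprintf("DFA model search: %d trials\n", nrow(x$table)))
  print(utils::head(x$table, n), digits = 4)
  invisible(x)
}
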