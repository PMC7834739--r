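# Shared fixtures, built in code. Heavier objects are memoised so several
# test files can reuse one generation pass.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small hand-built sample-record table: 2 groups, all 4 seasons, 3 years.
make_tiny_records <- function(biomass_a, biomass_b = NULL, years = 2000:2002,
                              per_season = 2) {
  rows <- list()
  i <- 0
  for (yr in years) {
    for (s in seq_along(c("01", "04", "07", "10"))) {
      mon <- c("01", "04", "07", "10")[s]
      for (r in seq_len(per_season)) {
        i <- i + 1
        rows[[i]] <- data.frame(
          station_id = "S1",
          date = as.Date(paste0(yr, "-", mon, "-10")) + r,
          region = "central",
          bottom_depth_m = 290,
          tow_start_depth_m = 250,
          day_night = "night",
          A = biomass_a[((i - 1) %% length(biomass_a)) + 1]
        )
      }
    }
  }
  rec <- do.call(rbind, rows)
  if (!is.null(biomass_b)) rec$B <- rep_len(biomass_b, nrow(rec))
  rec
}

# Joint-Gaussian log-likelihood of the DFA model at fixed parameters: the
# independent oracle for the Kalman filter (states integrated out exactly).
dfa_joint_loglik <- function(y, Z, R, v0 = 5) {
  m <- nrow(y); TT <- ncol(y); k <- ncol(Z)
  Sig <- matrix(0, m * TT, m * TT)
  for (s in 1:TT) for (t in 1:TT) {
    blk <- Z %*% diag(v0 + min(s, t), k) %*% t(Z)
    if (s == t) blk <- blk + R
    Sig[(s - 1) * m + 1:m, (t - 1) * m + 1:m] <- blk
  }
  yv <- as.vector(y)
  obs <- !is.na(yv)
  cS <- chol(Sig[obs, obs])
  e <- yv[obs]
  -0.5 * (sum(obs) * log(2 * pi) + 2 * sum(log(diag(cS))) +
            sum(backsolve(cS, e, transpose = TRUE)^2))
}

# Exhaustive within-SS of the best contiguous partition into k groups
# (brute force over all cut-point combinations; oracle for CONISS checks).
best_contiguous_ss <- function(X, k) {
  TT <- nrow(X)
  if (k == 1) return(zooptrends:::partition_ss(X, integer(0)))
  cuts <- utils::combn(TT - 1, k - 1, simplify = FALSE)
  min(vapply(cuts, function(cc) zooptrends:::partition_ss(X, cc), numeric(1)))
}

synthetic_fixture <- function() {
  memo("synthetic_fixture", {
    spec <- synthetic_spec(master_seed = 20260928L)
    rec <- generate_zooplankton_samples(spec)
    phys <- generate_physical_series(spec)
    anoms <- compute_zoop_anomalies(rec, rng_seed = 20260928L)
    list(spec = spec, records = rec, physical = phys, anomalies = anoms,
         wide = anomalies_wide(anoms))
  })
}
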