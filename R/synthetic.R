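# Seasonal sampling-effort profile emulating a multi-decadal monitoring
# program: sparse and seasonally patchy in the early years, dense since
# 2015. Counts are tows per season per year.
default_effort <- function(start_year = 1996, n_years = 23) {
  counts <- matrix(c(
    2, 2, 0, 0,
    1, 2, 4, 4,
    9, 7, 4, 2,
    0, 2, 5, 0,
    0, 2, 2, 0,
    0, 2, 6, 0,
    8, 1, 0, 0,
    0, 1, 1, 6,
    2, 14, 3, 8,
    3, 4, 1, 1,
    0, 5, 0, 4,
    2, 3, 1, 1,
    2, 4, 11, 13,
    9, 6, 15, 16,
    7, 0, 9, 5,
    4, 0, 3, 2,
    0, 3, 8, 6,
    0, 13, 7, 7,
    0, 12, 15, 10,
    3, 65, 42, 27,
    10, 59, 57, 30,
    14, 37, 31, 12,
    7, 31, 14, 9), ncol = 4, byrow = TRUE,
    dimnames = list(NULL, SEASONS))
  years <- start_year + seq_len(n_years) - 1L
  counts <- counts[rep_len(seq_len(nrow(counts)), n_years), , drop = FALSE]
  rownames(counts) <- years
  counts
}

#' Default synthetic study specification
#'
#' Bundles every knob of the synthetic-data generator: latent-trend model,
#' group loadings, per-sample lognormal dispersion, zero-inflation rates,
#' the seasonal sampling-effort profile, AR(1)+trend parameters for the
#' physical drivers, and the survival-generating model. Defaults emulate
#' the study conditions of a 23-year (1996-2018) coastal monitoring
#' program: two latent trends behind 12 zooplankton groups, uneven effort
#' (sparse mid-2000s, dense after 2014), multiplicative sample noise, and
#' salmon survival driven by a logistic-linear model of salinity,
#' temperature and zooplankton biomass anomalies.
#'
#' @param n_years number of years, default 23.
#' @param start_year first anomaly year, default 1996.
#' @param master_seed integer master seed; all generator randomness derives
#'   from it.
#' @param k number of true latent trends, default 2.
#' @param trend_sd random-walk innovation SD of the latent trends (log10
#'   biomass units), default 0.25.
#' @param sample_sdlog10 per-sample lognormal dispersion (SD of log10
#'   biomass around the seasonal mean), default 0.35.
#' @param effort year x season matrix of tow counts (default
#'   the uneven-effort profile described above).
#' @return list of class `generator_spec`.
#' @export
synthetic_spec <- function(n_years = 23, start_year = 1996,
                           master_seed = 1L, k = 2, trend_sd = 0.25,
                           sample_sdlog10 = 0.35,
                           effort = default_effort(start_year, n_years)) {
  groups <- c("AmphiHyp", "CalCops.larg", "CalCops.med", "CalCops.smal",
              "Chaetognatha", "Cladocera", "Ctenophora", "Euphs", "Fish",
              "Medusae", "Ostracoda", "PolychaetPelagic")
  loadings <- rbind(
    AmphiHyp         = c(0.45,  0.10),
    CalCops.larg     = c(0.80,  0.00),
    CalCops.med      = c(0.75,  0.10),
    CalCops.smal     = c(0.35, -0.30),
    Chaetognatha     = c(0.10,  0.70),
    Cladocera        = c(0.20, -0.20),
    Ctenophora       = c(0.05, -0.45),
    Euphs            = c(0.15,  0.10),
    Fish             = c(0.05, -0.60),
    Medusae          = c(0.10, -0.40),
    Ostracoda        = c(0.70,  0.15),
    PolychaetPelagic = c(0.30,  0.20)
  )[, seq_len(k), drop = FALSE]
  base_log10 <- c(AmphiHyp = 0.5, CalCops.larg = 0.7, CalCops.med = 0.9,
                  CalCops.smal = 0.2, Chaetognatha = 0.3, Cladocera = -0.3,
                  Ctenophora = -0.8, Euphs = 1.0, Fish = -0.9,
                  Medusae = -0.2, Ostracoda = -0.5, PolychaetPelagic = -0.6)
  season_offset <- c(winter = -0.35, spring = 0.15, summer = 0.30,
                     fall = -0.10)
  zero_prob <- c(AmphiHyp = 0.02, CalCops.larg = 0.02, CalCops.med = 0.01,
                 CalCops.smal = 0.01, Chaetognatha = 0.02, Cladocera = 0.10,
                 Ctenophora = 0.15, Euphs = 0.02, Fish = 0.15,
                 Medusae = 0.08, Ostracoda = 0.10, PolychaetPelagic = 0.12)
  physical <- list(
    Nan.vT    = list(cadence = "daily",  mean = 9.5,  sd = 0.5,  phi = 0.85, trend = 0.015),
    FR.flow   = list(cadence = "daily",  mean = 2700, sd = 900,  phi = 0.70, trend = 0),
    SH.WSpd   = list(cadence = "daily",  mean = 5.0,  sd = 2.0,  phi = 0.30, trend = 0),
    Entr.SST  = list(cadence = "daily",  mean = 11.5, sd = 1.2,  phi = 0.80, trend = 0.02),
    Entr.SSS  = list(cadence = "daily",  mean = 27.5, sd = 1.5,  phi = 0.80, trend = -0.02),
    Chrom.SST = list(cadence = "daily",  mean = 11.0, sd = 1.2,  phi = 0.80, trend = 0.02),
    Chrom.SSS = list(cadence = "daily",  mean = 28.5, sd = 1.2,  phi = 0.80, trend = -0.015),
    PDO       = list(cadence = "monthly", mean = 0,   sd = 0.9,  phi = 0.85, trend = 0),
    BloomDay  = list(cadence = "annual", mean = 95,   sd = 9,    phi = 0.30, trend = -0.3)
  )
  survival_model <- list(
    Cowichan = list(intercept = -0.35,
                    coef = c(Entr.SSS = -1.1, Chrom.SST = 0.8, TotBiom = 1.2),
                    sd = 0.45, centre = -4.82, scale = 0.53),
    BigQualicum = list(intercept = -0.31,
                       coef = c(TotBiom = 1.3, CalCops.smal = 0.7),
                       sd = 0.50, centre = -4.80, scale = 0.89)
  )
  structure(list(
    n_years = n_years, start_year = start_year,
    years = start_year + seq_len(n_years) - 1L,
    k = k, trend_sd = trend_sd, groups = groups, loadings = loadings,
    base_log10 = base_log10, season_offset = season_offset,
    zero_prob = zero_prob, sample_sdlog10 = sample_sdlog10,
    effort = effort, physical = physical,
    survival_model = survival_model, master_seed = as.integer(master_seed)
  ), class = "generator_spec")
}

# Latent random-walk trends (k x n_years), deterministic under the master
# seed.
synthetic_trends <- function(spec) {
  with_seed(derive_seed(spec$master_seed, "trends"), {
    x <- matrix(0, spec$k, spec$n_years)
    for (t in seq_len(spec$n_years)) {
      prev <- if (t == 1) rep(0, spec$k) else x[, t - 1]
      x[, t] <- prev + stats::rnorm(spec$k, 0, spec$trend_sd)
    }
    colnames(x) <- spec$years
    x
  })
}

# True annual log10 anomaly of each group implied by the trends (before the
# climatology shift): loadings %*% trends.
synthetic_true_anomalies <- function(spec, trends = synthetic_trends(spec)) {
  a <- spec$loadings %*% trends
  sweep(a, 1, rowMeans(a[, spec$years %in% (spec$start_year + 0:14),
                         drop = FALSE]))
}

#' Generate synthetic zooplankton sample records
#'
#' Latent random-walk trends drive each group's seasonal mean biomass on
#' the log10 scale; individual tows are lognormal around that mean (with
#' the meanlog chosen so the arithmetic mean equals the seasonal mean
#' biomass), true zeros are injected per group, and records carry dates,
#' regions, depths and day/night flags that pass the tow-selection rules.
#' A `TotBiom` column (sum over groups) is appended.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame of sample records; attributes `trends` (k x years)
#'   and `true_anomalies` (group x years, base-period centred) hold the
#'   generating truth.
#' @export
generate_zooplankton_samples <- function(spec = synthetic_spec()) {
  trends <- synthetic_trends(spec)
  sdlog <- spec$sample_sdlog10 * log(10)   # natural-log SD of the lognormal
  rows <- list()
  with_seed(derive_seed(spec$master_seed, "samples"), {
    for (yi in seq_len(spec$n_years)) {
      yr <- spec$years[yi]
      for (s in SEASONS) {
        n <- spec$effort[as.character(yr), s]
        if (n == 0) next
        months <- switch(s, winter = c(12, 1, 2), spring = 3:5,
                         summer = 6:8, fall = 9:11)
        mo <- sample(months, n, replace = TRUE)
        # December belongs to the winter of anomaly year yr
        cal_yr <- ifelse(mo == 12, yr - 1L, yr)
        dates <- as.Date(sprintf("%d-%02d-%02d", cal_yr, mo,
                                 sample(1:28, n, replace = TRUE)))
        biom <- matrix(0, n, length(spec$groups),
                       dimnames = list(NULL, spec$groups))
        for (g in spec$groups) {
          mean_log10 <- spec$base_log10[g] + spec$season_offset[s] +
            sum(spec$loadings[g, ] * trends[, yi])
          meanlog <- mean_log10 * log(10) - sdlog^2 / 2
          v <- stats::rlnorm(n, meanlog, sdlog)
          v[stats::runif(n) < spec$zero_prob[g]] <- 0
          biom[, g] <- v
        }
        rows[[length(rows) + 1L]] <- data.frame(
          station_id = sprintf("SYN%d", seq_len(n)),
          date = dates,
          region = sample(c("central", "northern"), n, replace = TRUE,
                          prob = c(0.7, 0.3)),
          bottom_depth_m = stats::runif(n, 200, 400),
          tow_start_depth_m = stats::runif(n, 160, 195),
          day_night = sample(c("day", "night"), n, replace = TRUE),
          biom
        )
      }
    }
  })
  rec <- do.call(rbind, rows)
  rec$TotBiom <- rowSums(rec[, spec$groups])
  rownames(rec) <- NULL
  attr(rec, "trends") <- trends
  attr(rec, "true_anomalies") <- synthetic_true_anomalies(spec, trends)
  rec
}

# AR(1) + linear trend series at a given cadence.
ar1_series <- function(n, mean, sd, phi, trend_per_step) {
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  mean + x + trend_per_step * (seq_len(n) - n / 2)
}

#' Generate synthetic physical driver series
#'
#' Produces AR(1)+trend series at each variable's native cadence (daily,
#' monthly, or one value per year), plus derived variables: wind stress
#' (`SH.WStr`, from the daily wind speeds through [wind_stress()]) and the
#' annual peak-flow day (`FR.pkDay`, from the daily flows through
#' [peak_flow_day()]).
#'
#' @param spec a [synthetic_spec()].
#' @return named list of data.frames, each `date`,`value` or
#'   `year`,`value`, ready for [compute_physical_anomalies()].
#' @export
generate_physical_series <- function(spec = synthetic_spec()) {
  years <- spec$years
  # physical series must cover Dec of (start_year - 1) for the first winter
  dates_d <- seq(as.Date(sprintf("%d-12-01", spec$start_year - 1L)),
                 as.Date(sprintf("%d-11-30", max(years))), by = "day")
  dates_m <- seq(as.Date(sprintf("%d-12-01", spec$start_year - 1L)),
                 as.Date(sprintf("%d-11-01", max(years))), by = "month")
  out <- list()
  with_seed(derive_seed(spec$master_seed, "physical"), {
    for (nm in names(spec$physical)) {
      p <- spec$physical[[nm]]
      if (p$cadence == "daily") {
        v <- ar1_series(length(dates_d), p$mean, p$sd, p$phi,
                        p$trend / 365.25)
        out[[nm]] <- data.frame(date = dates_d, value = v)
      } else if (p$cadence == "monthly") {
        v <- ar1_series(length(dates_m), p$mean, p$sd, p$phi, p$trend / 12)
        out[[nm]] <- data.frame(date = dates_m, value = v)
      } else {
        v <- ar1_series(length(years), p$mean, p$sd, p$phi, p$trend)
        out[[nm]] <- data.frame(year = years, value = round(v))
      }
    }
    # seasonal bulge in river flow so the peak-flow day is well defined
    doy <- as.integer(format(dates_d, "%j"))
    out$FR.flow$value <- pmax(out$FR.flow$value, 1) +
      4000 * exp(-((doy - 165) / 30)^2) *
        stats::runif(length(doy), 0.8, 1.2)
  })
  out$SH.WStr <- data.frame(date = out$SH.WSpd$date,
                            value = wind_stress(pmax(out$SH.WSpd$value, 0)))
  out$SH.WSpd <- NULL
  # the leading December (previous winter) is a deliberately partial year
  pk <- suppressWarnings(peak_flow_day(out$FR.flow$date, out$FR.flow$value))
  out$FR.pkDay <- pk[pk$year %in% years, ]
  out
}

#' Generate synthetic salmon survival series
#'
#' For each stock, the standardized logit survival is a linear function of
#' the supplied covariates plus Gaussian noise; survivals are obtained by
#' reversing the scaling and the logit transform. The generating
#' coefficients are stored for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param covariates wide year-by-variable matrix (e.g. from
#'   [anomalies_wide()]) containing every covariate named in the spec's
#'   survival model.
#' @return data.frame `stock`, `ocean_entry_year`, `survival`, `status`;
#'   attribute `truth` holds the generating models.
#' @export
generate_survival <- function(spec = synthetic_spec(), covariates) {
  covariates <- as.matrix(covariates)
  years <- as.integer(rownames(covariates))
  out <- list()
  with_seed(derive_seed(spec$master_seed, "survival"), {
    for (stock in names(spec$survival_model)) {
      sm <- spec$survival_model[[stock]]
      assert_that(all(names(sm$coef) %in% colnames(covariates)),
                  paste("generate_survival: covariates missing for", stock))
      Xs <- covariates[, names(sm$coef), drop = FALSE]
      ok <- stats::complete.cases(Xs)
      alpha <- sm$intercept + as.vector(Xs[ok, , drop = FALSE] %*% sm$coef) +
        stats::rnorm(sum(ok), 0, sm$sd)
      out[[stock]] <- data.frame(
        stock = stock,
        ocean_entry_year = years[ok],
        survival = inv_logit(alpha * sm$scale + sm$centre),
        status = ifelse(years[ok] > max(years) - 4L, "preliminary", "final")
      )
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- spec$survival_model
  res
}
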