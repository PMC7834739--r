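#' Wind stress from wind speed
#'
#' tau = rho_air * C_D * U^2 with air density 1.22 kg m^-3 and a
#' dimensionless drag coefficient 0.0013. Applied per observation (e.g.
#' hourly) before any seasonal averaging, since squaring does not commute
#' with averaging.
#'
#' @param U wind speed, m s^-1 (>= 0).
#' @param rho_air air density, kg m^-3.
#' @param C_D drag coefficient.
#' @return wind stress, N m^-2.
#' @examples
#' wind_stress(10) # 0.1586
#' @export
wind_stress <- function(U, rho_air = 1.22, C_D = 0.0013) {
  assert_that(all(U >= 0, na.rm = TRUE), "wind_stress: negative wind speed")
  rho_air * C_D * U^2
}

#' Day of year of the annual peak river flow
#'
#' @param dates `Date` vector of daily observations.
#' @param flow daily flow values (m^3 s^-1), same length.
#' @param min_days minimum daily observations for a year to be used,
#'   default 300; thinner years are omitted with a warning.
#' @return data.frame with `year` and `value` (ordinal day of the annual
#'   maximum; ties resolve to the earliest day).
#' @export
peak_flow_day <- function(dates, flow, min_days = 300L) {
  dates <- as.Date(dates)
  assert_that(length(dates) == length(flow), "peak_flow_day: length mismatch")
  ok <- !is.na(dates) & !is.na(flow)
  dates <- dates[ok]; flow <- flow[ok]
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  out <- lapply(split(seq_along(yr), yr), function(idx) {
    if (length(idx) < min_days) return(NULL)
    i <- idx[which.max(flow[idx])]   # which.max -> earliest maximum
    data.frame(year = yr[i], value = doy[i])
  })
  thin <- vapply(out, is.null, logical(1))
  if (any(thin)) {
    warning("peak_flow_day: omitting year(s) with < ", min_days, " days: ",
            paste(names(out)[thin], collapse = ", "))
  }
  res <- do.call(rbind, out[!thin])
  if (is.null(res)) {
    res <- data.frame(year = integer(0), value = integer(0))
  }
  rownames(res) <- NULL
  res
}

# Seasonal means of a timestamped physical series.
physical_seasonal_means <- function(dates, values) {
  sk <- assign_season(dates)
  ok <- !is.na(values)
  agg <- aggregate(values[ok],
                   by = list(season = sk$season[ok], year = sk$anomaly_year[ok]),
                   FUN = mean)
  names(agg)[3] <- "value"
  agg
}

#' Normalized annual anomaly of a physical variable
#'
#' Seasonal means are normalized against the base-period seasonal mean and
#' standard deviation (sample SD, n-1), then averaged over the seasons
#' available in each year. Annual-event variables (one value per year, e.g.
#' peak-flow day or bloom day) are normalized directly at annual cadence.
#'
#' @param x either a data.frame `date`,`value` (sub-annual cadence) or
#'   `year`,`value` (annual events).
#' @param variable name carried into the output.
#' @param base_period climatology years, default 1996:2010.
#' @return data.frame `variable`, `year`, `anomaly`, kind "physical".
#' @export
normalized_annual_anomaly <- function(x, variable = "physical",
                                      base_period = 1996:2010) {
  if ("date" %in% names(x)) {
    seas <- physical_seasonal_means(x$date, x$value)
    base <- seas[seas$year %in% base_period, , drop = FALSE]
    stats_b <- aggregate(base$value, by = list(season = base$season),
                         FUN = function(v) c(m = mean(v), s = stats::sd(v)))
    ref <- data.frame(season = stats_b$season,
                      m = stats_b$x[, "m"], s = stats_b$x[, "s"])
    if (any(!is.finite(ref$s) | ref$s == 0)) {
      stop("normalized_annual_anomaly: zero base-period variance for ",
           variable, " in season(s) ",
           paste(ref$season[!is.finite(ref$s) | ref$s == 0], collapse = ", "))
    }
    seas <- merge(seas, ref, by = "season")
    seas$anom <- (seas$value - seas$m) / seas$s
    ann <- aggregate(seas$anom, by = list(year = seas$year), FUN = mean)
    names(ann)[2] <- "anomaly"
  } else if ("year" %in% names(x)) {
    base <- x$value[x$year %in% base_period]
    s <- stats::sd(base)
    if (!is.finite(s) || s == 0) {
      stop("normalized_annual_anomaly: zero base-period variance for ",
           variable)
    }
    ann <- data.frame(year = x$year, anomaly = (x$value - mean(base)) / s)
  } else {
    stop("normalized_annual_anomaly: x must have a date or year column")
  }
  ann <- ann[order(ann$year), ]
  data.frame(variable = variable, year = as.integer(ann$year),
             anomaly = ann$anomaly, kind = "physical", row.names = NULL)
}

#' Annual anomalies for a set of physical series
#'
#' @param series named list; each element a data.frame with `value` and
#'   either `date` (daily/hourly/monthly series) or `year` (annual events).
#' @param base_period climatology years.
#' @return long data.frame of normalized annual anomalies.
#' @export
compute_physical_anomalies <- function(series, base_period = 1996:2010) {
  out <- lapply(names(series), function(nm) {
    normalized_annual_anomaly(series[[nm]], variable = nm,
                              base_period = base_period)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
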