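#' Assign sampling dates to anomaly seasons
#'
#' Maps calendar dates onto the four 3-month seasons used for anomaly
#' calculation. Winter is December-January-February, and December belongs to
#' the winter of the *following* calendar year, so the anomaly year of a
#' December record is incremented by one.
#'
#' @param date a `Date` vector (or something coercible via [as.Date()]).
#' @return a data.frame with columns `season` (factor with levels winter,
#'   spring, summer, fall) and `anomaly_year` (integer).
#' @examples
#' assign_season(as.Date(c("1997-12-15", "1996-03-01", "2018-11-30")))
#' @export
assign_season <- function(date) {
  date <- as.Date(date)
  assert_that(!anyNA(date), "assign_season: invalid or missing dates")
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  season <- MONTH_SEASON[m]
  year <- ifelse(m == 12L, y + 1L, y)
  data.frame(
    season = factor(season, levels = SEASONS),
    anomaly_year = as.integer(year)
  )
}

#' Select deep full-water-column tows from the study regions
#'
#' Keeps net tows from the central and northern regions over deep water
#' (bottom depth > 50 m) that sampled most of the water column: tow start
#' depth > 150 m, or, where the bottom is shallower than 150 m, a tow
#' covering at least 70% of the water column.
#'
#' @param records data.frame of sample records with columns `region`,
#'   `bottom_depth_m`, `tow_start_depth_m` (see [read_sample_records()]).
#' @param min_bottom_depth minimum bottom depth (m), default 50.
#' @param deep_tow_depth tow start depth (m) that qualifies on its own,
#'   default 150.
#' @param min_fraction minimum fraction of the water column for shallower
#'   stations, default 0.70.
#' @return the subset of `records` passing the selection. Records with
#'   missing depth fields are rejected with a warning.
#' @export
select_tows <- function(records, min_bottom_depth = 50,
                        deep_tow_depth = 150, min_fraction = 0.70) {
  needed <- c("region", "bottom_depth_m", "tow_start_depth_m")
  assert_that(all(needed %in% names(records)),
              paste("select_tows: records must have columns",
                    paste(needed, collapse = ", ")))
  bad <- is.na(records$bottom_depth_m) | is.na(records$tow_start_depth_m)
  if (any(bad)) {
    warning(sprintf("select_tows: rejecting %d record(s) with missing depths",
                    sum(bad)))
  }
  region_ok <- records$region %in% c("central", "northern")
  deep <- records$bottom_depth_m > min_bottom_depth
  full_column <- records$tow_start_depth_m > deep_tow_depth |
    (records$bottom_depth_m < deep_tow_depth &
       records$tow_start_depth_m / records$bottom_depth_m >= min_fraction)
  keep <- !bad & region_ok & deep & full_column
  records[keep, , drop = FALSE]
}

#' Correct daytime adult euphausiid catches for net avoidance
#'
#' Adult euphausiids see and avoid nets in daylight, so daytime euphausiid
#' biomass (and abundance) is multiplied by 3; night-time records and all
#' other groups are untouched.
#'
#' @param records data.frame of sample records with a `day_night` column
#'   ("day" or "night").
#' @param columns names of the columns holding the adult-euphausiid
#'   component (biomass, and abundance if carried).
#' @param factor correction multiplier, default 3.
#' @return `records` with corrected values.
#' @export
apply_euphausiid_correction <- function(records, columns = "Euphs",
                                        factor = 3) {
  assert_that("day_night" %in% names(records),
              "apply_euphausiid_correction: records need a day_night column")
  if (anyNA(records$day_night)) {
    stop("apply_euphausiid_correction: missing day/night flag; record cannot be corrected")
  }
  columns <- intersect(columns, names(records))
  is_day <- records$day_night == "day"
  for (cl in columns) {
    records[[cl]][is_day] <- records[[cl]][is_day] * factor
  }
  records
}

#' Replace true zeros before log transformation
#'
#' Implements the ICES zero-replacement rule: each zero is replaced by an
#' independent uniform draw strictly between 0 and one half of the lowest
#' non-zero value observed for that variable (scoped across all samples of
#' the variable, all years).
#'
#' @param values numeric vector of biomass values (>= 0) for one variable.
#' @param rng_seed integer seed making the draws reproducible; NULL uses the
#'   current RNG state.
#' @return `values` with zeros replaced.
#' @export
replace_zeros <- function(values, rng_seed = NULL) {
  assert_that(all(values >= 0, na.rm = TRUE),
              "replace_zeros: negative biomass")
  nz <- values[!is.na(values) & values > 0]
  zero <- !is.na(values) & values == 0
  if (!any(zero)) return(values)
  if (length(nz) == 0L) {
    stop("replace_zeros: all values are zero; replacement undefined")
  }
  half_min <- min(nz) / 2
  values[zero] <- with_seed(rng_seed, runif(sum(zero), 0, half_min))
  values
}

#' Seasonal mean biomass on the log10 scale
#'
#' The arithmetic mean of the sample biomasses is taken first and then
#' log10-transformed (not the mean of logs).
#'
#' @param samples numeric vector of (zero-replaced) biomass values, g m^-2.
#' @return log10 of the arithmetic mean; `NA` for an empty set.
#' @export
seasonal_mean_log10 <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) == 0L) return(NA_real_)
  log10(mean(samples))
}

#' Seasonal statistics for each group, season and year
#'
#' @param records selected (and euphausiid-corrected) sample records.
#' @param groups character vector of group column names; default every
#'   non-metadata column.
#' @param rng_seed master seed for zero replacement (one substream per
#'   group).
#' @return data.frame with columns `group`, `season`, `year`, `n_obs`,
#'   `mean_log10`.
#' @export
zoop_seasonal_stats <- function(records, groups = NULL, rng_seed = NULL) {
  meta <- c("station_id", "date", "region", "bottom_depth_m",
            "tow_start_depth_m", "day_night")
  groups <- groups %||% setdiff(names(records), meta)
  sk <- assign_season(records$date)
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    vals <- replace_zeros(records[[g]],
                          if (is.null(rng_seed)) NULL else derive_seed(rng_seed, g))
    agg <- aggregate(vals,
                     by = list(season = sk$season, year = sk$anomaly_year),
                     FUN = function(v) c(n = length(v), m = seasonal_mean_log10(v)))
    out[[i]] <- data.frame(
      group = g,
      season = agg$season,
      year = agg$year,
      n_obs = as.integer(agg$x[, "n"]),
      mean_log10 = agg$x[, "m"]
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Seasonal climatology over a base period
#'
#' @param stats output of [zoop_seasonal_stats()].
#' @param base_period integer years, default 1996:2010.
#' @return data.frame with `group`, `season`, `base_mean`, `n_years`.
#' @export
climatology <- function(stats, base_period = 1996:2010) {
  base <- stats[stats$year %in% base_period, , drop = FALSE]
  assert_that(nrow(base) > 0, "climatology: no seasonal stats in base period")
  agg <- aggregate(base$mean_log10,
                   by = list(group = base$group, season = base$season),
                   FUN = function(v) c(m = mean(v), n = length(v)))
  data.frame(
    group = agg$group,
    season = agg$season,
    base_mean = agg$x[, "m"],
    n_years = as.integer(agg$x[, "n"])
  )
}

#' Annual log10 biomass anomalies
#'
#' Seasonal anomalies (seasonal mean log10 biomass minus the climatological
#' seasonal mean) are averaged over the seasons with observations in each
#' year. A year is valid only if it has at least one observation in spring
#' or summer; other years are omitted.
#'
#' @param stats output of [zoop_seasonal_stats()].
#' @param clim output of [climatology()].
#' @return data.frame with `variable`, `year`, `anomaly`, attribute
#'   `seasonal` holding the per-season anomalies.
#' @export
annual_anomaly <- function(stats, clim) {
  m <- merge(stats, clim[, c("group", "season", "base_mean")],
             by = c("group", "season"), all.x = TRUE)
  if (anyNA(m$base_mean)) {
    miss <- unique(paste(m$group[is.na(m$base_mean)],
                         m$season[is.na(m$base_mean)]))
    stop("annual_anomaly: no climatology for: ", paste(miss, collapse = "; "))
  }
  m$seasonal_anomaly <- m$mean_log10 - m$base_mean
  # valid-year rule: at least one observation in spring or summer
  valid <- aggregate(m$season %in% c("spring", "summer"),
                     by = list(group = m$group, year = m$year), FUN = any)
  names(valid)[3] <- "valid"
  m <- merge(m, valid, by = c("group", "year"))
  m <- m[m$valid, , drop = FALSE]
  ann <- aggregate(m$seasonal_anomaly,
                   by = list(variable = m$group, year = m$year), FUN = mean)
  names(ann)[3] <- "anomaly"
  ann <- ann[order(ann$variable, ann$year), ]
  rownames(ann) <- NULL
  seasonal <- m[order(m$group, m$year, m$season),
                c("group", "season", "year", "n_obs", "seasonal_anomaly")]
  rownames(seasonal) <- NULL
  attr(ann, "seasonal") <- seasonal
  ann
}

#' Compute annual zooplankton biomass anomalies from sample records
#'
#' Convenience wrapper running tow selection, the daytime euphausiid
#' correction, zero replacement, seasonal means (Eq. arithmetic mean then
#' log10), climatology and annual anomalies in one call.
#'
#' @param records raw sample records (see [read_sample_records()]).
#' @param groups group columns to process (default: all biomass columns).
#' @param base_period climatology years, default 1996:2010.
#' @param euphausiid_columns columns receiving the daytime x3 correction.
#' @param select apply [select_tows()] first (default TRUE).
#' @param rng_seed master seed for zero replacement.
#' @return long data.frame `variable`, `year`, `anomaly` (kind zooplankton).
#' @export
compute_zoop_anomalies <- function(records, groups = NULL,
                                   base_period = 1996:2010,
                                   euphausiid_columns = "Euphs",
                                   select = TRUE, rng_seed = NULL) {
  if (select) records <- select_tows(records)
  assert_that(nrow(records) > 0, "compute_zoop_anomalies: no records selected")
  records <- apply_euphausiid_correction(records, euphausiid_columns)
  stats <- zoop_seasonal_stats(records, groups = groups, rng_seed = rng_seed)
  clim <- climatology(stats, base_period = base_period)
  ann <- annual_anomaly(stats, clim)
  ann$kind <- "zooplankton"
  ann
}

#' Screen annual anomaly series for multi-collinearity
#'
#' Pearson correlations are computed on pairwise-complete years. Variables
#' correlated beyond the threshold with at least `min_partners` other
#' variables are dropped greedily: the most-connected variable is removed
#' first (ties broken alphabetically) and degrees are recomputed after each
#' removal.
#'
#' @param anomalies long data.frame (`variable`, `year`, `anomaly`) or a
#'   wide year-by-variable matrix/data.frame.
#' @param threshold absolute correlation above which a pair counts as
#'   highly correlated, default 0.60.
#' @param min_partners minimum number of high-correlation partners for a
#'   variable to be a drop candidate ("several"), default 2.
#' @return list with `kept`, `dropped` (character vectors) and
#'   `correlation` (the full correlation matrix).
#' @export
screen_collinearity <- function(anomalies, threshold = 0.60,
                                min_partners = 2L) {
  wide <- if (is.data.frame(anomalies) &&
              all(c("variable", "year", "anomaly") %in% names(anomalies))) {
    anomalies_wide(anomalies)
  } else {
    as.matrix(anomalies)
  }
  assert_that(ncol(wide) >= 2, "screen_collinearity: need at least 2 series")
  sds <- apply(wide, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop("screen_collinearity: degenerate (zero-variance) series: ",
         paste(colnames(wide)[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  cm <- stats::cor(wide, use = "pairwise.complete.obs")
  dropped <- character(0)
  repeat {
    active <- setdiff(colnames(cm), dropped)
    sub <- cm[active, active, drop = FALSE]
    high <- abs(sub) > threshold & row(sub) != col(sub)
    degree <- rowSums(high, na.rm = TRUE)
    cand <- degree[degree >= min_partners]
    if (length(cand) == 0L) break
    worst <- sort(names(cand)[cand == max(cand)])[1]
    dropped <- c(dropped, worst)
  }
  list(kept = setdiff(colnames(cm), dropped), dropped = dropped,
       correlation = cm)
}

#' Reshape long anomaly series to a year-by-variable matrix
#'
#' @param anomalies long data.frame with `variable`, `year`, `anomaly`.
#' @return numeric matrix, rows named by year, columns by variable; missing
#'   years are NA.
#' @export
anomalies_wide <- function(anomalies) {
  years <- sort(unique(anomalies$year))
  vars <- sort(unique(as.character(anomalies$variable)))
  m <- matrix(NA_real_, length(years), length(vars),
              dimnames = list(years, vars))
  m[cbind(match(anomalies$year, years),
          match(as.character(anomalies$variable), vars))] <- anomalies$anomaly
  m
}
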