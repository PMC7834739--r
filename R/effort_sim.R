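#' Resample annual anomalies at reduced sampling effort
#'
#' Tests whether uneven sampling effort could explain an anomaly pattern:
#' in each repetition the records of the target years are subsampled
#' (without replacement) down to `n_subsample` tows per year — stratified
#' by season in proportion to `season_profile` — and the full anomaly
#' pipeline (zero replacement, seasonal means, climatology, annual
#' anomalies) is recomputed. Non-target years keep their full record sets.
#'
#' @param records selected, euphausiid-corrected sample records.
#' @param variable biomass column whose anomaly is tracked (e.g.
#'   "TotBiom").
#' @param target_years years whose effort is reduced (default: all years
#'   present).
#' @param n_subsample tows retained per target year, default 12.
#' @param n_reps repetitions, default 1000.
#' @param season_profile named proportions (winter, spring, summer, fall)
#'   describing how a low-effort year's samples were historically spread;
#'   the default mirrors the sparse mid-2000s regime.
#' @param base_period climatology years.
#' @param seed master seed.
#' @return object of class `effort_sim`: `draws` (matrix reps x years of
#'   annual anomalies, NA where a rep loses the valid-year rule), `summary`
#'   (per-year mean and 2.5/50/97.5% quantiles), `full` (the full-data
#'   anomalies), and the scenario parameters.
#' @export
subsampled_anomaly_distribution <- function(records, variable = "TotBiom",
                                            target_years = NULL,
                                            n_subsample = 12,
                                            n_reps = 1000,
                                            season_profile = c(winter = 0.12,
                                                               spring = 0.45,
                                                               summer = 0.10,
                                                               fall = 0.33),
                                            base_period = 1996:2010,
                                            seed = NULL) {
  assert_that(variable %in% names(records),
              "subsampled_anomaly_distribution: variable not in records")
  sk <- assign_season(records$date)
  records$.season <- as.character(sk$season)
  records$.year <- sk$anomaly_year
  years <- sort(unique(records$.year))
  target_years <- target_years %||% years
  pool_n <- table(records$.year)[as.character(target_years)]
  if (any(is.na(pool_n)) || any(pool_n < n_subsample)) {
    stop("subsampled_anomaly_distribution: a target year has fewer than ",
         n_subsample, " records")
  }
  season_profile <- season_profile[SEASONS]
  season_profile <- season_profile / sum(season_profile)

  full <- compute_zoop_anomalies(records[, setdiff(names(records),
                                                   c(".season", ".year"))],
                                 groups = variable,
                                 base_period = base_period,
                                 euphausiid_columns = character(0),
                                 select = FALSE,
                                 rng_seed = if (is.null(seed)) NULL else
                                   derive_seed(seed, "full"))

  draws <- matrix(NA_real_, n_reps, length(years),
                  dimnames = list(NULL, years))
  keep_rows <- which(!(records$.year %in% target_years))
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      sel <- keep_rows
      for (yy in target_years) {
        in_year <- which(records$.year == yy)
        take <- draw_stratified(records$.season[in_year], n_subsample,
                                season_profile)
        sel <- c(sel, in_year[take])
      }
      sub <- records[sel, setdiff(names(records), c(".season", ".year"))]
      ann <- tryCatch(
        compute_zoop_anomalies(sub, groups = variable,
                               base_period = base_period,
                               euphausiid_columns = character(0),
                               select = FALSE, rng_seed = NULL),
        error = function(e) NULL)
      if (!is.null(ann)) {
        idx <- match(ann$year, years)
        draws[rep, idx] <- ann$anomaly
      }
    }
  })
  qs <- apply(draws, 2, function(v)
    c(mean = mean(v, na.rm = TRUE),
      stats::quantile(v, c(0.025, 0.5, 0.975), na.rm = TRUE)))
  structure(list(draws = draws,
                 summary = data.frame(year = years, t(qs)),
                 full = full,
                 variable = variable, n_subsample = n_subsample,
                 n_reps = n_reps, target_years = target_years),
            class = "effort_sim")
}

# Allocate n draws across the season labels of a year's pool,
# proportionally to `profile` (largest-remainder rounding), capped by
# availability; any shortfall spills into seasons with spare records.
# Returns row indices into the pool. Sampling is without replacement.
draw_stratified <- function(season_labels, n, profile) {
  avail <- table(factor(season_labels, levels = SEASONS))
  want <- profile * n
  base <- floor(want)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(want - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  alloc <- pmin(base, as.numeric(avail))
  short <- n - sum(alloc)
  while (short > 0) {
    spare <- which(alloc < as.numeric(avail))
    if (length(spare) == 0L) break
    j <- spare[which.max(as.numeric(avail)[spare] - alloc[spare])]
    alloc[j] <- alloc[j] + 1
    short <- short - 1
  }
  idx <- integer(0)
  for (s in seq_along(SEASONS)) {
    if (alloc[s] > 0) {
      pool_s <- which(season_labels == SEASONS[s])
      idx <- c(idx, pool_s[sample.int(length(pool_s), alloc[s])])
    }
  }
  idx
}

#' Probability of a run of low anomalies
#'
#' Fraction of repetitions containing at least `run_length` consecutive
#' years with anomaly below `threshold`. Years with a missing anomaly in a
#' repetition break the run.
#'
#' @param anomaly_draws matrix (repetitions x years, columns in year order)
#'   or an `effort_sim` object.
#' @param threshold anomaly cut, default -0.10.
#' @param run_length consecutive years required, default 5.
#' @return the probability (a single number in \[0, 1\]).
#' @export
run_probability <- function(anomaly_draws, threshold = -0.10,
                            run_length = 5) {
  if (inherits(anomaly_draws, "effort_sim")) {
    anomaly_draws <- anomaly_draws$draws
  }
  anomaly_draws <- as.matrix(anomaly_draws)
  assert_that(nrow(anomaly_draws) >= 1, "run_probability: no repetitions")
  assert_that(run_length <= ncol(anomaly_draws),
              "run_probability: run_length exceeds the number of years")
  has_run <- apply(anomaly_draws, 1, function(v) {
    below <- !is.na(v) & v < threshold
    r <- rle(below)
    any(r$values & r$lengths >= run_length)
  })
  mean(has_run)
}
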