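#' Read zooplankton sample records from CSV
#'
#' Expected schema: one row per tow with columns `station_id`, `date` (ISO
#' 8601), `region` (central/northern/other), `bottom_depth_m`,
#' `tow_start_depth_m`, `day_night` (day/night), then one biomass column
#' (g m^-2) per taxonomic group.
#'
#' @param path CSV file path.
#' @return validated data.frame with `date` parsed as `Date`.
#' @export
read_sample_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("station_id", "date", "region", "bottom_depth_m",
              "tow_start_depth_m", "day_night")
  miss <- setdiff(needed, names(d))
  assert_that(length(miss) == 0,
              paste("read_sample_records: missing column(s):",
                    paste(miss, collapse = ", ")))
  d$date <- as.Date(d$date)
  assert_that(!anyNA(d$date), "read_sample_records: unparseable dates")
  groups <- setdiff(names(d), needed)
  assert_that(length(groups) >= 1,
              "read_sample_records: no biomass columns found")
  for (g in groups) {
    assert_that(is.numeric(d[[g]]),
                paste("read_sample_records: non-numeric biomass column", g))
    assert_that(all(d[[g]] >= 0, na.rm = TRUE),
                paste("read_sample_records: negative biomass in", g))
  }
  d
}

#' Write/read long anomaly tables
#'
#' Tidy long format (`variable`, `year`, `anomaly`, optional `kind`); the
#' wide form (rows = years, columns = variables) mirrors a supplementary
#' year-by-variable layout for direct comparisons.
#'
#' @param anomalies long anomaly data.frame.
#' @param path CSV destination.
#' @param wide also write `<path stem>_wide.csv` (default FALSE).
#' @return the path, invisibly.
#' @export
write_anomalies <- function(anomalies, path, wide = FALSE) {
  utils::write.csv(anomalies, path, row.names = FALSE)
  if (wide) {
    w <- anomalies_wide(anomalies)
    utils::write.csv(data.frame(year = as.integer(rownames(w)), w,
                                check.names = FALSE),
                     sub("\\.csv$", "_wide.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_anomalies
#' @export
read_anomalies <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("variable", "year", "anomaly") %in% names(d)),
              "read_anomalies: need variable, year, anomaly columns")
  d
}

#' Read a wide year-by-variable anomaly table
#'
#' First column must be the year; remaining columns one variable each;
#' blanks are missing years.
#'
#' @param path CSV path.
#' @return numeric matrix with years as rownames.
#' @export
read_anomalies_wide <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read a physical time series from CSV
#'
#' Two layouts are accepted: `date,value` (daily/hourly/monthly cadence,
#' ISO 8601 dates) or `year,value` (annual events such as the peak-flow or
#' bloom day). See `inst/extdata/example_sst_daily.csv` and
#' `example_bloom_day.csv` for samples of each.
#'
#' @param path CSV path.
#' @return data.frame ready for [normalized_annual_anomaly()].
#' @export
read_physical_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that("value" %in% names(d) &&
                any(c("date", "year") %in% names(d)),
              "read_physical_series: need (date|year) and value columns")
  if ("date" %in% names(d)) {
    d$date <- as.Date(d$date)
    assert_that(!anyNA(d$date), "read_physical_series: unparseable dates")
  }
  assert_that(is.numeric(d$value), "read_physical_series: non-numeric value")
  d
}

#' Read a salmon survival table
#'
#' @param path CSV with columns `stock`, `ocean_entry_year`, `survival`
#'   (proportion in (0,1)) and optional `status` (final/preliminary).
#' @return validated data.frame.
#' @export
read_survival <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("stock", "ocean_entry_year", "survival") %in% names(d)),
              "read_survival: need stock, ocean_entry_year, survival")
  assert_that(all(d$survival > 0 & d$survival < 1),
              "read_survival: survival must be in (0, 1)")
  if (is.null(d$status)) d$status <- "final"
  d
}

#' Default pipeline configuration
#'
#' All method constants default to the study values: climatology 1996-2010,
#' 50 m region depth, 150 m tow depth, 0.70 water-column fraction, x3
#' daytime euphausiid factor, 0.60 collinearity threshold, 0.05 KPSS
#' threshold, up to 5 covariates, 5x5 cross-validation.
#'
#' @param seed master seed for every stochastic step.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes its artifact tables there.
#' @param ... overrides for any default field.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, ...) {
  cfg <- list(
    base_period = 1996:2010,
    min_bottom_depth = 50, deep_tow_depth = 150, min_fraction = 0.70,
    euphausiid_factor = 3, euphausiid_columns = "Euphs",
    collinearity_threshold = 0.60, collinearity_min_partners = 2L,
    kpss_alpha = 0.05, max_covariates = 5,
    cv_repeats = 5, cv_folds = 5,
    dfa_structures = c("diagonal_equal", "diagonal_unequal",
                       "equalvarcov", "unconstrained"),
    dfa_k_range = NULL, dfa_em_tol = 1e-6, dfa_max_iter = 5000,
    broken_stick_n = 1000,
    effort_n_subsample = 12, effort_n_reps = 1000,
    effort_target_years = NULL,   # NULL: every year with enough records
    effort_threshold = -0.10, effort_run_length = 5,
    seed = as.integer(seed), out_dir = out_dir
  )
  utils::modifyList(cfg, list(...))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full workflow: zooplankton anomalies (tow selection,
#' euphausiid correction, zero replacement, seasonal/annual anomalies),
#' physical anomalies, collinearity screening, two DFA model searches with
#' varimax rotation, chronological clustering of the four latent trends
#' with the broken-stick test, staged regression models of each salmon
#' stock's scaled-logit survival, per-year predictions with 95% intervals,
#' and (optionally) the reduced-effort resampling simulation. Deterministic
#' given `config$seed`.
#'
#' @param records zooplankton sample records (data.frame or CSV path).
#' @param physical named list of physical series (or NULL to skip the
#'   physical/clustering stages).
#' @param survival salmon survival data.frame or CSV path (or NULL to
#'   skip survival modelling).
#' @param config list from [pipeline_config()].
#' @param effort_sim run the sampling-effort simulation (slowest stage;
#'   default FALSE).
#' @return list of artifacts: `zoop_anomalies`, `phys_anomalies`,
#'   `screen`, `dfa_zoop`, `dfa_phys`, `rotated_zoop`, `rotated_phys`,
#'   `zonation`, `survival_models`, `predictions`, `effort`, `manifest`.
#' @export
run_pipeline <- function(records, physical = NULL, survival = NULL,
                         config = pipeline_config(), effort_sim = FALSE) {
  if (is.character(records)) records <- read_sample_records(records)
  if (is.character(survival)) survival <- read_survival(survival)
  art <- list()

  sel <- select_tows(records, config$min_bottom_depth,
                     config$deep_tow_depth, config$min_fraction)
  sel <- apply_euphausiid_correction(sel, config$euphausiid_columns,
                                     config$euphausiid_factor)
  zoop <- compute_zoop_anomalies(sel, base_period = config$base_period,
                                 euphausiid_columns = character(0),
                                 select = FALSE,
                                 rng_seed = derive_seed(config$seed, "zeros"))
  art$zoop_anomalies <- zoop
  zoop_wide <- anomalies_wide(zoop)
  scr <- screen_collinearity(zoop_wide[, colnames(zoop_wide) != "TotBiom",
                                       drop = FALSE],
                             config$collinearity_threshold,
                             config$collinearity_min_partners)
  art$screen <- scr

  art$dfa_zoop <- dfa_model_search(
    zoop_wide[, scr$kept, drop = FALSE],
    k_range = config$dfa_k_range, structures = config$dfa_structures,
    em_tol = config$dfa_em_tol, max_iter = config$dfa_max_iter)
  art$rotated_zoop <- varimax_rotate(art$dfa_zoop$fits[[1]])

  if (!is.null(physical)) {
    phys <- compute_physical_anomalies(physical, config$base_period)
    art$phys_anomalies <- phys
    phys_wide <- anomalies_wide(phys)
    art$dfa_phys <- dfa_model_search(
      phys_wide, k_range = config$dfa_k_range,
      structures = config$dfa_structures,
      em_tol = config$dfa_em_tol, max_iter = config$dfa_max_iter)
    art$rotated_phys <- varimax_rotate(art$dfa_phys$fits[[1]])

    # trends are indexed by the wide-table years; cluster the common years
    zt <- art$rotated_zoop$trends
    pt <- art$rotated_phys$trends
    zy <- as.integer(rownames(zoop_wide))
    py <- as.integer(rownames(phys_wide))
    common <- intersect(zy, py)
    feats <- cbind(t(zt)[match(common, zy), , drop = FALSE],
                   t(pt)[match(common, py), , drop = FALSE])
    colnames(feats) <- c(paste0("Z", seq_len(nrow(zt))),
                         paste0("P", seq_len(nrow(pt))))
    rownames(feats) <- common
    zon <- coniss(feats)
    art$zonation <- broken_stick(zon, config$broken_stick_n,
                                 seed = derive_seed(config$seed, "bstick"))
  }

  if (!is.null(survival)) {
    covs <- zoop_wide
    if (!is.null(physical)) {
      phys_wide <- anomalies_wide(art$phys_anomalies)
      common <- intersect(rownames(covs), rownames(phys_wide))
      covs <- cbind(covs[common, , drop = FALSE],
                    phys_wide[common, , drop = FALSE])
    }
    art$survival_models <- list()
    art$predictions <- list()
    for (stock in unique(survival$stock)) {
      sv <- survival[survival$stock == stock, ]
      resp <- survival_response(sv)
      fit_years <- resp$data$ocean_entry_year[resp$data$status == "final"]
      fit_years <- intersect(fit_years, as.integer(rownames(covs)))
      y <- resp$data$alpha[match(fit_years, resp$data$ocean_entry_year)]
      X <- covs[as.character(fit_years), , drop = FALSE]
      keep <- colSums(is.na(X)) == 0
      lad <- regression_ladder(y, X[, keep, drop = FALSE],
                               max_size = config$max_covariates,
                               seed = derive_seed(config$seed, stock))
      art$survival_models[[stock]] <- list(ladder = lad, response = resp)
      if (!is.null(lad$selected)) {
        pred_years <- setdiff(as.integer(rownames(covs)), fit_years)
        if (length(pred_years) > 0) {
          nd <- data.frame(year = pred_years,
                           covs[as.character(pred_years),
                                lad$selected$covariates, drop = FALSE],
                           check.names = FALSE)
          art$predictions[[stock]] <- suppressWarnings(
            predict_intervals(lad$selected, nd,
                              back_transform = list(centre = resp$centre,
                                                    scale = resp$scale)))
        }
      }
    }
  }

  if (isTRUE(effort_sim)) {
    target <- config$effort_target_years
    if (is.null(target)) {
      yr <- assign_season(sel$date)$anomaly_year
      cnt <- table(yr)
      target <- as.integer(names(cnt)[cnt >= config$effort_n_subsample])
    }
    art$effort <- subsampled_anomaly_distribution(
      sel, variable = "TotBiom",
      target_years = target,
      n_subsample = config$effort_n_subsample,
      n_reps = config$effort_n_reps,
      base_period = config$base_period,
      seed = derive_seed(config$seed, "effort"))
    art$effort_run_probability <- run_probability(
      art$effort, config$effort_threshold, config$effort_run_length)
  }

  art$manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("zooptrends")),
    seed = config$seed,
    base_period = range(config$base_period),
    stages = names(art)
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(art, config$out_dir)
  art
}

# Writes the tabular artifacts of a pipeline run as CSVs plus a plain-text
# manifest. Round-trips through the read_* functions.
write_pipeline_artifacts <- function(art, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_anomalies(art$zoop_anomalies,
                  file.path(out_dir, "zoop_anomalies.csv"), wide = TRUE)
  if (!is.null(art$phys_anomalies)) {
    write_anomalies(art$phys_anomalies,
                    file.path(out_dir, "phys_anomalies.csv"), wide = TRUE)
  }
  if (!is.null(art$dfa_zoop)) {
    utils::write.csv(art$dfa_zoop$table,
                     file.path(out_dir, "dfa_zoop_table.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(variable = rownames(art$rotated_zoop$loadings) %||%
                                  seq_len(nrow(art$rotated_zoop$loadings)),
                                art$rotated_zoop$loadings),
                     file.path(out_dir, "dfa_zoop_loadings.csv"),
                     row.names = FALSE)
    tr <- t(art$rotated_zoop$trends)
    utils::write.csv(data.frame(year = rownames(tr) %||% seq_len(nrow(tr)),
                                tr, row.names = NULL),
                     file.path(out_dir, "dfa_zoop_trends.csv"),
                     row.names = FALSE)
  }
  if (!is.null(art$dfa_phys)) {
    utils::write.csv(art$dfa_phys$table,
                     file.path(out_dir, "dfa_phys_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(art$zonation)) {
    utils::write.csv(art$zonation$merges,
                     file.path(out_dir, "zonation_merges.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(k = seq_along(art$zonation$dispersion_by_k),
                                dispersion = art$zonation$dispersion_by_k),
                     file.path(out_dir, "zonation_dispersion.csv"),
                     row.names = FALSE)
    writeLines(zonation_newick(art$zonation),
               file.path(out_dir, "zonation_tree.nwk"))
  }
  if (!is.null(art$effort)) {
    utils::write.csv(data.frame(rep = seq_len(nrow(art$effort$draws)),
                                art$effort$draws, check.names = FALSE),
                     file.path(out_dir, "effort_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(art$effort$summary,
                     file.path(out_dir, "effort_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(art$survival_models)) {
    tab <- survival_model_table(art$survival_models)
    utils::write.csv(tab, file.path(out_dir, "survival_models.csv"),
                     row.names = FALSE)
    for (stock in names(art$predictions)) {
      utils::write.csv(art$predictions[[stock]],
                       file.path(out_dir,
                                 paste0("predictions_", stock, ".csv")),
                       row.names = FALSE)
    }
  }
  writeLines(paste(names(art$manifest),
                   vapply(art$manifest, function(v)
                     paste(format(v), collapse = " "), ""),
                   sep = ": "),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Summary table of fitted survival models
#'
#' One row per stock in the layout of the study's model tables: formula,
#' KPSS p-values, ARIMA order, AICc, Ljung-Box p, adjusted R2, model p,
#' CV R2, and the back-transform constants.
#'
#' @param survival_models the `survival_models` element of a
#'   [run_pipeline()] result.
#' @return data.frame.
#' @export
survival_model_table <- function(survival_models) {
  rows <- lapply(names(survival_models), function(stock) {
    sm <- survival_models[[stock]]
    lad <- sm$ladder
    if (is.null(lad$selected)) {
      return(data.frame(stock = stock, model = "no valid model",
                        kpss_trend_p = lad$kpss$trend_p,
                        kpss_level_p = lad$kpss$level_p,
                        order = NA, aicc = NA, ljung_box_p = NA,
                        adj_r2 = NA, p_value = NA, cv_r2 = NA,
                        centre = sm$response$centre,
                        scale = sm$response$scale))
    }
    sel <- lad$selected
    cf <- sel$coefficients[, "estimate"]
    terms <- c(
      if ("intercept" %in% names(cf)) sprintf("%.3f", cf[["intercept"]]),
      sprintf("%.3f*%s", cf[sel$covariates], sel$covariates))
    data.frame(
      stock = stock,
      model = paste(terms, collapse = " + "),
      kpss_trend_p = lad$kpss$trend_p,
      kpss_level_p = lad$kpss$level_p,
      order = paste(sel$order, collapse = ","),
      aicc = sel$aicc,
      ljung_box_p = sel$ljung_box_p,
      adj_r2 = if (is.null(lad$ols)) NA else lad$ols$adj_r2,
      p_value = if (is.null(lad$ols)) NA else lad$ols$p_value,
      cv_r2 = if (is.null(lad$cv)) NA else lad$cv$cv_r2,
      centre = sm$response$centre,
      scale = sm$response$scale)
  })
  do.call(rbind, rows)
}
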