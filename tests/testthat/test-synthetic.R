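test_that("generation is deterministic under the master seed", {
  r1 <- generate_zooplankton_samples(synthetic_spec(master_seed = 9))
  r2 <- generate_zooplankton_samples(synthetic_spec(master_seed = 9))
  expect_identical(r1, r2)
  r3 <- generate_zooplankton_samples(synthetic_spec(master_seed = 10))
  expect_false(identical(r1$TotBiom, r3$TotBiom))
  p1 <- generate_physical_series(synthetic_spec(master_seed = 9))
  p2 <- generate_physical_series(synthetic_spec(master_seed = 9))
  expect_identical(p1, p2)
})

test_that("records satisfy the tow-selection invariants and schema", {
  fx <- synthetic_fixture()
  rec <- fx$records
  expect_true(all(rec$bottom_depth_m > 0))
  expect_true(all(rec$tow_start_depth_m <= rec$bottom_depth_m))
  expect_true(all(rec[fx$spec$groups] >= 0))
  expect_equal(nrow(select_tows(rec)), nrow(rec))   # all pass by design
  expect_equal(nrow(rec), sum(fx$spec$effort))
})

test_that("a year with no spring or summer effort drops out downstream", {
  eff <- matrix(6, 5, 4, dimnames = list(2000:2004,
                                         c("winter", "spring", "summer",
                                           "fall")))
  eff["2002", c("spring", "summer")] <- 0
  spec <- synthetic_spec(n_years = 5, start_year = 2000, master_seed = 2,
                         effort = eff)
  rec <- generate_zooplankton_samples(spec)
  ann <- compute_zoop_anomalies(rec, base_period = 2000:2004, rng_seed = 2,
                                euphausiid_columns = character(0),
                                select = FALSE)
  expect_false(2002 %in% ann$year)
  expect_true(all(c(2000, 2001, 2003, 2004) %in% ann$year))
})

test_that("physical generator produces the stationarity regimes it claims", {
  spec <- synthetic_spec(master_seed = 6)
  spec$physical <- list(
    flat = list(cadence = "daily", mean = 10, sd = 1, phi = 0, trend = 0),
    trending = list(cadence = "daily", mean = 10, sd = 0.6, phi = 0.2,
                    trend = 0.35)
  )
  ser <- generate_physical_series(spec)
  an_flat <- normalized_annual_anomaly(ser$flat, "flat", 1996:2010)
  an_tr <- normalized_annual_anomaly(ser$trending, "trending", 1996:2010)
  expect_gt(kpss_test(an_flat$anomaly, "level")$p_value, 0.05)
  expect_false(kpss_check(an_flat$anomaly)$differenced)
  expect_true(kpss_check(an_tr$anomaly)$differenced)
})

test_that("survival generator hides a recoverable signal", {
  fx <- synthetic_fixture()
  covs <- fx$wide
  spec <- fx$spec
  # strong single covariate, low noise: the ladder finds exactly it
  spec$survival_model <- list(
    OneVar = list(intercept = 0, coef = c(CalCops.larg = 2.5), sd = 0.15,
                  centre = -4.8, scale = 0.6))
  sv <- generate_survival(spec, covs)
  resp <- survival_response(sv[, c("ocean_entry_year", "survival", "status")])
  fit_rows <- resp$data$status == "final"
  y <- resp$data$alpha[fit_rows]
  X <- covs[as.character(resp$data$ocean_entry_year[fit_rows]),
            c("CalCops.larg", "Chaetognatha", "Fish", "Euphs", "Medusae"),
            drop = FALSE]
  bs <- best_subsets(y, X, max_size = 3)
  cands <- lapply(attr(bs, "subsets"), function(s)
    arima_evaluate(y, X[, s, drop = FALSE], p_max = 1, q_max = 1))
  sel <- select_top_model(cands)
  expect_true("CalCops.larg" %in% sel$covariates)
  # noise-free survival: OLS recovers the relationship exactly
  spec$survival_model$OneVar$sd <- 0
  sv0 <- generate_survival(spec, covs)
  a0 <- survival_response(sv0[, c("ocean_entry_year", "survival", "status")])
  y0 <- a0$data$alpha[a0$data$status == "final"]
  X0 <- covs[as.character(a0$data$ocean_entry_year[a0$data$status == "final"]),
             "CalCops.larg", drop = FALSE]
  cand0 <- arima_evaluate(y0, X0, p_max = 0, d_max = 0, q_max = 0)
  expect_equal(finalize_ols(cand0)$adj_r2, 1, tolerance = 1e-6)
})

test_that("zero survival coefficients carry no cross-validatable signal", {
  # with independent survivals the selection filter rejects some replicates
  # outright; models that do slip through owe their fit to selection and
  # fail to cross-validate (subset selection inflates apparent
  # significance, so outright rejection is not the majority outcome)
  fx <- synthetic_fixture()
  spec <- fx$spec
  spec$survival_model <- list(
    Null = list(intercept = 0, coef = c(CalCops.larg = 0, Fish = 0),
                sd = 0.5, centre = -4.8, scale = 0.6))
  none <- 0
  cvr <- c()
  for (r in 1:15) {
    spec$master_seed <- 100 + r
    sv <- generate_survival(spec, fx$wide)
    resp <- survival_response(sv[, c("ocean_entry_year", "survival",
                                     "status")])
    keep <- resp$data$status == "final"
    y <- resp$data$alpha[keep]
    X <- fx$wide[as.character(resp$data$ocean_entry_year[keep]),
                 c("CalCops.larg", "Fish", "Euphs", "Medusae", "Cladocera"),
                 drop = FALSE]
    bs <- best_subsets(y, X, max_size = 3)
    cands <- lapply(attr(bs, "subsets"), function(s)
      arima_evaluate(y, X[, s, drop = FALSE],
                     p_max = 0, d_max = 0, q_max = 0))
    sel <- select_top_model(cands)
    if (is.null(sel)) none <- none + 1
    else cvr <- c(cvr, repeated_cv(sel, seed = r)$cv_r2)
  }
  message(sprintf("no-valid-model on null survival: %d/15", none))
  expect_gt(none, 2)
  expect_lt(median(cvr), 0.5)
})
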