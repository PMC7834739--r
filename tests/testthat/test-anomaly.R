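test_that("seasons map months to 3-month blocks and December rolls forward", {
  sk <- assign_season(as.Date(c("1997-12-15", "1996-03-01", "2018-11-30",
                                "2000-01-15", "2005-06-30", "2010-02-28")))
  expect_equal(as.character(sk$season),
               c("winter", "spring", "fall", "winter", "summer", "winter"))
  expect_equal(sk$anomaly_year, c(1998L, 1996L, 2018L, 2000L, 2005L, 2010L))
})

test_that("tow selection keeps deep or >=70%-coverage tows in the study regions", {
  rec <- data.frame(
    region = c("central", "central", "central", "other", "central", "northern"),
    bottom_depth_m = c(290, 120, 300, 290, 40, NA),
    tow_start_depth_m = c(250, 90, 100, 250, 35, 100)
  )
  expect_warning(kept <- select_tows(rec), "missing depths")
  expect_equal(rownames(kept), c("1", "2"))   # 250>150; 90/120 = 0.75 >= 0.70
  # fails both depth clauses / wrong region / too shallow are all rejected
  expect_false(any(c(3, 4, 5, 6) %in% as.integer(rownames(kept))))
})

test_that("daytime euphausiid biomass is tripled, night and other groups untouched", {
  rec <- data.frame(day_night = c("day", "night", "day"),
                    Euphs = c(2, 2, 0.5), CalCops.med = c(1.5, 1.5, 1.5))
  out <- apply_euphausiid_correction(rec, "Euphs")
  expect_equal(out$Euphs, c(6, 2, 1.5))
  expect_equal(out$CalCops.med, rec$CalCops.med)
  rec$day_night[2] <- NA
  expect_error(apply_euphausiid_correction(rec), "day/night")
})

test_that("zero replacement draws below half the minimum non-zero value", {
  out <- replace_zeros(c(0, 4, 8), rng_seed = 1)
  expect_true(out[1] > 0 && out[1] < 2)
  expect_equal(out[2:3], c(4, 8))
  expect_equal(replace_zeros(c(1, 2, 3)), c(1, 2, 3))
  expect_error(replace_zeros(c(0, 0, 0)), "all values are zero")
  # reproducible under seed, different across seeds
  expect_identical(replace_zeros(c(0, 4, 8), 5), replace_zeros(c(0, 4, 8), 5))
  expect_false(replace_zeros(c(0, 4, 8), 5)[1] ==
                 replace_zeros(c(0, 4, 8), 6)[1])
})

test_that("seasonal mean is arithmetic-mean-then-log10", {
  expect_equal(seasonal_mean_log10(c(10, 100)), log10(55), tolerance = 1e-12)
  expect_equal(round(seasonal_mean_log10(c(10, 100)), 4), 1.7404)
  expect_equal(seasonal_mean_log10(1), 0)
  expect_equal(seasonal_mean_log10(c(0.1, 0.1, 0.1)), -1)
  # mean of logs would give a different (smaller) answer
  expect_gt(seasonal_mean_log10(c(10, 100)), mean(log10(c(10, 100))))
})

test_that("annual anomaly averages seasons present and enforces the valid-year rule", {
  stats <- data.frame(
    group = "A",
    season = factor(c("spring", "summer", "winter", "fall", "summer"),
                    levels = c("winter", "spring", "summer", "fall")),
    year = c(2001, 2001, 2002, 2002, 2003),
    n_obs = 1L,
    mean_log10 = c(0.2, -0.2, 0.3, 0.1, -0.15)
  )
  clim <- data.frame(group = "A",
                     season = factor(c("winter", "spring", "summer", "fall"),
                                     levels = levels(stats$season)),
                     base_mean = 0, n_years = 3L)
  ann <- annual_anomaly(stats, clim)
  expect_equal(ann$anomaly[ann$year == 2001], 0)        # symmetric mean
  expect_false(2002 %in% ann$year)                      # no spring/summer
  expect_equal(ann$anomaly[ann$year == 2003], -0.15)    # single season
  expect_error(annual_anomaly(stats, clim[clim$season != "summer", ]),
               "summer")
})

test_that("climatology-period anomalies average to zero when coverage is complete", {
  rec <- make_tiny_records(biomass_a = c(2, 4, 8, 16, 3, 9), years = 1996:2010)
  ann <- compute_zoop_anomalies(rec, base_period = 1996:2010, select = FALSE,
                                euphausiid_columns = character(0))
  expect_equal(mean(ann$anomaly[ann$year %in% 1996:2010]), 0,
               tolerance = 1e-10)
  seas <- attr(ann, "seasonal")
  for (s in c("winter", "spring", "summer", "fall")) {
    expect_equal(mean(seas$seasonal_anomaly[seas$season == s &
                                              seas$year %in% 1996:2010]),
                 0, tolerance = 1e-10)
  }
})

test_that("a 10-fold biomass change in one year shifts its anomaly by exactly +1", {
  rec <- make_tiny_records(biomass_a = c(2, 4, 8, 16, 3, 9), years = 1996:2005)
  base <- compute_zoop_anomalies(rec, base_period = 1996:2003, select = FALSE,
                                 euphausiid_columns = character(0))
  yr <- assign_season(rec$date)$anomaly_year
  rec2 <- rec
  rec2$A[yr == 2005] <- rec2$A[yr == 2005] * 10
  shifted <- compute_zoop_anomalies(rec2, base_period = 1996:2003,
                                    select = FALSE,
                                    euphausiid_columns = character(0))
  expect_equal(shifted$anomaly[shifted$year == 2005],
               base$anomaly[base$year == 2005] + 1, tolerance = 1e-10)
  expect_equal(shifted$anomaly[shifted$year < 2005],
               base$anomaly[base$year < 2005], tolerance = 1e-10)
})

test_that("seasonal statistics are invariant to sample order", {
  rec <- make_tiny_records(biomass_a = c(1, 5, 2, 7, 3, 11), years = 2000:2002)
  perm <- withr::with_seed(1, sample(nrow(rec)))
  s1 <- zoop_seasonal_stats(rec, groups = "A")
  s2 <- zoop_seasonal_stats(rec[perm, ], groups = "A")
  s1 <- s1[order(s1$year, s1$season), ]
  s2 <- s2[order(s2$year, s2$season), ]
  expect_equal(s1$mean_log10, s2$mean_log10, tolerance = 1e-12)
  expect_equal(s1$n_obs, s2$n_obs)
})

test_that("collinearity screen drops multi-partner variables, keeps 1-partner pairs", {
  set.seed(42)
  n <- 23
  hub <- rnorm(n)
  # a,b,c all track the hub (so hub has 3 partners, a/b/c have >= 2 each);
  # d,e correlate only with each other; f is independent
  w <- anomalies_wide(data.frame(
    variable = rep(c("hub", "a", "b", "c", "d", "e", "f"), each = n),
    year = rep(2000 + 1:n, 7),
    anomaly = c(hub,
                hub + rnorm(n, 0, 0.3), hub + rnorm(n, 0, 0.3),
                hub + rnorm(n, 0, 0.3),
                (dd <- rnorm(n)), dd + rnorm(n, 0, 0.2), rnorm(n))
  ))
  scr <- screen_collinearity(w)
  expect_true(all(c("d", "e", "f") %in% scr$kept))   # 1 partner: retained
  # removals come from the hub cluster only, and stop once no kept
  # variable has >= 2 high-correlation partners
  expect_length(scr$dropped, 2)
  expect_true(all(scr$dropped %in% c("hub", "a", "b", "c")))
  kept_cor <- scr$correlation[scr$kept, scr$kept]
  degrees <- rowSums(abs(kept_cor) > 0.60) - 1
  expect_true(all(degrees < 2))
  # three mutually identical series: one removal suffices (after it, the
  # survivors have a single partner each, below the "several" threshold)
  m <- cbind(x = hub, y = hub, z = hub)
  rownames(m) <- 2000 + 1:n
  scr2 <- screen_collinearity(m)
  expect_length(scr2$kept, 2)
  expect_identical(scr2$dropped, "x")   # alphabetical tie-break
  # two independent white-noise series both kept
  m2 <- withr::with_seed(7, cbind(p = rnorm(n), q = rnorm(n)))
  rownames(m2) <- 2000 + 1:n
  expect_length(screen_collinearity(m2)$kept, 2)
  expect_error(screen_collinearity(cbind(a = rep(1, 5), b = 1:5)),
               "degenerate")
})

test_that("estimated climatology converges to generator truth with heavy effort", {
  spec <- synthetic_spec(master_seed = 3, sample_sdlog10 = 0.05,
                         effort = matrix(40, 23, 4,
                                         dimnames = list(1996:2018,
                                                         c("winter", "spring",
                                                           "summer", "fall"))))
  rec <- generate_zooplankton_samples(spec)
  ann <- compute_zoop_anomalies(rec, rng_seed = 3,
                                euphausiid_columns = character(0),
                                select = FALSE)
  truth <- attr(rec, "true_anomalies")
  w <- anomalies_wide(ann)
  for (g in c("CalCops.larg", "Chaetognatha", "Fish")) {
    expect_equal(unname(w[, g]), unname(truth[g, colnames(truth)]),
                 tolerance = 0.06)
  }
})
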