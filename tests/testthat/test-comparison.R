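toy_annual <- function(years, wtd) tibble::tibble(year = years, mean_wtd = wtd)

test_that("year pairing prefers exact matches and averages exact ties", {
  ann <- toy_annual(1950:1960, seq(1, 11))
  rec <- tibble::tibble(age_yr = c(1950, 1955.2, 1960), wtd_pred = c(5, 6, 7))
  p <- pair_years(ann, rec)
  expect_equal(p$wtd_model, c(1, 6, 11))
  expect_equal(attr(p, "n_dropped"), 0)

  # 1950.4 rounds to 1950 even though 1951 exists
  p2 <- pair_years(ann, tibble::tibble(age_yr = 1950.4, wtd_pred = 1))
  expect_equal(p2$wtd_model, 1)

  # a year missing from the model series, equidistant neighbours: average
  gappy <- toy_annual(c(1950, 1952), c(2, 8))
  p3 <- pair_years(gappy, tibble::tibble(age_yr = 1951, wtd_pred = 1))
  expect_equal(p3$wtd_model, 5)

  # out-of-tolerance samples are dropped and counted
  p4 <- pair_years(gappy, tibble::tibble(age_yr = c(1950, 1956), wtd_pred = c(1, 2)))
  expect_equal(nrow(p4), 1)
  expect_equal(attr(p4, "n_dropped"), 1)
  expect_error(pair_years(gappy, tibble::tibble(age_yr = 1990, wtd_pred = 1)),
               "no reconstruction sample")
})

test_that("offset regression recovers known lines and rejects degenerate input", {
  x <- seq(5, 25, length.out = 10)
  exact <- tibble::tibble(wtd_recon = x, wtd_model = x)
  reg <- fit_offset(exact)
  expect_equal(reg$slope, 1)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  expect_equal(reg$r2, 1)

  # simulated pairs around the reference offset line are recovered within CI
  set.seed(33)
  xr <- runif(60, 18, 32)
  noisy <- tibble::tibble(wtd_recon = xr,
                          wtd_model = 1.79 * xr - 39.57 + rnorm(60, 0, 1.5))
  regn <- fit_offset(noisy)
  se <- tidy(regn)$std.error
  expect_lt(abs(regn$slope - 1.79), 3 * se[2])
  expect_lt(abs(regn$intercept + 39.57), 3 * se[1])
  expect_gt(regn$r2, 0.5)

  expect_error(fit_offset(tibble::tibble(wtd_recon = c(4, 4, 4),
                                         wtd_model = c(1, 2, 3))), "zero variance")
  expect_error(fit_offset(exact[1:2, ]), "at least 3")
})

test_that("offset correction is idempotent on its training pairs", {
  set.seed(34)
  pairs <- tibble::tibble(wtd_recon = runif(20, 10, 30))
  pairs$wtd_model <- 1.4 * pairs$wtd_recon - 20 + rnorm(20, 0, 1)
  reg <- fit_offset(pairs)
  corrected <- apply_offset(tibble::tibble(wtd_pred = pairs$wtd_recon), reg)
  refit <- fit_offset(tibble::tibble(wtd_recon = corrected$wtd_pred,
                                     wtd_model = pairs$wtd_model))
  expect_equal(refit$slope, 1, tolerance = 1e-9)
  expect_equal(refit$intercept, 0, tolerance = 1e-9)

  ident <- structure(list(slope = 1, intercept = 0, r2 = 1, n_pairs = 3),
                     class = "offset_regression")
  rec <- tibble::tibble(wtd_pred = c(3, 4), se_boot = c(1, 1))
  expect_equal(apply_offset(rec, ident)$wtd_pred, c(3, 4))
  expect_equal(apply_offset(rec, ident)$se_boot, c(1, 1))
})

test_that("period summaries use sample SD and hand-checked arithmetic", {
  ann <- tibble::tibble(year = 2000:2002, mean_wtd = c(2, 4, 9),
                        co2_flux = c(300, 310, 320), ch4_net = c(5, 5, 5),
                        peat_increment = c(0.1, 0, -0.1),
                        soil_c_budget = c(10, -10, 30))
  s <- period_summary(ann, c(2000, 2002))
  expect_equal(s$wtd_mean, 5)
  expect_equal(s$wtd_sd, sd(c(2, 4, 9)))                # n-1 denominator
  expect_equal(s$budget_mean, 10)
  expect_equal(s$ch4_sd, 0)
  one <- period_summary(ann, c(2001, 2001))
  expect_equal(one$wtd_sd, 0)
  expect_false(one$sd_defined)
  expect_error(period_summary(ann, c(1990, 1995)), "no simulated years")
})

test_that("scenario differences subtract means and check periods", {
  ann <- tibble::tibble(year = 1851:1950, mean_wtd = 5, co2_flux = 400,
                        ch4_net = 10, peat_increment = 0.05,
                        soil_c_budget = 12.7)
  ann_b <- ann; ann_b$soil_c_budget <- -38.6
  sa <- period_summary(ann, c(1851, 1950))
  sb <- period_summary(ann_b, c(1851, 1950))
  d <- scenario_diff(sa, sb)
  expect_equal(d$budget_diff, 12.7 - (-38.6))    # = 51.3
  expect_equal(d$wtd_diff, 0)
  sa2 <- period_summary(ann, c(1851, 1900))
  expect_error(scenario_diff(sa2, sb), "different periods")
  same <- scenario_diff(sa, sa)
  expect_true(all(abs(as.numeric(same[, -(1:2)])) < 1e-12))
})
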