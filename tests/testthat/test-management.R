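test_that("burn rotation produces the dated sequence", {
  s <- scenario_schedule()
  b <- burn_years(s)
  expect_equal(b, c(1851, 1871, 1891, 1911, 1931))
  expect_true(all(diff(b) == 20))
  single <- scenario_schedule(rotation = 200)
  expect_equal(burn_years(single), 1851)
  expect_length(burn_years(scenario_schedule(burning = FALSE)), 0)
})

test_that("NPP recovery is sigmoidal, pinned at 1% and 100%", {
  for (R in c(5, 10)) {
    s <- scenario_schedule(recovery_years = R)
    v <- npp_multiplier(0:(R + 3), s)
    expect_equal(v[1], 0.01)
    expect_true(all(v[(R + 1):(R + 4)] == 1))
    expect_true(all(diff(v) >= 0))
    # interior inflection: growth accelerates then decelerates
    d <- diff(v[1:(R + 1)])
    expect_gt(which.max(d), 1)
    expect_lt(which.max(d), R)
    # midpoint of the documented logistic parameterization
    g <- function(t) 1 / (1 + exp(-(t - R / 2) / (R / 8)))
    mid_expected <- 0.01 + 0.99 * (g(R / 2) - g(0)) / (g(R) - g(0))
    expect_equal(npp_multiplier(R / 2, s), mid_expected)
  }
})

test_that("charcoal is 5% of burnt biomass and stays inert", {
  s <- scenario_schedule()
  expect_equal(charcoal_input(100, s), 5)
  expect_equal(charcoal_input(0, s), 0)
  # an inert pool survives decomposition untouched
  col <- structure(list(pools = matrix(c(10, 10, 10, 10), 1, 4,
                                       dimnames = list(NULL, c("fast", "mid", "slow", "humic"))),
                        inert = 50, birth_year = 0, thickness = 5,
                        total_depth = 5, n = 1L, wtd = 0, year = 1),
                   class = "peat_column")
  dec <- decompose(col, 20, 10, decomp_params())
  expect_equal(col$inert, 50)               # untouched by design
  expect_lt(sum(dec$pools), sum(col$pools)) # while litter pools decay
})

test_that("drainage efficiency follows the dated schedule", {
  s <- scenario_schedule()
  expect_equal(drain_efficiency(1840, s), 1)
  expect_equal(drain_efficiency(1870, s), 0.60)   # year before renewal
  expect_equal(drain_efficiency(1871, s), 1)      # renewal jump
  expect_equal(drain_efficiency(1905, s), 1)
  expect_equal(drain_efficiency(1930, s), 0.5)    # halfway through final decline
  expect_equal(drain_efficiency(1955, s), 0)
  expect_equal(drain_efficiency(1830, s), 0)
  expect_equal(drain_efficiency(1990, s), 0)
  # within the first optimum the efficiency stays 1; decline is linear
  expect_true(all(drain_efficiency(1831:1855, s) == 1))
  dec <- drain_efficiency(1855:1870, s)
  expect_close(diff(dec), rep(-0.4 / 15, 15))
})

test_that("drainage lowers the water table linearly in efficiency", {
  s <- scenario_schedule()
  expect_equal(apply_drainage(4, 1840, s), 9)     # full 5 cm lowering
  expect_equal(apply_drainage(4, 1870, s), 4 + 5 * 0.6)
  expect_equal(apply_drainage(4, 1990, s), 4)
})

test_that("managed runs are drier and lose carbon relative to unmanaged twins", {
  un <- run_scenario("no_shoot")
  man10 <- run_scenario("burn_drain_10")
  man5 <- run_scenario("burn_drain_5")
  per <- c(1851, 1950)
  s_un <- period_summary(un$annual, per)
  s_10 <- period_summary(man10$annual, per)
  s_5 <- period_summary(man5$annual, per)
  # drained twin deeper, by at most the drain depth
  expect_gt(s_10$wtd_mean, s_un$wtd_mean)
  expect_lte(s_10$wtd_mean - s_un$wtd_mean, 5)
  # management century carbon contrast: managed budget below unmanaged
  expect_lt(s_10$budget_mean, s_un$budget_mean)
  # faster vegetation recovery loses less carbon
  expect_gt(s_5$budget_mean, s_10$budget_mean)
  # methane falls under drainage
  expect_lt(s_10$ch4_mean, s_un$ch4_mean)
})
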