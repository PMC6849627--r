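test_that("climate generator honours its moments and is reproducible", {
  # zero variance pins every year at the mean
  c0 <- gen_climate(1000, mean_temp = 5.1, temp_sd = 0, precip_sd = 0, seed = 1)
  expect_true(all(c0$temp_c == 5.1))
  expect_true(all(c0$precip_mm == 2000))

  c1 <- gen_climate(1000, seed = 1)
  expect_lt(abs(mean(c1$temp_c) - 5.1), 3 * 0.6 / sqrt(1000))
  expect_lt(abs(mean(c1$precip_mm) - 2000), 3 * 200 / sqrt(1000))

  expect_identical(gen_climate(50, seed = 9), gen_climate(50, seed = 9))
  expect_error(gen_climate(0), "n_years")

  # law of large numbers at n = 10,000
  big <- gen_climate(10000, seed = 5)
  expect_lt(abs(mean(big$temp_c) - 5.1), 3 * 0.6 / sqrt(10000))
  expect_lt(abs(mean(big$precip_mm) - 2000), 3 * 200 / sqrt(10000))
  expect_true(all(big$precip_mm >= 0))
})

test_that("precipitation is truncated at zero and trend is applied", {
  dry <- gen_climate(2000, mean_precip = 50, precip_sd = 300, seed = 2)
  expect_true(all(dry$precip_mm >= 0))
  tr <- gen_climate(201, trend_temp = 1, temp_sd = 0, seed = 1)
  expect_equal(tr$temp_c[201] - tr$temp_c[1], 2)   # 1 degC per century over 200 yr
})

test_that("training assemblages are multinomial draws from Gaussian responses", {
  taxa <- default_taxa()
  tr <- gen_training_set(taxa, n_samples = 20, count_total = 150, seed = 7)
  counts <- as.matrix(tr[, taxa$taxon])
  expect_true(all(rowSums(counts) == 150))

  # single taxon occupies every sample completely
  one <- gen_training_set(taxa[2, ], n_samples = 5, wtd_range = c(0, 10),
                          count_total = 100, seed = 1)
  expect_true(all(one[[taxa$taxon[2]]] == 100))

  # unimodal ordering: at the wet optimum the wet taxon dominates
  two <- tibble::tibble(taxon = c("wet", "dry"), optimum = c(2, 30),
                        tolerance = c(6, 6), max_abundance = c(1, 1))
  wtr <- gen_training_set(two, n_samples = 3, wtd_range = c(2, 2),
                          count_total = 10000, seed = 3)
  expect_true(all(wtr$wet > wtr$dry))

  # noiseless limit: proportions converge to the normalized response curves
  x <- 8
  resp <- taxa$max_abundance * exp(-(x - taxa$optimum)^2 / (2 * taxa$tolerance^2))
  expected <- resp / sum(resp)
  lim <- gen_training_set(taxa, n_samples = 3, wtd_range = c(x, x),
                          count_total = 2e5, seed = 4)
  props <- as.matrix(lim[, taxa$taxon]) / 2e5
  expect_lt(max(abs(t(props) - expected)), 0.01)
})

test_that("fossil cores keep their truth and respond to step changes", {
  taxa <- default_taxa()
  expect_error(gen_fossil_core(tibble::tibble(depth_cm = numeric(0),
                                              wtd_true = numeric(0))), "empty")
  expect_error(gen_fossil_core(tibble::tibble(depth_cm = c(1, 1), wtd_true = c(2, 3))),
               "strictly increasing")

  # constant truth, huge counts: assemblages near-identical at all depths
  const <- gen_fossil_core(tibble::tibble(depth_cm = 1:5, wtd_true = rep(8, 5)),
                           taxa, count_total = 1e5, seed = 8)
  props <- as.matrix(const[, taxa$taxon]) / 1e5
  expect_lt(max(apply(props, 2, function(p) diff(range(p)))), 0.02)

  # step change flips the dominant taxon across the step
  stepc <- gen_fossil_core(tibble::tibble(depth_cm = 1:6,
                                          wtd_true = c(2, 2, 2, 30, 30, 30)),
                           taxa, count_total = 5000, seed = 9)
  dom <- apply(as.matrix(stepc[, taxa$taxon]), 1, which.max)
  expect_true(all(dom[1:3] != dom[4:6]))

  # a gradient no taxon covers is rejected
  narrow <- tibble::tibble(taxon = "only", optimum = 0, tolerance = 0.5,
                           max_abundance = 1)
  expect_error(gen_fossil_core(tibble::tibble(depth_cm = 1, wtd_true = 60),
                               narrow, seed = 1), "outside")
})

test_that("SCP generator produces the marker structure", {
  prof <- gen_scp_profile()
  expect_true(all(prof$conc_per_g >= 0))
  expect_true(all(prof$conc_per_g[prof$depth_cm >= 14] == 0))
  expect_equal(prof$depth_cm[which.max(prof$conc_per_g)], 4.5)
  expect_error(gen_scp_profile(start_depth = 4, increase_depth = 9, peak_depth = 14),
               "peak_depth < increase_depth < start_depth")
  noisy <- gen_scp_profile(noise_sd = 500, seed = 2)
  expect_true(all(noisy$conc_per_g >= 0))
  expect_identical(gen_scp_profile(noise_sd = 100, seed = 3),
                   gen_scp_profile(noise_sd = 100, seed = 3))
})
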