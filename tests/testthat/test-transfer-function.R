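test_that("WA-Tol reproduces the hand-worked 3-sample, 2-taxon example", {
  counts <- tibble::tibble(A = c(10, 5, 0), B = c(0, 5, 10))
  wtd <- c(10, 20, 30)
  tf <- fit_wa_tol(counts, wtd)
  # hand arithmetic: proportions (1,0),(.5,.5),(0,1); column sums 1.5 each
  uA <- (1 * 10 + 0.5 * 20) / 1.5          # 13.333...
  uB <- (0.5 * 20 + 1 * 30) / 1.5          # 26.666...
  tA <- sqrt((1 * (10 - uA)^2 + 0.5 * (20 - uA)^2) / 1.5)
  tB <- sqrt((0.5 * (20 - uB)^2 + 1 * (30 - uB)^2) / 1.5)
  expect_equal(tf$taxa$optimum, c(uA, uB))
  expect_equal(tf$taxa$tolerance, c(tA, tB))
  # equal tolerances: initial estimates are plain weighted averages
  init <- c(uA, (uA + uB) / 2, uB)
  b1 <- sum((init - mean(init)) * (wtd - mean(wtd))) / sum((init - mean(init))^2)
  b0 <- mean(wtd) - b1 * mean(init)
  expect_equal(tf$b1, b1)
  expect_equal(tf$b0, b0)
  expect_equal(tf$rmse, 0, tolerance = 1e-9)
  # pure assemblages predict the deshrunk optima
  expect_equal(predict(tf, tibble::tibble(A = 7, B = 0)), b0 + b1 * uA)
  # equal abundance of equal-tolerance taxa: deshrunk mean of the optima
  expect_equal(predict(tf, tibble::tibble(A = 3, B = 3)), b0 + b1 * (uA + uB) / 2)
})

test_that("predictions are invariant to count scaling and bounded before deshrinking", {
  tf <- tf_fixture()
  core <- gen_fossil_core(tibble::tibble(depth_cm = 1:10,
                                         wtd_true = seq(0, 30, length.out = 10)),
                          count_total = 150, seed = 21)
  p1 <- predict(tf, core)
  scaled <- core
  taxa <- tf$taxa$taxon
  scaled[taxa] <- scaled[taxa] * 10
  expect_equal(predict(tf, scaled), p1)
  # raw WA estimates stay within the span of the optima
  raw <- (p1 - tf$b0) / tf$b1
  expect_true(all(raw >= min(tf$taxa$optimum) - 1e-9))
  expect_true(all(raw <= max(tf$taxa$optimum) + 1e-9))
})

test_that("degenerate inputs are rejected informatively", {
  tf <- tf_fixture()
  expect_error(predict(tf, tibble::tibble(Unknown = c(5, 5))), "no taxa shared")
  mixed <- tibble::tibble(Aquatica_a = c(0, 3), Unknown = c(4, 0))
  expect_error(predict(tf, mixed), "no taxon shared")
  expect_error(fit_wa_tol(tibble::tibble(A = c(1, 2)), c(1, 2)), "at least 3")
  # a single-occurrence taxon gets the tolerance floor, with a warning
  counts <- tibble::tibble(A = c(10, 8, 6, 4), B = c(0, 0, 0, 2))
  expect_warning(tf2 <- fit_wa_tol(counts, c(0, 5, 10, 15)), "floored")
  expect_equal(tf2$taxa$tolerance[tf2$taxa$taxon == "B"], 0.01 * 15)
})

test_that("single taxon at 100% predicts the deshrunk optimum everywhere", {
  counts <- tibble::tibble(Only = c(50, 80, 120))
  tf <- fit_wa_tol(counts, c(5, 10, 15))
  # u = mean WTD; the degenerate deshrinking keeps predictions at u
  expect_equal(tf$taxa$optimum, 10)
  expect_equal(unname(predict(tf, tibble::tibble(Only = 33))), 10)
})

test_that("noiseless synthetic recovery beats the taxon tolerance scale", {
  tf <- tf_fixture()
  truth <- seq(2, 18, length.out = 30)
  core <- gen_fossil_core(tibble::tibble(depth_cm = seq(0.5, 15, by = 0.5),
                                         wtd_true = truth),
                          count_total = 150, seed = 12)
  pred <- predict(tf, core)
  rmse <- sqrt(mean((pred - truth)^2))
  expect_lt(rmse, mean(tf$taxa$tolerance))
})

test_that("bootstrap errors are reproducible and track real prediction error", {
  tf <- tf_fixture()
  # truths span the calibration gradient so the realized error is
  # representative of the model's prediction error, not just its easiest range
  truth <- seq(0, 30, length.out = 20)
  core <- gen_fossil_core(tibble::tibble(depth_cm = 1:20, wtd_true = truth),
                          count_total = 150, seed = 22)
  r1 <- reconstruct_wtd(tf, core, n_boot = 200, seed = 31)
  r2 <- reconstruct_wtd(tf, core, n_boot = 200, seed = 31)
  expect_identical(r1$se_boot, r2$se_boot)
  expect_true(all(r1$se_boot > 0))
  emp_rmse <- sqrt(mean((r1$wtd_pred - truth)^2))
  expect_gt(mean(r1$se_boot), emp_rmse / 2)
  expect_lt(mean(r1$se_boot), emp_rmse * 2)
  expect_error(reconstruct_wtd(tf, core, n_boot = 1), "n_boot")
})

test_that("standardization yields exact z-scores and affine invariance", {
  rec <- tibble::tibble(wtd_pred = c(2, 4, 6))
  z <- standardize_recon(rec)$z
  expect_equal(z, c(-1, 0, 1))                  # sd(2,4,6) = 2
  long <- tibble::tibble(wtd_pred = rnorm(40, 10, 3))
  zs <- standardize_recon(long)$z
  expect_equal(mean(zs), 0, tolerance = 1e-9)
  expect_equal(sd(zs), 1, tolerance = 1e-9)
  shifted <- tibble::tibble(wtd_pred = 3 * long$wtd_pred - 7)
  expect_equal(standardize_recon(shifted)$z, zs)
  expect_error(standardize_recon(tibble::tibble(wtd_pred = c(5, 5))), "zero variance")
})

test_that("comparing transfer functions recovers identity and constructed shifts", {
  tf <- tf_fixture()
  core <- gen_fossil_core(tibble::tibble(depth_cm = 1:15,
                                         wtd_true = seq(2, 25, length.out = 15)),
                          count_total = 300, seed = 23)
  same <- compare_transfer_functions(tf, tf, core)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-9)
  expect_equal(same$r2, 1)
  # a training set shifted +6 cm along the gradient shifts predictions by ~6
  tr_b <- training_fixture()
  tr_b$wtd_obs <- tr_b$wtd_obs + 6
  tf_b <- fit_wa_tol(tr_b)
  shift <- compare_transfer_functions(tf_b, tf, core)
  expect_equal(shift$slope, 1, tolerance = 0.05)
  expect_equal(shift$intercept, 6, tolerance = 0.8)
})
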