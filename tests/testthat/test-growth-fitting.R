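# growth_fitting: biomass transform, QC, Gompertz fitting, significance
# screen.

test_that("compute_biomass multiplies, floors at 1, and log2-transforms", {
  expect_equal(compute_biomass(8, 32), 8)
  expect_equal(compute_biomass(0, 500), 0)
  expect_equal(compute_biomass(1, 1), 0)
  expect_equal(compute_biomass(c(2, 4), c(2, 4)), c(2, 4))
  expect_error(compute_biomass(-1, 5), "non-negative")
})

test_that("qc_filter excludes short series and truncates long ones", {
  t4 <- seq(2, 8, by = 2)
  expect_false(qc_filter(t4, rep(1, 4))$pass)
  expect_equal(qc_filter(t4, rep(1, 4))$reason, "too_few_points")
  t5 <- seq(2, 10, by = 2)
  expect_true(qc_filter(t5, rep(1, 5))$pass)
  t23 <- seq(2, 46, by = 2)
  q <- qc_filter(t23, seq_len(23))
  expect_true(q$pass)
  expect_equal(length(q$times), 20L)
  expect_equal(q$times, t23[1:20])  # the first 20 points are kept
  # undefined biomass points do not count
  b <- rep(1, 6); b[2] <- NA
  expect_true(qc_filter(seq(2, 12, 2), b)$pass)
  b[3] <- NA
  expect_false(qc_filter(seq(2, 12, 2), b)$pass)
})

test_that("noiseless Gompertz series are recovered to 1e-4 relative", {
  grid <- seq(0, 48, by = 2)
  cases <- list(c(A = 10, k = 0.15, t_i = 24),
                c(A = 8, k = 0.3, t_i = 10),
                c(A = 12, k = 0.2, t_i = 18))
  for (tr in cases) {
    y <- gompertz(grid, tr["A"], tr["k"], tr["t_i"])
    f <- fit_gompertz(grid, y)
    expect_equal(f$status, "accepted")
    expect_lt(abs(f$A - tr["A"]) / tr["A"], 1e-4)
    expect_lt(abs(f$k - tr["k"]) / tr["k"], 1e-4)
    expect_lt(abs(f$t_i - tr["t_i"]) / tr["t_i"], 1e-4)
  }
})

test_that("fitted curves are monotone and pass the parameterization checks", {
  grid <- seq(0, 48, by = 2)
  y <- gompertz(grid, 9, 0.22, 15) + sin(seq_along(grid)) * 0.03
  f <- fit_gompertz(grid, y)
  expect_equal(f$status, "accepted")
  tt <- seq(0, 96, by = 0.5)
  pred <- predict(f, tt)
  expect_true(all(diff(pred) >= -1e-9))           # monotone nondecreasing
  expect_equal(predict(f, f$t_i), f$A / exp(1))   # y(t_i) = A/e exactly
  # refitting the model to its own predictions reproduces the parameters
  f2 <- fit_gompertz(f$times, predict(f))
  expect_lt(abs(f2$A - f$A), 1e-6)
  expect_lt(abs(f2$k - f$k), 1e-6)
  expect_lt(abs(f2$t_i - f$t_i), 1e-6)
})

test_that("degenerate series are rejected, never an error", {
  grid <- seq(0, 38, by = 2)
  f <- fit_gompertz(grid, rep(0, length(grid)))
  expect_match(f$status, "^rejected")
  f2 <- fit_gompertz(grid, rep(3.7, length(grid)))
  expect_match(f2$status, "^rejected")
  expect_error(fit_gompertz(c(2, 4, 6), c(1, 2, 3)), "QC")
})

test_that("validate_fit applies the strict all-parameters screen", {
  base <- list(A = 10, k = 0.2, t_i = 15, p_A = 0.001, p_k = 0.01,
               p_ti = 0.049)
  fit <- structure(base, class = "growth_fit")
  expect_equal(validate_fit(fit), "accepted")
  fit$p_ti <- 0.051
  expect_equal(validate_fit(fit), "rejected_significance")
  fit$p_ti <- NA_real_  # singular covariance: p undefined
  expect_equal(validate_fit(fit), "rejected_significance")
  fit$p_ti <- 0.01; fit$A <- -1
  expect_equal(validate_fit(fit), "rejected_significance")
})

test_that("parameter recovery under noise is unbiased within 2%", {
  # 50 replicate fits at sigma = 0.05; median estimate within +/-2% of truth
  set.seed(42)
  grid <- seq(0, 48, by = 2)
  truth <- c(A = 10, k = 0.15, t_i = 24)
  est <- t(replicate(50, {
    y <- gompertz(grid, truth["A"], truth["k"], truth["t_i"]) +
      rnorm(length(grid), 0, 0.05)
    f <- fit_gompertz(grid, y)
    c(f$A, f$k, f$t_i)
  }))
  med <- apply(est, 2L, median)
  expect_true(all(abs(med / truth - 1) < 0.02))
})

test_that("fit_growth_table flags QC failures and keeps accepted fits", {
  grid <- seq(8, 46, by = 2)
  good <- data.frame(plate_id = "P", position = "B2", time_h = grid,
                     biomass = gompertz(grid, 10, 0.25, 16))
  short <- data.frame(plate_id = "P", position = "B3", time_h = grid[1:4],
                      biomass = rep(1, 4))
  fits <- fit_growth_table(rbind(good, short))
  expect_equal(nrow(fits), 2L)
  expect_equal(fits$status[fits$position == "B2"], "accepted")
  expect_equal(fits$status[fits$position == "B3"], "rejected_qc")
  expect_true(is.na(fits$A[fits$position == "B3"]))
})
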