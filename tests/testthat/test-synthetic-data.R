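# synthetic_data: determinism, format validity, noiseless recovery, MSD
# calibration.

test_that("the generator is deterministic given config + seed", {
  cfg <- simulation_config(seed = 5L, n_isolates = 8L, msd_draws = 60L)
  b1 <- simulate_experiment(cfg)
  b2 <- simulate_experiment(cfg)
  expect_identical(b1$quant, b2$quant)
  expect_identical(b1$halos, b2$halos)
  expect_identical(b1$truth$pairs, b2$truth$pairs)
  # and the written bundles are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 5L)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # the generator does not disturb the session RNG stream
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(simulate_experiment(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated bundles pass IO validation and round trip", {
  b <- small_bundle()
  d <- withr::local_tempdir()
  write_bundle(b, d)
  back <- read_bundle(d)
  expect_named(back$layouts, names(b$layouts), ignore.order = TRUE)
  expect_equal(nrow(back$quant), nrow(b$quant))
  expect_equal(sort(unique(back$quant$plate_id)), sort(names(b$layouts)))
  q1 <- back$quant[order(back$quant$plate_id, back$quant$time_h, back$quant$position), ]
  q0 <- b$quant[order(b$quant$plate_id, b$quant$time_h, b$quant$position), ]
  expect_equal(q1$size, q0$size, tolerance = 1e-9)
  expect_equal(nrow(back$halos), nrow(b$halos))
  # size * opacity reproduces 2^biomass by construction
  expect_equal(log2(q0$size * q0$opacity), log2(q0$size) * 2, tolerance = 1e-12)
})

test_that("a noiseless experiment is recovered exactly by the pipeline", {
  cfg <- simulation_config(seed = 3L, n_isolates = 8L, sigma = 0,
                           position_sigma = 0, plate_sigma = 0, dropout = 0,
                           p_cooperation = 0, p_competition = 0,
                           msd_draws = 40L)
  b <- simulate_experiment(cfg)
  expect_equal(b$truth$msd_expected, 0)
  res <- run_pipeline(b)
  fits <- res$fits[res$fits$role %in% c("main_source", "replicate_source"), ]
  expect_true(all(fits$status == "accepted"))
  tr <- b$truth$isolates
  m <- match(fits$isolate_1, tr$isolate)
  expect_lt(max(abs(fits$A - tr$A[m]) / tr$A[m]), 1e-4)
  expect_lt(max(abs(fits$k - tr$k[m]) / tr$k[m]), 1e-4)
  expect_lt(max(abs(fits$t_i - tr$t_i[m]) / tr$t_i[m]), 1e-4)
})

test_that("under the generator's own null, >= 99% of pairs score neutral", {
  # the "sigma small" limit: all noise scales small and no dropout (a spot
  # whose whole rise phase happens to fall into dropped images has an
  # ill-conditioned fit that amplifies even tiny noise; that is a
  # missing-data pathology, not the classification chain under test)
  cfg <- simulation_config(seed = 9L, n_isolates = 96L, sigma = 0.01,
                           position_sigma = 0.01, plate_sigma = 0.02,
                           dropout = 0, p_cooperation = 0, p_competition = 0,
                           msd_draws = 200L)
  b <- simulate_experiment(cfg)
  expect_true(all(b$truth$pairs$eco_class_true == "neutral"))
  res <- run_pipeline(b)
  scored <- res$interactions$eco_class[res$interactions$eco_class != "unscored"]
  expect_gt(length(scored), 100L)
  expect_gte(mean(scored == "neutral"), 0.99)
})

test_that("ground-truth class frequencies match the configured rates", {
  b <- acceptance_run()$bundle
  cfg <- b$config
  pairs <- b$truth$pairs[!b$truth$pairs$self_pair, ]
  n <- nrow(pairs)
  for (cls in c("cooperation", "competition")) {
    p_cfg <- if (cls == "cooperation") cfg$p_cooperation else cfg$p_competition
    p_hat <- mean(pairs$eco_class_true == cls)
    expect_lt(abs(p_hat - p_cfg), 4 * sqrt(p_cfg * (1 - p_cfg) / n))
  }
  iso <- b$truth$isolates
  prev <- cfg$antifungal_prevalence[["LM17"]]
  for (tg in cfg$targets) {
    p_hat <- mean(iso[[tg]])
    expect_lt(abs(p_hat - prev), 4 * sqrt(prev * (1 - prev) / nrow(iso)))
  }
})

test_that("expected_msd responds to sigma as a noise scale", {
  base <- simulation_config(seed = 21L, n_isolates = 8L, sigma = 0,
                            position_sigma = 0, dropout = 0, msd_draws = 400L)
  expect_equal(expected_msd(base, n_draws = 40L), 0, tolerance = 1e-10)
  # sigma = 0 -> 0 exactly only with no positional variance either
  lo <- simulation_config(seed = 21L, n_isolates = 8L, sigma = 0.05,
                          position_sigma = 0, dropout = 0, msd_draws = 1000L)
  hi <- simulation_config(seed = 21L, n_isolates = 8L, sigma = 0.10,
                          position_sigma = 0, dropout = 0, msd_draws = 1000L)
  m_lo <- expected_msd(lo)
  m_hi <- expected_msd(hi)
  expect_gt(m_lo, 0)
  # IF is near-linear in additive biomass noise: doubling sigma ~ doubles MSD
  expect_lt(abs(m_hi / m_lo - 2), 0.2)
  # stable across seeds within 5% at 1000 draws
  lo2 <- simulation_config(seed = 1234L, n_isolates = 8L, sigma = 0.05,
                           position_sigma = 0, dropout = 0, msd_draws = 1000L)
  expect_lt(abs(expected_msd(lo2) / m_lo - 1), 0.05)
})

test_that("impossible configurations are refused", {
  expect_error(simulation_config(p_cooperation = 0.2, delta_msd = 1.5),
               "impossible")
  expect_error(simulation_config(dropout = 1.2), "probabilities")
  expect_error(simulation_config(n_isolates = 10), "multiple of 4")
  expect_error(simulation_config(media = "XYZ"), "prevalence")
  expect_error(simulation_config(sigma = -0.1), "non-negative")
})
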