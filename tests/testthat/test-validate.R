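test_that("bootstrap bias formula matches its definition", {
  expect_equal(round(bootstrap_bias(213.82, 207.29), 2), 3.15)
  expect_identical(bootstrap_bias(100, 100), 0)
  expect_equal(bootstrap_bias(c(1.1, 0.9), c(1, 1)), c(10, -10),
               tolerance = 1e-12)
})

test_that("bootstrap on cloned subjects collapses to zero-width intervals", {
  est <- ref_est()
  d1 <- generate_rich_cohort(n = 3, truth = est, seed = 33)
  one <- as.data.frame(d1)[d1$ID == 1, ]
  clones <- do.call(rbind, lapply(1:8, function(k) {
    x <- one
    x$ID <- k
    x
  }))
  dc <- pk_dataset(clones)
  spec <- model_spec(estimate_omega = character(0))
  b <- suppressWarnings(pk_bootstrap(dc, spec, est, n_resamples = 4,
                                     seed = 1))
  width <- (b$summary$ci_hi - b$summary$ci_lo) / abs(b$summary$median)
  expect_true(all(width < 1e-6))
  expect_true(all(abs(b$summary$bias_pct) < 0.1))
  expect_identical(length(b$resample_ids), 4L)
  expect_identical(b$n_failed, 0L)
  # percentile ordering
  expect_true(all(b$summary$ci_lo <= b$summary$median + 1e-12))
  expect_true(all(b$summary$median <= b$summary$ci_hi + 1e-12))
  # seeded rerun reproduces the resample draws exactly
  b2 <- suppressWarnings(pk_bootstrap(dc, spec, est, n_resamples = 4,
                                      seed = 1))
  expect_identical(b$resample_ids, b2$resample_ids)
  expect_equal(b$summary$median, b2$summary$median, tolerance = 1e-10)
})

test_that("CWRES reduces to scaled residuals without random effects", {
  est0 <- ref_est()
  est0$omega <- omega_spec(0, 0, 0, 0)
  est0$sigma <- sigma_spec(vcz = list(model = "additive", add = 0.3),
                           vno = list(model = "additive", add = 0.2))
  d <- generate_rich_cohort(n = 3, truth = est0, seed = 9)
  fit <- fit_foce(d, model_spec(), est0, eval_only = TRUE)
  cw <- cwres(d, fit)
  sig <- ifelse(cw$analyte == "vcz", 0.3, 0.2)
  expect_equal(cw$CWRES, (cw$DV - cw$IPRED) / sig, tolerance = 1e-8)
  expect_true(all(!cw$singular))
})

test_that("CWRES from a well-specified fit is standard-normal calibrated", {
  sf <- cached_small_fit()
  cw <- cwres(sf$data, sf$fit)
  expect_gt(nrow(cw), 400)
  expect_lt(abs(mean(cw$CWRES)), 0.1)
  expect_gt(sd(cw$CWRES), 0.85)
  expect_lt(sd(cw$CWRES), 1.15)
  expect_gte(mean(abs(cw$CWRES) < 3), 0.99)
})

test_that("gof table export is a plain delimited file", {
  sf <- cached_small_fit()
  path <- tempfile(fileext = ".csv")
  tab <- write_gof_table(sf$data, sf$fit, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(tab))
  expect_true(all(c("DV", "IPRED", "PRED", "CWRES", "TIME") %in%
                  names(back)))
})

test_that("degenerate VPC collapses onto the typical prediction", {
  est0 <- ref_est()
  est0$fixed$theta_IM <- 0          # one shared typical subject
  est0$fixed$theta_PM <- 0
  est0$omega <- omega_spec(0, 0, 0, 0)
  est0$sigma <- sigma_spec()        # all-zero residual error
  d <- generate_rich_cohort(n = 3, truth = est0, seed = 14)
  fit <- list(fixed = est0$fixed, omega_sd = c(V1 = 0, CL1 = 0, CL2 = 0,
                                               Vmax = 0),
              sigma = est0$sigma, spec = model_spec(), covinfo = list())
  v <- vpc(d, fit, n_sim = 20, seed = 3, n_bins = 4)
  # every replicate reproduces the observations, so the simulated percentile
  # bands have zero width and coincide with the observed percentiles
  expect_equal(v$table$sim_p50_lo, v$table$sim_p50_hi, tolerance = 1e-9)
  expect_equal(v$table$obs_p50, v$table$sim_p50_med, tolerance = 1e-5)
  expect_equal(v$table$obs_p2.5, v$table$sim_p2.5_med, tolerance = 1e-5)
  expect_equal(v$table$obs_p97.5, v$table$sim_p97.5_med, tolerance = 1e-5)
})

test_that("VPC bands are ordered, cover self-simulated data, and are
          invariant to subject relabeling", {
  sf <- cached_small_fit()
  v <- vpc(sf$data, sf$fit, n_sim = 120, seed = 5)
  with(v$table, {
    expect_true(all(sim_p2.5_med <= sim_p50_med + 1e-12))
    expect_true(all(sim_p50_med <= sim_p97.5_med + 1e-12))
    expect_true(all(sim_p50_lo <= sim_p50_hi))
  })
  inside <- with(v$table, obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi)
  expect_gte(mean(inside), 0.9)
  # relabel IDs without reordering rows
  df <- as.data.frame(sf$data)
  df$ID <- df$ID + 1000
  v2 <- vpc(pk_dataset(df), sf$fit, n_sim = 120, seed = 5)
  expect_equal(v$table$sim_p50_med, v2$table$sim_p50_med, tolerance = 1e-12)
  expect_equal(v$table$obs_p50, v2$table$obs_p50, tolerance = 1e-12)
})

test_that("VPC flags a misspecified model", {
  sf <- cached_small_fit()
  wrong <- sf$fit
  wrong$fixed$Vmax <- wrong$fixed$Vmax * 2
  v <- vpc(sf$data, wrong, n_sim = 120, seed = 6)
  # a clearance misspecification shows in the elimination-phase bins
  # (late time-after-dose); absorption-phase samples are insensitive to it
  ss <- v$table$analyte == "vcz" & v$table$t_mid > 5
  outside <- with(v$table[ss, ], obs_p50 > sim_p50_hi)
  expect_gt(mean(outside), 0.5)
})
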