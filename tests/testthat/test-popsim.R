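test_that("omega conventions convert tabulated percentages correctly", {
  o_var <- omega_spec(V1 = 240.77, Vmax = 21.13, convention = "var_times_100")
  expect_equal(o_var$sd[["V1"]], sqrt(2.4077), tolerance = 1e-12)
  o_sd <- omega_spec(V1 = 240.77, convention = "sd_times_100")
  expect_equal(o_sd$sd[["V1"]], 2.4077, tolerance = 1e-12)
  o_cv <- omega_spec(Vmax = 21.13, convention = "cv_percent")
  expect_equal(o_cv$sd[["Vmax"]], sqrt(log(1 + 0.2113^2)), tolerance = 1e-12)
  expect_error(omega_spec(V1 = -1), "nonnegative")
})

test_that("individual parameter sampling follows the lognormal model", {
  est <- ref_est()
  # degenerate IIV returns the typical subject exactly
  o0 <- omega_spec(0, 0, 0, 0)
  p <- sample_individual(est$fixed, o0, "IM", rng_seed = 1)
  expect_equal(p$Vmax_i, 18.80 * exp(-0.31), tolerance = 1e-12)
  expect_equal(p$V1_i, 207.29, tolerance = 1e-12)
  # seeded draws are reproducible
  a <- sample_individual(est$fixed, est$omega, "NM", rng_seed = 7)
  b <- sample_individual(est$fixed, est$omega, "NM", rng_seed = 7)
  expect_identical(unclass(a), unclass(b))
  # log-scale sample SD over many draws approaches the omega value
  om <- omega_spec(Vmax = 21.13, convention = "sd_times_100")
  set.seed(42)
  pm <- voripk:::sample_pars_matrix(est$fixed, om, "NM", 1e5)
  lsd <- sd(log(pm[, 6]))
  expect_lt(abs(lsd - 0.2113) / 0.2113, 0.02)
  # lognormal median equals the typical value
  expect_lt(abs(median(pm[, 6]) - 18.80) / 18.80, 0.01)
})

test_that("residual error models apply and flag negatives", {
  sig <- sigma_spec(vcz = list(model = "proportional", prop = 0.4697),
                    vno = list(model = "additive", add = 0.2))
  # zero-sigma identity
  sig0 <- sigma_spec()
  set.seed(1)
  expect_identical(as.numeric(apply_residual(c(1, 2), sig0, "vcz")), c(1, 2))
  # empirical CV of proportional noise matches sigma
  set.seed(2)
  obs <- apply_residual(rep(1, 1e5), sig, "vcz")
  expect_lt(abs(sd(obs) - 0.4697) / 0.4697, 0.02)
  expect_lt(abs(mean(obs) - 1), 0.01)
  # negative simulated values retained and flagged, not truncated
  expect_true(any(obs < 0))
  expect_identical(attr(obs, "negative"), as.vector(obs < 0))
  # additive branch
  set.seed(3)
  add <- apply_residual(rep(2, 1e4), sig, "vno")
  expect_lt(abs(sd(add) - 0.2) / 0.2, 0.05)
  expect_error(apply_residual(-1, sig, "vcz"), "nonnegative")
})

test_that("exposure metrics: window extrema and integrated AUC", {
  # constant synthetic profile
  tt <- seq(140, 170, by = 0.5)
  prof <- data.frame(time = tt, C1 = 2, C2 = 1,
                     cumAUC1 = 2 * tt, cumAUC2 = 1 * tt)
  m <- exposure_metrics(prof, 144, 168)
  expect_equal(m$vcz$Cmin, 2)
  expect_equal(m$vcz$Cmax, 2)
  expect_equal(m$vcz$AUC24, 48, tolerance = 1e-12)
  expect_equal(m$MR, 0.5, tolerance = 1e-12)
  expect_error(exposure_metrics(prof, 100, 168), "outside")
})

test_that("in the linear limit AUC24 is volume-independent and troughs match
          the closed form", {
  reg <- regimen_bid(200, days = 20)
  tt <- seq(456, 480, by = 0.25)
  lin_prof <- function(V1) {
    f0 <- fixed_effects(F = 0.895, ka = 1.1, V1 = V1, CL1 = 7, V2 = 10.01,
                        Vmax = 1e-300, Km = 1.15, CL2 = 4.65, Imax = 0,
                        IC50 = 14.6)
    solve_profile(reg, individual_params(f0, "NM"), tt)
  }
  m1 <- exposure_metrics(lin_prof(207.29), 456, 480)
  m2 <- exposure_metrics(lin_prof(103.6), 456, 480)
  expect_equal(m1$vcz$AUC24, m2$vcz$AUC24, tolerance = 1e-5)
  expect_equal(m1$vcz$AUC24, 0.895 * 400 / 7, tolerance = 1e-4)
  # the window minimum is the superposed-Bateman trough at 456 h
  oracle <- bateman_superpose(reg, 456, 0.895, 1.1, 7, 207.29)
  expect_equal(m1$vcz$Cmin, oracle, tolerance = 1e-6)
})

test_that("metabolic ratio basics and phenotype ordering", {
  expect_identical(metabolic_ratio(3, 3), 1)
  expect_identical(metabolic_ratio(2, 4), 0.5)
  expect_error(metabolic_ratio(1, 0), "positive")
  est <- ref_est()
  reg <- regimen_bid(200, days = 8)
  tt <- seq(144, 168, by = 0.5)
  mr <- vapply(c("NM", "IM", "PM"), function(ph) {
    prof <- solve_profile(reg, individual_params(est$fixed, ph), tt)
    exposure_metrics(prof, 144, 168)$MR
  }, numeric(1))
  # metabolic capacity ordering: NM > IM > PM, all of order one
  expect_true(mr[["NM"]] > mr[["IM"]])
  expect_true(mr[["IM"]] > mr[["PM"]])
  expect_true(all(mr > 0.1 & mr < 10))
})
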