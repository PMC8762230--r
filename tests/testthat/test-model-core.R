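test_that("nonlinear clearance follows the saturable auto-inhibited form", {
  est <- ref_est()
  p <- individual_params(est$fixed, "NM")

  # hand value: Vmax/(C1+Km) at C1 = Km = 1.15, no metabolite
  expect_equal(nonlinear_clearance(1.15, 0, p), 18.80 / 2.30,
               tolerance = 1e-12)
  # saturating metabolite: inhibition factor tends to 1 - Imax = 0.25
  hi <- nonlinear_clearance(1, 1e9, p) / nonlinear_clearance(1, 0, p)
  expect_equal(hi, 0.25, tolerance = 1e-6)
  # half-maximal inhibition exactly at C2 = IC50
  half <- nonlinear_clearance(1, est$fixed$IC50, p) /
    nonlinear_clearance(1, 0, p)
  expect_equal(half, 1 - 0.75 / 2, tolerance = 1e-12)
  # strictly decreasing in both concentrations
  c1 <- seq(0.1, 8, length.out = 25)
  expect_true(all(diff(nonlinear_clearance(c1, 1, p)) < 0))
  c2 <- seq(0, 40, length.out = 25)
  expect_true(all(diff(nonlinear_clearance(1, c2, p)) < 0))
  expect_error(nonlinear_clearance(-1, 0, p), "nonnegative")
  expect_error(nonlinear_clearance(1, -0.1, p), "nonnegative")
})

test_that("CYP2C19 phenotype effects scale Vmax multiplicatively", {
  est <- ref_est()
  expect_identical(typical_vmax(18.80, "NM", est$fixed), 18.80)
  expect_equal(typical_vmax(18.80, "IM", est$fixed), 18.80 * exp(-0.31),
               tolerance = 1e-12)
  expect_equal(round(typical_vmax(18.80, "IM", est$fixed), 2), 13.79)
  expect_equal(round(typical_vmax(18.80, "PM", est$fixed), 2), 10.21)
  expect_error(typical_vmax(18.80, "UM", est$fixed), "phenotype")
})

test_that("ODE right-hand side matches the structural equations", {
  est <- ref_est()
  p <- individual_params(est$fixed, "NM")
  expect_identical(ode_rhs(c(0, 0, 0, 0, 0), p), c(0, 0, 0, 0, 0))
  d <- ode_rhs(c(200, 0, 0, 0, 0), p)
  expect_equal(d[2], 0.895 * 200 * 1.1, tolerance = 1e-12)  # 196.9 mg/h
  # with kn = 1 and no linear clearances, conversion conserves amount
  f0 <- est$fixed
  f0$CL1 <- 1e-12; f0$CL2 <- 1e-12
  pc <- individual_params(f0, "NM")
  st <- c(50, 30, 10, 0, 0)
  dc <- ode_rhs(st, pc)
  expect_equal(dc[2] + dc[3], pc$F * pc$ka * st[1], tolerance = 1e-9)
})

test_that("Mosteller body surface area", {
  expect_equal(mosteller_bsa(170, 64), sqrt(170 * 64 / 3600),
               tolerance = 1e-12)
  expect_equal(round(mosteller_bsa(170, 64), 3), 1.738)
  expect_identical(mosteller_bsa(100, 36), 1)
  expect_equal(mosteller_bsa(180, 72), sqrt(3.6), tolerance = 1e-12)
  expect_error(mosteller_bsa(-170, 64), "positive")
  expect_error(mosteller_bsa(170, 0), "positive")
})

test_that("Bateman closed form behaves at its landmarks", {
  C <- function(t) bateman_oracle(200, t, 0.895, 1.1, 7, 207)
  expect_identical(C(0), 0)
  expect_lt(C(1e5), 1e-12)
  k <- 7 / 207
  tmax <- log(1.1 / k) / (1.1 - k)
  expect_gt(C(tmax), C(tmax * 0.9))
  expect_gt(C(tmax), C(tmax * 1.1))
  # ka == k limiting form is continuous
  lim <- bateman_oracle(100, 5, 1, 0.5, 1, 2)       # ka = k = 0.5
  near <- bateman_oracle(100, 5, 1, 0.5 + 1e-9, 1, 2)
  expect_equal(lim, near, tolerance = 1e-6)
})

test_that("regimens validate and build standard schedules", {
  r <- regimen_bid(200, days = 2)
  expect_identical(r$time, c(0, 12, 24, 36))
  r8 <- regimen_tid(150, days = 1)
  expect_identical(r8$time, c(0, 8, 16))
  sr <- standard_regimen(days = 2)
  expect_identical(sr$amt[1:3], c(400, 400, 200))
  expect_error(regimen(c(0, 0), 100), "increasing")
  expect_error(regimen(c(-1, 5), 100), "nonnegative")
  expect_error(regimen(c(0, 12), c(100, -5)), "positive")
})

test_that("solver reproduces the no-elimination retention limit", {
  est <- ref_est()
  f0 <- fixed_effects(F = 0.895, ka = 1.1, V1 = 207.29, CL1 = 1e-12,
                      V2 = 10.01, Vmax = 1e-12, Km = 1.15, CL2 = 4.65,
                      Imax = 0, IC50 = 14.6)
  p <- individual_params(f0, "NM")
  prof <- solve_profile(regimen(0, 200), p, c(100, 200))
  expect_equal(prof$A1[2], 0.895 * 200, tolerance = 1e-7)
})

test_that("linear-limit trajectories match the superposed Bateman oracle", {
  f0 <- fixed_effects(F = 0.895, ka = 1.1, V1 = 207.29, CL1 = 7,
                      V2 = 10.01, Vmax = 1e-300, Km = 1.15, CL2 = 4.65,
                      Imax = 0, IC50 = 14.6)
  p <- individual_params(f0, "NM")
  reg <- regimen_bid(200, days = 14)
  tt <- seq(5, 330, length.out = 50)
  prof <- solve_profile(reg, p, tt)
  oracle <- bateman_superpose(reg, tt, 0.895, 1.1, 7, 207.29)
  expect_lt(max(abs(prof$C1 - oracle) / oracle), 1e-6)
})

test_that("doubling every dose doubles concentrations in the linear limit", {
  f0 <- fixed_effects(F = 0.895, ka = 1.1, V1 = 207.29, CL1 = 7,
                      V2 = 10.01, Vmax = 1e-300, Km = 1.15, CL2 = 4.65,
                      Imax = 0, IC50 = 14.6)
  p <- individual_params(f0, "NM")
  tt <- c(13, 50, 100)
  c1 <- solve_profile(regimen_bid(200, days = 5), p, tt)$C1
  c2 <- solve_profile(regimen_bid(400, days = 5), p, tt)$C1
  expect_equal(c2, 2 * c1, tolerance = 1e-8)
})

test_that("compiled integrator agrees with the deSolve reference", {
  est <- ref_est()
  p <- individual_params(est$fixed, "IM")
  reg <- regimen_bid(200, days = 3)
  tt <- c(13, 25, 47, 71.5)
  a <- solve_profile(reg, p, tt, engine = "dopri")
  b <- solve_profile(reg, p, tt, engine = "lsoda")
  expect_equal(a$C1, b$C1, tolerance = 1e-7)
  expect_equal(a$C2, b$C2, tolerance = 1e-7)
  expect_equal(a$cumAUC1, b$cumAUC1, tolerance = 1e-7)
})

test_that("observations at a dose time use the pre-dose (trough) state", {
  est <- ref_est()
  p <- individual_params(est$fixed, "NM")
  reg <- regimen_bid(200, days = 2)
  at_dose <- solve_profile(reg, p, 24)$A_gut
  just_before <- solve_profile(reg, p, 24 - 1e-9)$A_gut
  expect_equal(at_dose, just_before, tolerance = 1e-6)
})

test_that("solver input validation", {
  est <- ref_est()
  p <- individual_params(est$fixed, "NM")
  reg <- regimen_bid(200, days = 1)
  expect_error(solve_profile(reg, p, c(5, 1)), "nondecreasing")
  expect_error(solve_profile(reg, p, -1), "nonnegative")
  expect_error(solve_profile(reg, p, 5, rtol = 0), "positive")
})

test_that("mass balance holds with kn = 1 over two weeks of dosing", {
  est <- ref_est()
  p <- individual_params(est$fixed, "NM")
  reg <- regimen_bid(200, days = 14)
  prof <- solve_profile(reg, p, 336, rtol = 1e-10, atol = 1e-12)
  dosed <- sum(reg$amt)
  absorbed <- p$F * (dosed - prof$A_gut)
  accounted <- prof$A1 + prof$A2 + p$CL1_i * prof$cumAUC1 +
    p$CL2_i * prof$cumAUC2
  expect_lt(abs(absorbed - accounted) / (p$F * dosed), 1e-6)
})

test_that("steady-state trough responds monotonically to CL1, Vmax, dose", {
  est <- ref_est()
  trough <- function(cl1 = 1.91, vmax = 18.80, dose = 200) {
    f <- est$fixed
    f$CL1 <- cl1; f$Vmax <- vmax
    p <- individual_params(f, "NM")
    solve_profile(regimen_bid(dose, days = 14), p, 336)$C1
  }
  tr_cl1 <- vapply(c(1, 2, 4, 8), function(x) trough(cl1 = x), numeric(1))
  expect_true(all(diff(tr_cl1) < 0))
  tr_vm <- vapply(c(10, 19, 30, 45), function(x) trough(vmax = x), numeric(1))
  expect_true(all(diff(tr_vm) < 0))
  tr_d <- vapply(c(150, 200, 300, 400), function(x) trough(dose = x),
                 numeric(1))
  expect_true(all(diff(tr_d) > 0))
})

test_that("dose-normalized exposure rises with dose (saturable elimination)", {
  est <- ref_est()
  p <- individual_params(est$fixed, "NM")
  auc_per_mg <- vapply(c(150, 200, 400), function(dose) {
    prof <- solve_profile(regimen_bid(dose, days = 8), p, c(168, 192))
    (prof$cumAUC1[2] - prof$cumAUC1[1]) / dose
  }, numeric(1))
  expect_true(all(diff(auc_per_mg) > 0))
})
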