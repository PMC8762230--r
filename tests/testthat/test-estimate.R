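test_that("information criteria identities", {
  ic <- information_criteria(1320.48, 11, 427)
  expect_equal(ic[["AIC"]], 1320.48 + 22, tolerance = 1e-12)
  expect_equal(ic[["BIC"]], 1320.48 + 11 * log(427), tolerance = 1e-12)
  ic0 <- information_criteria(5, 0, 10)
  expect_identical(unname(ic0), c(5, 5))
  expect_error(information_criteria(1, -1, 10), "p >= 0")
})

test_that("covariate transforms: power and exponential forms", {
  expect_identical(covariate_transform(10, 70, 64, "power", 0), 10)
  expect_identical(covariate_transform(10, 64, 64, "power", 0.75), 10)
  expect_equal(covariate_transform(10, 80, 64, "power", 0.75),
               10 * (80 / 64)^0.75, tolerance = 1e-12)
  expect_identical(covariate_transform(10, form = "exponential",
                                       theta_cov = 0), 10)
  # categorical effect: a theta of -0.31 is a 26.7% reduction
  red <- 1 - covariate_transform(1, form = "exponential", theta_cov = -0.31)
  expect_equal(round(100 * red, 1), 26.7)
  expect_error(covariate_transform(10, -1, 64, "power", 1), "positive")
  expect_error(covariate_transform(10, form = "power"), "cov_value")
})

test_that("reference Laplace objective is exact for eta-linear models", {
  G <- cbind(c(1, 2, 0.5), c(0.3, -1, 1.2))
  a <- c(1, 2, 3)
  y <- c(1.4, 1.1, 3.6)
  om2 <- c(0.5, 0.3)
  sig2 <- 0.04
  ref <- laplace_ofv_ref(function(eta) a + drop(G %*% eta), y,
                         function(f) rep(sig2, 3), om2)
  S <- diag(sig2, 3) + G %*% diag(om2) %*% t(G)
  exact <- drop(log(det(2 * pi * S)) + t(y - a) %*% solve(S) %*% (y - a))
  expect_equal(ref$ofv, exact, tolerance = 1e-8)
  # conditional mode equals the BLUP of the linear mixed model
  blup <- drop(diag(om2) %*% t(G) %*% solve(S) %*% (y - a))
  expect_equal(ref$eta, blup, tolerance = 1e-6)
})

test_that("compiled engine matches the R reference on a nonlinear subject", {
  est <- ref_est()
  d1 <- generate_rich_cohort(n = 3, truth = est, seed = 5)
  sub <- d1[d1$ID == 2, ]
  obs <- sub[sub$EVID == 0 & sub$BLQ == 0, ]
  reg <- regimen(seq(0, 108, 12), 200)
  f_fun <- function(eta) {
    p <- individual_params(est$fixed, "IM",
                           c(V1 = eta[1], CL1 = eta[2], CL2 = eta[3],
                             Vmax = eta[4]))
    prof <- solve_profile(reg, p, unique(obs$TIME), rtol = 1e-10,
                          atol = 1e-12)
    ifelse(obs$DVID == 1, prof$C1[match(obs$TIME, prof$time)],
           prof$C2[match(obs$TIME, prof$time)])
  }
  v_fun <- function(f) ifelse(obs$DVID == 1, (0.4697 * f)^2, (0.2793 * f)^2)
  ref <- laplace_ofv_ref(f_fun, obs$DV, v_fun, est$omega$sd^2)
  eng <- fit_foce(pk_dataset(sub), final_model_spec(), est, eval_only = TRUE,
                  control = list(rtol = 1e-10, atol = 1e-12))
  expect_lt(abs(eng$ofv - ref$ofv) / abs(ref$ofv), 1e-4)
})

test_that("zero-IIV additive-error OFV equals the closed-form Gaussian -2LL", {
  est0 <- ref_est()
  est0$omega <- omega_spec(0, 0, 0, 0)
  est0$sigma <- sigma_spec(vcz = list(model = "additive", add = 0.3),
                           vno = list(model = "additive", add = 0.2))
  d <- generate_rich_cohort(n = 3, truth = est0, seed = 9)
  eng <- fit_foce(d, final_model_spec(), est0, eval_only = TRUE,
                  control = list(rtol = 1e-10, atol = 1e-12))
  reg <- regimen(seq(0, 108, 12), 200)
  ll <- 0
  for (i in 1:3) {
    obs <- d[d$ID == i & d$EVID == 0 & d$BLQ == 0, ]
    p <- attr(d, "truth_params")[[i]]
    prof <- solve_profile(reg, p, unique(obs$TIME), rtol = 1e-10,
                          atol = 1e-12)
    pred <- ifelse(obs$DVID == 1, prof$C1[match(obs$TIME, prof$time)],
                   prof$C2[match(obs$TIME, prof$time)])
    s2 <- ifelse(obs$DVID == 1, 0.09, 0.04)
    ll <- ll + sum(log(2 * pi * s2) + (obs$DV - pred)^2 / s2)
  }
  expect_lt(abs(eng$ofv - ll), 1e-6)
})

test_that("estimated-parameter counts: 11 base, 13 with the CYP2C19 effect", {
  est <- ref_est()
  d <- generate_rich_cohort(n = 3, truth = est, seed = 13)
  f_base <- fit_foce(d, model_spec(), est, eval_only = TRUE)
  f_final <- fit_foce(d, final_model_spec(), est, eval_only = TRUE)
  expect_identical(f_base$p, 11L)
  expect_identical(f_final$p, 13L)
  expect_equal(f_base$aic, f_base$ofv + 22, tolerance = 1e-10)
  expect_equal(f_final$bic, f_final$ofv + 13 * log(f_final$n_obs),
               tolerance = 1e-10)
})

test_that("OFV is invariant to subject order and to time-unit rescaling", {
  est <- ref_est()
  d <- generate_rich_cohort(n = 4, truth = est, seed = 17)
  f1 <- fit_foce(d, final_model_spec(), est, eval_only = TRUE)
  # permute subjects
  df <- as.data.frame(d)
  perm <- do.call(rbind, lapply(c(3, 1, 4, 2), function(i) df[df$ID == i, ]))
  f2 <- fit_foce(pk_dataset(perm), final_model_spec(), est, eval_only = TRUE)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-8)
  # hours -> days with consistently rescaled rate parameters
  df_d <- df
  df_d$TIME <- df_d$TIME / 24
  est_d <- est
  est_d$fixed$ka <- est$fixed$ka * 24
  est_d$fixed$CL1 <- est$fixed$CL1 * 24
  est_d$fixed$CL2 <- est$fixed$CL2 * 24
  est_d$fixed$Vmax <- est$fixed$Vmax * 24
  f3 <- fit_foce(pk_dataset(df_d), final_model_spec(), est_d,
                 eval_only = TRUE)
  expect_equal(f1$ofv, f3$ofv, tolerance = 1e-5)
})

test_that("empirical Bayes modes: prior mode without data, shrink with omega",
{
  est <- ref_est()
  sf <- cached_small_fit()
  # a dose-only subject gets eta = 0
  df <- as.data.frame(sf$data)
  extra <- df[df$ID == 1 & df$EVID == 1, ]
  extra$ID <- 999
  d2 <- pk_dataset(rbind(df, extra))
  eb <- empirical_bayes(d2, sf$fit)
  row <- eb[eb$ID == 999, ]
  expect_identical(unname(unlist(row[paste0("eta_",
                                            c("V1", "CL1", "CL2", "Vmax"))])),
                   c(0, 0, 0, 0))
  # omega -> 0 forces all etas to 0
  fit0 <- sf$fit
  fit0$omega_sd <- c(V1 = 0, CL1 = 0, CL2 = 0, Vmax = 0)
  eb0 <- empirical_bayes(sf$data, fit0)
  expect_true(all(abs(as.matrix(eb0[, 2:5])) == 0))
})

test_that("empirical Bayes estimates track the generating individuals", {
  sf <- cached_small_fit()
  eb <- empirical_bayes(sf$data, sf$fit)
  tp <- attr(sf$data, "truth_params")
  rel <- function(col, truth_name) {
    vapply(seq_len(nrow(eb)), function(i)
      abs(eb[[col]][i] - tp[[i]][[truth_name]]) / tp[[i]][[truth_name]],
      numeric(1))
  }
  expect_lt(median(rel("CL2_i", "CL2_i")), 0.15)
  expect_lt(median(rel("Vmax_i", "Vmax_i")), 0.15)
})

test_that("collinearity screen flags dependent covariates", {
  set.seed(31)
  n <- 1e4
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  tab$dup <- tab$a
  tab$const <- 1
  sc <- collinearity_screen(tab)
  expect_identical(sc$constant, "const")
  expect_true(any(sc$excluded_pairs$var1 == "a" &
                  sc$excluded_pairs$var2 == "dup"))
  expect_equal(sc$correlation["a", "dup"], 1, tolerance = 1e-12)
  expect_lt(abs(sc$correlation["a", "b"]), 0.05)
  # weight and body surface area from the study generator are collinear
  d <- generate_cohort(cohort_design(n_subjects = 40,
                                     phenotype_counts = c(NM = 20, IM = 10,
                                                          PM = 8, UNK = 2),
                                     seed = 8))
  covs <- as.data.frame(d)[!duplicated(d$ID), c("WT", "HT", "BSA", "AGE")]
  sc2 <- collinearity_screen(covs)
  expect_gt(sc2$correlation["WT", "BSA"], 0.5)
  expect_true(any((sc2$excluded_pairs$var1 == "WT" &
                   sc2$excluded_pairs$var2 == "BSA") |
                  (sc2$excluded_pairs$var1 == "BSA" &
                   sc2$excluded_pairs$var2 == "WT")))
})

test_that("a trough-only cohort's fitted OFV is no worse than at the truth", {
  est <- ref_est()
  design <- cohort_design(n_subjects = 24,
                          phenotype_counts = c(NM = 9, IM = 9, PM = 5,
                                               UNK = 1),
                          first_sample_window = c(23, 700), seed = 12)
  d <- generate_cohort(design, est)
  at_truth <- fit_foce(d, final_model_spec(), est, eval_only = TRUE,
                       control = list(hfix = 0.5))
  fit <- suppressWarnings(fit_foce(d, final_model_spec(), est,
                                   control = list(se = FALSE,
                                                  rel_tol = 1e-5,
                                                  tol_eta = 1e-5,
                                                  restarts = 1,
                                                  outer_iter = 30)))
  expect_lte(fit$ofv, at_truth$ofv + 0.1)
})
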