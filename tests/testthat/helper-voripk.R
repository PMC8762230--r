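# Shared fixtures, built once per test run and cached.

ref_est <- function(...) vcz_final_estimates(...)

.fixtures <- new.env(parent = emptyenv())

# small rich-design cohort fitted at the final model; reused by the
# residual-diagnostic and empirical-Bayes tests
cached_small_fit <- function() {
  if (is.null(.fixtures$small_fit)) {
    est <- ref_est()
    d <- generate_rich_cohort(n = 30, truth = est, seed = 21)
    fit <- suppressWarnings(
      fit_foce(d, final_model_spec(), est,
               control = list(se = FALSE, rel_tol = 1e-5, tol_eta = 1e-5,
                              restarts = 1)))
    .fixtures$small_fit <- list(data = d, fit = fit, est = est)
  }
  .fixtures$small_fit
}

# displaced starting values for recovery fits: structural values off by
# 15% (alternating direction), covariate effects shrunk 30% toward zero,
# inflated variability terms
perturbed_init <- function(est) {
  init <- est
  init$fixed$V1 <- est$fixed$V1 * 1.15
  init$fixed$CL1 <- est$fixed$CL1 * 0.87
  init$fixed$V2 <- est$fixed$V2 * 1.15
  init$fixed$Vmax <- est$fixed$Vmax * 0.87
  init$fixed$CL2 <- est$fixed$CL2 * 1.15
  init$fixed$theta_IM <- est$fixed$theta_IM * 0.7
  init$fixed$theta_PM <- est$fixed$theta_PM * 0.7
  init$omega$sd <- est$omega$sd * 1.2
  init$sigma$vcz$prop <- 0.35
  init$sigma$vno$prop <- 0.35
  init
}

fit_estimates <- function(fit) {
  setNames(fit$estimates$estimate, fit$estimates$parameter)
}
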