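#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement (original cohort size), refits the
#' model on each resample, and summarizes every estimated parameter by the
#' bootstrap median, the 2.5th/97.5th percentiles, and the relative bias
#' `(bootstrap median - original estimate) / original estimate * 100`.
#' Resamples whose refit fails or does not converge are excluded and
#' counted; a nonconvergence rate above 20% raises a warning in the report.
#'
#' @param data the original [pk_dataset()].
#' @param spec,init as in [fit_foce()]; refits start from the original
#'   estimates.
#' @param n_resamples number of bootstrap datasets (the reference analysis
#'   used 1000; tests use far fewer).
#' @param seed integer seed controlling the resampling.
#' @param stratify_by optional covariate column (e.g. `"PHEN"`); resampling
#'   is then done within strata.
#' @param control passed to [fit_foce()] (standard errors are off).
#' @return An object of class `pk_boot`: `summary` data frame (estimate,
#'   median, ci_lo, ci_hi, bias_pct per parameter), `estimates` matrix of
#'   per-resample estimates, `resample_ids` list (logged for
#'   reproducibility), `n_failed`, `failure_rate`.
#' @export
pk_bootstrap <- function(data, spec, init, n_resamples = 1000, seed = 1,
                         stratify_by = NULL, control = list()) {
  control <- modifyList(list(se = FALSE), control)
  orig <- fit_foce(data, spec, init, control)
  df <- as.data.frame(data)
  ids <- unique(df$ID)
  set.seed(seed)
  strata <- if (is.null(stratify_by)) rep(1L, length(ids))
            else df[[stratify_by]][match(ids, df$ID)]

  draws <- vector("list", n_resamples)
  ests <- matrix(NA_real_, n_resamples, length(orig$par),
                 dimnames = list(NULL, names(orig$par)))
  ok <- logical(n_resamples)
  init_warm <- list(fixed = orig$fixed,
                    omega = orig$init$omega, sigma = orig$sigma)
  init_warm$omega$sd <- orig$omega_sd
  for (b in seq_len(n_resamples)) {
    take <- unlist(lapply(unique(strata), function(s) {
      pool <- ids[strata == s]
      sample(pool, length(pool), replace = TRUE)
    }))
    draws[[b]] <- take
    pieces <- lapply(seq_along(take), function(k) {
      d <- df[df$ID == take[k], , drop = FALSE]
      d$ID <- k
      d
    })
    bd <- pk_dataset(do.call(rbind, pieces))
    f <- tryCatch(fit_foce(bd, spec, init_warm, control),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      ests[b, ] <- setNames(f$estimates$estimate, f$estimates$parameter)[
        colnames(ests)]
      ok[b] <- TRUE
    }
  }
  keep <- ests[ok, , drop = FALSE]
  orig_est <- setNames(orig$estimates$estimate, orig$estimates$parameter)
  summ <- data.frame(
    parameter = colnames(ests),
    estimate = orig_est[colnames(ests)],
    median = apply(keep, 2, median),
    ci_lo = apply(keep, 2, quantile, 0.025),
    ci_hi = apply(keep, 2, quantile, 0.975),
    row.names = NULL
  )
  summ$bias_pct <- bootstrap_bias(summ$median, summ$estimate)
  rate <- 1 - mean(ok)
  if (rate > 0.2)
    warning(sprintf("bootstrap nonconvergence rate %.1f%% exceeds 20%%",
                    100 * rate), call. = FALSE)
  structure(list(summary = summ, estimates = keep, resample_ids = draws,
                 n_failed = sum(!ok), failure_rate = rate, seed = seed,
                 original = orig),
            class = "pk_boot")
}

#' Bootstrap relative bias
#'
#' `bias% = (bootstrap median - original estimate) / original estimate * 100`.
#'
#' @param boot_median bootstrap median estimate(s).
#' @param original original model estimate(s).
#' @return Bias in percent.
#' @export
bootstrap_bias <- function(boot_median, original) {
  (boot_median - original) / original * 100
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d resamples, %d failed (%.1f%%)\n",
              nrow(x$estimates) + x$n_failed, x$n_failed,
              100 * x$failure_rate))
  print(transform(x$summary, estimate = signif(estimate, 5),
                  median = signif(median, 5), ci_lo = signif(ci_lo, 4),
                  ci_hi = signif(ci_hi, 4), bias_pct = round(bias_pct, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the observed design (same subjects,
#' dosing and sampling times; new random effects and residual errors drawn
#' from the fitted model), bins observations by time after the most recent
#' dose (quantile bins, default 8; empty or single-observation bins are
#' merged with their neighbor and logged), and compares the observed
#' 2.5/50/97.5 percentiles per bin with the simulation-based 95% confidence
#' band of each percentile.
#'
#' @param data a [pk_dataset()] supplying the design and the observations.
#' @param fit a [fit_foce()] result (or a list with `fixed`, `omega_sd`,
#'   `sigma`, `spec`, `covinfo` at which to simulate).
#' @param n_sim number of simulated replicates (reference analysis: 1000).
#' @param seed integer seed.
#' @param n_bins target number of time-after-dose bins.
#' @param prediction_corrected if TRUE, observations and simulations are
#'   scaled by the bin median population prediction first (pcVPC).
#' @return An object of class `pk_vpc`: per-analyte binned table with
#'   observed percentiles, simulated percentile medians and their 95%
#'   confidence bands, plus a tidy `table` for external plotting.
#' @export
vpc <- function(data, fit, n_sim = 1000, seed = 1, n_bins = 8,
                prediction_corrected = FALSE) {
  set.seed(seed)
  subj <- pack_subjects(data)
  resolved <- resolve_covariates(fit$spec, subj)
  typ <- build_typicals(fit$fixed, fit$covinfo, resolved)
  n <- length(subj)
  omega_sd <- fit$omega_sd

  # time after the most recent dose for every observation
  tad <- unlist(lapply(subj, function(s) {
    vapply(s$obs_t, function(t) {
      prev <- s$dose_t[s$dose_t <= t]
      if (length(prev)) t - max(prev) else t
    }, numeric(1))
  }))
  tabs <- unlist(lapply(subj, `[[`, "obs_t"))
  analyte <- unlist(lapply(subj, `[[`, "analyte"))
  yobs <- unlist(lapply(subj, `[[`, "y"))

  # typical population prediction per observation (for pcVPC)
  pred_typ <- unlist(lapply(seq_len(n), function(i) {
    s <- subj[[i]]
    p <- list(F = fit$fixed$F, ka = fit$fixed$ka, V2 = fit$fixed$V2,
              Km = fit$fixed$Km, Imax = fit$fixed$Imax,
              IC50 = fit$fixed$IC50, kn = fit$fixed$kn,
              V1_i = typ[i, "V1"], CL1_i = typ[i, "CL1"],
              CL2_i = typ[i, "CL2"], Vmax_i = typ[i, "Vmax"])
    st <- cpp_solve_profile(s$dose_t, s$dose_a, s$obs_t, pars_vector(p),
                            1e-6, 1e-8)
    ifelse(s$analyte == 1, st[, "A1"] / p$V1_i, st[, "A2"] / p$V2)
  }))

  nobs_i <- vapply(subj, function(s) length(s$y), 0L)
  sims <- matrix(NA_real_, length(yobs), n_sim)
  for (r in seq_len(n_sim)) {
    row0 <- 0L
    for (i in seq_len(n)) {
      s <- subj[[i]]
      eta <- rnorm(4, 0, omega_sd)
      p <- list(F = fit$fixed$F, ka = fit$fixed$ka, V2 = fit$fixed$V2,
                Km = fit$fixed$Km, Imax = fit$fixed$Imax,
                IC50 = fit$fixed$IC50, kn = fit$fixed$kn,
                V1_i = typ[i, "V1"] * exp(eta[1]),
                CL1_i = typ[i, "CL1"] * exp(eta[2]),
                CL2_i = typ[i, "CL2"] * exp(eta[3]),
                Vmax_i = typ[i, "Vmax"] * exp(eta[4]))
      st <- cpp_solve_profile(s$dose_t, s$dose_a, s$obs_t, pars_vector(p),
                              1e-6, 1e-8)
      f <- ifelse(s$analyte == 1, st[, "A1"] / p$V1_i, st[, "A2"] / p$V2)
      obs <- f
      for (a in 1:2) {
        ja <- s$analyte == a
        if (any(ja))
          obs[ja] <- apply_residual(f[ja], fit$sigma,
                                    c("vcz", "vno")[a])
      }
      sims[row0 + seq_len(nobs_i[i]), r] <- obs
      row0 <- row0 + nobs_i[i]
    }
  }

  merged_bins <- character(0)
  out <- list()
  tidy <- NULL
  for (a in 1:2) {
    ja <- analyte == a
    br <- unique(quantile(tad[ja], probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(tad[ja], br, include.lowest = TRUE)
    # merge single-observation bins with their left neighbor
    tab <- table(bins)
    while (any(tab < 2) && length(levels(bins)) > 1) {
      k <- which(tab < 2)[1]
      merged_bins <- c(merged_bins, levels(bins)[k])
      neighbor <- if (k == 1) 2L else k - 1L
      levels(bins)[k] <- levels(bins)[neighbor]
      bins <- droplevels(bins)
      tab <- table(bins)
    }
    yo <- yobs[ja]
    sm <- sims[ja, , drop = FALSE]
    if (prediction_corrected) {
      pc <- pred_typ[ja]
      for (b in levels(bins)) {
        jb <- bins == b
        mref <- median(pc[jb])
        yo[jb] <- yo[jb] * mref / pc[jb]
        sm[jb, ] <- sm[jb, ] * mref / pc[jb]
      }
    }
    rows <- lapply(levels(bins), function(b) {
      jb <- bins == b
      obs_q <- quantile(yo[jb], c(0.025, 0.5, 0.975))
      sim_q <- apply(sm[jb, , drop = FALSE], 2, quantile,
                     c(0.025, 0.5, 0.975))
      ci <- apply(sim_q, 1, quantile, c(0.025, 0.5, 0.975))
      data.frame(analyte = c("vcz", "vno")[a], bin = b,
                 t_mid = median(tad[ja][jb]),
                 t_abs = median(tabs[ja][jb]), n = sum(jb),
                 obs_p2.5 = obs_q[1], obs_p50 = obs_q[2],
                 obs_p97.5 = obs_q[3],
                 sim_p2.5_med = ci[2, 1], sim_p2.5_lo = ci[1, 1],
                 sim_p2.5_hi = ci[3, 1],
                 sim_p50_med = ci[2, 2], sim_p50_lo = ci[1, 2],
                 sim_p50_hi = ci[3, 2],
                 sim_p97.5_med = ci[2, 3], sim_p97.5_lo = ci[1, 3],
                 sim_p97.5_hi = ci[3, 3], row.names = NULL)
    })
    tidy <- rbind(tidy, do.call(rbind, rows))
  }
  structure(list(table = tidy, n_sim = n_sim, seed = seed,
                 merged_bins = merged_bins,
                 prediction_corrected = prediction_corrected),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check: %d simulated replicates%s\n",
              x$n_sim,
              if (x$prediction_corrected) " (prediction-corrected)" else ""))
  print(transform(x$table, t_mid = round(t_mid, 1)), row.names = FALSE,
        digits = 3)
  invisible(x)
}

#' Conditional weighted residuals
#'
#' CWRES from the FOCE linearization: with `f` the conditional prediction,
#' `G` the sensitivity of the prediction to the random effects, `eta_hat`
#' the conditional mode, and `V` the residual variance at the mode, the
#' population-linearized observation has mean `f - G eta_hat` and covariance
#' `V + G Omega G'`; CWRES is the Cholesky-whitened deviation of the
#' observations from that mean. For a model without random effects and
#' additive error this reduces to `(obs - pred) / sigma`.
#'
#' @param data a [pk_dataset()].
#' @param fit a [fit_foce()] result.
#' @return A data frame with one row per (non-BLQ) observation: `ID`,
#'   `TIME`, `TAD` (time after dose), `analyte`, `DV`, `IPRED` (conditional
#'   prediction), `PRED` (linearized population prediction) and `CWRES`;
#'   observations hitting a numerically singular covariance are flagged in
#'   the `singular` column.
#' @export
cwres <- function(data, fit) {
  subj <- pack_subjects(data)
  resolved <- resolve_covariates(fit$spec, subj)
  typ <- build_typicals(fit$fixed, fit$covinfo, resolved)
  csub <- lapply(subj, function(s)
    s[c("dose_t", "dose_a", "obs_t", "y", "analyte")])
  ctl <- fit$control
  res <- cpp_foce_ofv(csub, typ, c(fit$fixed$F, fit$fixed$ka, fit$fixed$V2,
                                   fit$fixed$Km, fit$fixed$Imax,
                                   fit$fixed$IC50, fit$fixed$kn),
                      fit$omega_sd^2, sigma_matrix(fit$sigma),
                      errmodel_codes(fit$sigma),
                      matrix(0, length(subj), 4), ctl$rtol, ctl$atol,
                      ctl$inner_maxit, ctl$tol_eta, TRUE, ctl$hfix)
  act <- which(fit$omega_sd > 0)
  out <- lapply(seq_along(subj), function(i) {
    s <- subj[[i]]
    cond <- res$cond[[i]]
    f <- cond$f
    G <- cond$G
    v <- cond$v
    eta <- res$eta[i, ]
    if (length(act)) {
      Om <- diag(fit$omega_sd[act]^2, length(act))
      Cov <- diag(v, length(v)) + G %*% Om %*% t(G)
      Epop <- f - drop(G %*% eta[act])
    } else {
      Cov <- diag(v, length(v))
      Epop <- f
    }
    ch <- tryCatch(chol(Cov), error = function(e) NULL)
    if (is.null(ch)) {
      w <- rep(NA_real_, length(f))
      sing <- TRUE
    } else {
      w <- drop(backsolve(ch, s$y - Epop, transpose = TRUE))
      sing <- FALSE
    }
    tad <- vapply(s$obs_t, function(t) {
      prev <- s$dose_t[s$dose_t <= t]
      if (length(prev)) t - max(prev) else t
    }, numeric(1))
    data.frame(ID = s$id, TIME = s$obs_t, TAD = tad,
               analyte = c("vcz", "vno")[s$analyte], DV = s$y,
               IPRED = f, PRED = Epop, CWRES = w, singular = sing)
  })
  do.call(rbind, out)
}

#' Export goodness-of-fit tables
#'
#' Writes the DV/IPRED/PRED/CWRES/time table of [cwres()] as a delimited
#' text file so any plotting layer can render the usual diagnostic panels.
#'
#' @param data,fit as in [cwres()].
#' @param path output file.
#' @return The table, invisibly.
#' @export
write_gof_table <- function(data, fit, path) {
  tab <- cwres(data, fit)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
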