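#' Model specification for estimation
#'
#' Declares what [fit_foce()] estimates: which structural parameters are
#' free (on the log scale), which random-effect and residual terms are
#' estimated, and the covariate map. `F`, `ka`, `Km`, `Imax` and `IC50` are
#' always fixed (trough-only designs cannot identify them); the estimable
#' structural set is `V1`, `CL1`, `V2`, `Vmax`, `CL2`. The base model
#' (no covariates) therefore carries 5 + 4 + 2 = 11 estimated parameters
#' and the CYP2C19 final model 13.
#'
#' @param covariates list of covariate entries, each a list with `param`
#'   (one of `"V1"`, `"CL1"`, `"CL2"`, `"Vmax"`), `cov` (covariate column
#'   name), and `form` (`"exponential"` for categorical covariates --
#'   reference level first, one theta per non-reference level -- or
#'   `"power"` for continuous covariates, centred at the data median).
#'   For categorical covariates an optional `ref` names the reference
#'   level (default `"NM"` for `PHEN`, otherwise the first sorted level);
#'   unknown phenotype codes (`"UNK"`) fall in the reference category.
#' @param estimate structural parameters to estimate.
#' @param estimate_omega random-effect standard deviations to estimate
#'   (`NULL`: all whose initial value is positive).
#' @param estimate_sigma estimate residual error magnitudes?
#' @return An object of class `pk_model_spec`.
#' @export
model_spec <- function(covariates = list(),
                       estimate = c("V1", "CL1", "V2", "Vmax", "CL2"),
                       estimate_omega = NULL,
                       estimate_sigma = TRUE) {
  estimate <- match.arg(estimate, c("V1", "CL1", "V2", "Vmax", "CL2"),
                        several.ok = TRUE)
  for (cv in covariates) {
    if (!all(c("param", "cov", "form") %in% names(cv)))
      stop("each covariate entry needs 'param', 'cov' and 'form'",
           call. = FALSE)
    if (!cv$param %in% c("V1", "CL1", "CL2", "Vmax"))
      stop("covariates are supported on V1, CL1, CL2, Vmax", call. = FALSE)
  }
  structure(list(covariates = covariates, estimate = estimate,
                 estimate_omega = estimate_omega,
                 estimate_sigma = estimate_sigma),
            class = "pk_model_spec")
}

#' Final-model specification with the CYP2C19 effect on Vmax
#'
#' Convenience wrapper: the base [model_spec()] plus the categorical
#' CYP2C19 phenotype effect on the saturable clearance capacity.
#' @return A `pk_model_spec`.
#' @export
final_model_spec <- function() {
  model_spec(covariates = list(
    list(param = "Vmax", cov = "PHEN", form = "exponential", ref = "NM")
  ))
}

# ---- data packing -----------------------------------------------------------

# Split a pk_dataset into per-subject dose/observation arrays; BLQ
# observations are excluded from the likelihood with a logged count.
pack_subjects <- function(data, require_obs = TRUE) {
  stopifnot(inherits(data, "pk_dataset"))
  df <- as.data.frame(data)
  blq <- if ("BLQ" %in% names(df)) !is.na(df$BLQ) & df$BLQ == 1
         else df$EVID == 0 & !is.na(df$DV) & df$DV < VCZ_LLOQ
  n_blq <- sum(blq & df$EVID == 0)
  ids <- unique(df$ID)
  covcols <- setdiff(names(df), c("ID", "TIME", "EVID", "AMT", "DV", "DVID",
                                  "BLQ"))
  subj <- lapply(ids, function(id) {
    d <- df[df$ID == id, , drop = FALSE]
    dose <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & !(blq[df$ID == id]), , drop = FALSE]
    list(id = id,
         dose_t = dose$TIME, dose_a = dose$AMT,
         obs_t = obs$TIME, y = obs$DV, analyte = as.integer(obs$DVID),
         cov = d[1, covcols, drop = FALSE])
  })
  if (require_obs) {
    empty <- vapply(subj, function(s) length(s$y) == 0, TRUE)
    if (any(empty))
      stop("subject(s) without quantifiable observations: ",
           paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  structure(subj, n_blq = n_blq, ids = ids)
}

# Resolve covariate entries against the data: levels, reference, medians,
# and the theta parameter names they introduce.
resolve_covariates <- function(spec, subj) {
  covtab <- do.call(rbind, lapply(subj, `[[`, "cov"))
  if (is.null(covtab) || nrow(covtab) != length(subj))
    covtab <- data.frame(.id = seq_along(subj))
  out <- list()
  for (cv in spec$covariates) {
    if (!cv$cov %in% names(covtab))
      stop("covariate column '", cv$cov, "' not in dataset", call. = FALSE)
    vals <- covtab[[cv$cov]]
    if (cv$form == "exponential") {
      lev <- unique(as.character(vals))
      lev <- setdiff(lev, "UNK")
      ref <- if (!is.null(cv$ref)) cv$ref
             else if (cv$cov == "PHEN") "NM" else sort(lev)[1]
      nonref <- setdiff(lev, ref)
      if (cv$cov == "PHEN") nonref <- intersect(c("IM", "PM"), nonref)
      cv$ref <- ref
      cv$levels <- nonref
      cv$theta_names <- paste0("theta_", cv$cov, "_", nonref)
    } else {
      if (any(vals <= 0))
        stop("power-form covariate '", cv$cov, "' must be positive",
             call. = FALSE)
      cv$median <- median(vals)
      cv$theta_names <- paste0("theta_", cv$cov)
    }
    out[[length(out) + 1L]] <- cv
  }
  list(covariates = out, covtab = covtab)
}

# n x 4 matrix of covariate-adjusted typical values (V1, CL1, CL2, Vmax)
build_typicals <- function(theta, covinfo, resolved) {
  n <- nrow(resolved$covtab)
  typ <- matrix(rep(c(theta[["V1"]], theta[["CL1"]], theta[["CL2"]],
                      theta[["Vmax"]]), each = n), nrow = n)
  colnames(typ) <- c("V1", "CL1", "CL2", "Vmax")
  for (cv in resolved$covariates) {
    j <- match(cv$param, colnames(typ))
    vals <- resolved$covtab[[cv$cov]]
    if (cv$form == "exponential") {
      mult <- rep(1, n)
      for (k in seq_along(cv$levels)) {
        th <- covinfo[[cv$theta_names[k]]]
        mult[as.character(vals) == cv$levels[k]] <-
          exp(if (is.null(th)) 0 else th)
      }
      typ[, j] <- typ[, j] * mult
    } else {
      th <- covinfo[[cv$theta_names]]
      typ[, j] <- typ[, j] * (vals / cv$median)^(if (is.null(th)) 0 else th)
    }
  }
  typ
}

sigma_matrix <- function(sigma) {
  rbind(c(sigma$vcz$add, sigma$vcz$prop),
        c(sigma$vno$add, sigma$vno$prop))
}

errmodel_codes <- function(sigma) {
  code <- c(additive = 1L, proportional = 2L, combined = 3L)
  c(code[[sigma$vcz$model]], code[[sigma$vno$model]])
}

# ---- parameter vector <-> estimate list ------------------------------------

build_parmap <- function(spec, init, resolved, analytes_present) {
  est_om <- spec$estimate_omega
  if (is.null(est_om)) est_om <- names(init$omega$sd)[init$omega$sd > 0]
  sig_par <- character(0)
  if (isTRUE(spec$estimate_sigma)) {
    for (a in c("vcz", "vno")) {
      if (!(match(a, c("vcz", "vno")) %in% analytes_present)) next
      m <- init$sigma[[a]]$model
      if (m %in% c("additive", "combined"))
        sig_par <- c(sig_par, paste0("sigma_", a, "_add"))
      if (m %in% c("proportional", "combined"))
        sig_par <- c(sig_par, paste0("sigma_", a, "_prop"))
    }
  }
  thetas <- unlist(lapply(resolved$covariates, `[[`, "theta_names"))
  list(structural = spec$estimate, thetas = thetas,
       omega = est_om, sigma = sig_par)
}

pars_to_vector <- function(pm, init) {
  v <- c(log(unlist(init$fixed[pm$structural])),
         setNames(rep(0, length(pm$thetas)), pm$thetas))
  # covariate theta inits: reuse values in init$fixed when they exist
  # (theta_PHEN_IM <-> theta_IM naming bridge for the CYP2C19 effect)
  for (tn in pm$thetas) {
    short <- sub("^theta_PHEN_", "theta_", tn)
    if (!is.null(init$fixed[[short]])) v[tn] <- init$fixed[[short]]
  }
  if (length(pm$omega))
    v <- c(v, setNames(log(init$omega$sd[pm$omega]),
                       paste0("omega_", pm$omega)))
  for (sn in pm$sigma) {
    a <- sub("^sigma_(vcz|vno)_(add|prop)$", "\\1", sn)
    w <- sub("^sigma_(vcz|vno)_(add|prop)$", "\\2", sn)
    v <- c(v, setNames(log(init$sigma[[a]][[w]]), sn))
  }
  v
}

vector_to_pars <- function(par, pm, init) {
  fixed <- init$fixed
  for (nm in pm$structural) fixed[[nm]] <- exp(par[[nm]])
  covinfo <- as.list(par[pm$thetas])
  omega_sd <- init$omega$sd
  for (nm in pm$omega) omega_sd[[nm]] <- exp(par[[paste0("omega_", nm)]])
  sigma <- init$sigma
  for (sn in pm$sigma) {
    a <- sub("^sigma_(vcz|vno)_(add|prop)$", "\\1", sn)
    w <- sub("^sigma_(vcz|vno)_(add|prop)$", "\\2", sn)
    sigma[[a]][[w]] <- exp(par[[sn]])
  }
  list(fixed = fixed, covinfo = covinfo, omega_sd = omega_sd, sigma = sigma)
}

# ---- the fitter -------------------------------------------------------------

#' FOCE-style estimation of the joint population model
#'
#' Maximizes the FOCE-I (Laplace with Gauss-Newton conditional Hessian and
#' eta-interaction residual variances) approximate marginal likelihood. The
#' inner problem -- the conditional mode of each subject's random effects --
#' is solved by damped Gauss-Newton in compiled code and warm-started across
#' outer iterations; the outer problem runs quasi-Newton (PORT) over
#' unconstrained transforms (log for positive parameters). The objective
#' function value (OFV) is -2 times the approximate log marginal likelihood
#' including all normalizing constants, so `AIC = OFV + 2p` and
#' `BIC = OFV + p log(n)` hold as identities.
#'
#' @param data a [pk_dataset()]; every subject needs at least one
#'   quantifiable observation. Below-LLOQ rows are excluded with a count
#'   recorded on the result.
#' @param spec a [model_spec()].
#' @param init initial values: list with `fixed`, `omega`, `sigma` (see
#'   [vcz_final_estimates()] for the shape).
#' @param control list: `rtol`/`atol` (integration tolerances during
#'   fitting, default 1e-6/1e-8), `inner_maxit` (30), `tol_eta` (1e-6),
#'   `outer_iter` (150), `se` (compute standard errors, default TRUE),
#'   `trace` (0).
#' @param eval_only if TRUE, skip the outer optimization and return the OFV
#'   and conditional modes at `init`.
#' @return An object of class `pk_fit`: estimates with SE (percent),
#'   `ofv`/`aic`/`bic`, per-subject eta modes, convergence information,
#'   the parameter map and packed data (reused by [cwres()],
#'   [empirical_bayes()] and [pk_bootstrap()]).
#' @export
fit_foce <- function(data, spec, init, control = list(), eval_only = FALSE) {
  ctl <- modifyList(list(rtol = 1e-6, atol = 1e-8, inner_maxit = 30,
                         tol_eta = 1e-6, outer_iter = 150, rel_tol = 1e-7,
                         hfix = NULL, grad_step = 1e-3, restarts = 2,
                         se = TRUE, trace = 0), control)
  # during optimization a fixed-step integration grid (hours) keeps the
  # objective smooth in the parameters so finite-difference gradients are
  # reliable; plain evaluations default to the adaptive integrator
  if (is.null(ctl$hfix)) ctl$hfix <- if (eval_only) 0 else 0.5
  subj <- pack_subjects(data)
  n <- length(subj)
  resolved <- resolve_covariates(spec, subj)
  analytes_present <- sort(unique(unlist(lapply(subj, `[[`, "analyte"))))
  pm <- build_parmap(spec, init, resolved, analytes_present)
  par0 <- pars_to_vector(pm, init)
  if (any(!is.finite(par0)))
    stop("initial values for estimated parameters must be positive: ",
         paste(names(par0)[!is.finite(par0)], collapse = ", "),
         call. = FALSE)
  csub <- lapply(subj, function(s)
    s[c("dose_t", "dose_a", "obs_t", "y", "analyte")])
  fixed_order <- function(f) c(f$F, f$ka, f$V2, f$Km, f$Imax, f$IC50, f$kn)

  eta_env <- new.env(parent = emptyenv())
  eta_env$eta <- matrix(0, n, 4)
  n_fail <- 0L
  n_evals <- 0L

  objective <- function(par) {
    n_evals <<- n_evals + 1L
    names(par) <- names(par0)
    pr <- vector_to_pars(par, pm, init)
    typ <- build_typicals(pr$fixed, pr$covinfo, resolved)
    res <- tryCatch(
      cpp_foce_ofv(csub, typ, fixed_order(pr$fixed), pr$omega_sd^2,
                   sigma_matrix(pr$sigma), errmodel_codes(pr$sigma),
                   eta_env$eta, ctl$rtol, ctl$atol, ctl$inner_maxit,
                   ctl$tol_eta, FALSE, ctl$hfix),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) {
      n_fail <<- n_fail + 1L
      return(1e10)
    }
    eta_env$eta <- res$eta
    if (ctl$trace > 0) message("OFV ", format(res$ofv, digits = 10))
    res$ofv
  }

  if (eval_only) {
    ofv <- objective(par0)
    par_hat <- par0
    outer <- list(convergence = 0L, message = "evaluation only")
  } else {
    lo <- par0 - 8
    hi <- par0 + 8
    # covariate thetas are signed and start at 0: give them a wide box
    lo[pm$thetas] <- -10
    hi[pm$thetas] <- 10
    # central differences: the objective's curvature on the transformed
    # scale is large enough that one-sided differences carry an O(h f'')
    # bias that stalls the outer optimizer near the optimum
    gradient <- function(par) {
      g <- numeric(length(par))
      for (k in seq_along(par)) {
        up <- par
        dn <- par
        up[k] <- par[k] + ctl$grad_step
        dn[k] <- par[k] - ctl$grad_step
        g[k] <- (objective(up) - objective(dn)) / (2 * ctl$grad_step)
      }
      g
    }
    run_port <- function(start) {
      nlminb(start, objective, gradient = gradient, lower = lo, upper = hi,
             control = list(iter.max = ctl$outer_iter,
                            eval.max = 20 * ctl$outer_iter,
                            rel.tol = ctl$rel_tol))
    }
    outer <- run_port(par0)
    # PORT's trust region can collapse prematurely on this objective
    # (finite-difference gradients over a warm-started inner problem);
    # a restart from the solution is cheap and recovers those stalls
    for (rs in seq_len(ctl$restarts)) {
      again <- run_port(outer$par)
      if (again$objective < outer$objective - 1e-8) outer <- again else break
    }
    par_hat <- setNames(outer$par, names(par0))
    ofv <- outer$objective
  }
  if (!is.finite(ofv) || ofv >= 1e10)
    stop("non-finite objective at the solution; parameter dump: ",
         paste(names(par_hat), signif(par_hat, 4), collapse = ", "),
         call. = FALSE)

  pr <- vector_to_pars(par_hat, pm, init)
  n_obs <- sum(vapply(subj, function(s) length(s$y), 0L))
  p <- length(par_hat)
  ic <- information_criteria(ofv, p, n_obs)

  # natural-scale estimates
  est <- exp(par_hat)
  est[pm$thetas] <- par_hat[pm$thetas]

  se_nat <- setNames(rep(NA_real_, p), names(par_hat))
  cond_warn <- NULL
  if (isTRUE(ctl$se) && !eval_only) {
    H <- tryCatch(optimHess(par_hat, objective), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0 || max(ev) / min(ev) > 1e8)
        cond_warn <- sprintf(
          "ill-conditioned information matrix (condition number %.3g)",
          max(ev) / max(min(ev), .Machine$double.eps))
      vc <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        se_t <- sqrt(pmax(diag(vc), 0))
        se_nat <- se_t * est           # delta method for log-scale entries
        se_nat[pm$thetas] <- se_t[match(pm$thetas, names(par_hat))]
      }
    }
  }
  if (!is.null(cond_warn)) warning(cond_warn, call. = FALSE)

  # PORT's 'false convergence' is routinely triggered by the finite-
  # difference noise floor of the FOCE objective near its optimum; treat any
  # stationary-point message as converged, but not hitting iteration limits
  conv <- eval_only || outer$convergence == 0 ||
    grepl("relative convergence|X-convergence|singular convergence|false convergence",
          outer$message %||% "")

  structure(list(
    estimates = data.frame(parameter = names(par_hat), estimate = est,
                           se = se_nat,
                           se_pct = 100 * abs(se_nat / est),
                           row.names = NULL),
    fixed = pr$fixed, omega_sd = pr$omega_sd, sigma = pr$sigma,
    covinfo = pr$covinfo,
    ofv = ofv, aic = ic[["AIC"]], bic = ic[["BIC"]], p = p, n_obs = n_obs,
    eta = structure(eta_env$eta,
                    dimnames = list(attr(subj, "ids"),
                                    c("V1", "CL1", "CL2", "Vmax"))),
    par = par_hat, parmap = pm, spec = spec, init = init,
    converged = conv, outer = outer[c("convergence", "message")],
    n_obj_failures = n_fail, n_obj_evals = n_evals, n_blq_excluded = attr(subj, "n_blq"),
    condition_warning = cond_warn,
    subjects = subj, resolved = resolved,
    control = ctl
  ), class = "pk_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pk_fit <- function(x, ...) {
  cat("Joint VCZ/VNO population fit (FOCE-I)\n")
  cat(sprintf("  subjects: %d   observations: %d   parameters: %d\n",
              nrow(x$eta), x$n_obs, x$p))
  cat(sprintf("  OFV %.2f   AIC %.2f   BIC %.2f   converged: %s\n",
              x$ofv, x$aic, x$bic, x$converged))
  print(transform(x$estimates, estimate = signif(estimate, 5),
                  se = signif(se, 3), se_pct = signif(se_pct, 4)),
        row.names = FALSE)
  if (x$n_blq_excluded > 0)
    cat(sprintf("  (%d below-LLOQ observation(s) excluded)\n",
                x$n_blq_excluded))
  invisible(x)
}

#' Information criteria from an objective function value
#'
#' `AIC = OFV + 2p`, `BIC = OFV + p log(n)`, where OFV is -2 log-likelihood,
#' `p` the number of estimated parameters and `n` the number of
#' observations.
#'
#' @param ofv objective function value.
#' @param p number of estimated parameters (>= 0).
#' @param n number of observations (>= 1).
#' @return Named vector `c(AIC =, BIC =)`.
#' @export
information_criteria <- function(ofv, p, n) {
  if (p < 0 || n < 1) stop("need p >= 0 and n >= 1", call. = FALSE)
  c(AIC = ofv + 2 * p, BIC = ofv + p * log(n))
}

#' Empirical Bayes (post hoc) individual estimates
#'
#' Conditional modes of the random effects given the population estimates of
#' a converged fit, and the implied individual parameters. Subjects without
#' quantifiable observations get the prior mode, eta = 0.
#'
#' @param data a [pk_dataset()] (may be the fitted data or new subjects
#'   with the same covariates).
#' @param fit a [fit_foce()] result.
#' @return A data frame: one row per subject with the eta modes and the
#'   realized `V1_i`, `CL1_i`, `CL2_i`, `Vmax_i`.
#' @export
empirical_bayes <- function(data, fit) {
  subj <- pack_subjects(data, require_obs = FALSE)
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
                      ctl$inner_maxit, ctl$tol_eta, FALSE, ctl$hfix)
  eta <- res$eta
  data.frame(ID = attr(subj, "ids"),
             eta_V1 = eta[, 1], eta_CL1 = eta[, 2], eta_CL2 = eta[, 3],
             eta_Vmax = eta[, 4],
             V1_i = typ[, "V1"] * exp(eta[, 1]),
             CL1_i = typ[, "CL1"] * exp(eta[, 2]),
             CL2_i = typ[, "CL2"] * exp(eta[, 3]),
             Vmax_i = typ[, "Vmax"] * exp(eta[, 4]))
}

#' Pairwise covariate collinearity screen
#'
#' Computes the pairwise correlation matrix of candidate covariates
#' (rank-based by default, robust to the skewed laboratory values) and flags
#' pairs whose absolute correlation exceeds the threshold as mutually
#' exclusive for covariate modelling. Constant columns have undefined
#' correlation and are flagged separately.
#'
#' @param covariate_table data frame of subject-level covariates (numeric
#'   columns are used).
#' @param threshold exclusion threshold on |correlation| (default 0.5).
#' @param method correlation type, `"spearman"` (default) or `"pearson"`.
#' @return A list: `correlation` (matrix), `excluded_pairs` (data frame of
#'   flagged pairs with their correlation), `constant` (names of constant
#'   columns).
#' @export
collinearity_screen <- function(covariate_table, threshold = 0.5,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  num <- covariate_table[vapply(covariate_table, is.numeric, TRUE)]
  if (ncol(num) < 2) stop("need at least two numeric covariates",
                          call. = FALSE)
  const <- names(num)[vapply(num, function(x) sd(x) == 0, TRUE)]
  use <- num[setdiff(names(num), const)]
  cm <- cor(use, method = method)
  idx <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  excl <- data.frame(var1 = rownames(cm)[idx[, 1]],
                     var2 = colnames(cm)[idx[, 2]],
                     correlation = cm[idx])
  list(correlation = cm, excluded_pairs = excl, constant = const)
}

#' Stepwise covariate selection by likelihood ratio
#'
#' Forward selection followed by backward elimination on the OFV scale:
#' a candidate enters when it lowers the OFV by more than `forward_dofv`
#' (3.84, chi-squared df = 1, p <= 0.05) -- the best candidate first,
#' repeated until none qualifies -- and a retained covariate survives
#' backward elimination only if removing it raises the OFV by at least
#' `backward_dofv` (6.63, p <= 0.01). Candidates whose fits fail are
#' recorded in the trace and skipped, never silently dropped.
#'
#' @param data a [pk_dataset()].
#' @param base_spec the covariate-free [model_spec()].
#' @param candidates list of covariate entries (see [model_spec()]);
#'   apply [collinearity_screen()] beforehand and pass an admissible set.
#' @param init initial values as in [fit_foce()].
#' @param forward_dofv,backward_dofv OFV thresholds.
#' @param control passed to [fit_foce()].
#' @return A list: `spec` (final [model_spec()]), `fit` (final
#'   [fit_foce()]), `trace` (data frame of every tested step).
#' @export
stepwise_covariates <- function(data, base_spec, candidates, init,
                                forward_dofv = 3.84, backward_dofv = 6.63,
                                control = list()) {
  control <- modifyList(list(se = FALSE), control)
  trace <- data.frame(step = integer(), phase = character(),
                      candidate = character(), ofv = numeric(),
                      delta_ofv = numeric(), decision = character())
  note <- function(step, phase, cand, ofv, dofv, dec)
    trace[nrow(trace) + 1L, ] <<- list(step, phase, cand, ofv, dofv, dec)
  lab <- function(cv) paste0(cv$cov, "->", cv$param, " (", cv$form, ")")
  # identical covariate sets recur (backward elimination of the only
  # covariate re-tests the base model): cache fits by covariate-set key
  memo <- new.env(parent = emptyenv())
  safe_fit <- function(sp) {
    key <- paste0("k:", paste(sort(vapply(sp$covariates, lab, "")),
                              collapse = "|"))
    if (!is.null(memo[[key]])) return(memo[[key]])
    f <- tryCatch(fit_foce(data, sp, init, control), error = function(e) NULL)
    if (!is.null(f)) memo[[key]] <- f
    f
  }

  current <- base_spec$covariates
  fit <- safe_fit(base_spec)
  if (is.null(fit)) stop("base model fit failed", call. = FALSE)
  step <- 0L
  note(step, "base", "(none)", fit$ofv, NA, "start")

  pool <- candidates
  repeat {
    step <- step + 1L
    best <- NULL
    best_dofv <- -Inf
    for (k in seq_along(pool)) {
      sp <- model_spec(c(current, pool[k]), estimate = base_spec$estimate,
                       estimate_omega = base_spec$estimate_omega,
                       estimate_sigma = base_spec$estimate_sigma)
      f <- safe_fit(sp)
      if (is.null(f) || !f$converged) {
        note(step, "forward", lab(pool[[k]]), NA, NA, "fit failed; skipped")
        next
      }
      dofv <- fit$ofv - f$ofv
      note(step, "forward", lab(pool[[k]]), f$ofv, dofv,
           if (dofv > forward_dofv) "eligible" else "rejected")
      if (dofv > forward_dofv && dofv > best_dofv) {
        best <- list(k = k, fit = f)
        best_dofv <- dofv
      }
    }
    if (is.null(best)) break
    current <- c(current, pool[best$k])
    pool <- pool[-best$k]
    fit <- best$fit
    note(step, "forward", lab(current[[length(current)]]), fit$ofv,
         best_dofv, "added")
    if (!length(pool)) break
  }

  repeat {
    if (!length(current)) break
    step <- step + 1L
    worst <- NULL
    worst_rise <- Inf
    for (k in seq_along(current)) {
      sp <- model_spec(current[-k], estimate = base_spec$estimate,
                       estimate_omega = base_spec$estimate_omega,
                       estimate_sigma = base_spec$estimate_sigma)
      f <- safe_fit(sp)
      if (is.null(f) || !f$converged) {
        note(step, "backward", lab(current[[k]]), NA, NA,
             "fit failed; covariate kept")
        next
      }
      rise <- f$ofv - fit$ofv
      note(step, "backward", lab(current[[k]]), f$ofv, rise,
           if (rise < backward_dofv) "removable" else "retained")
      if (rise < backward_dofv && rise < worst_rise) {
        worst <- list(k = k, fit = f)
        worst_rise <- rise
      }
    }
    if (is.null(worst)) break
    note(step, "backward", lab(current[[worst$k]]), worst$fit$ofv,
         worst_rise, "removed")
    current <- current[-worst$k]
    fit <- worst$fit
  }

  final_spec <- model_spec(current, estimate = base_spec$estimate,
                           estimate_omega = base_spec$estimate_omega,
                           estimate_sigma = base_spec$estimate_sigma)
  list(spec = final_spec, fit = fit, trace = trace)
}

#' Reference Laplace/FOCE objective for a single subject
#'
#' A slow, dependency-free R implementation of the per-subject conditional
#' estimation step with a pluggable prediction function: damped Gauss-Newton
#' to the conditional mode of `eta`, then the Laplace correction with the
#' Gauss-Newton (first-order) Hessian. For models whose predictions are
#' linear in `eta` with additive Gaussian error this equals the exact
#' marginal -2 log-likelihood, which makes it the correctness oracle for
#' the compiled estimation engine.
#'
#' @param f_fun function `eta -> predictions` (numeric vector).
#' @param y observations.
#' @param v_fun function `f -> residual variances` (numeric vector).
#' @param omega2 vector of random-effect variances (diagonal), all > 0.
#' @param eta_init starting value (default 0).
#' @param maxit,tol Gauss-Newton iteration cap and step tolerance.
#' @return A list: `ofv` (the -2 log marginal likelihood contribution) and
#'   `eta` (the conditional mode).
#' @export
laplace_ofv_ref <- function(f_fun, y, v_fun, omega2,
                            eta_init = rep(0, length(omega2)),
                            maxit = 50, tol = 1e-10) {
  q <- length(omega2)
  m_obj <- function(eta) {
    f <- f_fun(eta)
    v <- v_fun(f)
    sum(log(2 * pi * v) + (y - f)^2 / v) +
      sum(log(2 * pi * omega2) + eta^2 / omega2)
  }
  num_jac <- function(eta) {
    del <- 1e-6
    vapply(seq_len(q), function(k) {
      e <- numeric(q); e[k] <- del
      (f_fun(eta + e) - f_fun(eta - e)) / (2 * del)
    }, numeric(length(y)))
  }
  # derivative of the residual variance wrt the prediction (elementwise)
  num_dv <- function(f) {
    del <- 1e-6
    (v_fun(f + del) - v_fun(f - del)) / (2 * del)
  }
  eta <- eta_init
  mcur <- m_obj(eta)
  lambda <- 0
  for (it in seq_len(maxit)) {
    f <- f_fun(eta)
    v <- v_fun(f)
    dv <- num_dv(f)
    G <- num_jac(eta)
    A <- crossprod(G / sqrt(v)) + diag(1 / omega2, q)
    # full conditional gradient, including the variance-interaction term
    wr <- (y - f) / v - 0.5 * dv * (1 / v - (y - f)^2 / v^2)
    b <- crossprod(G, wr) - eta / omega2
    ok <- FALSE
    for (tries in 1:10) {
      d <- tryCatch(solve(A + lambda * diag(diag(A), q), b),
                    error = function(e) NULL)
      if (!is.null(d)) {
        etat <- eta + drop(d)
        mt <- m_obj(etat)
        if (mt <= mcur + 1e-12) {
          eta <- etat; mcur <- mt; ok <- TRUE
          lambda <- if (lambda > 1e-8) lambda / 3 else 0
          break
        }
      }
      lambda <- max(1e-4, lambda * 10)
    }
    if (!ok || max(abs(d)) < tol) break
  }
  f <- f_fun(eta)
  v <- v_fun(f)
  G <- num_jac(eta)
  A <- crossprod(G / sqrt(v)) + diag(1 / omega2, q)
  ofv <- m_obj(eta) - q * log(2 * pi) + determinant(A)$modulus[1]
  list(ofv = ofv, eta = eta)
}
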