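#' Study-design description for the synthetic cohort generator
#'
#' Captures the design of the emulated TDM study: adult inpatients on oral
#' voriconazole 200 mg every 12 h without a loading dose, trough-only
#' sampling (at most 8 samples per subject, first sample between 23 and
#' 4223 h after the first dose), a CYP2C19 phenotype mix of 27 NM / 32 IM /
#' 16 PM / 3 ungenotyped, and demographic/laboratory covariate distributions
#' matching the study population summaries.
#'
#' @param n_subjects cohort size.
#' @param phenotype_counts named integer vector over `NM`, `IM`, `PM`,
#'   `UNK`; must sum to `n_subjects`. Ungenotyped (`UNK`) subjects are
#'   simulated with normal-metabolizer kinetics but carry the `UNK` label,
#'   exercising the estimation-side imputation policy.
#' @param dose,interval maintenance regimen (mg, h).
#' @param sampling `"trough_only"` (pre-dose samples, the study design) or
#'   `"rich"` (see [generate_rich_cohort()]).
#' @param max_samples cap on sampling occasions per subject.
#' @param mean_samples target mean number of occasions per subject (the
#'   study's 214 parent observations over 78 subjects give about 2.74).
#' @param first_sample_window first-occasion window in hours; occasion
#'   times are drawn log-uniformly inside it.
#' @param seed integer seed stored with the design.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 78,
                          phenotype_counts = c(NM = 27, IM = 32, PM = 16,
                                               UNK = 3),
                          dose = 200, interval = 12,
                          sampling = c("trough_only", "rich"),
                          max_samples = 8, mean_samples = 214 / 78,
                          first_sample_window = c(23, 4223),
                          seed = 1) {
  sampling <- match.arg(sampling)
  if (sum(phenotype_counts) != n_subjects)
    stop("phenotype counts must sum to n_subjects", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 phenotype_counts = phenotype_counts,
                 dose = dose, interval = interval, sampling = sampling,
                 max_samples = max_samples, mean_samples = mean_samples,
                 first_sample_window = first_sample_window, seed = seed),
            class = "cohort_design")
}

# study-population covariate summaries: mean, sd, range, and a distribution
# family (truncated normal for the roughly symmetric variables, lognormal
# for the right-skewed laboratory values)
covariate_catalog <- function() {
  list(
    AGE  = list(mean = 37.5, sd = 14.7, min = 14, max = 70, dist = "normal"),
    WT   = list(mean = 63.2, sd = 12.3, min = 44, max = 111, dist = "normal"),
    HT   = list(mean = 167.6, sd = 6.0, min = 151, max = 190,
                dist = "normal"),
    BUN  = list(mean = 7.71, sd = 5.90, min = 1.36, max = 35.21,
                dist = "lognormal"),
    UA   = list(mean = 273.2, sd = 128.2, min = 1.7, max = 677.6,
                dist = "normal"),
    SCR  = list(mean = 84.0, sd = 63.7, min = 30.4, max = 667.7,
                dist = "lognormal"),
    TBIL = list(mean = 11.3, sd = 7.8, min = 2.9, max = 60.1,
                dist = "lognormal"),
    DBIL = list(mean = 6.1, sd = 6.2, min = 0.9, max = 50.6,
                dist = "lognormal"),
    IBIL = list(mean = 5.4, sd = 2.9, min = 0.8, max = 25.9,
                dist = "lognormal"),
    TBA  = list(mean = 10.6, sd = 11.6, min = 1.0, max = 86.1,
                dist = "lognormal"),
    ALT  = list(mean = 27.8, sd = 33.5, min = 3, max = 256,
                dist = "lognormal"),
    AST  = list(mean = 25.7, sd = 29.8, min = 3, max = 261,
                dist = "lognormal"),
    ALP  = list(mean = 134.4, sd = 120.3, min = 30, max = 898,
                dist = "lognormal"),
    GGT  = list(mean = 122.4, sd = 182.1, min = 10, max = 1445,
                dist = "lognormal"),
    TP   = list(mean = 60.6, sd = 9.5, min = 30.1, max = 84.7,
                dist = "normal"),
    ALB  = list(mean = 39.1, sd = 6.4, min = 20.0, max = 51.8,
                dist = "normal"),
    GLB  = list(mean = 21.6, sd = 5.1, min = 7.9, max = 39.1,
                dist = "normal")
  )
}

# draw n values from a truncated normal/lognormal matched to mean, sd, range
draw_covariate <- function(spec, n) {
  draw1 <- function(m) {
    if (spec$dist == "normal") {
      rnorm(m, spec$mean, spec$sd)
    } else {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      exp(rnorm(m, log(spec$mean) - s2 / 2, sqrt(s2)))
    }
  }
  out <- numeric(0)
  for (tries in 1:50) {
    x <- draw1(2L * n)
    out <- c(out, x[x >= spec$min & x <= spec$max])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  pmin(pmax(draw1(n), spec$min), spec$max)  # degenerate spec fallback
}

#' Generate a synthetic TDM cohort
#'
#' Forward-simulates the emulated study design at the supplied
#' ground-truth parameters: covariates are drawn from the catalogued
#' distributions (body surface area computed from height and weight by the
#' Mosteller formula, so it is deliberately collinear with both), phenotypes
#' assigned by count, individual parameters sampled via the population
#' model, trough sampling occasions placed in the final half hour before a
#' dose, and both analytes observed with residual error (one metabolite
#' observation is dropped at random, mirroring the study's 214 parent / 213
#' metabolite imbalance). The generating truth is attached as the `truth`
#' attribute for recovery scoring.
#'
#' @param design a [cohort_design()].
#' @param truth list with `fixed`, `omega`, `sigma` (see
#'   [vcz_final_estimates()]).
#' @return A [pk_dataset()] with covariate columns and attributes `truth`,
#'   `design`, `truth_params` (per-subject realized parameters).
#' @export
generate_cohort <- function(design = cohort_design(),
                            truth = vcz_final_estimates()) {
  set.seed(design$seed)
  n <- design$n_subjects
  tau <- design$interval
  if (design$max_samples > floor(design$first_sample_window[2] / tau))
    stop("infeasible design: more samples than dosing intervals",
         call. = FALSE)

  phen <- rep(names(design$phenotype_counts), design$phenotype_counts)
  phen <- sample(phen)
  cat_specs <- covariate_catalog()
  covs <- as.data.frame(lapply(cat_specs, draw_covariate, n = n))
  covs$BSA <- mosteller_bsa(covs$HT, covs$WT)
  covs$SEX <- rbinom(n, 1, 57 / 78)            # 1 = male
  covs$PPI <- rbinom(n, 1, 51 / 78)
  covs$GC <- rbinom(n, 1, 33 / 78)
  covs$PHEN <- phen

  # occasion counts: 1 + Binomial(max-1, p) with mean matched to the study
  p_occ <- (design$mean_samples - 1) / (design$max_samples - 1)
  n_occ <- 1L + rbinom(n, design$max_samples - 1L, p_occ)

  rows <- vector("list", n)
  truth_params <- vector("list", n)
  for (i in seq_len(n)) {
    sim_phen <- if (phen[i] == "UNK") "NM" else phen[i]
    eta <- rnorm(4, 0, truth$omega$sd)
    names(eta) <- names(truth$omega$sd)
    p <- individual_params(truth$fixed, sim_phen, eta)
    truth_params[[i]] <- p

    # trough occasions: dose-interval indices, first log-uniform in window
    w <- design$first_sample_window
    k1 <- max(2L, ceiling(exp(runif(1, log(w[1]), log(w[2]))) / tau))
    ks <- k1
    while (length(ks) < n_occ[i]) {
      nxt <- ks[length(ks)] + sample.int(14L, 1L)   # up to one week later
      if (nxt * tau > w[2]) break
      ks <- c(ks, nxt)
    }
    obs_t <- ks * tau - runif(length(ks), 0, 0.5)
    dose_t <- seq(0, max(ks) * tau, by = tau)
    reg <- regimen(dose_t, design$dose)
    prof <- solve_profile(reg, p, sort(obs_t))
    dv1 <- apply_residual(prof$C1, truth$sigma, "vcz")
    dv2 <- apply_residual(prof$C2, truth$sigma, "vno")

    sub <- rbind(
      data.frame(TIME = dose_t, EVID = 1L, AMT = design$dose, DV = NA_real_,
                 DVID = NA_integer_),
      data.frame(TIME = rep(prof$time, 2), EVID = 0L, AMT = NA_real_,
                 DV = c(dv1, dv2), DVID = rep(c(1L, 2L), each = nrow(prof)))
    )
    sub <- sub[order(sub$TIME, sub$EVID), , drop = FALSE]
    sub <- cbind(ID = i, sub, covs[rep(i, nrow(sub)), , drop = FALSE])
    rows[[i]] <- sub
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL

  # drop one metabolite observation at random (214 vs 213 analyte imbalance)
  vno_rows <- which(df$EVID == 0 & df$DVID == 2)
  if (length(vno_rows) > 1) df <- df[-sample(vno_rows, 1), , drop = FALSE]
  df$BLQ <- ifelse(df$EVID == 0 & df$DV < VCZ_LLOQ, 1L, 0L)

  out <- pk_dataset(df)
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  attr(out, "truth_params") <- truth_params
  out
}

#' Generate a rich-sampling cohort for parameter recovery
#'
#' An identifiability-friendly design: 200 mg every 12 h for five days,
#' with samples on the first dosing day (1, 3, 6, 11.5 h) and densely
#' across a near-steady-state interval starting at 96 h (accumulation is
#' above 95% complete by day 5 at typical parameters), both analytes at
#' every time. Phenotypes cycle through NM/IM/PM so the CYP2C19 effects are
#' estimable. Used by the estimation recovery suite.
#'
#' @param n number of subjects (>= 3 so all phenotypes appear).
#' @param samples_per_interval samples across the steady-state interval.
#' @param truth generating parameters (list with `fixed`, `omega`,
#'   `sigma`).
#' @param seed integer seed.
#' @param null_phenotype if TRUE, generate with no CYP2C19 effect
#'   (`theta_IM = theta_PM = 0`) while keeping the phenotype labels -- the
#'   null case for covariate-selection calibration.
#' @return A [pk_dataset()] with attributes as in [generate_cohort()].
#' @export
generate_rich_cohort <- function(n = 100, samples_per_interval = 8,
                                 truth = vcz_final_estimates(), seed = 1,
                                 null_phenotype = FALSE) {
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  set.seed(seed)
  if (null_phenotype) {
    truth$fixed$theta_IM <- 0
    truth$fixed$theta_PM <- 0
  }
  phen <- rep_len(c("NM", "IM", "PM"), n)
  dose_t <- seq(0, 108, by = 12)
  day1 <- c(1, 3, 6, 11.5)
  ss <- 96 + seq(0.5, 11.5, length.out = samples_per_interval)
  obs_t <- sort(c(day1, ss))
  cat_specs <- covariate_catalog()[c("AGE", "WT", "HT")]
  covs <- as.data.frame(lapply(cat_specs, draw_covariate, n = n))
  covs$BSA <- mosteller_bsa(covs$HT, covs$WT)
  covs$SEX <- rbinom(n, 1, 57 / 78)
  covs$PHEN <- phen

  rows <- vector("list", n)
  truth_params <- vector("list", n)
  for (i in seq_len(n)) {
    eta <- rnorm(4, 0, truth$omega$sd)
    names(eta) <- names(truth$omega$sd)
    p <- individual_params(truth$fixed, phen[i], eta)
    truth_params[[i]] <- p
    prof <- solve_profile(regimen(dose_t, 200), p, obs_t)
    dv1 <- apply_residual(prof$C1, truth$sigma, "vcz")
    dv2 <- apply_residual(prof$C2, truth$sigma, "vno")
    sub <- rbind(
      data.frame(TIME = dose_t, EVID = 1L, AMT = 200, DV = NA_real_,
                 DVID = NA_integer_),
      data.frame(TIME = rep(obs_t, 2), EVID = 0L, AMT = NA_real_,
                 DV = c(dv1, dv2), DVID = rep(c(1L, 2L), each = length(obs_t)))
    )
    sub <- sub[order(sub$TIME, sub$EVID), , drop = FALSE]
    rows[[i]] <- cbind(ID = i, sub, covs[rep(i, nrow(sub)), , drop = FALSE])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$BLQ <- ifelse(df$EVID == 0 & df$DV < VCZ_LLOQ, 1L, 0L)
  out <- pk_dataset(df)
  attr(out, "truth") <- truth
  attr(out, "truth_params") <- truth_params
  out
}
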