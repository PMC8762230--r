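#' Draw one individual's parameters from the population model
#'
#' Samples `eta ~ N(0, omega^2)` for `V1`, `CL1`, `CL2` and `Vmax` and
#' applies them to the phenotype-adjusted typical values,
#' `P_i = theta_typical * exp(eta_i)`. Draws use the current R random
#' number stream; set the seed (or pass one) for reproducibility.
#'
#' @param f a [fixed_effects()] object.
#' @param omega an [omega_spec()].
#' @param phenotype CYP2C19 phenotype (`"NM"`, `"IM"`, `"PM"`).
#' @param rng_seed optional integer; if supplied, the seed is set before
#'   drawing.
#' @return An [individual_params()] object.
#' @export
sample_individual <- function(f, omega, phenotype = "NM", rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  eta <- rnorm(4, 0, omega$sd)
  names(eta) <- names(omega$sd)
  individual_params(f, phenotype, eta)
}

# n x 11 parameter matrix for the compiled batch simulator
sample_pars_matrix <- function(f, omega, phenotype, n) {
  eta <- matrix(rnorm(4L * n, 0, rep(omega$sd, each = n)), nrow = n)
  vmax_t <- typical_vmax(f$Vmax, phenotype, f)
  cbind(f$F, f$ka,
        f$V1 * exp(eta[, 1]), f$CL1 * exp(eta[, 2]), f$V2,
        vmax_t * exp(eta[, 4]), f$Km, f$CL2 * exp(eta[, 3]),
        f$Imax, f$IC50, f$kn)
}

#' Apply residual (unexplained) error to model predictions
#'
#' Additive: `pred + eps`; proportional: `pred * (1 + eps)`; combined:
#' `pred * (1 + eps1) + eps2`. Negative simulated observations are retained
#' (not truncated) and flagged in the `"negative"` attribute.
#'
#' @param pred residual-free predictions (mg/L, nonnegative).
#' @param sigma an [sigma_spec()].
#' @param analyte `"vcz"` or `"vno"`, selecting the error model.
#' @return Simulated observations with attribute `negative` (logical
#'   vector).
#' @export
apply_residual <- function(pred, sigma, analyte = c("vcz", "vno")) {
  analyte <- match.arg(analyte)
  if (any(pred < 0)) stop("predictions must be nonnegative", call. = FALSE)
  s <- sigma[[analyte]]
  n <- length(pred)
  out <- switch(s$model,
    additive = pred + rnorm(n, 0, s$add),
    proportional = pred * (1 + rnorm(n, 0, s$prop)),
    combined = pred * (1 + rnorm(n, 0, s$prop)) + rnorm(n, 0, s$add)
  )
  structure(out, negative = out < 0)
}

#' Steady-state exposure metrics over a time window
#'
#' Extracts trough (`Cmin`), peak (`Cmax`) and the 24-hour AUC for both
#' analytes over a window of the residual-free profile (default 144-168 h,
#' i.e. day 7 of twice-daily dosing). `Cmin`/`Cmax` are window extrema of
#' the model prediction; the AUC is the difference of the integrated AUC
#' state at the window edges, not a trapezoidal sum.
#'
#' @param profile a data frame from [solve_profile()] whose `time` grid
#'   covers `[window_start, window_end]` (the window edges must be on the
#'   grid; use a dense grid for sharp extrema).
#' @param window_start,window_end window edges in hours.
#' @return A list of class `exposure_metrics`: `vcz` and `vno`, each with
#'   `Cmin`, `Cmax` (mg/L) and `AUC24` (mg*h/L), plus `MR`, the metabolic
#'   ratio `AUC_vno / AUC_vcz`.
#' @export
exposure_metrics <- function(profile, window_start = 144, window_end = 168) {
  tt <- profile$time
  if (window_start < min(tt) || window_end > max(tt))
    stop("window outside the solved profile", call. = FALSE)
  i0 <- match(window_start, tt)
  i1 <- match(window_end, tt)
  if (is.na(i0) || is.na(i1))
    stop("window edges must lie on the profile time grid", call. = FALSE)
  win <- tt >= window_start & tt <= window_end
  auc1 <- profile$cumAUC1[i1] - profile$cumAUC1[i0]
  auc2 <- profile$cumAUC2[i1] - profile$cumAUC2[i0]
  out <- list(
    vcz = list(Cmin = min(profile$C1[win]), Cmax = max(profile$C1[win]),
               AUC24 = auc1),
    vno = list(Cmin = min(profile$C2[win]), Cmax = max(profile$C2[win]),
               AUC24 = auc2),
    MR = metabolic_ratio(auc2, auc1)
  )
  structure(out, class = "exposure_metrics")
}

#' Metabolic ratio
#'
#' Ratio of metabolite to parent exposure over the same window,
#' `MR = AUC_VNO / AUC_VCZ` -- a surrogate of CYP2C19 metabolic capacity.
#'
#' @param auc_vno,auc_vcz AUCs over a common window (mg*h/L);
#'   `auc_vcz` must be positive.
#' @return The dimensionless ratio.
#' @export
metabolic_ratio <- function(auc_vno, auc_vcz) {
  if (any(auc_vcz <= 0))
    stop("parent AUC must be positive", call. = FALSE)
  auc_vno / auc_vcz
}
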