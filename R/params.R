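#' Population fixed-effect parameters of the joint VCZ/VNO model
#'
#' Container for the typical-value (fixed-effect) parameters of the joint
#' voriconazole / voriconazole N-oxide structural model. Amounts are tracked
#' in mg, times in hours, volumes in litres, concentrations in mg/L.
#'
#' @param F oral bioavailability (fraction, 0 < F <= 1).
#' @param ka first-order absorption rate constant (1/h).
#' @param V1 central volume of distribution of the parent drug (L).
#' @param CL1 linear clearance of the parent other than the N-oxidation
#'   pathway (L/h).
#' @param V2 volume of distribution of the metabolite (L).
#' @param Vmax maximum rate of the saturable (Michaelis-Menten) parent
#'   elimination, i.e. the N-oxidation pathway (mg/h).
#' @param Km Michaelis constant of the saturable pathway (mg/L).
#' @param CL2 clearance of the metabolite (L/h).
#' @param Imax maximal fractional inhibition of the saturable pathway by the
#'   circulating metabolite (0 to 1).
#' @param IC50 metabolite concentration producing half-maximal inhibition
#'   (mg/L).
#' @param theta_NM,theta_IM,theta_PM log-scale CYP2C19 phenotype effects on
#'   `Vmax`; the normal-metabolizer effect is the reference and must be 0.
#' @param kn amount-conversion factor from parent to metabolite for the
#'   saturable pathway (dimensionless). The default 1 tracks the metabolite
#'   in mg of parent-drug equivalents; set to the VNO/VCZ molar-mass ratio
#'   (about 1.046) to track true metabolite mass.
#' @param fixed_mask character vector naming the entries treated as fixed
#'   (not estimated) by [fit_foce()].
#'
#' @return An object of class `fixed_effects` (a named list).
#' @seealso [vcz_final_estimates()] for the published adult estimates.
#' @export
fixed_effects <- function(F, ka, V1, CL1, V2, Vmax, Km, CL2, Imax, IC50,
                          theta_NM = 0, theta_IM = 0, theta_PM = 0, kn = 1,
                          fixed_mask = c("F", "ka", "Km", "Imax", "IC50",
                                         "theta_NM")) {
  x <- list(F = F, ka = ka, V1 = V1, CL1 = CL1, V2 = V2, Vmax = Vmax,
            Km = Km, CL2 = CL2, Imax = Imax, IC50 = IC50,
            theta_NM = theta_NM, theta_IM = theta_IM, theta_PM = theta_PM,
            kn = kn, fixed_mask = fixed_mask)
  pos <- c("ka", "V1", "CL1", "V2", "Vmax", "Km", "CL2", "IC50", "kn")
  for (nm in pos) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || x[[nm]] <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  if (F <= 0 || F > 1) stop("'F' must be in (0, 1]", call. = FALSE)
  if (Imax < 0 || Imax > 1) stop("'Imax' must be in [0, 1]", call. = FALSE)
  if (theta_NM != 0) stop("'theta_NM' is the reference and must be 0",
                          call. = FALSE)
  structure(x, class = "fixed_effects")
}

#' Reference adult population estimates for the joint VCZ/VNO model
#'
#' Final-model population estimates from the adult oral-voriconazole TDM
#' analysis the package implements (200 mg twice daily, trough sampling,
#' CYP2C19-genotyped cohort): fixed effects, inter-individual variability
#' and proportional residual error for both analytes. `Km`, `Imax`, `IC50`,
#' `F` and `ka` are literature-fixed values; the CYP2C19 intermediate and
#' poor metabolizer effects act multiplicatively on `Vmax` as
#' `exp(theta)`.
#'
#' @param omega_convention how the tabulated inter-individual variability
#'   percentages are converted to log-scale standard deviations; see
#'   [omega_spec()].
#' @return A list with elements `fixed` ([fixed_effects()]), `omega`
#'   ([omega_spec()]) and `sigma` ([sigma_spec()]).
#' @export
vcz_final_estimates <- function(omega_convention = "var_times_100") {
  list(
    fixed = fixed_effects(F = 0.895, ka = 1.1, V1 = 207.29, CL1 = 1.91,
                          V2 = 10.01, Vmax = 18.80, Km = 1.15, CL2 = 4.65,
                          Imax = 0.75, IC50 = 14.6,
                          theta_NM = 0, theta_IM = -0.31, theta_PM = -0.61),
    omega = omega_spec(V1 = 240.77, CL1 = 6.02, CL2 = 25.57, Vmax = 21.13,
                       convention = omega_convention),
    sigma = sigma_spec(vcz = list(model = "proportional", prop = 0.4697),
                       vno = list(model = "proportional", prop = 0.2793))
  )
}

#' Inter-individual variability specification
#'
#' Inter-individual variability (IIV) enters the model exponentially,
#' `P_i = theta * exp(eta_i)` with `eta_i ~ N(0, omega^2)`. Published PopPK
#' tables report omega terms as percentages without always defining the
#' transform, so the convention is explicit here:
#'
#' * `"var_times_100"` (default): the tabulated value is `100 * omega^2`,
#'   so `omega = sqrt(value / 100)`. This is the convention under which the
#'   reference estimates reproduce the published dose-simulation table, and
#'   matches estimation software that reports omega-squared (variance)
#'   output.
#' * `"sd_times_100"`: the tabulated value is `100 * omega`.
#' * `"cv_percent"`: the tabulated value is a lognormal coefficient of
#'   variation in percent, `omega = sqrt(log(1 + (value/100)^2))`.
#'
#' @param V1,CL1,CL2,Vmax tabulated IIV values (percent scale) for the four
#'   parameters carrying random effects; 0 switches the random effect off.
#' @param convention one of `"var_times_100"`, `"sd_times_100"`,
#'   `"cv_percent"`.
#' @return An object of class `omega_spec` with the raw values, the
#'   convention, and `$sd`, the log-scale standard deviations
#'   (named `V1`, `CL1`, `CL2`, `Vmax`).
#' @export
omega_spec <- function(V1 = 0, CL1 = 0, CL2 = 0, Vmax = 0,
                       convention = c("var_times_100", "sd_times_100",
                                      "cv_percent")) {
  convention <- match.arg(convention)
  raw <- c(V1 = V1, CL1 = CL1, CL2 = CL2, Vmax = Vmax)
  if (any(raw < 0)) stop("omega values must be nonnegative", call. = FALSE)
  sd <- switch(convention,
    var_times_100 = sqrt(raw / 100),
    sd_times_100  = raw / 100,
    cv_percent    = sqrt(log(1 + (raw / 100)^2))
  )
  structure(list(raw = raw, convention = convention, sd = sd),
            class = "omega_spec")
}

#' Residual (unexplained) variability specification
#'
#' Residual error models per analyte: additive `C = Cpred + eps`,
#' proportional `C = Cpred * (1 + eps)`, or combined
#' `C = Cpred * (1 + eps1) + eps2`, with each `eps ~ N(0, sigma^2)`.
#'
#' @param vcz,vno per-analyte lists with elements `model` (one of
#'   `"additive"`, `"proportional"`, `"combined"`), `prop` (proportional SD,
#'   fraction) and `add` (additive SD, mg/L); unused components default to 0.
#' @return An object of class `sigma_spec`.
#' @export
sigma_spec <- function(vcz = list(model = "proportional", prop = 0),
                       vno = list(model = "proportional", prop = 0)) {
  norm1 <- function(x, label) {
    model <- match.arg(x$model, c("additive", "proportional", "combined"))
    prop <- if (is.null(x$prop)) 0 else x$prop
    add <- if (is.null(x$add)) 0 else x$add
    if (prop < 0 || add < 0)
      stop("sigma values for ", label, " must be nonnegative", call. = FALSE)
    list(model = model, prop = prop, add = add)
  }
  structure(list(vcz = norm1(vcz, "vcz"), vno = norm1(vno, "vno")),
            class = "sigma_spec")
}

#' Typical Vmax for a CYP2C19 phenotype
#'
#' Applies the categorical CYP2C19 covariate effect to the population
#' maximum elimination rate: `Vmax * exp(theta_phenotype)`, with the normal
#' metabolizer (NM) as reference (`theta_NM = 0`).
#'
#' @param base_vmax population `Vmax` (mg/h).
#' @param phenotype one of `"NM"`, `"IM"`, `"PM"`.
#' @param f a [fixed_effects()] object carrying the theta terms.
#' @return Typical `Vmax` (mg/h) for the phenotype.
#' @export
typical_vmax <- function(base_vmax, phenotype, f) {
  theta <- switch(as.character(phenotype),
                  NM = f$theta_NM, IM = f$theta_IM, PM = f$theta_PM,
                  stop("unknown CYP2C19 phenotype: '", phenotype,
                       "' (expected NM, IM or PM)", call. = FALSE))
  base_vmax * exp(theta)
}

#' Covariate-parameter transforms
#'
#' The two covariate forms used in screening: a power model for continuous
#' covariates, `theta * (cov / cov_median)^theta_cov`, and an exponential
#' model for categorical covariates, `theta * exp(theta_cov)` (reference
#' category `theta_cov = 0`).
#'
#' @param theta population typical value.
#' @param cov_value covariate value (continuous form only).
#' @param cov_median covariate median used for centring (continuous form
#'   only).
#' @param form `"power"` or `"exponential"`.
#' @param theta_cov covariate effect coefficient.
#' @return The covariate-adjusted parameter.
#' @export
covariate_transform <- function(theta, cov_value = NULL, cov_median = NULL,
                                form = c("power", "exponential"),
                                theta_cov = 0) {
  form <- match.arg(form)
  if (form == "power") {
    if (is.null(cov_value) || is.null(cov_median))
      stop("power form needs 'cov_value' and 'cov_median'", call. = FALSE)
    if (any(cov_value <= 0) || cov_median <= 0)
      stop("power form needs positive covariate values", call. = FALSE)
    theta * (cov_value / cov_median)^theta_cov
  } else {
    theta * exp(theta_cov)
  }
}

#' Realized per-subject parameters
#'
#' Combines typical values, the CYP2C19 covariate effect on `Vmax` and
#' subject-level random effects into the individual parameter set used by
#' the solver: `P_i = theta_typical * exp(eta_i)` for `V1`, `CL1`, `CL2`
#' and `Vmax`; `F`, `ka`, `V2`, `Km`, `Imax`, `IC50` and `kn` pass through.
#'
#' @param f a [fixed_effects()] object.
#' @param phenotype CYP2C19 phenotype (`"NM"`, `"IM"`, `"PM"`).
#' @param eta named numeric vector of log-scale random effects with entries
#'   `V1`, `CL1`, `CL2`, `Vmax` (missing entries default to 0).
#' @return An object of class `individual_params`: named list with `V1_i`,
#'   `CL1_i`, `CL2_i`, `Vmax_i` and the pass-through entries, plus the
#'   decomposition attributes `phenotype` and `eta`.
#' @export
individual_params <- function(f, phenotype = "NM",
                              eta = c(V1 = 0, CL1 = 0, CL2 = 0, Vmax = 0)) {
  e <- c(V1 = 0, CL1 = 0, CL2 = 0, Vmax = 0)
  e[names(eta)] <- eta
  p <- list(
    V1_i = f$V1 * exp(e[["V1"]]),
    CL1_i = f$CL1 * exp(e[["CL1"]]),
    CL2_i = f$CL2 * exp(e[["CL2"]]),
    Vmax_i = typical_vmax(f$Vmax, phenotype, f) * exp(e[["Vmax"]]),
    F = f$F, ka = f$ka, V2 = f$V2, Km = f$Km, Imax = f$Imax,
    IC50 = f$IC50, kn = f$kn
  )
  structure(p, class = "individual_params", phenotype = phenotype, eta = e)
}

#' Body surface area by the Mosteller formula
#'
#' `BSA = sqrt(height * weight / 3600)`.
#'
#' @param height height in cm (positive).
#' @param weight body weight in kg (positive).
#' @return Body surface area in m^2.
#' @examples
#' mosteller_bsa(170, 64) # 1.738
#' @export
mosteller_bsa <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive", call. = FALSE)
  sqrt(height * weight / 3600)
}

# 11-element parameter vector in the order the compiled solver expects
pars_vector <- function(p) {
  c(p$F, p$ka, p$V1_i, p$CL1_i, p$V2, p$Vmax_i, p$Km, p$CL2_i, p$Imax,
    p$IC50, p$kn)
}
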