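#' Concentration-dependent nonlinear clearance of the parent drug
#'
#' The saturable (Michaelis-Menten) clearance of voriconazole to its N-oxide,
#' inhibited by the circulating metabolite:
#' `CL_nonlin = Vmax_i / (C1 + Km) * (1 - Imax * C2 / (IC50 + C2))`.
#' It is strictly decreasing in both concentrations.
#'
#' @param C1 parent (VCZ) plasma concentration, mg/L (>= 0).
#' @param C2 metabolite (VNO) plasma concentration, mg/L (>= 0).
#' @param p an [individual_params()] object (or any list with `Vmax_i`,
#'   `Km`, `Imax`, `IC50`).
#' @return Nonlinear clearance in L/h.
#' @export
nonlinear_clearance <- function(C1, C2, p) {
  if (any(C1 < 0) || any(C2 < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  p$Vmax_i / (C1 + p$Km) * (1 - p$Imax * C2 / (p$IC50 + C2))
}

#' Right-hand side of the structural ODE system
#'
#' Pure-R derivative of the five-state system: gut depot, parent central
#' amount, metabolite amount, and running time-integrals of both
#' concentrations. Used for cross-checking the compiled integrator (e.g.
#' through [deSolve::lsoda()]); the solver itself uses the compiled
#' equivalent.
#'
#' @param state numeric vector `(A_gut, A1, A2, cumAUC1, cumAUC2)`: amounts
#'   in mg, integrals in mg*h/L.
#' @param p an [individual_params()] object.
#' @return Numeric vector of derivatives in the same order.
#' @export
ode_rhs <- function(state, p) {
  A_gut <- state[[1]]; A1 <- state[[2]]; A2 <- state[[3]]
  C1 <- A1 / p$V1_i
  C2 <- A2 / p$V2
  clnl <- p$Vmax_i / (C1 + p$Km) * (1 - p$Imax * C2 / (p$IC50 + C2))
  c(-p$ka * A_gut,
    p$F * A_gut * p$ka - (p$CL1_i + clnl) / p$V1_i * A1,
    clnl / p$V1_i * A1 * p$kn - p$CL2_i / p$V2 * A2,
    C1,
    C2)
}

#' Dosing regimens
#'
#' A regimen is an ordered table of instantaneous oral dose events. `regimen`
#' builds one from explicit times and amounts; `regimen_bid` and
#' `regimen_tid` build every-12-hour and every-8-hour maintenance schedules,
#' optionally preceded by loading doses. `standard_regimen` is the labelled
#' adult schedule: 400 mg every 12 h for two doses, then 200 mg every 12 h.
#'
#' @param times dose times in hours since first dose (nonnegative, strictly
#'   increasing).
#' @param amounts dose amounts in mg (positive); recycled to `length(times)`.
#' @param dose maintenance dose in mg.
#' @param days duration of the schedule in days.
#' @param loading optional numeric vector of loading-dose amounts given at
#'   the start of the schedule in place of the first maintenance doses.
#' @return An object of class `pk_regimen`: data frame with columns `time`
#'   (h) and `amt` (mg).
#' @export
regimen <- function(times, amounts) {
  amounts <- rep_len(amounts, length(times))
  if (length(times) == 0) stop("regimen needs at least one dose", call. = FALSE)
  if (any(times < 0)) stop("dose times must be nonnegative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("dose times must be strictly increasing", call. = FALSE)
  if (any(amounts <= 0)) stop("dose amounts must be positive", call. = FALSE)
  structure(data.frame(time = as.numeric(times), amt = as.numeric(amounts)),
            class = c("pk_regimen", "data.frame"))
}

#' @rdname regimen
#' @export
regimen_bid <- function(dose, days = 14, loading = NULL) {
  times <- seq(0, days * 24 - 12, by = 12)
  amounts <- rep(dose, length(times))
  if (!is.null(loading)) amounts[seq_along(loading)] <- loading
  regimen(times, amounts)
}

#' @rdname regimen
#' @export
regimen_tid <- function(dose, days = 14, loading = NULL) {
  times <- seq(0, days * 24 - 8, by = 8)
  amounts <- rep(dose, length(times))
  if (!is.null(loading)) amounts[seq_along(loading)] <- loading
  regimen(times, amounts)
}

#' @rdname regimen
#' @export
standard_regimen <- function(days = 20) {
  regimen_bid(200, days = days, loading = c(400, 400))
}

#' Solve the joint concentration-time profile for one subject
#'
#' Integrates the structural ODE system across all dose events of a regimen
#' and evaluates the states at the requested observation times. Doses are
#' instantaneous additions to the gut depot; an observation falling exactly
#' on a dose time is evaluated pre-dose (trough convention). The running
#' concentration integrals `cumAUC1`/`cumAUC2` are carried as ODE states, so
#' window AUCs are solver-accurate rather than trapezoidal.
#'
#' @param reg a [regimen()].
#' @param p an [individual_params()] object.
#' @param obs_times observation times in hours (nonnegative, nondecreasing).
#' @param rtol,atol relative and absolute integration tolerances.
#' @param engine `"dopri"` for the compiled Dormand-Prince 5(4) stepper
#'   (default), or `"lsoda"` for [deSolve::lsoda()] on the R right-hand
#'   side (slow; retained as an independent numerical cross-check).
#' @return A data frame with columns `time`, `C1`, `C2` (mg/L), `cumAUC1`,
#'   `cumAUC2` (mg*h/L), `A_gut`, `A1`, `A2` (mg).
#' @export
solve_profile <- function(reg, p, obs_times, rtol = 1e-8, atol = 1e-10,
                          engine = c("dopri", "lsoda")) {
  engine <- match.arg(engine)
  stopifnot(inherits(reg, "pk_regimen"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  obs_times <- as.numeric(obs_times)
  if (any(obs_times < 0)) stop("obs_times must be nonnegative", call. = FALSE)
  if (is.unsorted(obs_times))
    stop("obs_times must be nondecreasing", call. = FALSE)
  if (engine == "dopri") {
    st <- cpp_solve_profile(reg$time, reg$amt, obs_times, pars_vector(p),
                            rtol, atol)
  } else {
    st <- lsoda_profile(reg, p, obs_times, rtol, atol)
  }
  if (any(!is.finite(st)))
    stop("solver returned non-finite states", call. = FALSE)
  data.frame(time = obs_times,
             C1 = st[, "A1"] / p$V1_i,
             C2 = st[, "A2"] / p$V2,
             cumAUC1 = st[, "cumAUC1"],
             cumAUC2 = st[, "cumAUC2"],
             A_gut = st[, "A_gut"],
             A1 = st[, "A1"],
             A2 = st[, "A2"])
}

# deSolve-based reference integration (event handling via lsoda events)
lsoda_profile <- function(reg, p, obs_times, rtol, atol) {
  deriv <- function(t, y, parms) list(ode_rhs(y, p))
  times <- sort(unique(c(0, obs_times, reg$time)))
  ev <- data.frame(var = "A_gut", time = reg$time, value = reg$amt,
                   method = "add")
  y0 <- c(A_gut = 0, A1 = 0, A2 = 0, cumAUC1 = 0, cumAUC2 = 0)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL, rtol = rtol,
                        atol = atol, events = list(data = ev), maxsteps = 1e5)
  out <- out[match(obs_times, out[, "time"]), , drop = FALSE]
  # lsoda applies events before reporting; shift dose-coincident rows back to
  # the pre-dose gut amount so both engines share the trough convention
  hit <- obs_times %in% reg$time
  if (any(hit)) {
    amt <- reg$amt[match(obs_times[hit], reg$time)]
    out[hit, "A_gut"] <- out[hit, "A_gut"] - amt
  }
  out[, c("A_gut", "A1", "A2", "cumAUC1", "cumAUC2"), drop = FALSE]
}

#' Closed-form one-compartment oral concentration (Bateman function)
#'
#' Concentration after a single oral dose under first-order absorption and
#' first-order elimination:
#' `C(t) = F D ka / (V (ka - k)) (exp(-k t) - exp(-ka t))`, `k = CL/V`.
#' At `ka == k` the analytic limit `F D k t exp(-k t) / V` is used. This is
#' the linear-limit oracle for the ODE solver (`Vmax = 0`).
#'
#' @param dose dose amount (mg).
#' @param t_since_dose time since the dose (h); vectorized.
#' @param F bioavailability, `ka` absorption rate (1/h), `CL` clearance
#'   (L/h), `V` volume (L).
#' @param ka,CL,V see above.
#' @return Concentration in mg/L (0 for negative times).
#' @export
bateman_oracle <- function(dose, t_since_dose, F, ka, CL, V) {
  k <- CL / V
  t <- t_since_dose
  dose <- rep_len(dose, length(t))
  out <- numeric(length(t))
  pos <- t >= 0
  if (isTRUE(all.equal(ka, k))) {
    out[pos] <- F * dose[pos] * k * t[pos] * exp(-k * t[pos]) / V
  } else {
    out[pos] <- F * dose[pos] * ka / (V * (ka - k)) *
      (exp(-k * t[pos]) - exp(-ka * t[pos]))
  }
  out
}

#' Superposed Bateman concentrations for a multi-dose regimen
#'
#' Sums the single-dose closed form over all doses given at or before each
#' observation time (linear pharmacokinetics superposition).
#'
#' @inheritParams bateman_oracle
#' @param reg a [regimen()].
#' @param times observation times in hours.
#' @return Concentration in mg/L at `times`.
#' @export
bateman_superpose <- function(reg, times, F, ka, CL, V) {
  vapply(times, function(t) {
    sum(bateman_oracle(reg$amt, t - reg$time, F, ka, CL, V))
  }, numeric(1))
}
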