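# Analytical bleb-initiation model: Laplace pressure balance, Bell-kinetics
# bond-density dynamics of membrane-actin linkers, the critical detachment
# pressure/tension from a saddle-node analysis, a parametric rupture-tension
# model, and mechanism phase diagrams.

#' Parameters of the analytical bleb-initiation model
#'
#' Surface densities are per um^2 of membrane: `rho_H` membrane-bindable
#' linkers, `rho_Hb` of them bound to F-actin, `rho_Nb` bound plain linkers,
#' `rho_A` available F-actin binding sites beneath the membrane. Kinetic
#' constants `k_on` (um^2/s, per pair of free partners) and `k_off0` (1/s)
#' define the 2D dissociation constant `Km2D = k_off0 / k_on` (um^-2).
#' `r0` is the Bell barrier distance (um), `kBT` thermal energy (pN um),
#' `R`/`R0` current and initial vesicle radius (um), and `gamma_m`,
#' `gamma_m0`, `gamma_c` the membrane (current, initial) and cortex tensions
#' (pN/um).
#'
#' @param ... Overrides of the defaults.
#' @return A `theory_params` list with derived `Km2D`.
#' @export
theory_params <- function(...) {
  p <- list(
    rho_H = 80, rho_Hb = NA_real_, rho_Nb = 0, rho_A = 1000,
    k_on = 1, k_off0 = exp(-10),     # Km2D = e^-10 * rho_A scale: ln A = 10
    r0 = 0.001, kBT = 0.0041,
    R = 4, R0 = 4, gamma_m = 0, gamma_m0 = 0, gamma_c = 0
  )
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(p), "Km2D"))
  if (length(bad)) stop("unknown theory parameter(s): ", paste(bad, collapse = ", "))
  keep <- intersect(names(dots), names(p))
  p[keep] <- dots[keep]
  if (!is.null(dots$Km2D)) {
    p$k_off0 <- dots$Km2D * p$k_on
  }
  p$Km2D <- p$k_off0 / p$k_on
  stopifnot(p$rho_H >= 0, p$rho_Nb >= 0, p$rho_A >= 0, p$Km2D > 0,
            p$r0 > 0, p$kBT > 0)
  class(p) <- "theory_params"
  p
}

#' Laplace pressure across the vesicle membrane
#'
#' Full form `2 (gamma_m + gamma_c) / R - 2 gamma_m0 / R0`; the approximate
#' form `2 gamma_c / R` holds when the cortex tension dominates.
#'
#' @param p A `theory_params`.
#' @param approximate Use the cortex-dominated approximation.
#' @return Pressure difference in pN/um^2 (= Pa).
#' @export
laplace_pressure <- function(p, approximate = FALSE) {
  if (p$R <= 0 || p$R0 <= 0) stop("radius must be positive")
  if (approximate) return(2 * p$gamma_c / p$R)
  2 * (p$gamma_m + p$gamma_c) / p$R - 2 * p$gamma_m0 / p$R0
}

#' Bound-linker density dynamics under load
#'
#' Right-hand side of the kinetic equation for the actin-bound
#' membrane-linker density: mass-action binding
#' `k_on (rho_H - rho_Hb)(rho_A - rho_Hb - rho_Nb)` minus Bell-accelerated
#' unbinding `k_off0 rho_Hb exp(r0 dP / (kBT rho_Hb))`, where the pressure
#' load `dP` is shared equally over the `rho_Hb` bonds.
#'
#' @param rho_Hb Bound linker density (um^-2), > 0.
#' @param dP Pressure load (pN/um^2).
#' @param p A `theory_params`.
#' @return d(rho_Hb)/dt (um^-2 s^-1).
#' @export
bond_ode_rhs <- function(rho_Hb, dP, p) {
  if (any(rho_Hb <= 0) && any(dP > 0)) {
    stop("rho_Hb = 0 with positive load: Bell exponent singular")
  }
  on <- p$k_on * (p$rho_H - rho_Hb) * (p$rho_A - rho_Hb - p$rho_Nb)
  off <- p$k_off0 * rho_Hb * exp(p$r0 * dP / (p$kBT * rho_Hb))
  on - off
}

# nondimensional critical pressure: p* = max_x x * log(A (1-x) / x)
critical_p_star <- function(logA, tol = 1e-10) {
  if (logA <= 0) return(0)
  f <- function(x) x * (logA + log((1 - x) / x))
  opt <- optimize(f, c(1e-12, 1 - 1e-12), maximum = TRUE, tol = tol)
  max(opt$objective, 0)
}

#' Critical pressure for cortex-membrane detachment
#'
#' Saddle-node pressure above which no stable bound-linker state exists. In
#' the abundant-binding-site regime (`rho_A >> rho_Hb + rho_Nb`) the steady
#' state nondimensionalizes to `p = x ln(A (1-x)/x)` with `x = rho_Hb/rho_H`
#' and `A = rho_A / Km2D`, and the critical value is the maximum over
#' `x in (0, 1)`, approximately `0.7 ln A` for `ln A` around 10. With
#' `abundant_sites = FALSE` the maximization runs on the full fixed-point
#' relation including linker depletion of binding sites.
#'
#' @param p A `theory_params`.
#' @param abundant_sites Assume `rho_A >> rho_Hb + rho_Nb`.
#' @return Critical pressure (pN/um^2); 0 when no bound state exists
#'   (`rho_A <= Km2D`).
#' @export
critical_pressure <- function(p, abundant_sites = TRUE) {
  if (p$rho_H <= 0) return(0)
  A <- p$rho_A / p$Km2D
  if (A <= 1) return(0)
  scale <- p$kBT * p$rho_H / p$r0
  if (abundant_sites) {
    return(scale * critical_p_star(log(A)))
  }
  # full fixed point: dP(x) = (kBT rho_H x / r0) *
  #   log[(1 - x)(rho_A - x rho_H - rho_Nb) / (Km2D x)]
  f <- function(x) {
    arg <- (1 - x) * (p$rho_A - x * p$rho_H - p$rho_Nb) / (p$Km2D * x)
    ifelse(arg > 0, x * log(arg), -Inf)
  }
  opt <- optimize(f, c(1e-12, 1 - 1e-12), maximum = TRUE, tol = 1e-10)
  max(scale * opt$objective, 0)
}

#' Critical cortex tension for the detachment mechanism
#'
#' Via the cortex-dominated Laplace relation, `gamma_CD* = dP* R / 2`.
#' The closed-form variant uses the printed prefactor
#' `0.35 (kBT rho_H R / r0) ln(rho_A / Km2D)` (half the pressure prefactor).
#' Exactly linear in `rho_H` and hence in the coupling ratio `R_C`.
#'
#' @param p A `theory_params`.
#' @param closed_form Use the closed-form prefactor instead of the numerical
#'   saddle-node value.
#' @return Critical tension (pN/um).
#' @export
critical_detachment_tension <- function(p, closed_form = FALSE) {
  if (p$R <= 0) stop("radius must be positive")
  if (closed_form) {
    A <- p$rho_A / p$Km2D
    if (A <= 1 || p$rho_H <= 0) return(0)
    return(0.35 * p$kBT * p$rho_H * p$R / p$r0 * log(A))
  }
  critical_pressure(p) * p$R / 2
}

#' Parametric rupture-tension model
#'
#' The critical cortex tension for network rupture, `gamma_CR*`, is modeled
#' as a nondecreasing function of the connectivity `R_X` and independent of
#' the coupling `R_C`: by default linear through the origin with slope
#' `slope` (pN/um per unit `R_X`), or an interpolated table calibrated from
#' simulations.
#'
#' @param slope Linear slope (pN/um per unit `R_X`).
#' @param table Optional data.frame with columns `R_X`, `gamma` for a
#'   monotone interpolated model.
#' @return Function `R_X -> gamma_CR*` with class `rupture_tension_model`.
#' @export
rupture_tension_model <- function(slope = NULL, table = NULL) {
  if (is.null(slope) && is.null(table)) slope <- default_rupture_slope()
  if (!is.null(table)) {
    stopifnot(all(diff(table$gamma) >= 0), all(diff(table$R_X) > 0))
    f <- function(R_X) stats::approx(table$R_X, table$gamma, xout = R_X,
                                     rule = 2)$y
  } else {
    stopifnot(slope >= 0)
    f <- function(R_X) slope * R_X
  }
  class(f) <- c("rupture_tension_model", "function")
  f
}

# default slope calibrated so that, at the reference connectivity R_X = 0.08,
# the predicted detachment -> rupture switch sits at intermediate coupling
# (R_C ~ 0.032), matching where both mechanisms coexist in simulations
default_rupture_slope <- function(tp = theory_params()) {
  p <- tp
  p$rho_H <- 0.032 * p$rho_A
  critical_detachment_tension(p) / 0.08
}

#' Predict the bleb initiation mechanism
#'
#' As the cortex tension ramps up from zero, the mechanism whose critical
#' tension is reached first wins: `"Detachment"` iff
#' `gamma_CD*(R_C) < gamma_CR*(R_X)`, else `"Rupture"` (ties break to
#' rupture). The linker density follows the coupling ratio via
#' `rho_H = R_C * rho_A`.
#'
#' @param R_C Membrane-coupling ratio.
#' @param R_X Connectivity ratio.
#' @param p A `theory_params` (its `rho_H` is overridden by `R_C * rho_A`).
#' @param rupture A [rupture_tension_model()].
#' @return `"Detachment"` or `"Rupture"`.
#' @export
predict_mechanism <- function(R_C, R_X, p = theory_params(),
                              rupture = rupture_tension_model()) {
  p$rho_H <- R_C * p$rho_A
  gcd <- critical_detachment_tension(p)
  gcr <- rupture(R_X)
  if (gcd < gcr) "Detachment" else "Rupture"
}

#' Mechanism phase diagram over (R_C, R_X)
#'
#' Evaluates [predict_mechanism()] on a grid. The detachment/rupture boundary
#' is monotone: the switching `R_C` is nondecreasing in `R_X`.
#'
#' @param R_C,R_X Numeric grid axes.
#' @param p A `theory_params`.
#' @param rupture A [rupture_tension_model()].
#' @return Tibble with columns `R_C`, `R_X`, `gamma_CD`, `gamma_CR`,
#'   `mechanism`.
#' @export
phase_diagram <- function(R_C, R_X, p = theory_params(),
                          rupture = rupture_tension_model()) {
  if (!length(R_C) || !length(R_X)) stop("grid must be nonempty")
  grid <- expand.grid(R_C = R_C, R_X = R_X)
  gcd <- vapply(grid$R_C, function(rc) {
    pp <- p; pp$rho_H <- rc * p$rho_A
    critical_detachment_tension(pp)
  }, 0)
  gcr <- rupture(grid$R_X)
  tibble::tibble(R_C = grid$R_C, R_X = grid$R_X, gamma_CD = gcd,
                 gamma_CR = gcr,
                 mechanism = ifelse(gcd < gcr, "Detachment", "Rupture"))
}
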