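#' Simulation parameter set
#'
#' Builds and validates the full parameter container for a simulation run.
#' All lengths are in micrometres, forces in piconewtons, times in seconds;
#' consequently energies are pN um, spring stiffnesses pN/um, viscosities in
#' Pa s (numerically compatible with the pN/um/s system), and pressures in
#' pN/um^2 (= Pa).
#'
#' The key composition ratios follow the standard notation of reconstituted
#' actomyosin systems: `R_X` is the cross-linker-to-actin molar ratio (network
#' connectivity), `R_C` the membrane-bindable cross-linker-to-actin ratio
#' (actin-membrane coupling strength, `R_C <= R_X`), and `R_M` the
#' myosin-to-actin molar ratio (motor density).
#'
#' @param ... Named overrides of any default listed below.
#'
#' @section Core mechanical defaults:
#' * `kBT = 0.0041` pN um (thermal energy at 25 C)
#' * `seg_len = 0.14` um filament segment rest length
#' * `k_ext = 100` pN/um segment extensional stiffness
#' * `Lp_actin = 9` um actin persistence length (bending stiffness
#'   `kappa = Lp_actin * kBT / seg_len`)
#' * `d_actin = 0.007` um filament diameter; the repulsive range is
#'   `3 * d_actin` for numerical stability
#' * `eta = 0.086` Pa s medium viscosity, with multiplicative `drag_scale`
#'
#' @section Kinetics defaults:
#' * `k_on = 30` 1/s per eligible site, `k_off0 = 0.5` 1/s, `r0_bond = 0.001`
#'   um (Bell mechanosensitivity distance); `anchor_r0_bond` (defaults to
#'   `r0_bond`) is the Bell distance of the membrane-anchor linkage, which
#'   may be set larger to make anchors the weakest bond in the chain
#' * `F_sev = 300` pN tensile severing threshold
#' * motors: `F_stall = 5.7` pN per head, `heads_per_side = 8`,
#'   `k_walk0 = 20` steps/s unloaded, `step_size = 0.007` um,
#'   `motor_k_off0 = 0.1` 1/s zero-force head unbinding
#'
#' @section Membrane defaults:
#' * `mean_fil_len` (um): target mean filament length for nucleation
#'   calibration; when `NA` a region-dependent default is used
#' * `R_mem = 4` um radius (8 um diameter), `mesh_subdiv = 3`
#' * `k_area = 120` pN/um area stiffness, `k_bend_mem = 0.1` pN um dihedral
#'   rigidity, `k_vol = 10000` pN/um^2 volume-penalty stiffness
#' * `k_anchor = 100` pN/um anchor spring, `anchor_drag = 0.2` pN s/um
#'   in-plane drag of membrane attachment points
#' * `excess_area = 0.04`: relative membrane area reservoir over the sphere
#'   area (slack that lets blebs inflate without stretching, as in floppy
#'   vesicles); `vol_inflate = 1`: reference-volume multiplier (slight
#'   osmotic inflation tautens the membrane against part of the slack)
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(R_mem = 1.5, R_X = 0.08, R_C = 0.08)
#' p$R_C
#' @export
sim_params <- function(...) {
  p <- list(
    # thermodynamics / filament mechanics
    kBT = 0.0041, seg_len = 0.14, k_ext = 100, Lp_actin = 9,
    d_actin = 0.007, eta = 0.086, drag_scale = 1, dt = NULL,
    # composition
    C_A = 10, actin_scale = 1, R_X = 0.08, R_C = 0.08, R_M = 0.01,
    monomers_per_um = 370, mean_fil_len = NA,
    # kinetics
    F_sev = 300, k_on = 30, k_off0 = 0.5, r0_bond = 0.001,
    # motors (bipolar mini-filaments)
    F_stall = 5.7, k_walk0 = 20, step_size = 0.007, heads_per_side = 8,
    motor_k_off0 = 0.1,
    motor_backbone = 0.42, k_backbone = 300, k_motor = 100, motor_rest = 0.03,
    # cross-linkers
    k_acp = 100, acp_rest = 0.07, k_anchor = 100, anchor_rest = 0.05,
    anchor_r0_bond = NULL,
    anchor_drag = 0.2, capture_range = 0.14, max_arms_per_seg = 4,
    # membrane
    R_mem = 4, mesh_subdiv = 3, k_area = 120, k_bend_mem = 0.1, k_vol = 10000,
    k_mem_rep = 50, excess_area = 0.04, vol_inflate = 1,
    # excluded volume
    k_rep = 100, rep_range_scale = 3,
    # schedule
    t_assembly = 20, t_activate = 20, t_end = 300,
    # numerics
    n_kinetics = 10, measure_every = 0.5, snapshot_every = 5,
    # measurement defaults
    bleb_cutoff = 0.8, bleb_height = 0.15, shell_thickness = 0.4,
    weak_threshold = 1.05,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (is.null(p$anchor_r0_bond)) p$anchor_r0_bond <- p$r0_bond
  if (is.null(p$dt)) p$dt <- stable_dt(p)
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' Largest stable integration time step
#'
#' Conservative explicit-Euler stability bound `dt = zeta_min / (2 * k_max)`
#' over all stiff elements (segment extension, cross-linker/anchor/motor
#' springs, motor backbone, membrane area elasticity), scaled by a safety
#' factor.
#'
#' @param p A `sim_params` object or plain list of parameters.
#' @param safety Fraction of the bound to use (default 0.8).
#' @return Time step in seconds.
#' @export
stable_dt <- function(p, safety = 0.8) {
  zeta_seg <- 3 * pi * p$eta * p$drag_scale * p$seg_len
  zeta_vert <- 6 * pi * p$eta * p$drag_scale * 0.5 * p$seg_len
  k_max_net <- max(p$k_ext, p$k_acp, p$k_anchor, p$k_motor, p$k_backbone,
                   p$k_rep)
  k_max_mem <- max(p$k_area * 4, p$k_anchor, p$k_mem_rep)
  safety * min(zeta_seg / (2 * k_max_net), zeta_vert / (2 * k_max_mem))
}

validate_params <- function(p) {
  stopifnot(
    p$kBT >= 0, p$seg_len > 0, p$k_ext > 0, p$Lp_actin > 0, p$eta > 0,
    p$dt > 0, p$C_A >= 0,
    p$R_X >= 0, p$R_C >= 0, p$R_C <= p$R_X, p$R_M >= 0,
    p$F_sev > 0, p$k_on >= 0, p$k_off0 >= 0, p$r0_bond >= 0,
    p$R_mem > 0, p$mesh_subdiv >= 2,
    p$t_assembly <= p$t_activate, p$t_activate <= p$t_end,
    p$t_assembly >= 0
  )
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  membrane: R = %.2f um, subdivision %d\n", x$R_mem, x$mesh_subdiv))
  cat(sprintf("  actin: C_A = %g uM (scale %g), R_X = %g, R_C = %g, R_M = %g\n",
              x$C_A, x$actin_scale, x$R_X, x$R_C, x$R_M))
  cat(sprintf("  schedule: assembly %g s, activate %g s, end %g s, dt = %.2g s\n",
              x$t_assembly, x$t_activate, x$t_end, x$dt))
  cat(sprintf("  severing threshold: %g pN\n", x$F_sev))
  invisible(x)
}

#' Paper-scale reference configuration
#'
#' The full-scale reference condition: 8-um-diameter membrane, 10 uM actin,
#' `R_X = R_C = 0.08`, `R_M = 0.01`, 300 pN severing threshold, motor
#' activation after network assembly, 300 s of model time. Runs at this scale
#' are long; see `scaled_params()` for a desk-scale analogue.
#'
#' @param region `"shell"` for the cortical 2D network, `"volume"` for the
#'   volume-spanning 3D network.
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
reference_params <- function(region = c("shell", "volume"), ...) {
  region <- match.arg(region)
  p <- sim_params(R_mem = 4, mesh_subdiv = 4, C_A = 10, actin_scale = 1,
                  R_X = 0.08, R_C = 0.08, R_M = 0.01, F_sev = 300,
                  t_assembly = 50, t_activate = 50, t_end = 300, ...)
  attr(p, "region") <- region
  p
}

#' Desk-scale reference configuration
#'
#' A scaled-down analogue of the reference condition used for fast runs:
#' 3-um-diameter membrane, reduced monomer budget, inflated drag (larger
#' stable time step), a proportionally reduced severing threshold, and a
#' short activation schedule. These conditions reproduce the qualitative
#' regimes (contraction cluster, detachment bleb, rupture bleb, multiple
#' blebs) at a few seconds of wall time per run; they are not quantitatively
#' comparable to the paper-scale configuration.
#'
#' @param region `"shell"` or `"volume"`.
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
scaled_params <- function(region = c("shell", "volume"), ...) {
  region <- match.arg(region)
  base <- list(R_mem = 1.5, mesh_subdiv = 3, C_A = 10, actin_scale = 0.45,
               mean_fil_len = 2.8,
               R_X = 0.08, R_C = 0.08, R_M = 0.04, F_sev = 16,
               k_off0 = 0.12, r0_bond = 3e-4, anchor_r0_bond = 1.5e-3,
               k_walk0 = 80, motor_k_off0 = 0.05,
               drag_scale = 30, k_area = 100, k_vol = 4000,
               k_bend_mem = 0.3, excess_area = 0.035, vol_inflate = 1.015,
               dt = if (region == "shell") 0.0028 else 0.0022,
               t_assembly = 3, t_activate = 3, t_end = 20,
               measure_every = 0.5, snapshot_every = 2,
               bleb_cutoff = 0.8, bleb_height = 0.15)
  dots <- list(...)
  base[names(dots)] <- dots
  p <- do.call(sim_params, base)
  attr(p, "region") <- region
  p
}
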