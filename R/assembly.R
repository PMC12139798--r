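# Network self-assembly: nucleation at fixed count, geometric elongation from
# the monomer pool, cross-linker recruitment by binding kinetics, motor
# placement, and membrane coupling.

#' Nucleation count for a target mean filament length
#'
#' With a fixed monomer budget, the mean filament length is set by the number
#' of nucleated filaments: `count = budget / (monomers_per_um * target)`.
#'
#' @param target_mean_length Target mean filament length (um).
#' @param params A `sim_params`.
#' @param budget Optional monomer budget (computed from the membrane
#'   geometry when `NULL`).
#' @return Integer filament count (>= 1).
#' @export
calibrate_nucleation <- function(target_mean_length, params, budget = NULL) {
  if (target_mean_length <= 2 * params$seg_len) {
    stop("target mean length must exceed 2 segment lengths")
  }
  if (is.null(budget)) {
    mesh <- build_icosphere(params$R_mem, params$mesh_subdiv)
    budget <- monomer_budget(params$C_A, mesh, params$actin_scale)
  }
  total_len <- budget / params$monomers_per_um
  if (target_mean_length > total_len) stop("target length exceeds total polymer")
  max(1L, as.integer(round(budget / (params$monomers_per_um * target_mean_length))))
}

default_mean_length <- function(params, region) {
  # reference condition: ~4.2 um (cortical shell) / ~5.2 um (volume network)
  # in an 8-um membrane; scaled with membrane radius for desk-scale runs
  base <- if (region == "shell") 4.2 else 5.2
  base * params$R_mem / 4
}

radial_band <- function(region, params) {
  if (region == "shell") c(0.9 * params$R_mem, 0.985 * params$R_mem)
  else c(0, 0.985 * params$R_mem)
}

clamp_radial <- function(x, band) {
  r <- sqrt(rowSums(x^2))
  rc <- pmin(pmax(r, band[1]), band[2])
  scale <- ifelse(r > 1e-12, rc / r, 1)
  x * scale
}

random_in_band <- function(n, band) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  # radii sampled with volume weighting within the band
  r <- (runif(n) * (band[2]^3 - band[1]^3) + band[1]^3)^(1 / 3)
  u * r
}

random_unit <- function(n) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u / sqrt(rowSums(u^2))
}

#' Self-assemble an actomyosin network inside the membrane
#'
#' Nucleates filaments at random positions and orientations inside the chosen
#' region (`"shell"`: the cortical layer between 0.9 R and R; `"volume"`: the
#' whole interior), elongates them from the monomer pool, recruits
#' cross-linkers by binding kinetics and places motor mini-filaments. The
#' membrane is held rigid throughout assembly and motors are inactive; the
#' network relaxes by Brownian dynamics between kinetics cycles.
#'
#' @param params A `sim_params`.
#' @param region `"shell"` or `"volume"`.
#' @param mean_length Target mean filament length (um); default ~4.2 um
#'   (shell) or ~5.2 um (volume) scaled by `R_mem / 4`.
#' @param progress Print progress lines.
#' @return A simulation state at `t = t_assembly` (membrane still spherical).
#' @export
assemble_network <- function(params, region = c("shell", "volume"),
                             mean_length = NULL, progress = FALSE) {
  region <- match.arg(region)
  p <- params
  mesh <- build_icosphere(p$R_mem, p$mesh_subdiv)
  # membrane area reservoir: unstressed area exceeds the spherical area, so
  # protrusions can inflate without stretching (floppy-vesicle slack)
  mesh$ref_area <- mesh$ref_area * (1 + p$excess_area)
  # slight osmotic inflation tautens the membrane against part of the slack
  mesh$ref_volume <- mesh$ref_volume * p$vol_inflate
  budget <- monomer_budget(p$C_A, mesh, p$actin_scale)
  state <- new_state(p, mesh, pool = budget)
  attr(state, "region") <- region
  if (budget == 0) {
    state$time <- p$t_assembly
    return(state)
  }
  if (is.null(mean_length)) {
    mean_length <- if (is.finite(p$mean_fil_len)) p$mean_fil_len
                   else default_mean_length(p, region)
  }
  nfil <- calibrate_nucleation(mean_length, p, budget)
  band <- radial_band(region, p)
  seg_mono <- p$seg_len * p$monomers_per_um
  if (budget < 2 * seg_mono) stop("monomer pool insufficient for one filament")
  nfil <- min(nfil, floor(budget / (2 * seg_mono)))

  # nucleate: 2-node seeds
  origins <- random_in_band(nfil, band)
  dirs <- random_unit(nfil)
  if (region == "shell") {
    # keep seeds tangential so they fit in the shell
    rad <- origins / sqrt(rowSums(origins^2))
    dirs <- dirs - rowSums(dirs * rad) * rad
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
  }
  x <- matrix(0, 2 * nfil, 3)
  x[seq(1, 2 * nfil, 2), ] <- origins
  x[seq(2, 2 * nfil, 2), ] <- origins + p$seg_len * dirs
  x <- clamp_radial(x, band)
  state$x <- x
  state$fil_id <- rep(seq_len(nfil), each = 2)
  state$seg_rest <- rep(c(p$seg_len, NA), nfil)
  state$pool <- budget - nfil * seg_mono

  # cross-linker reservoir (all plain until membrane coupling is assigned)
  n_acp <- round(p$R_X * budget)
  state$acp_free_plain <- n_acp
  state$acp_free_bindable <- 0

  # motor mini-filaments: R_M * budget myosin molecules grouped into
  # mini-filaments of 2 * heads_per_side molecules
  n_mot <- round(p$R_M * budget / (2 * p$heads_per_side))
  if (n_mot > 0) {
    cen <- random_in_band(n_mot, band)
    mdir <- random_unit(n_mot)
    if (region == "shell") {
      rad <- cen / sqrt(rowSums(cen^2))
      mdir <- mdir - rowSums(mdir * rad) * rad
      mdir <- mdir / pmax(sqrt(rowSums(mdir^2)), 1e-9)
    }
    ends <- matrix(0, 2 * n_mot, 3)
    ends[seq(1, 2 * n_mot, 2), ] <- cen - p$motor_backbone / 2 * mdir
    ends[seq(2, 2 * n_mot, 2), ] <- cen + p$motor_backbone / 2 * mdir
    state$motors$ends <- ends
    state$motors$df <- data.frame(
      h1_fil = rep(NA_integer_, n_mot), h1_pos = NA_real_,
      h2_fil = NA_integer_, h2_pos = NA_real_, h1_F = 0, h2_F = 0)
  }

  # growth schedule: exhaust the pool by ~80% of the assembly window
  dt_kin <- p$n_kinetics * p$dt
  n_cycles <- max(1L, ceiling(p$t_assembly / dt_kin))
  grow_len <- (state$pool / p$monomers_per_um) / nfil    # um left per filament
  p_grow <- min(1, grow_len / p$seg_len / (0.8 * n_cycles))

  for (cyc in seq_len(n_cycles)) {
    state <- grow_filaments(state, p_grow, band, region)
    state <- advance_cycle(state, p$n_kinetics, membrane_active = FALSE,
                           band = band)
    state <- crosslinker_kinetics_step(state, dt_kin,
                                       forces = attr(state, "last_forces"),
                                       membrane_binding = FALSE)
    state <- motor_step(state, dt_kin, forces = attr(state, "last_forces"))
    state$time <- cyc * dt_kin
    if (progress && cyc %% 20 == 0) {
      message(sprintf("assembly t=%.2f pool=%d acps=%d", state$time,
                      state$pool, nrow(state$acps)))
    }
  }
  state$time <- p$t_assembly
  state
}

# geometric elongation at the barbed end (last node of each filament)
grow_filaments <- function(state, p_grow, band, region) {
  p <- state$params
  seg_mono <- p$seg_len * p$monomers_per_um
  if (state$pool < seg_mono) return(state)
  rng <- fil_ranges(state$fil_id)
  grow <- which(runif(nrow(rng)) < p_grow)
  if (!length(grow)) return(state)
  n_afford <- floor(state$pool / seg_mono)
  if (length(grow) > n_afford) grow <- grow[seq_len(n_afford)]
  # persistence-correlated growth direction
  sd_ang <- sqrt(p$seg_len / p$Lp_actin)
  newx <- matrix(0, length(grow), 3)
  for (q in seq_along(grow)) {
    to <- rng$to[grow[q]]
    d <- state$x[to, ] - state$x[to - 1L, ]
    d <- d / max(sqrt(sum(d^2)), 1e-12)
    d <- d + sd_ang * rnorm(3)
    d <- d / sqrt(sum(d^2))
    xn <- state$x[to, ] + p$seg_len * d
    # reflect the growth direction at the band boundaries instead of piling
    # nodes against them
    r <- sqrt(sum(xn^2))
    if (r > band[2] || r < band[1]) {
      rh <- state$x[to, ] / max(sqrt(sum(state$x[to, ]^2)), 1e-12)
      d <- d - 2 * sum(d * rh) * rh
      xn <- state$x[to, ] + p$seg_len * d
    }
    newx[q, ] <- xn
  }
  newx <- clamp_radial(newx, band)
  # splice new nodes in (keeping filament blocks contiguous)
  ins_after <- rng$to[grow]
  ord <- order(ins_after)
  pieces_x <- list(); pieces_id <- list(); pieces_rest <- list()
  prev <- 0L
  for (q in ord) {
    to <- ins_after[q]
    pieces_x[[length(pieces_x) + 1]] <- state$x[(prev + 1L):to, , drop = FALSE]
    pieces_id[[length(pieces_id) + 1]] <- state$fil_id[(prev + 1L):to]
    rest <- state$seg_rest[(prev + 1L):to]
    rest[length(rest)] <- p$seg_len   # former end node now starts a segment
    pieces_rest[[length(pieces_rest) + 1]] <- rest
    pieces_x[[length(pieces_x) + 1]] <- newx[q, , drop = FALSE]
    pieces_id[[length(pieces_id) + 1]] <- rng$fil[grow[q]]
    pieces_rest[[length(pieces_rest) + 1]] <- NA_real_
    prev <- to
  }
  if (prev < nrow(state$x)) {
    pieces_x[[length(pieces_x) + 1]] <- state$x[(prev + 1L):nrow(state$x), , drop = FALSE]
    pieces_id[[length(pieces_id) + 1]] <- state$fil_id[(prev + 1L):length(state$fil_id)]
    pieces_rest[[length(pieces_rest) + 1]] <- state$seg_rest[(prev + 1L):length(state$seg_rest)]
  }
  state$x <- do.call(rbind, pieces_x)
  state$fil_id <- unlist(pieces_id)
  state$seg_rest <- unlist(pieces_rest)
  state$pool <- state$pool - length(grow) * seg_mono
  state
}

#' Couple a fraction of cross-linkers to the membrane
#'
#' Flags a uniformly random fraction `R_C / R_X` of all cross-linkers as
#' membrane-bindable and immediately anchors the flagged ones lying within
#' the capture range of the mesh (anchor at the nearest face point,
#' barycentric). Subsequent anchor turnover is handled by the binding
#' kinetics.
#'
#' @param state A simulation state.
#' @param params A `sim_params` (defaults to the state's own).
#' @return The updated state.
#' @export
couple_to_membrane <- function(state, params = state$params) {
  p <- params
  if (p$R_C > p$R_X) stop("R_C must not exceed R_X")
  frac <- if (p$R_X > 0) p$R_C / p$R_X else 0
  a <- state$acps
  if (nrow(a)) {
    a$bindable <- runif(nrow(a)) < frac
    state$acps <- a
  }
  nfree <- state$acp_free_bindable + state$acp_free_plain
  nb <- rbinom(1, nfree, frac)
  state$acp_free_bindable <- nb
  state$acp_free_plain <- nfree - nb
  a <- state$acps
  cand <- which(a$bindable & (!is.na(a$f1) | !is.na(a$f2)))
  if (length(cand)) {
    fa <- ifelse(!is.na(a$f1[cand]), a$f1[cand], a$f2[cand])
    pa <- ifelse(!is.na(a$f1[cand]), a$p1[cand], a$p2[cand])
    pts <- arc_point(state, fa, pa)
    prj <- project_to_mesh(state$mesh, pts)
    sel <- which(prj$dist <= p$capture_range)
    rows <- cand[sel]
    a$a_face[rows] <- prj$face[sel]
    a$a_w1[rows] <- prj$w[sel, 1]
    a$a_w2[rows] <- prj$w[sel, 2]
    a$a_w3[rows] <- prj$w[sel, 3]
    state$acps <- a
  }
  state
}
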