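# Overdamped Euler-Maruyama time stepping and the simulation driver.

drag_coefficients <- function(sys, p) {
  zeta <- numeric(nrow(sys$pos))
  if (sys$nfil) {
    zeta[seq_len(sys$nfil)] <- 3 * pi * p$eta * p$drag_scale * p$seg_len
  }
  if (sys$nmot) {
    zeta[sys$mot_off + seq_len(sys$nmot)] <-
      3 * pi * p$eta * p$drag_scale * p$motor_backbone / 2
  }
  if (sys$nmesh) {
    # effective bead radius ~ half the mean edge length
    e <- sys$edges
    el <- sqrt(rowSums((sys$pos[e[, 2], , drop = FALSE] -
                          sys$pos[e[, 1], , drop = FALSE])^2))
    zeta[sys$mesh_off + seq_len(sys$nmesh)] <-
      6 * pi * p$eta * p$drag_scale * mean(el) / 2
  }
  zeta
}

#' One overdamped Langevin step
#'
#' Moves every point by `(F / zeta) * dt + sqrt(2 kBT dt / zeta) * xi` with
#' independent standard-normal `xi` per coordinate; drags derive from the
#' local geometry and `eta * drag_scale`. Membrane anchor points move only
#' tangentially to their face, with their own in-plane drag. Errors if any
#' displacement exceeds two segment lengths (instability signal).
#'
#' @param state A simulation state.
#' @param dt Time step (s); defaults to `params$dt`.
#' @param membrane_active If `FALSE`, mesh vertices are frozen.
#' @return The updated state (time advanced by `dt`).
#' @export
langevin_step <- function(state, dt = state$params$dt, membrane_active = TRUE) {
  state <- advance_cycle(state, 1L, membrane_active = membrane_active, dt = dt)
  state
}

# Advance n_steps of Brownian dynamics on a compiled system, then write the
# moved coordinates back into the state. The last force evaluation is kept as
# attr(state, "last_forces") for the kinetics step that typically follows.
advance_cycle <- function(state, n_steps, membrane_active = TRUE, band = NULL,
                          dt = state$params$dt) {
  p <- state$params
  sys <- compile_system(state)
  pairs <- build_pairs(sys, p, skin = 0.1)
  zeta <- drag_coefficients(sys, p)
  n <- nrow(sys$pos)
  if (n == 0) {
    state$time <- state$time + n_steps * dt
    return(state)
  }
  noise_sd <- sqrt(2 * p$kBT * dt / zeta)
  mesh_rows <- if (sys$nmesh) sys$mesh_off + seq_len(sys$nmesh) else integer(0)
  fil_rows <- seq_len(sys$nfil)

  anchor_rows <- which(sys$spr_type == "anchor")
  an_face <- if (length(anchor_rows)) {
    state$acps$a_face[sys$spr_owner[anchor_rows]]
  } else integer(0)
  adj <- state$mesh$face_adj
  if (is.null(adj)) adj <- face_adjacency(state$mesh$F)

  noise <- noise_sd * matrix(rnorm(3 * n * n_steps), ncol = 3)
  r_rep <- p$rep_range_scale * p$d_actin
  out <- run_chunk_cpp(
    sys$pos, sys$seg_a, sys$seg_b, sys$seg_rest, p$k_ext,
    sys$bend, p$Lp_actin * p$kBT / p$seg_len,
    pairs$rep, r_rep, p$k_rep,
    sys$spr_ia, sys$spr_wa, sys$spr_ib, sys$spr_wb, sys$spr_k, sys$spr_rest,
    sys$faces, sys$ref_area, if (membrane_active) p$k_area else 0,
    sys$edges, if (membrane_active) p$k_bend_mem else 0,
    sys$ref_vol, if (membrane_active) p$k_vol else 0,
    pairs$mem, mem_rep_range(p), p$k_mem_rep,
    as.integer(n_steps), dt, zeta, noise, membrane_active,
    sys$nfil, sys$mesh_off,
    if (is.null(band)) numeric(0) else as.numeric(band),
    anchor_rows, an_face, state$mesh$F, adj,
    p$anchor_drag, 2 * p$seg_len)
  if (isTRUE(out$unstable)) {
    stop(sprintf("integration unstable: displacement %.3g um in one step (dt=%.2g)",
                 out$max_disp, dt))
  }
  # write back
  pos <- out$pos
  if (sys$nfil) state$x <- pos[fil_rows, , drop = FALSE]
  if (sys$nmot) state$motors$ends <- pos[sys$mot_off + seq_len(sys$nmot), , drop = FALSE]
  if (sys$nmesh) state$mesh$V <- pos[mesh_rows, , drop = FALSE]
  if (length(anchor_rows)) {
    acp_row <- sys$spr_owner[anchor_rows]
    wb <- out$spr_wb[anchor_rows, , drop = FALSE]
    state$acps$a_face[acp_row] <- out$an_face
    state$acps$a_w1[acp_row] <- wb[, 1]
    state$acps$a_w2[acp_row] <- wb[, 2]
    state$acps$a_w3[acp_row] <- wb[, 3]
  }
  state$time <- state$time + n_steps * dt
  attr(state, "last_forces") <- list(
    seg_tension = out$seg_tension, spr_tension = out$spr_tension,
    spr_type = sys$spr_type, spr_owner = sys$spr_owner,
    volume = out$volume, face_area = out$face_area)
  state
}

face_adjacency <- function(F) {
  m <- nrow(F)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edge_faces <- new.env(hash = TRUE)
  for (f in seq_len(m)) {
    for (k in 1:3) {
      e <- key(F[f, c(2, 3, 1)[k]], F[f, c(3, 1, 2)[k]])  # edge opposite vertex k
      edge_faces[[e]] <- c(edge_faces[[e]], f)
    }
  }
  adj <- matrix(0L, m, 3)
  for (f in seq_len(m)) {
    for (k in 1:3) {
      e <- key(F[f, c(2, 3, 1)[k]], F[f, c(3, 1, 2)[k]])
      fs <- edge_faces[[e]]
      adj[f, k] <- fs[fs != f][1]
    }
  }
  adj
}

#' Run a full simulation
#'
#' Executes the complete workflow: network assembly inside a rigid spherical
#' membrane, membrane coupling, all-or-none motor activation, and the
#' production phase with a deformable membrane, stochastic binding kinetics
#' and tensile severing. Time series are sampled every `measure_every`
#' seconds and full snapshots stored every `snapshot_every` seconds.
#'
#' @param params A `sim_params`.
#' @param region `"shell"` (cortical 2D network) or `"volume"` (3D network);
#'   defaults to the region attribute of `params` if present.
#' @param seed Random seed (defaults to `params$seed`).
#' @param progress Print progress lines.
#' @return A `cortosim_trajectory`: list with `params`, `region`, `series`
#'   (tibble of time, tensions, volume, bleb count/diameter, deformation),
#'   `snapshots` (list of mesh + network coordinates), `events`, and the
#'   final `state`.
#' @export
run_simulation <- function(params, region = NULL, seed = params$seed,
                           progress = FALSE) {
  run_simulation_hooked(params, region, seed, progress = progress)
}

# driver with optional hooks, used by the perturbation module
run_simulation_hooked <- function(params, region = NULL, seed = params$seed,
                                  after_couple = NULL, each_cycle = NULL,
                                  progress = FALSE) {
  p <- params
  if (is.null(region)) region <- attr(params, "region")
  if (is.null(region)) region <- "shell"
  set.seed(seed)
  state <- assemble_network(p, region, progress = progress)
  state <- couple_to_membrane(state)
  if (!is.null(after_couple)) state <- after_couple(state)

  dt_kin <- p$n_kinetics * p$dt
  snapshots <- list()
  series <- list()
  take_snapshot <- function(state) {
    list(t = state$time, V = state$mesh$V, F = state$mesh$F,
         x = state$x, fil_id = state$fil_id,
         motors = state$motors, acps = state$acps)
  }
  Dinit <- 2 * p$R_mem
  measure <- function(state, forces) {
    ten <- global_tension(state, forces = forces)
    det <- detect_blebs(state$mesh, cutoff_diameter = p$bleb_cutoff,
                        height = p$bleb_height)
    tibble::tibble(
      t = state$time,
      T_net_global = ten$network, T_mem_global = ten$membrane,
      volume = if (is.null(forces)) mesh_volume(state$mesh$V, state$mesh$F)
               else forces$volume,
      n_blebs = length(det),
      max_bleb_diameter = if (length(det)) max(vapply(det, `[[`, 0, "diameter")) else 0,
      caliper = max_caliper(state$mesh$V) )
  }

  snapshots[[1]] <- take_snapshot(state)
  lf <- attr(state, "last_forces")
  series[[1]] <- measure(state, lf)
  next_meas <- state$time + p$measure_every
  next_snap <- state$time + p$snapshot_every

  n_cycles <- max(0L, ceiling((p$t_end - state$time) / dt_kin))
  for (cyc in seq_len(n_cycles)) {
    state <- advance_cycle(state, p$n_kinetics, membrane_active = TRUE)
    lf <- attr(state, "last_forces")
    n_ev <- nrow(state$events)
    state <- severing_step(state, seg_tension = lf$seg_tension)
    if (nrow(state$events) > n_ev) lf <- NULL   # topology changed; stale
    state <- crosslinker_kinetics_step(state, dt_kin, forces = lf,
                                       membrane_binding = TRUE)
    state <- motor_step(state, dt_kin, forces = lf)
    if (!is.null(each_cycle)) state <- each_cycle(state)
    if (state$time >= next_meas - 1e-9) {
      series[[length(series) + 1]] <- measure(state, attr(state, "last_forces"))
      next_meas <- next_meas + p$measure_every
    }
    if (state$time >= next_snap - 1e-9) {
      snapshots[[length(snapshots) + 1]] <- take_snapshot(state)
      next_snap <- next_snap + p$snapshot_every
    }
    if (progress && cyc %% 50 == 0) {
      message(sprintf("t=%.1f  segs=%d  acps=%d  events=%d", state$time,
                      length(segment_table(state)$a), nrow(state$acps),
                      nrow(state$events)))
    }
  }
  snapshots[[length(snapshots) + 1]] <- take_snapshot(state)
  ser <- do.call(rbind, series)
  ser$Lmax_over_Dinit <- cummax(ser$caliper) / Dinit
  structure(list(params = p, region = region, seed = seed, series = ser,
                 snapshots = snapshots, events = state$events, state = state),
            class = "cortosim_trajectory")
}

#' @export
print.cortosim_trajectory <- function(x, ...) {
  cat("<cortosim_trajectory>\n")
  cat(sprintf("  region %s, seed %s, %d samples, %d snapshots, %d events\n",
              x$region, x$seed, nrow(x$series), length(x$snapshots),
              nrow(x$events)))
  cat(sprintf("  final t = %.1f s, final bleb count = %d\n",
              max(x$series$t), x$series$n_blebs[nrow(x$series)]))
  invisible(x)
}

# maximum caliper width of a point cloud: equals the set diameter (max
# pairwise distance), computed exactly
max_caliper <- function(V) {
  n <- nrow(V)
  if (n < 2) return(0)
  if (n <= 3000) return(max(stats::dist(V)))
  # chunked pairwise maximum for large clouds
  best <- 0
  idx <- split(seq_len(n), ceiling(seq_len(n) / 1500))
  for (a in seq_along(idx)) {
    for (b in a:length(idx)) {
      A <- V[idx[[a]], , drop = FALSE]; B <- V[idx[[b]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      best <- max(best, sqrt(max(d2)))
    }
  }
  best
}

fibonacci_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
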