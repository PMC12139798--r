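# Stochastic per-step kinetics: cross-linker and motor binding/unbinding with
# Bell force dependence, motor walking with a linear force-velocity relation,
# and tensile filament severing.

#' Motor activation schedule
#'
#' Motors are switched on in an all-or-none fashion at `t_activate`, after
#' network assembly; before that they bind but generate no active stepping.
#'
#' @param t Model time (s).
#' @param params A `sim_params`.
#' @return Logical: are motors active?
#' @export
activation_schedule <- function(t, params) {
  t >= params$t_activate
}

bell_prob <- function(F, params, dt, k_off0 = params$k_off0) {
  rate <- k_off0 * exp(pmax(F, 0) * params$r0_bond / params$kBT)
  1 - exp(-rate * dt)
}

#' Tension-threshold filament severing
#'
#' Removes every filament segment whose axial tension exceeds `F_sev`
#' (descending-tension order within the step; all over-threshold segments
#' sever). Each removed segment splits its filament in two, returns its
#' monomers to the free pool, and is appended to the event log. Single-node
#' remnants are discarded. Cross-linker arms and motor heads are remapped to
#' the surviving pieces; attachments within a removed segment unbind.
#'
#' @param state A simulation state.
#' @param seg_tension Optional precomputed per-segment tensions (pN); when
#'   `NULL` they are evaluated from the current force field.
#' @return The updated state.
#' @export
severing_step <- function(state, seg_tension = NULL) {
  p <- state$params
  if (!is.finite(p$F_sev)) return(state)
  seg <- segment_table(state)
  if (!length(seg$a)) return(state)
  if (is.null(seg_tension)) seg_tension <- net_forces(state)$seg_tension
  over <- which(seg_tension > p$F_sev)
  if (!length(over)) return(state)
  over <- over[order(seg_tension[over], decreasing = TRUE)]
  remove_segments(state, seg, over)
}

# Remove the given segment rows (indices into segment_table) and rebuild the
# whole filament bookkeeping. Used by severing.
remove_segments <- function(state, seg, rows) {
  p <- state$params
  n <- nrow(state$x)
  cut_after <- rep(FALSE, n)          # node i: segment (i, i+1) removed
  cut_after[seg$a[rows]] <- TRUE

  # piece id per node: increments at filament boundaries and removed segments
  newf <- integer(n)
  fid <- 0L
  for (i in seq_len(n)) {
    if (i == 1L || state$fil_id[i] != state$fil_id[i - 1L] || cut_after[i - 1L]) {
      fid <- fid + 1L
    }
    newf[i] <- fid
  }
  keep_piece <- tabulate(newf) >= 2L
  keep_node <- keep_piece[newf]
  node_map <- integer(n)
  node_map[keep_node] <- seq_len(sum(keep_node))
  piece_map <- integer(max(newf))
  piece_map[keep_piece] <- seq_len(sum(keep_piece))

  # event log + pool return
  removed_a <- seg$a[rows]
  mid <- (state$x[removed_a, , drop = FALSE] +
            state$x[removed_a + 1L, , drop = FALSE]) / 2
  state$events <- rbind(state$events, data.frame(
    t = state$time, type = "sever", x = mid[, 1], y = mid[, 2], z = mid[, 3],
    fil = state$fil_id[removed_a]))
  returned <- sum(state$seg_rest[removed_a])

  # arc remapping tables per old filament: for each old segment, its piece and
  # the arc offset of that piece's start
  old_seg_piece <- newf[seg$a]
  piece_start <- tapply(seq_along(seg$a), old_seg_piece, min)
  cum_by_fil <- function(fid_vec, rest) {
    out <- numeric(length(rest))
    for (f in unique(fid_vec)) {
      s <- fid_vec == f
      out[s] <- cumsum(c(0, rest[s]))[seq_len(sum(s))]
    }
    out
  }
  seg_start_arc <- cum_by_fil(seg$fil, seg$rest)
  seg_end_arc <- seg_start_arc + seg$rest
  removed_flag <- rep(FALSE, length(seg$a))
  removed_flag[rows] <- TRUE

  remap_attachment <- function(f, pos) {
    # returns list(f, pos) with NA where the attachment unbinds
    nf <- rep(NA_integer_, length(f))
    np <- rep(NA_real_, length(f))
    bound <- which(!is.na(f))
    for (q in bound) {
      ss <- which(seg$fil == f[q] & seg_start_arc <= pos[q] + 1e-9 &
                    seg_end_arc >= pos[q] - 1e-9)
      if (!length(ss)) next
      ss <- ss[1]
      if (removed_flag[ss]) next
      pc <- old_seg_piece[ss]
      if (!keep_piece[pc]) next
      nf[q] <- piece_map[pc]
      np[q] <- pos[q] - seg_start_arc[piece_start[[as.character(pc)]]]
    }
    list(f = nf, pos = np)
  }

  a <- state$acps
  if (nrow(a)) {
    r1 <- remap_attachment(a$f1, a$p1)
    r2 <- remap_attachment(a$f2, a$p2)
    a$f1 <- r1$f; a$p1 <- r1$pos; a$f2 <- r2$f; a$p2 <- r2$pos
    state$acps <- a
  }
  m <- state$motors$df
  if (nrow(m)) {
    r1 <- remap_attachment(m$h1_fil, m$h1_pos)
    r2 <- remap_attachment(m$h2_fil, m$h2_pos)
    m$h1_fil <- r1$f; m$h1_pos <- r1$pos; m$h2_fil <- r2$f; m$h2_pos <- r2$pos
    state$motors$df <- m
  }

  state$x <- state$x[keep_node, , drop = FALSE]
  state$fil_id <- piece_map[newf[keep_node]]
  new_rest <- state$seg_rest
  new_rest[seg$a[rows]] <- NA          # removed segments
  # nodes at new filament ends get NA rest
  state$seg_rest <- new_rest[keep_node]
  nn <- length(state$fil_id)
  if (nn) {
    endnode <- c(state$fil_id[-nn] != state$fil_id[-1], TRUE)
    state$seg_rest[endnode] <- NA
  }
  state$pool <- state$pool + returned * p$monomers_per_um
  state <- drop_unbound_acps(state)
  state
}

drop_unbound_acps <- function(state) {
  a <- state$acps
  if (!nrow(a)) return(state)
  dead <- is.na(a$f1) & is.na(a$f2)
  if (any(dead)) {
    state$acp_free_bindable <- state$acp_free_bindable + sum(dead & a$bindable)
    state$acp_free_plain <- state$acp_free_plain + sum(dead & !a$bindable)
    state$acps <- a[!dead, , drop = FALSE]
    rownames(state$acps) <- NULL
  }
  # anchors on rows that lost all arms are gone with the row; anchors must sit
  # on a bound arm, which compile_system guarantees by construction
  state
}

# occupancy: arms bound per segment, used to cap pile-up
segment_occupancy <- function(state, seg) {
  rows <- c(locate_segment(seg, state$acps$f1, state$acps$p1),
            locate_segment(seg, state$acps$f2, state$acps$p2))
  tabulate(rows[rows > 0], nbins = length(seg$a))
}

in_perturbed_cap <- function(state, pts, target) {
  pb <- state$perturb
  if (is.null(pb) || pb$target != target || state$time < pb$t_apply) {
    return(rep(FALSE, nrow(pts)))
  }
  r <- sqrt(rowSums(pts^2))
  u <- pts / pmax(r, 1e-12)
  inside_cone <- drop(u %*% pb$axis) >= pb$cos_ang
  if (target == "RX") inside_cone & r >= 0.75 * state$params$R_mem else inside_cone
}

#' Cross-linker binding and unbinding kinetics
#'
#' One stochastic kinetics step of duration `dt`: bound arms and membrane
#' anchors unbind with Bell's force-dependent rate
#' `k_off0 * exp(F * r0_bond / kBT)`; free arms of singly bound cross-linkers
#' bind the nearest eligible filament site within the capture range with
#' probability `1 - exp(-k_on * dt)`; free cross-linkers from the reservoir
#' are recruited onto filament segments; membrane-bindable cross-linkers
#' within capture range of the mesh acquire a sliding anchor.
#'
#' @param state A simulation state.
#' @param dt Kinetics time step (s).
#' @param forces Optional output of [net_forces()] (recomputed when `NULL`).
#' @param membrane_binding Allow anchor formation (off during assembly before
#'   membrane coupling is switched on).
#' @return The updated state.
#' @export
crosslinker_kinetics_step <- function(state, dt, forces = NULL,
                                      membrane_binding = TRUE) {
  p <- state$params
  a <- state$acps
  seg <- segment_table(state)
  if (!is.null(forces) && length(forces$spr_owner)) {
    ow <- forces$spr_owner[forces$spr_type %in% c("acp", "anchor")]
    if (length(ow) && max(ow) > nrow(a)) forces <- NULL   # stale after severing
  }
  if (is.null(forces)) forces <- net_forces(state)

  # --- unbinding ---
  if (nrow(a)) {
    arm_F <- matrix(0, nrow(a), 2)
    anch_F <- numeric(nrow(a))
    ft <- forces$spr_tension; fo <- forces$spr_owner; fy <- forces$spr_type
    acp_spr <- fy == "acp"
    arm_F[fo[acp_spr], 1] <- pmax(ft[acp_spr], 0)
    arm_F[fo[acp_spr], 2] <- pmax(ft[acp_spr], 0)
    anch_spr <- fy == "anchor"
    anch_F[fo[anch_spr]] <- pmax(ft[anch_spr], 0)
    # force on an arm bond: arm-arm spring tension; a singly bound anchored
    # arm carries the anchor spring tension instead
    single <- is.na(a$f1) | is.na(a$f2)
    arm_F[single, ] <- pmax(arm_F[single, ], anch_F[single])

    u1 <- !is.na(a$f1) & runif(nrow(a)) < bell_prob(arm_F[, 1], p, dt)
    u2 <- !is.na(a$f2) & runif(nrow(a)) < bell_prob(arm_F[, 2], p, dt)
    anch_rate <- p$k_off0 * exp(pmax(anch_F, 0) * p$anchor_r0_bond / p$kBT)
    ua <- !is.na(a$a_face) & runif(nrow(a)) < 1 - exp(-anch_rate * dt)
    a$f1[u1] <- NA_integer_; a$p1[u1] <- NA_real_
    a$f2[u2] <- NA_integer_; a$p2[u2] <- NA_real_
    # anchor must sit on a bound arm: drop it if its host arm unbound
    host1 <- !is.na(a$a_face) & (u1 & is.na(a$f2))
    ua <- ua | host1 | (!is.na(a$a_face) & is.na(a$f1) & is.na(a$f2))
    a$a_face[ua] <- NA_integer_
    a$a_w1[ua] <- NA_real_; a$a_w2[ua] <- NA_real_; a$a_w3[ua] <- NA_real_
    state$acps <- a
    state <- drop_unbound_acps(state)
    a <- state$acps
  }

  if (!length(seg$a)) return(state)
  occ <- segment_occupancy(state, seg)
  sys_pos <- rbind(state$x)   # filament nodes only; segment indices match
  p_bind <- 1 - exp(-p$k_on * dt)

  # --- second-arm binding of singly bound cross-linkers ---
  if (nrow(a)) {
    single1 <- which(!is.na(a$f1) & is.na(a$f2))
    single2 <- which(is.na(a$f1) & !is.na(a$f2))
    singles <- c(single1, single2)
    if (length(singles)) {
      f_of <- c(a$f1[single1], a$f2[single2])
      p_of <- c(a$p1[single1], a$p2[single2])
      pts <- arc_point(state, f_of, p_of)
      # nearest site on a *different* filament (pairs of filaments only)
      hit <- point_seg_nearest_cpp(pts, sys_pos, seg$a, seg$b, p$capture_range,
                                   seg$fil, as.integer(f_of))
      trial <- runif(length(singles)) < p_bind
      offs <- seg_arc_offsets(seg)
      cand <- which(trial & hit[, 1] > 0)
      if (length(cand)) {
        sidv <- hit[cand, 1]
        cand <- cand[seg$fil[sidv] != f_of[cand]]
        if (length(cand)) {
          sidv <- hit[cand, 1]
          tgt <- (1 - hit[cand, 2]) * sys_pos[seg$a[sidv], , drop = FALSE] +
            hit[cand, 2] * sys_pos[seg$b[sidv], , drop = FALSE]
          blocked <- in_perturbed_cap(state, tgt, "RX")
          cand <- cand[!blocked]
        }
      }
      for (q in cand) {
        sid <- hit[q, 1]
        if (occ[sid] >= p$max_arms_per_seg) next
        newpos <- offs[sid] + hit[q, 2] * seg$rest[sid]
        row <- singles[q]
        if (q <= length(single1)) {
          a$f2[row] <- seg$fil[sid]; a$p2[row] <- newpos
        } else {
          a$f1[row] <- seg$fil[sid]; a$p1[row] <- newpos
        }
        occ[sid] <- occ[sid] + 1L
      }
      state$acps <- a
    }
  }

  # --- first-arm recruitment from the free reservoir ---
  n_free <- state$acp_free_bindable + state$acp_free_plain
  if (n_free > 0) {
    open <- which(occ < p$max_arms_per_seg)
    if (length(open)) {
      n_try <- rbinom(1, length(open), p_bind)
      n_new <- min(n_try, n_free)
      if (n_new > 0) {
        picked <- sample(open, n_new)
        tpos <- runif(n_new)
        pts <- (1 - tpos) * sys_pos[seg$a[picked], , drop = FALSE] +
          tpos * sys_pos[seg$b[picked], , drop = FALSE]
        blocked <- in_perturbed_cap(state, pts, "RX")
        picked <- picked[!blocked]; tpos <- tpos[!blocked]
        n_new <- length(picked)
        if (n_new > 0) {
          bindable <- runif(n_new) < state$acp_free_bindable / n_free
          nb <- sum(bindable)
          nb <- min(nb, state$acp_free_bindable)
          npl <- min(n_new - nb, state$acp_free_plain)
          kinds <- c(rep(TRUE, nb), rep(FALSE, npl))
          n_new <- length(kinds)
          picked <- picked[seq_len(n_new)]; tpos <- tpos[seq_len(n_new)]
          if (n_new > 0) {
            arc0 <- seg_arc_offsets(seg)[picked]
            add <- data.frame(bindable = kinds, f1 = seg$fil[picked],
                              p1 = arc0 + tpos * seg$rest[picked],
                              f2 = NA_integer_, p2 = NA_real_,
                              a_face = NA_integer_, a_w1 = NA_real_,
                              a_w2 = NA_real_, a_w3 = NA_real_)
            state$acps <- rbind(state$acps, add)
            state$acp_free_bindable <- state$acp_free_bindable - nb
            state$acp_free_plain <- state$acp_free_plain - npl
          }
        }
      }
    }
  }

  # --- membrane anchor formation ---
  if (membrane_binding) {
    a <- state$acps
    cand <- which(a$bindable & is.na(a$a_face) & (!is.na(a$f1) | !is.na(a$f2)))
    if (length(cand)) {
      fa <- ifelse(!is.na(a$f1[cand]), a$f1[cand], a$f2[cand])
      pa <- ifelse(!is.na(a$f1[cand]), a$p1[cand], a$p2[cand])
      pts <- arc_point(state, fa, pa)
      prj <- project_to_mesh(state$mesh, pts)
      ok <- prj$dist <= p$capture_range & runif(length(cand)) < p_bind
      if (!is.null(state$perturb) && state$perturb$target == "RC" &&
          state$time >= state$perturb$t_apply) {
        ok <- ok & !(prj$face %in% state$perturb$faces)
      }
      sel <- which(ok)
      if (length(sel)) {
        rows <- cand[sel]
        a$a_face[rows] <- prj$face[sel]
        a$a_w1[rows] <- prj$w[sel, 1]
        a$a_w2[rows] <- prj$w[sel, 2]
        a$a_w3[rows] <- prj$w[sel, 3]
        state$acps <- a
      }
    }
  }
  state
}

# nearest point on the mesh for each query point, via the faces incident to
# the nearest vertex. Returns face id, barycentric weights, distance.
project_to_mesh <- function(mesh, pts) {
  V <- mesh$V
  if (is.null(mesh$vertex_faces)) {
    vf <- vector("list", nrow(V))
    for (f in seq_len(nrow(mesh$F))) {
      for (k in 1:3) {
        v <- mesh$F[f, k]
        vf[[v]] <- c(vf[[v]], f)
      }
    }
    mesh$vertex_faces <- vf
  }
  n <- nrow(pts)
  face <- integer(n); w <- matrix(0, n, 3); dist <- numeric(n)
  for (q in seq_len(n)) {
    p0 <- pts[q, ]
    d2 <- (V[, 1] - p0[1])^2 + (V[, 2] - p0[2])^2 + (V[, 3] - p0[3])^2
    nv <- which.min(d2)
    best <- Inf; bf <- 0L; bw <- c(1, 0, 0)
    for (f in mesh$vertex_faces[[nv]]) {
      tri <- mesh$F[f, ]
      res <- closest_point_triangle(p0, V[tri[1], ], V[tri[2], ], V[tri[3], ])
      if (res$dist < best) { best <- res$dist; bf <- f; bw <- res$w }
    }
    face[q] <- bf; w[q, ] <- bw; dist[q] <- best
  }
  list(face = face, w = w, dist = dist)
}

closest_point_triangle <- function(p, a, b, c) {
  # Ericson, RTCD 5.1.5
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(w = c(1, 0, 0), dist = sqrt(sum((p - a)^2))))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(w = c(0, 1, 0), dist = sqrt(sum((p - b)^2))))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(list(w = c(1 - v, v, 0), dist = sqrt(sum((p - a - v * ab)^2))))
  }
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(w = c(0, 0, 1), dist = sqrt(sum((p - c)^2))))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    v <- d2 / (d2 - d6)
    return(list(w = c(1 - v, 0, v), dist = sqrt(sum((p - a - v * ac)^2))))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    v <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    q <- b + v * (c - b)
    return(list(w = c(0, 1 - v, v), dist = sqrt(sum((p - q)^2))))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; u <- vc * denom
  q <- a + ab * v + ac * u
  list(w = c(1 - v - u, v, u), dist = sqrt(sum((p - q)^2)))
}

#' Motor stepping and binding kinetics
#'
#' Bound heads advance toward the barbed end by `step_size` at rate
#' `k_walk0 * max(0, 1 - F_parallel / F_stall_arm)` where `F_stall_arm =
#' F_stall * heads_per_side` is the ensemble stall force of one side of the
#' mini-filament; heads reaching the barbed end unbind, as do heads drawn by
#' Bell kinetics. Free heads bind the nearest filament within capture range.
#' No stepping occurs before `t_activate`.
#'
#' @inheritParams crosslinker_kinetics_step
#' @return The updated state.
#' @export
motor_step <- function(state, dt, forces = NULL) {
  p <- state$params
  m <- state$motors$df
  if (!nrow(m)) return(state)
  if (is.null(forces)) forces <- net_forces(state)
  active <- activation_schedule(state$time, p)
  flen <- fil_lengths(state)
  seg <- segment_table(state)
  ft <- forces$spr_tension; fo <- forces$spr_owner; fy <- forces$spr_type
  f_stall_arm <- p$F_stall * p$heads_per_side

  for (h in 1:2) {
    fcol <- paste0("h", h, "_fil"); pcol <- paste0("h", h, "_pos")
    Fcol <- paste0("h", h, "_F")
    htag <- paste0("head", h)
    tension <- numeric(nrow(m))
    tension[fo[fy == htag]] <- pmax(ft[fy == htag], 0)
    m[[Fcol]] <- tension
    bound <- which(!is.na(m[[fcol]]))
    if (length(bound) && active) {
      # load along the barbed-end direction
      loc <- arc_locate(state, m[[fcol]][bound], m[[pcol]][bound])
      uhat <- state$x[loc$j, , drop = FALSE] - state$x[loc$i, , drop = FALSE]
      uhat <- uhat / pmax(sqrt(rowSums(uhat^2)), 1e-12)
      ends <- state$motors$ends[2 * (bound - 1) + h, , drop = FALSE]
      att <- (1 - loc$w) * state$x[loc$i, , drop = FALSE] +
        loc$w * state$x[loc$j, , drop = FALSE]
      sep <- ends - att
      dist <- pmax(sqrt(rowSums(sep^2)), 1e-12)
      fvec <- (tension[bound] / dist) * sep       # force on head, toward end
      load <- pmax(0, -rowSums(fvec * uhat))
      kw <- p$k_walk0 * pmax(0, 1 - load / f_stall_arm)
      nstep <- stats::rpois(length(bound), kw * dt)
      newp <- m[[pcol]][bound] + nstep * p$step_size
      offend <- newp >= flen[as.character(m[[fcol]][bound])] - 1e-9
      m[[pcol]][bound] <- pmin(newp, flen[as.character(m[[fcol]][bound])])
      m[[fcol]][bound][offend] <- NA_integer_
      m[[pcol]][bound][offend] <- NA_real_
    }
    # Bell unbinding
    bound <- which(!is.na(m[[fcol]]))
    if (length(bound)) {
      ub <- runif(length(bound)) < bell_prob(tension[bound], p, dt, p$motor_k_off0)
      m[[fcol]][bound][ub] <- NA_integer_
      m[[pcol]][bound][ub] <- NA_real_
    }
    # binding of free heads
    free <- which(is.na(m[[fcol]]))
    if (length(free) && length(seg$a)) {
      ends <- state$motors$ends[2 * (free - 1) + h, , drop = FALSE]
      hit <- point_seg_nearest_cpp(ends, state$x, seg$a, seg$b, p$capture_range)
      trial <- runif(length(free)) < (1 - exp(-p$k_on * dt))
      offs <- seg_arc_offsets(seg)
      ok <- which(trial & hit[, 1] > 0)
      if (length(ok)) {
        sid <- hit[ok, 1]
        m[[fcol]][free[ok]] <- seg$fil[sid]
        m[[pcol]][free[ok]] <- offs[sid] + hit[ok, 2] * seg$rest[sid]
      }
    }
  }
  state$motors$df <- m
  state
}
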