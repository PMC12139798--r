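# Assemble the flat arrays consumed by the C++ force kernel.
#
# DOF layout in `pos`: filament nodes, then motor backbone ends, then mesh
# vertices. Springs are generic: each endpoint is a weighted combination of
# up to 3 DOF rows (2 for a point on a filament segment, 1 for a motor end,
# 3 for a barycentric point on a mesh face). By convention the B side of a
# membrane-anchor spring is the anchor, so the per-spring force returned for
# side B drives the tangential sliding of anchor points.

compile_system <- function(state) {
  p <- state$params
  nfil <- nrow(state$x)
  nmot <- nrow(state$motors$ends)
  nmesh <- nrow(state$mesh$V)
  pos <- rbind(state$x, state$motors$ends, state$mesh$V)
  mot_off <- nfil
  mesh_off <- nfil + nmot

  seg <- segment_table(state)
  trip <- bend_triples(state)

  ia <- list(); wa <- list(); ib <- list(); wb <- list()
  kk <- list(); rr <- list(); tag <- list(); owner <- list()
  blk <- 0L
  add_block <- function(iA, wA, iB, wB, k, rest, type, own) {
    blk <<- blk + 1L
    ia[[blk]] <<- iA; wa[[blk]] <<- wA; ib[[blk]] <<- iB; wb[[blk]] <<- wB
    n <- nrow(iA)
    kk[[blk]] <<- rep_len(k, n); rr[[blk]] <<- rep_len(rest, n)
    tag[[blk]] <<- rep_len(type, n); owner[[blk]] <<- own
  }

  # cross-linker arm-arm springs and membrane anchors
  a <- state$acps
  if (nrow(a)) {
    both <- which(!is.na(a$f1) & !is.na(a$f2))
    if (length(both)) {
      l1 <- arc_locate(state, a$f1[both], a$p1[both])
      l2 <- arc_locate(state, a$f2[both], a$p2[both])
      add_block(cbind(l1$i, l1$j, 0L), cbind(1 - l1$w, l1$w, 0),
                cbind(l2$i, l2$j, 0L), cbind(1 - l2$w, l2$w, 0),
                p$k_acp, p$acp_rest, "acp", both)
    }
    anch <- which(!is.na(a$a_face))
    if (length(anch)) {
      # anchor attaches to arm 1 if bound, else arm 2
      fa <- ifelse(!is.na(a$f1[anch]), a$f1[anch], a$f2[anch])
      pa <- ifelse(!is.na(a$f1[anch]), a$p1[anch], a$p2[anch])
      la <- arc_locate(state, fa, pa)
      Fm <- state$mesh$F[a$a_face[anch], , drop = FALSE]
      add_block(cbind(la$i, la$j, 0L), cbind(1 - la$w, la$w, 0),
                mesh_off + Fm,
                cbind(a$a_w1[anch], a$a_w2[anch], a$a_w3[anch]),
                p$k_anchor, p$anchor_rest, "anchor", anch)
    }
  }

  # motor backbones (stiff spring keeping the mini-filament length) and heads
  m <- state$motors$df
  if (nrow(m)) {
    nm <- nrow(m)
    e1 <- mot_off + 2L * seq_len(nm) - 1L
    e2 <- mot_off + 2L * seq_len(nm)
    z3 <- function(v) cbind(v, 0L, 0L)
    zw <- function(n) cbind(rep(1, n), 0, 0)
    add_block(z3(e1), zw(nm), z3(e2), zw(nm),
              p$k_backbone, p$motor_backbone, "backbone", seq_len(nm))
    for (h in 1:2) {
      bnd <- which(!is.na(m[[paste0("h", h, "_fil")]]))
      if (length(bnd)) {
        lh <- arc_locate(state, m[[paste0("h", h, "_fil")]][bnd],
                         m[[paste0("h", h, "_pos")]][bnd])
        ends <- if (h == 1) e1[bnd] else e2[bnd]
        add_block(z3(ends), zw(length(bnd)),
                  cbind(lh$i, lh$j, 0L), cbind(1 - lh$w, lh$w, 0),
                  p$k_motor, p$motor_rest, paste0("head", h), bnd)
      }
    }
  }

  ia <- do.call(rbind, ia); wa <- do.call(rbind, wa)
  ib <- do.call(rbind, ib); wb <- do.call(rbind, wb)
  kk <- unlist(kk); rr <- unlist(rr)
  tag <- unlist(tag); owner <- unlist(owner)
  ns <- length(kk)
  list(
    pos = pos, mot_off = mot_off, mesh_off = mesh_off,
    nfil = nfil, nmot = nmot, nmesh = nmesh,
    seg_a = seg$a, seg_b = seg$b, seg_rest = seg$rest, seg_fil = seg$fil,
    bend = trip,
    spr_ia = if (ns) ia else matrix(0L, 0, 3),
    spr_wa = if (ns) wa else matrix(0, 0, 3),
    spr_ib = if (ns) ib else matrix(0L, 0, 3),
    spr_wb = if (ns) wb else matrix(0, 0, 3),
    spr_k = if (ns) kk else numeric(0),
    spr_rest = if (ns) rr else numeric(0),
    spr_type = if (ns) tag else character(0),
    spr_owner = if (ns) owner else integer(0),
    faces = state$mesh$F + mesh_off,
    ref_area = state$mesh$ref_area,
    edges = state$mesh$edges + mesh_off,
    ref_vol = state$mesh$ref_volume
  )
}

bend_triples <- function(state) {
  n <- nrow(state$x)
  if (n < 3) return(matrix(0L, 0, 3))
  id <- state$fil_id
  j <- which(id[-c(1, n)] == id[-c(n - 1, n)] &
               id[-c(1, n)] == id[-c(1, 2)]) + 1L
  cbind(j - 1L, j, j + 1L)
}

# candidate pair lists for the excluded-volume terms, with a skin so that
# lists stay valid between rebuilds
build_pairs <- function(sys, p, skin = 0.1) {
  r_rep <- p$rep_range_scale * p$d_actin
  rp <- if (length(sys$seg_a)) {
    seg_pairs_cpp(sys$pos, sys$seg_a, sys$seg_b, r_rep + skin)
  } else matrix(0L, 0, 2)
  mp <- if (length(sys$seg_a) && sys$nmesh) {
    vert_seg_pairs_cpp(sys$pos, sys$mesh_off + seq_len(sys$nmesh),
                       sys$seg_a, sys$seg_b, mem_rep_range(p) + skin)
  } else matrix(0L, 0, 2)
  list(rep = rp, mem = mp)
}

mem_rep_range <- function(p) 0.5 * p$seg_len

# One full force evaluation through the C++ kernel.
eval_forces <- function(sys, p, pairs, membrane_active = TRUE) {
  out <- net_forces_cpp(
    sys$pos, sys$seg_a, sys$seg_b, sys$seg_rest, p$k_ext,
    sys$bend, p$Lp_actin * p$kBT / p$seg_len,
    pairs$rep, p$rep_range_scale * p$d_actin, p$k_rep,
    sys$spr_ia, sys$spr_wa, sys$spr_ib, sys$spr_wb, sys$spr_k, sys$spr_rest,
    sys$faces, sys$ref_area, if (membrane_active) p$k_area else 0,
    sys$edges, if (membrane_active) p$k_bend_mem else 0,
    sys$ref_vol, if (membrane_active) p$k_vol else 0,
    pairs$mem, mem_rep_range(p), p$k_mem_rep)
  out
}

#' Evaluate the deterministic force field of a state
#'
#' Computes all force terms (filament extension and bending, excluded-volume
#' repulsion, cross-linker/motor/anchor springs, membrane area elasticity,
#' dihedral bending and volume penalty) and returns them split by component.
#'
#' @param state A simulation state.
#' @param membrane_active If `FALSE`, membrane elastic terms are switched off
#'   (used while the membrane is held rigid during network assembly).
#' @return A list with `fil`, `motors`, `mesh` force matrices (pN),
#'   `seg_tension` (pN, positive = stretched) per filament segment,
#'   `spr_tension` and `spr_type` per spring, the force on each spring's
#'   membrane-side endpoint (`spr_fB`), and the current enclosed `volume`.
#' @export
net_forces <- function(state, membrane_active = TRUE) {
  sys <- compile_system(state)
  pairs <- build_pairs(sys, state$params, skin = 0)
  out <- eval_forces(sys, state$params, pairs, membrane_active)
  F <- out$F
  list(
    fil = F[seq_len(sys$nfil), , drop = FALSE],
    motors = F[sys$mot_off + seq_len(sys$nmot), , drop = FALSE],
    mesh = F[sys$mesh_off + seq_len(sys$nmesh), , drop = FALSE],
    seg_tension = out$seg_tension,
    spr_tension = out$spr_tension, spr_type = sys$spr_type,
    spr_owner = sys$spr_owner, spr_fB = out$spr_fB,
    volume = out$volume, face_area = out$face_area
  )
}
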