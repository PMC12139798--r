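# Pure-R potential-energy implementation. This mirrors the potentials whose
# exact negative gradients the C++ kernel returns, and is kept independent of
# it: the test suite checks force = -grad(energy) by central finite
# differences on small fixtures.

seg_seg_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  cc <- sum(d1 * r); b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-14) min(max((b * f - cc * e) / denom, 0), 1) else 0
  t <- if (e > 1e-14) (b * s + f) / e else 0
  if (t < 0) { t <- 0; s <- if (a > 1e-14) min(max(-cc / a, 0), 1) else 0 }
  if (t > 1) { t <- 1; s <- if (a > 1e-14) min(max((b - cc) / a, 0), 1) else 0 }
  sqrt(sum((p1 + s * d1 - p2 - t * d2)^2))
}

point_seg_distance <- function(p, a, b) {
  d <- b - a
  dd <- sum(d * d)
  t <- if (dd > 1e-14) min(max(sum((p - a) * d) / dd, 0), 1) else 0
  sqrt(sum((p - a - t * d)^2))
}

dihedral_angle <- function(x1, x2, x3, x4) {
  e0 <- x2 - x1
  n1 <- pracma_cross(e0, x3 - x1)
  n2 <- pracma_cross(x4 - x1, e0)
  l0 <- sqrt(sum(e0^2))
  sin_t <- sum(pracma_cross(n1, n2) * e0) /
    (sqrt(sum(n1^2)) * sqrt(sum(n2^2)) * l0)
  cos_t <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  atan2(sin_t, cos_t)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Total potential energy of a compiled system at positions `pos`.
energy_system <- function(pos, sys, p, pairs, membrane_active = TRUE) {
  E <- 0
  if (length(sys$seg_a)) {
    len <- sqrt(rowSums((pos[sys$seg_b, , drop = FALSE] -
                           pos[sys$seg_a, , drop = FALSE])^2))
    E <- E + 0.5 * p$k_ext * sum((len - sys$seg_rest)^2)
  }
  if (nrow(sys$bend)) {
    kappa <- p$Lp_actin * p$kBT / p$seg_len
    for (r in seq_len(nrow(sys$bend))) {
      a <- pos[sys$bend[r, 1], ] - pos[sys$bend[r, 2], ]
      b <- pos[sys$bend[r, 3], ] - pos[sys$bend[r, 2], ]
      cosA <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      theta <- pi - acos(min(max(cosA, -1), 1))
      E <- E + 0.5 * kappa * theta^2
    }
  }
  r_rep <- p$rep_range_scale * p$d_actin
  if (nrow(pairs$rep)) {
    for (r in seq_len(nrow(pairs$rep))) {
      i <- pairs$rep[r, 1]; j <- pairs$rep[r, 2]
      d <- seg_seg_distance(pos[sys$seg_a[i], ], pos[sys$seg_b[i], ],
                            pos[sys$seg_a[j], ], pos[sys$seg_b[j], ])
      if (d < r_rep) E <- E + 0.5 * p$k_rep * (r_rep - d)^2
    }
  }
  if (length(sys$spr_k)) {
    for (s in seq_along(sys$spr_k)) {
      iA <- sys$spr_ia[s, ]; iB <- sys$spr_ib[s, ]
      pA <- colSums(sys$spr_wa[s, iA > 0] * pos[iA[iA > 0], , drop = FALSE])
      pB <- colSums(sys$spr_wb[s, iB > 0] * pos[iB[iB > 0], , drop = FALSE])
      len <- sqrt(sum((pB - pA)^2))
      E <- E + 0.5 * sys$spr_k[s] * (len - sys$spr_rest[s])^2
    }
  }
  if (membrane_active && nrow(sys$faces)) {
    A <- face_areas(pos, sys$faces)
    E <- E + 0.5 * p$k_area * sum((A - sys$ref_area)^2 / sys$ref_area)
    V <- mesh_volume(pos, sys$faces)
    E <- E + 0.5 * p$k_vol * (V - sys$ref_vol)^2 / sys$ref_vol
    if (p$k_bend_mem > 0) {
      for (e in seq_len(nrow(sys$edges))) {
        th <- dihedral_angle(pos[sys$edges[e, 1], ], pos[sys$edges[e, 2], ],
                             pos[sys$edges[e, 3], ], pos[sys$edges[e, 4], ])
        E <- E + 0.5 * p$k_bend_mem * th^2
      }
    }
  }
  if (nrow(pairs$mem)) {
    r_m <- mem_rep_range(p)
    for (r in seq_len(nrow(pairs$mem))) {
      iv <- pairs$mem[r, 1]; js <- pairs$mem[r, 2]
      d <- point_seg_distance(pos[iv, ], pos[sys$seg_a[js], ],
                              pos[sys$seg_b[js], ])
      if (d < r_m) E <- E + 0.5 * p$k_mem_rep * (r_m - d)^2
    }
  }
  E
}

#' Total potential energy of a state
#'
#' Sum of all declared potentials: harmonic segment extension, angular
#' filament bending with stiffness `Lp_actin * kBT / seg_len`, pairwise
#' harmonic excluded-volume repulsion, cross-linker/anchor/motor springs,
#' membrane area elasticity, dihedral bending, volume penalty and
#' membrane-filament repulsion. Implemented independently of the force
#' kernel; forces are the exact negative gradient of this quantity.
#'
#' @param state A simulation state.
#' @param membrane_active If `FALSE`, membrane elastic terms are excluded.
#' @return Energy in pN um.
#' @export
potential_energy <- function(state, membrane_active = TRUE) {
  sys <- compile_system(state)
  pairs <- build_pairs(sys, state$params, skin = 0)
  energy_system(sys$pos, sys, state$params, pairs, membrane_active)
}

# central finite-difference gradient of the system energy (test oracle)
fd_gradient <- function(pos, sys, p, pairs, membrane_active = TRUE, h = 1e-6) {
  G <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      G[i, c] <- (energy_system(pp, sys, p, pairs, membrane_active) -
                    energy_system(pm, sys, p, pairs, membrane_active)) / (2 * h)
    }
  }
  G
}
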