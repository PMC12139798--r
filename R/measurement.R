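# Observables: cutting-plane tension estimators, bleb detection and tracking,
# initiation-mechanism and morphology classification, deformation magnitude,
# density profiles and motor orientation angles.

#' Least-squares sphere fit with outlier trimming
#'
#' Algebraic least-squares sphere through a vertex cloud, iteratively
#' refitted after discarding vertices whose radial residual exceeds
#' `k * mad` (robust to protruding bleb regions).
#'
#' @param V n x 3 vertex matrix.
#' @param iters Trimming iterations.
#' @param k Residual cut in units of the median absolute deviation.
#' @return list(center, radius, keep) where `keep` flags inlier vertices.
#' @export
fit_sphere <- function(V, iters = 3, k = 4) {
  keep <- rep(TRUE, nrow(V))
  cen <- c(0, 0, 0); R <- 1
  for (it in seq_len(iters)) {
    W <- V[keep, , drop = FALSE]
    if (nrow(W) < 10) break
    A <- cbind(2 * W, 1)
    b <- rowSums(W^2)
    coef <- qr.solve(A, b)
    cen <- coef[1:3]
    R <- sqrt(coef[4] + sum(cen^2))
    res <- sqrt(rowSums((V - matrix(cen, nrow(V), 3, byrow = TRUE))^2)) - R
    s <- stats::mad(res[keep])
    if (!is.finite(s) || s < 1e-9) break
    keep <- abs(res) < k * s
    if (sum(keep) < 0.3 * nrow(V)) { keep <- rep(TRUE, nrow(V)); break }
  }
  if (!is.finite(R) || R <= 0) stop("sphere fit failed")
  list(center = cen, radius = R, keep = keep)
}

# per-face membrane tension (pN/um) from the local area strain
face_tension <- function(state, face_area = NULL) {
  if (is.null(face_area)) face_area <- face_areas(state$mesh$V, state$mesh$F)
  state$params$k_area * (face_area - state$mesh$ref_area) / state$mesh$ref_area
}

# length of the intersection of plane (point c, normal nh) with a triangle
tri_plane_len <- function(a, b, cc, c0, nh) {
  d <- c(sum((a - c0) * nh), sum((b - c0) * nh), sum((cc - c0) * nh))
  P <- rbind(a, b, cc)
  pts <- NULL
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    d1 <- d[e[1]]; d2 <- d[e[2]]
    if ((d1 > 0) != (d2 > 0)) {
      t <- d1 / (d1 - d2)
      pts <- rbind(pts, P[e[1], ] + t * (P[e[2], ] - P[e[1], ]))
    }
  }
  if (is.null(pts) || nrow(pts) < 2) 0 else sqrt(sum((pts[1, ] - pts[2, ])^2))
}

#' Global network and membrane tension
#'
#' Cutting-plane estimator: for each of several great-circle planes through
#' the membrane centre, the tensile axial force components of network
#' segments crossing the plane (respectively the in-plane tensions of
#' membrane faces intersected by it, weighted by intersection length) are
#' summed and divided by the cut contour length `2 pi R` of the best-fit
#' sphere; the estimates are averaged over planes. Units pN/um.
#'
#' @param state A simulation state.
#' @param planes Matrix of plane normals (rows); default the three coordinate
#'   planes.
#' @param forces Optional precomputed [net_forces()] output.
#' @return list(time, network, membrane, scope, per_plane).
#' @export
global_tension <- function(state, planes = diag(3), forces = NULL) {
  if (is.null(forces)) {
    forces <- if (length(segment_table(state)$a) || nrow(state$mesh$V)) {
      net_forces(state)
    } else NULL
  }
  fs <- fit_sphere(state$mesh$V)
  c0 <- fs$center; R <- fs$radius
  seg <- segment_table(state)
  segT <- if (!is.null(forces)) pmax(forces$seg_tension, 0) else numeric(0)
  fa <- if (!is.null(forces) && !is.null(forces$face_area)) forces$face_area else NULL
  gamma_f <- face_tension(state, fa)
  Fm <- state$mesh$F; V <- state$mesh$V
  net <- mem <- numeric(nrow(planes))
  for (q in seq_len(nrow(planes))) {
    nh <- planes[q, ] / sqrt(sum(planes[q, ]^2))
    if (length(seg$a)) {
      da <- drop((state$x[seg$a, , drop = FALSE] -
                    matrix(c0, length(seg$a), 3, byrow = TRUE)) %*% nh)
      db <- drop((state$x[seg$b, , drop = FALSE] -
                    matrix(c0, length(seg$b), 3, byrow = TRUE)) %*% nh)
      cross_seg <- which((da > 0) != (db > 0))
      if (length(cross_seg)) {
        u <- state$x[seg$b[cross_seg], , drop = FALSE] -
          state$x[seg$a[cross_seg], , drop = FALSE]
        u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
        net[q] <- sum(segT[cross_seg] * abs(drop(u %*% nh)))
      }
    }
    dv <- drop((V - matrix(c0, nrow(V), 3, byrow = TRUE)) %*% nh)
    sgn <- dv > 0
    fcross <- which(sgn[Fm[, 1]] != sgn[Fm[, 2]] | sgn[Fm[, 1]] != sgn[Fm[, 3]])
    tot <- 0
    for (f in fcross) {
      l <- tri_plane_len(V[Fm[f, 1], ], V[Fm[f, 2], ], V[Fm[f, 3], ], c0, nh)
      tot <- tot + gamma_f[f] * l
    }
    mem[q] <- tot
    net[q] <- net[q] / (2 * pi * R)
    mem[q] <- mem[q] / (2 * pi * R)
  }
  list(time = state$time, network = mean(net), membrane = mean(mem),
       scope = "global", per_plane = cbind(network = net, membrane = mem))
}

#' Local tension in a cap window around a membrane region
#'
#' Same estimator as [global_tension()] restricted to a spherical-cap window
#' around the centroid direction of `region` (default half-angle 30 deg):
#' planes contain the cap axis, only crossings inside the cap (and, for the
#' network, within the cortical shell beneath it) are counted, and the
#' contour length is the arc of the cut inside the cap.
#'
#' @param state A simulation state.
#' @param region Integer vector of face indices (nonempty).
#' @param shell Radial depth of the cortical layer counted for the network
#'   (um).
#' @param cap_angle Cap half-angle (degrees).
#' @param n_planes Number of axial planes.
#' @param forces Optional precomputed force evaluation.
#' @return list(time, network, membrane, scope).
#' @export
local_tension <- function(state, region, shell = state$params$shell_thickness,
                          cap_angle = 30, n_planes = 4, forces = NULL) {
  if (!length(region)) stop("empty region")
  if (is.null(forces)) forces <- net_forces(state)
  fs <- fit_sphere(state$mesh$V)
  c0 <- fs$center; R <- fs$radius
  V <- state$mesh$V; Fm <- state$mesh$F
  fc <- (V[Fm[region, 1], , drop = FALSE] + V[Fm[region, 2], , drop = FALSE] +
           V[Fm[region, 3], , drop = FALSE]) / 3
  axis <- colMeans(fc) - c0
  axis <- axis / sqrt(sum(axis^2))
  alpha <- cap_angle * pi / 180
  # orthonormal frame around the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- pracma_cross(axis, ref); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- pracma_cross(axis, u1)
  in_cap <- function(pts) {
    d <- pts - matrix(c0, nrow(pts), 3, byrow = TRUE)
    r <- sqrt(rowSums(d^2))
    ang <- acos(pmin(pmax(drop(d %*% axis) / pmax(r, 1e-12), -1), 1))
    list(inside = ang <= alpha, r = r)
  }
  seg <- segment_table(state)
  segT <- pmax(forces$seg_tension, 0)
  gamma_f <- face_tension(state, forces$face_area)
  net <- mem <- numeric(n_planes)
  for (q in seq_len(n_planes)) {
    phi <- pi * (q - 1) / n_planes
    nh <- cos(phi) * u1 + sin(phi) * u2   # plane contains the axis
    if (length(seg$a)) {
      da <- drop((state$x[seg$a, , drop = FALSE] -
                    matrix(c0, length(seg$a), 3, byrow = TRUE)) %*% nh)
      db <- drop((state$x[seg$b, , drop = FALSE] -
                    matrix(c0, length(seg$b), 3, byrow = TRUE)) %*% nh)
      cross_seg <- which((da > 0) != (db > 0))
      if (length(cross_seg)) {
        t <- da[cross_seg] / (da[cross_seg] - db[cross_seg])
        pt <- (1 - t) * state$x[seg$a[cross_seg], , drop = FALSE] +
          t * state$x[seg$b[cross_seg], , drop = FALSE]
        ic <- in_cap(pt)
        ok <- ic$inside & ic$r >= R - shell
        if (any(ok)) {
          u <- state$x[seg$b[cross_seg[ok]], , drop = FALSE] -
            state$x[seg$a[cross_seg[ok]], , drop = FALSE]
          u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
          net[q] <- sum(segT[cross_seg[ok]] * abs(drop(u %*% nh)))
        }
      }
    }
    dv <- drop((V - matrix(c0, nrow(V), 3, byrow = TRUE)) %*% nh)
    sgn <- dv > 0
    fcross <- which(sgn[Fm[, 1]] != sgn[Fm[, 2]] | sgn[Fm[, 1]] != sgn[Fm[, 3]])
    fcen <- (V[Fm[fcross, 1], , drop = FALSE] + V[Fm[fcross, 2], , drop = FALSE] +
               V[Fm[fcross, 3], , drop = FALSE]) / 3
    if (length(fcross)) {
      ic <- in_cap(fcen)
      tot <- 0
      for (w in which(ic$inside)) {
        f <- fcross[w]
        tot <- tot + gamma_f[f] *
          tri_plane_len(V[Fm[f, 1], ], V[Fm[f, 2], ], V[Fm[f, 3], ], c0, nh)
      }
      mem[q] <- tot
    }
    arc <- 2 * alpha * R
    net[q] <- net[q] / arc
    mem[q] <- mem[q] / arc
  }
  list(time = state$time, network = mean(net), membrane = mean(mem),
       scope = "local")
}

#' Detect bleb-like protrusions on a membrane mesh
#'
#' Fits a sphere to the main body (robust to outliers), finds connected
#' components of vertices protruding beyond `fit radius + height`, and keeps
#' a component as a bleb iff its boundary ring contains negative mean
#' curvature (a neck) and its diameter (max pairwise vertex distance) is at
#' least `cutoff_diameter` (default 0.8 um, below which bulges are ignored).
#'
#' @param mesh A `membrane_mesh` (or list with `V`, `F`).
#' @param cutoff_diameter Minimum bleb diameter (um).
#' @param height Protrusion threshold above the fitted radius (um).
#' @return List of blebs: each `list(vertices, faces, diameter, centroid_dir,
#'   height)`.
#' @export
detect_blebs <- function(mesh, cutoff_diameter = 0.8, height = 0.15) {
  V <- mesh$V; Fm <- mesh$F
  fs <- fit_sphere(V)
  r <- sqrt(rowSums((V - matrix(fs$center, nrow(V), 3, byrow = TRUE))^2))
  prot <- r > fs$radius + height
  if (!any(prot)) return(list())
  # connected components over mesh edges
  e <- rbind(Fm[, 1:2], Fm[, 2:3], Fm[, c(3, 1)])
  e <- e[prot[e[, 1]] & prot[e[, 2]], , drop = FALSE]
  comp <- seq_len(nrow(V)); comp[!prot] <- 0L
  idx <- which(prot)
  lab <- stats::setNames(seq_along(idx), idx)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      a <- lab[[as.character(e[k, 1])]]; b <- lab[[as.character(e[k, 2])]]
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  H <- mean_curvature(V, Fm)
  # vertex adjacency for boundary rings
  adj_e <- rbind(Fm[, 1:2], Fm[, 2:3], Fm[, c(3, 1)])
  blebs <- list()
  for (rt in unique(roots)) {
    verts <- idx[roots == rt]
    W <- V[verts, , drop = FALSE]
    diam <- if (length(verts) > 1) max(stats::dist(W)) else 0
    if (diam < cutoff_diameter) next
    nb <- unique(c(adj_e[adj_e[, 1] %in% verts, 2],
                   adj_e[adj_e[, 2] %in% verts, 1]))
    ring <- setdiff(nb, verts)
    if (!length(ring) || min(H[ring]) >= 0) next
    faces <- which(Fm[, 1] %in% verts | Fm[, 2] %in% verts | Fm[, 3] %in% verts)
    cen <- colMeans(W) - fs$center
    blebs[[length(blebs) + 1]] <- list(
      vertices = verts, faces = faces, diameter = diam,
      centroid_dir = cen / sqrt(sum(cen^2)),
      height = max(r[verts]) - fs$radius)
  }
  blebs
}

#' Track blebs across trajectory snapshots
#'
#' Per-snapshot detections are linked into tracks when consecutive face sets
#' overlap with Jaccard index > 0.3; each track records its onset time,
#' maximum diameter and the face set at onset.
#'
#' @param traj A `cortosim_trajectory`.
#' @return List of tracks: `list(onset, faces, vertices, max_diameter,
#'   centroid_dir, snapshots)`.
#' @export
track_blebs <- function(traj) {
  p <- traj$params
  tracks <- list()
  active <- list()   # index into tracks
  for (s in seq_along(traj$snapshots)) {
    sn <- traj$snapshots[[s]]
    det <- detect_blebs(list(V = sn$V, F = sn$F), p$bleb_cutoff, p$bleb_height)
    matched <- rep(FALSE, length(active))
    for (b in det) {
      best <- 0; bi <- 0
      for (ai in seq_along(active)) {
        tr <- tracks[[active[[ai]]]]
        jac <- length(intersect(tr$faces, b$faces)) /
          length(union(tr$faces, b$faces))
        if (jac > best) { best <- jac; bi <- ai }
      }
      if (best > 0.3) {
        ti <- active[[bi]]
        matched[bi] <- TRUE
        tracks[[ti]]$faces <- b$faces
        tracks[[ti]]$vertices <- b$vertices
        tracks[[ti]]$max_diameter <- max(tracks[[ti]]$max_diameter, b$diameter)
        tracks[[ti]]$snapshots <- c(tracks[[ti]]$snapshots, s)
      } else {
        tracks[[length(tracks) + 1]] <- list(
          onset = sn$t, faces = b$faces, vertices = b$vertices,
          onset_faces = b$faces, max_diameter = b$diameter,
          centroid_dir = b$centroid_dir, snapshots = s)
        active[[length(active) + 1]] <- length(tracks)
        matched <- c(matched, TRUE)
      }
    }
    active <- active[matched]
  }
  tracks
}

#' Deformation magnitude Lmax / Dinit
#'
#' Maximum caliper width of the membrane over the trajectory divided by the
#' initial diameter; >= 1 for a trajectory starting from a sphere and
#' invariant under global rotations.
#'
#' @param traj A `cortosim_trajectory` or list of snapshots.
#' @return Scalar ratio.
#' @export
deformation_magnitude <- function(traj) {
  snaps <- if (inherits(traj, "cortosim_trajectory")) traj$snapshots else traj
  if (length(snaps) < 1) stop("need at least one snapshot")
  Dinit <- max_caliper(snaps[[1]]$V)
  Lmax <- max(vapply(snaps, function(s) max_caliper(s$V), 0))
  Lmax / Dinit
}

#' Four-way morphology classification
#'
#' `MultipleBlebs` if at least two distinct bleb tracks occurred (simultaneous
#' or cumulative), `SingleBleb` for exactly one, otherwise `WeakDeformation`
#' if `Lmax/Dinit` exceeds `weak_threshold` and `NoDeformation` below it.
#'
#' @param traj A `cortosim_trajectory`.
#' @param weak_threshold Deformation ratio separating weak deformation from
#'   none (default 1.05).
#' @return One of `"NoDeformation"`, `"WeakDeformation"`, `"SingleBleb"`,
#'   `"MultipleBlebs"`.
#' @export
classify_morphology <- function(traj, weak_threshold = traj$params$weak_threshold) {
  tracks <- track_blebs(traj)
  n <- length(tracks)
  if (n >= 2) return("MultipleBlebs")
  if (n == 1) return("SingleBleb")
  if (deformation_magnitude(traj) > weak_threshold) return("WeakDeformation")
  "NoDeformation"
}

#' Classify the initiation mechanism of a bleb
#'
#' Around the bleb's onset, compares the cortical network density beneath the
#' bleb region with its pre-onset value and measures the membrane-network
#' gap. `"Rupture"`: density collapsed below `25%` of the pre-onset mean with
#' at least one severing event logged beneath the region within the window.
#' `"Detachment"`: density retained (`>= 75%`) while the cortex receded by
#' more than twice the anchor rest length. Otherwise `"Undetermined"`.
#'
#' @param traj A `cortosim_trajectory`.
#' @param bleb A track from [track_blebs()].
#' @param window Half-window around onset (s).
#' @return `"Rupture"`, `"Detachment"` or `"Undetermined"`.
#' @export
classify_initiation <- function(traj, bleb, window = 5) {
  p <- traj$params
  onset <- bleb$onset
  times <- vapply(traj$snapshots, `[[`, 0, "t")
  pre <- which(times < onset & times >= onset - window - p$snapshot_every)
  post <- which(times >= onset & times <= onset + window)
  if (!length(pre) || !length(post)) stop("missing snapshots around bleb onset")
  axis <- bleb$centroid_dir
  # one consistent support region for both measurements: the cone under the
  # bleb, at least as wide as the density window
  cone <- max(0.6, cone_angle(bleb, traj))
  cone_density <- function(sn) {
    fs <- fit_sphere(sn$V)
    seg_len_in_cone(sn, axis, fs, p, cone = cone)
  }
  dpre <- mean(vapply(traj$snapshots[pre], cone_density, 0))
  dpost <- min(vapply(traj$snapshots[post], cone_density, 0))
  ratio <- if (dpre > 0) dpost / dpre else 1
  # severing events beneath the region in the window
  ev <- traj$events
  sev <- FALSE
  if (nrow(ev)) {
    sel <- ev$type == "sever" & abs(ev$t - onset) <= window
    if (any(sel)) {
      pts <- as.matrix(ev[sel, c("x", "y", "z")])
      r <- sqrt(rowSums(pts^2))
      ang <- acos(pmin(pmax(drop(pts %*% axis) / pmax(r, 1e-12), -1), 1))
      sev <- any(ang <= cone)
    }
  }
  gap <- cortex_gap(traj$snapshots[post], axis, bleb, traj)
  out <- if (ratio < 0.25 && sev) "Rupture"
         else if (ratio >= 0.75 && gap > 2 * p$anchor_rest) "Detachment"
         else "Undetermined"
  structure(out, details = c(density_ratio = ratio, sever = sev, gap = gap))
}

cone_angle <- function(bleb, traj) {
  sn <- traj$snapshots[[bleb$snapshots[1]]]
  fs <- fit_sphere(sn$V)
  W <- sn$V[bleb$vertices, , drop = FALSE] -
    matrix(fs$center, length(bleb$vertices), 3, byrow = TRUE)
  r <- sqrt(rowSums(W^2))
  max(acos(pmin(pmax(drop(W %*% bleb$centroid_dir) / pmax(r, 1e-12), -1), 1))) + 0.15
}

seg_len_in_cone <- function(sn, axis, fs, p, rmin_frac = 0.6, cone = 0.6) {
  n <- nrow(sn$x)
  if (n < 2) return(0)
  same <- sn$fil_id[-n] == sn$fil_id[-1]
  a <- which(same)
  mid <- (sn$x[a, , drop = FALSE] + sn$x[a + 1L, , drop = FALSE]) / 2 -
    matrix(fs$center, length(a), 3, byrow = TRUE)
  r <- sqrt(rowSums(mid^2))
  ang <- acos(pmin(pmax(drop(mid %*% axis) / pmax(r, 1e-12), -1), 1))
  len <- sqrt(rowSums((sn$x[a + 1L, , drop = FALSE] - sn$x[a, , drop = FALSE])^2))
  sum(len[ang <= cone & r >= rmin_frac * fs$radius])
}

# radial separation between the bleb membrane and the cortex beneath it:
# max radial extent of membrane vertices in the cone minus max radial extent
# of network nodes in the same cone (positive once membrane and network part)
cortex_gap <- function(snaps, axis, bleb, traj) {
  gaps <- vapply(snaps, function(sn) {
    fs <- fit_sphere(sn$V)
    dv <- sn$V - matrix(fs$center, nrow(sn$V), 3, byrow = TRUE)
    rv <- sqrt(rowSums(dv^2))
    angv <- acos(pmin(pmax(drop(dv %*% axis) / pmax(rv, 1e-12), -1), 1))
    mem_r <- if (any(angv <= 0.6)) max(rv[angv <= 0.6]) else fs$radius
    n <- nrow(sn$x)
    if (n == 0) return(Inf)
    d <- sn$x - matrix(fs$center, n, 3, byrow = TRUE)
    r <- sqrt(rowSums(d^2))
    ang <- acos(pmin(pmax(drop(d %*% axis) / pmax(r, 1e-12), -1), 1))
    sel <- ang <= 0.6
    if (!any(sel)) return(Inf)
    mem_r - max(r[sel])
  }, 0)
  max(gaps)
}

#' Motor orientation angles relative to the membrane surface
#'
#' For each mini-filament, the acute angle between its backbone vector and
#' the vector from the membrane centre to the backbone centroid is computed
#' and subtracted from 90 degrees, giving 0 for backbones tangential to the
#' membrane and 90 for radial ones.
#'
#' @param state A simulation state.
#' @param center Membrane centre (default best-fit sphere centre).
#' @return Numeric vector of angles in degrees, one per motor.
#' @export
motor_orientation <- function(state, center = NULL) {
  m <- state$motors$ends
  nm <- nrow(m) / 2
  if (nm == 0) return(numeric(0))
  if (is.null(center)) center <- fit_sphere(state$mesh$V)$center
  e1 <- m[seq(1, 2 * nm, 2), , drop = FALSE]
  e2 <- m[seq(2, 2 * nm, 2), , drop = FALSE]
  mb <- e2 - e1
  om <- (e1 + e2) / 2 - matrix(center, nm, 3, byrow = TRUE)
  lb <- sqrt(rowSums(mb^2)); lo <- sqrt(rowSums(om^2))
  if (any(lb < 1e-12)) stop("zero-length motor backbone")
  ct <- abs(rowSums(mb * om)) / pmax(lb * lo, 1e-300)   # acute angle
  90 - acos(pmin(ct, 1)) * 180 / pi
}

#' F-actin, motor and cross-linker density profiles
#'
#' Polymer length per volume in the outer shell of thickness `shell` beneath
#' the membrane (`rho_memb`) and in the interior (`rho_bulk`), their ratio,
#' and per-area surface densities of motors, cross-linkers and membrane-bound
#' cross-linkers in the shell.
#'
#' @param state A simulation state.
#' @param shell Shell thickness (um).
#' @return A tibble with one row.
#' @export
density_profile <- function(state, shell = state$params$shell_thickness) {
  fs <- fit_sphere(state$mesh$V)
  R <- fs$radius
  seg <- segment_table(state)
  shell_vol <- 4 / 3 * pi * (R^3 - (R - shell)^3)
  bulk_vol <- 4 / 3 * pi * (R - shell)^3
  area <- 4 * pi * R^2
  lm <- lb <- 0
  if (length(seg$a)) {
    mid <- (state$x[seg$a, , drop = FALSE] + state$x[seg$b, , drop = FALSE]) / 2 -
      matrix(fs$center, length(seg$a), 3, byrow = TRUE)
    r <- sqrt(rowSums(mid^2))
    len <- sqrt(rowSums((state$x[seg$b, , drop = FALSE] -
                           state$x[seg$a, , drop = FALSE])^2))
    lm <- sum(len[r >= R - shell])
    lb <- sum(len[r < R - shell])
  }
  rho_memb <- lm / shell_vol
  rho_bulk <- lb / bulk_vol
  nm <- nrow(state$motors$ends) / 2
  mot_shell <- 0
  if (nm > 0) {
    cen <- (state$motors$ends[seq(1, 2 * nm, 2), , drop = FALSE] +
              state$motors$ends[seq(2, 2 * nm, 2), , drop = FALSE]) / 2 -
      matrix(fs$center, nm, 3, byrow = TRUE)
    mot_shell <- sum(sqrt(rowSums(cen^2)) >= R - shell)
  }
  a <- state$acps
  acp_shell <- 0; acp_bound_mem <- 0
  if (nrow(a)) {
    fa <- ifelse(!is.na(a$f1), a$f1, a$f2)
    pa <- ifelse(!is.na(a$f1), a$p1, a$p2)
    ok <- !is.na(fa)
    if (any(ok)) {
      pts <- arc_point(state, fa[ok], pa[ok]) -
        matrix(fs$center, sum(ok), 3, byrow = TRUE)
      acp_shell <- sum(sqrt(rowSums(pts^2)) >= R - shell)
    }
    acp_bound_mem <- sum(!is.na(a$a_face))
  }
  tibble::tibble(
    rho_memb = rho_memb, rho_bulk = rho_bulk,
    ratio = if (rho_bulk > 0) rho_memb / rho_bulk
            else if (rho_memb > 0) Inf else NA_real_,
    motor_surface_density = mot_shell / area,
    acp_surface_density = acp_shell / area,
    bound_acp_surface_density = acp_bound_mem / area)
}
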