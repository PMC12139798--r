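# Local perturbations of actin-membrane coupling (R_C) or network
# connectivity (R_X) over a spherical-cap fraction of the membrane surface,
# and the bleb positional-control statistics.

#' Spherical-cap face set with a given area fraction
#'
#' Faces are sorted by polar angle from the cap axis and accumulated until
#' their area reaches `fp` of the total (within one face).
#'
#' @param mesh A `membrane_mesh`.
#' @param fp Target area fraction (0..1).
#' @param axis Cap axis (default +z pole).
#' @return list(faces, axis, cos_ang, area_fraction).
#' @export
cap_face_set <- function(mesh, fp, axis = c(0, 0, 1)) {
  if (fp < 0 || fp > 1) stop("fp must be in [0, 1]")
  axis <- axis / sqrt(sum(axis^2))
  area <- face_areas(mesh$V, mesh$F)
  total <- sum(area)
  if (fp == 0) {
    return(list(faces = integer(0), axis = axis, cos_ang = 1, area_fraction = 0))
  }
  fc <- (mesh$V[mesh$F[, 1], ] + mesh$V[mesh$F[, 2], ] + mesh$V[mesh$F[, 3], ]) / 3
  r <- sqrt(rowSums(fc^2))
  ct <- drop(fc %*% axis) / pmax(r, 1e-12)
  ord <- order(ct, decreasing = TRUE)
  cum <- cumsum(area[ord])
  k <- which(cum >= fp * total)[1]
  if (is.na(k)) k <- length(ord)
  faces <- ord[seq_len(k)]
  list(faces = faces, axis = axis, cos_ang = ct[ord[k]],
       area_fraction = cum[k] / total)
}

#' Apply a local coupling or connectivity perturbation
#'
#' Marks a spherical cap covering an area fraction `fp` of the membrane.
#' Target `"RC"`: cross-linkers anchored inside the cap lose their anchors
#' and anchor formation is barred there (local `R_C = 0`). Target `"RX"`:
#' cross-linker arms beneath the cap (in the cortical shell) are freed and
#' rebinding is barred while there (local `R_X = 0`). The marking persists
#' for the rest of the run and is carried by the face set, which moves with
#' the mesh.
#'
#' @param state A simulation state.
#' @param target `"RC"` or `"RX"`.
#' @param fp Perturbed area fraction.
#' @param t_apply Time at which the perturbation takes effect (default now).
#' @param axis Cap axis.
#' @return The updated state.
#' @export
apply_local_perturbation <- function(state, target = c("RC", "RX"), fp,
                                     t_apply = state$time, axis = c(0, 0, 1)) {
  target <- match.arg(target)
  cap <- cap_face_set(state$mesh, fp, axis)
  state$perturb <- list(target = target, faces = cap$faces, axis = cap$axis,
                        cos_ang = cap$cos_ang, fp = fp, t_apply = t_apply,
                        area_fraction = cap$area_fraction)
  if (fp == 0 || state$time < t_apply) return(state)
  enforce_perturbation(state)
}

# strip existing bonds violating the active perturbation
enforce_perturbation <- function(state) {
  pb <- state$perturb
  if (is.null(pb) || state$time < pb$t_apply) return(state)
  a <- state$acps
  if (!nrow(a)) return(state)
  if (pb$target == "RC") {
    anch <- which(!is.na(a$a_face) & a$a_face %in% pb$faces)
    if (length(anch)) {
      a$a_face[anch] <- NA_integer_
      a$a_w1[anch] <- NA_real_; a$a_w2[anch] <- NA_real_; a$a_w3[anch] <- NA_real_
    }
    state$acps <- a
  } else {
    for (arm in 1:2) {
      fcol <- paste0("f", arm); pcol <- paste0("p", arm)
      bound <- which(!is.na(a[[fcol]]))
      if (!length(bound)) next
      pts <- arc_point(state, a[[fcol]][bound], a[[pcol]][bound])
      inside <- in_perturbed_cap(state, pts, "RX")
      kill <- bound[inside]
      a[[fcol]][kill] <- NA_integer_
      a[[pcol]][kill] <- NA_real_
    }
    # anchors whose host arm vanished
    dead_anchor <- !is.na(a$a_face) & is.na(a$f1) & is.na(a$f2)
    a$a_face[dead_anchor] <- NA_integer_
    a$a_w1[dead_anchor] <- NA_real_
    a$a_w2[dead_anchor] <- NA_real_
    a$a_w3[dead_anchor] <- NA_real_
    state$acps <- a
    state <- drop_unbound_acps(state)
  }
  state
}

#' Run a simulation with a local perturbation
#'
#' Convenience driver: assembles and couples the network exactly as
#' [run_simulation()], applies the perturbation at the start of production,
#' and keeps enforcing it through the binding kinetics.
#'
#' @param params A `sim_params`.
#' @param target `"RC"` or `"RX"`.
#' @param fp Perturbed area fraction.
#' @param region `"shell"` or `"volume"`.
#' @param seed Random seed.
#' @param axis Cap axis.
#' @return A `cortosim_trajectory` with the perturbation recorded in
#'   `$perturb`.
#' @export
run_perturbed <- function(params, target, fp, region = NULL,
                          seed = params$seed, axis = c(0, 0, 1)) {
  force(target); force(fp); force(axis)
  traj <- run_simulation_hooked(params, region, seed,
    after_couple = function(state) {
      state <- apply_local_perturbation(state, target, fp, axis = axis)
      enforce_perturbation(state)
    },
    each_cycle = enforce_perturbation)
  traj$perturb <- traj$state$perturb
  traj
}

#' Bleb positional-control efficiency
#'
#' Fraction of runs whose first bleb (earliest onset; ties broken by larger
#' diameter) emerged with its centroid inside the perturbed cap.
#'
#' @param runs List of `cortosim_trajectory` objects from [run_perturbed()].
#' @param cap Optional cap description (default: each run's own).
#' @return Fraction in [0, 1] (NA if no run formed a bleb).
#' @export
bleb_position_efficiency <- function(runs, cap = NULL) {
  hits <- vapply(runs, function(tr) {
    cp <- if (is.null(cap)) tr$perturb else cap
    tracks <- track_blebs(tr)
    if (!length(tracks)) return(NA)
    onsets <- vapply(tracks, `[[`, 0, "onset")
    diams <- vapply(tracks, `[[`, 0, "max_diameter")
    first <- which(onsets == min(onsets))
    first <- first[which.max(diams[first])]
    drop(tracks[[first]]$centroid_dir %*% cp$axis) >= cp$cos_ang
  }, NA)
  hits <- hits[!is.na(hits)]
  if (!length(hits)) return(NA_real_)
  mean(hits)
}
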