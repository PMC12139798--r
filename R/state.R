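#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom optimize uniroot sd median setNames
#' @importFrom utils head tail
NULL

# Internal representation -----------------------------------------------------
#
# A simulation state is a list with:
#   time      model time (s)
#   params    sim_params
#   x         N x 3 filament node coordinates (um), nodes of one filament
#             contiguous, ordered pointed -> barbed end
#   fil_id    integer filament id per node (nondecreasing, contiguous blocks)
#   seg_rest  per-node rest length of the segment starting at that node
#             (NA on the last node of each filament)
#   acps      data.frame of cross-linkers with at least one bound arm:
#             bindable, f1, p1, f2, p2 (filament id + arc position, NA free),
#             a_face, a_w1..a_w3 (membrane anchor barycentric, NA none)
#   acp_free_bindable / acp_free_plain   free cross-linker reservoir counts
#   motors    list(ends = 2M x 3 backbone end coordinates,
#                  df = data.frame(h1_fil, h1_pos, h2_fil, h2_pos,
#                                  h1_F, h2_F))
#   mesh      membrane_mesh
#   pool      free monomer count
#   budget    initial monomer budget
#   events    data.frame(t, type, x, y, z, fil)
#   perturb   NULL or list(target, faces, t_apply)
#
# Arc positions are measured in um of rest length from the pointed end, so
# they are material coordinates that survive node motion.

new_state <- function(params, mesh, x = matrix(0, 0, 3), fil_id = integer(0),
                      seg_rest = numeric(0), pool = 0, budget = pool) {
  list(
    time = 0, params = params, x = x, fil_id = fil_id, seg_rest = seg_rest,
    acps = empty_acps(), acp_free_bindable = 0, acp_free_plain = 0,
    motors = list(ends = matrix(0, 0, 3), df = empty_motors()),
    mesh = mesh, pool = pool, budget = budget,
    events = data.frame(t = numeric(0), type = character(0), x = numeric(0),
                        y = numeric(0), z = numeric(0), fil = integer(0)),
    perturb = NULL
  )
}

empty_acps <- function() {
  data.frame(bindable = logical(0), f1 = integer(0), p1 = numeric(0),
             f2 = integer(0), p2 = numeric(0), a_face = integer(0),
             a_w1 = numeric(0), a_w2 = numeric(0), a_w3 = numeric(0))
}

empty_motors <- function() {
  data.frame(h1_fil = integer(0), h1_pos = numeric(0), h2_fil = integer(0),
             h2_pos = numeric(0), h1_F = numeric(0), h2_F = numeric(0))
}

# per-filament bookkeeping: first/last node row of each filament id
fil_ranges <- function(fil_id) {
  if (!length(fil_id)) {
    return(data.frame(fil = integer(0), from = integer(0), to = integer(0)))
  }
  r <- rle(fil_id)
  to <- cumsum(r$lengths)
  data.frame(fil = r$values, from = to - r$lengths + 1L, to = to)
}

# segment table: rows (a, b) of consecutive nodes within one filament
segment_table <- function(state) {
  n <- nrow(state$x)
  if (n < 2) {
    return(list(a = integer(0), b = integer(0), rest = numeric(0),
                fil = integer(0)))
  }
  same <- state$fil_id[-n] == state$fil_id[-1]
  a <- which(same)
  list(a = a, b = a + 1L, rest = state$seg_rest[a], fil = state$fil_id[a])
}

# cumulative rest-length offset of each segment's start, per filament
fil_lengths <- function(state) {
  seg <- segment_table(state)
  if (!length(seg$a)) return(numeric(0))
  tapply(seg$rest, seg$fil, sum)
}

# arc offset of each segment's start within its filament (vectorized; relies
# on segments being ordered within contiguous filament blocks)
seg_arc_offsets <- function(seg) {
  n <- length(seg$a)
  if (!n) return(numeric(0))
  cs <- cumsum(seg$rest)
  off_global <- c(0, cs[-n])
  first <- which(c(TRUE, seg$fil[-1] != seg$fil[-n]))
  block <- rep(seq_along(first), times = diff(c(first, n + 1L)))
  off_global - off_global[first[block]]
}

# global segment row for arc position `pos` on filament `f` (vectorized over
# queries; loops only over the distinct filaments involved)
locate_segment <- function(seg, f, pos) {
  out <- integer(length(f))
  first <- which(c(TRUE, seg$fil[-1] != seg$fil[-length(seg$fil)]))
  fil_of_block <- seg$fil[first]
  last <- c(first[-1] - 1L, length(seg$a))
  for (fb in unique(f[!is.na(f)])) {
    bi <- match(fb, fil_of_block)
    if (is.na(bi)) next
    rows <- first[bi]:last[bi]
    ends <- cumsum(seg$rest[rows])
    idx <- which(!is.na(f) & f == fb)
    pq <- pmin(pmax(pos[idx], 0), ends[length(ends)] - 1e-12)
    k <- findInterval(pq, c(0, ends), rightmost.closed = TRUE)
    out[idx] <- rows[pmin(pmax(k, 1L), length(rows))]
  }
  out
}

# world position of arc coordinate `pos` (um of rest length) on filament f;
# returns list(i, j, w) such that point = (1-w)*x[i,] + w*x[j,]
arc_locate <- function(state, f, pos) {
  seg <- segment_table(state)
  n <- length(seg$a)
  if (!n) stop("arc_locate: state has no segments")
  out_i <- integer(length(f)); out_j <- integer(length(f)); out_w <- numeric(length(f))
  # contiguous filament blocks in the segment table
  first <- which(c(TRUE, seg$fil[-1] != seg$fil[-n]))
  last <- c(first[-1] - 1L, n)
  fil_of_block <- seg$fil[first]
  offs <- seg_arc_offsets(seg)                  # arc start of each segment
  flen_by_block <- offs[last] + seg$rest[last]  # total length per block
  bi <- match(f, fil_of_block)
  if (anyNA(bi)) stop("arc_locate: filament ", f[which(is.na(bi))[1]],
                      " has no segments")
  groups <- split(seq_along(f), bi)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    blk <- bi[idx[1]]
    rows <- first[blk]:last[blk]
    ends <- offs[rows] + seg$rest[rows]
    p <- pmin(pmax(pos[idx], 0), flen_by_block[blk] - 1e-12)
    k <- findInterval(p, c(offs[rows][1], ends), rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), length(rows))
    s <- rows[k]
    out_i[idx] <- seg$a[s]
    out_j[idx] <- seg$b[s]
    out_w[idx] <- (p - offs[s]) / seg$rest[s]
  }
  list(i = out_i, j = out_j, w = out_w)
}

arc_point <- function(state, f, pos) {
  loc <- arc_locate(state, f, pos)
  (1 - loc$w) * state$x[loc$i, , drop = FALSE] +
    loc$w * state$x[loc$j, , drop = FALSE]
}

anchor_points <- function(state) {
  a <- state$acps
  sel <- which(!is.na(a$a_face))
  if (!length(sel)) return(list(sel = sel, pts = matrix(0, 0, 3)))
  Fm <- state$mesh$F[a$a_face[sel], , drop = FALSE]
  V <- state$mesh$V
  pts <- a$a_w1[sel] * V[Fm[, 1], , drop = FALSE] +
    a$a_w2[sel] * V[Fm[, 2], , drop = FALSE] +
    a$a_w3[sel] * V[Fm[, 3], , drop = FALSE]
  list(sel = sel, pts = pts)
}

#' Validate a simulation state
#'
#' Asserts the structural invariants of the state: filament nodes contiguous
#' with at least 2 nodes each and bounded segment stretch, cross-linker arms
#' and anchors referencing existing filaments/faces (anchor implies the
#' membrane-bindable flag; barycentric weights form a partition of unity),
#' motor heads within filament lengths, a valid closed membrane mesh,
#' monomer conservation (polymerised + pool = budget) and a nondecreasing
#' event log.
#'
#' @param state A simulation state.
#' @return The state, invisibly; errors on violation.
#' @export
validate_state <- function(state) {
  p <- state$params
  rng <- fil_ranges(state$fil_id)
  if (nrow(rng) && any(rng$to - rng$from + 1L < 2L)) {
    stop("filament with fewer than 2 nodes")
  }
  if (any(duplicated(rng$fil))) stop("filament nodes not contiguous")
  seg <- segment_table(state)
  if (length(seg$a)) {
    len <- sqrt(rowSums((state$x[seg$b, , drop = FALSE] -
                           state$x[seg$a, , drop = FALSE])^2))
    if (any(len > 2 * seg$rest + 1e-9)) {
      stop("segment stretched beyond 2x rest length")
    }
  }
  flen <- fil_lengths(state)
  a <- state$acps
  for (arm in 1:2) {
    f <- a[[paste0("f", arm)]]; pos <- a[[paste0("p", arm)]]
    bound <- !is.na(f)
    if (any(bound & is.na(pos))) stop("bound arm without arc position")
    if (any(bound)) {
      if (!all(as.character(f[bound]) %in% names(flen))) {
        stop("cross-linker arm bound to missing filament")
      }
      if (any(pos[bound] > flen[as.character(f[bound])] + 1e-9) ||
          any(pos[bound] < -1e-9)) {
        stop("cross-linker arc position outside filament")
      }
    }
  }
  anch <- !is.na(a$a_face)
  if (any(anch & !a$bindable)) stop("anchored cross-linker not membrane_bindable")
  if (any(anch)) {
    if (any(a$a_face[anch] > nrow(state$mesh$F))) stop("anchor references missing face")
    w <- a$a_w1[anch] + a$a_w2[anch] + a$a_w3[anch]
    if (any(abs(w - 1) > 1e-6)) stop("anchor barycentric weights do not sum to 1")
  }
  m <- state$motors$df
  if (nrow(m)) {
    if (nrow(state$motors$ends) != 2L * nrow(m)) stop("motor end matrix size mismatch")
    for (h in 1:2) {
      f <- m[[paste0("h", h, "_fil")]]; pos <- m[[paste0("h", h, "_pos")]]
      bound <- !is.na(f)
      if (any(bound)) {
        if (!all(as.character(f[bound]) %in% names(flen))) {
          stop("motor head bound to missing filament")
        }
        if (any(pos[bound] > flen[as.character(f[bound])] + 1e-9)) {
          stop("motor head beyond filament length")
        }
      }
    }
    blen <- sqrt(rowSums((state$motors$ends[seq(2, 2 * nrow(m), 2), , drop = FALSE] -
                            state$motors$ends[seq(1, 2 * nrow(m), 2), , drop = FALSE])^2))
    if (any(abs(blen - p$motor_backbone) > 0.5 * p$motor_backbone)) {
      stop("motor backbone length outside tolerance")
    }
  }
  validate_mesh(state$mesh)
  polymerised <- sum(seg$rest) * p$monomers_per_um
  if (abs(polymerised + state$pool - state$budget) > 1e-6 * max(1, state$budget) + 1) {
    stop("monomer conservation violated: ", polymerised, " + ", state$pool,
         " != ", state$budget)
  }
  if (is.unsorted(state$events$t)) stop("event log times decreasing")
  invisible(state)
}

#' Deterministic test fixtures
#'
#' Small hand-built simulation states used throughout the test suite:
#' \describe{
#'   \item{`empty_shell`}{membrane only; the full monomer budget in the pool.}
#'   \item{`single_filament_motor`}{one straight filament along x with one
#'     motor mini-filament whose first head is bound at mid-filament.}
#'   \item{`crosslinked_pair`}{two parallel filaments joined by one doubly
#'     bound cross-linker.}
#'   \item{`sphere_with_protrusion`}{membrane with a crafted bleb-like
#'     spherical protrusion of diameter `d` (no network).}
#' }
#'
#' @param name Fixture name.
#' @param params A `sim_params` object.
#' @param d Protrusion diameter (um) for `sphere_with_protrusion`.
#' @return A simulation state passing [validate_state()].
#' @export
make_fixture <- function(name, params = sim_params(), d = 2) {
  mesh <- build_icosphere(params$R_mem, params$mesh_subdiv)
  budget <- monomer_budget(params$C_A, mesh, params$actin_scale)
  if (name == "empty_shell") {
    return(new_state(params, mesh, pool = budget))
  }
  if (name == "single_filament_motor") {
    nn <- 8L
    x <- cbind(seq(0, by = params$seg_len, length.out = nn) -
                 params$seg_len * (nn - 1) / 2, 0, 0)
    st <- new_state(params, mesh, x = x, fil_id = rep(1L, nn),
                    seg_rest = c(rep(params$seg_len, nn - 1L), NA),
                    pool = budget - (nn - 1) * params$seg_len *
                      params$monomers_per_um,
                    budget = budget)
    mid <- (nn - 1) * params$seg_len / 2
    ends <- rbind(c(0, params$motor_rest, 0),
                  c(params$motor_backbone, params$motor_rest, 0))
    st$motors$ends <- ends
    st$motors$df <- data.frame(h1_fil = 1L, h1_pos = mid, h2_fil = NA_integer_,
                               h2_pos = NA_real_, h1_F = 0, h2_F = 0)
    return(st)
  }
  if (name == "crosslinked_pair") {
    nn <- 5L
    sl <- params$seg_len
    x1 <- cbind(seq(0, by = sl, length.out = nn), 0, 0)
    x2 <- cbind(seq(0, by = sl, length.out = nn), params$acp_rest, 0)
    st <- new_state(params, mesh, x = rbind(x1, x2),
                    fil_id = rep(1:2, each = nn),
                    seg_rest = rep(c(rep(sl, nn - 1L), NA), 2),
                    pool = budget - 2 * (nn - 1) * sl * params$monomers_per_um,
                    budget = budget)
    mid <- (nn - 1) * sl / 2
    st$acps <- data.frame(bindable = FALSE, f1 = 1L, p1 = mid, f2 = 2L,
                          p2 = mid, a_face = NA_integer_, a_w1 = NA_real_,
                          a_w2 = NA_real_, a_w3 = NA_real_)
    return(st)
  }
  if (name == "sphere_with_protrusion") {
    mesh <- add_protrusion(mesh, d = d)
    return(new_state(params, mesh, pool = budget))
  }
  stop("unknown fixture name: ", name)
}

# Crafted bleb-like bump around +z: vertices inside a cone are pushed out
# radially onto a raised dome, producing a protrusion with a concave neck
# ring. The dome footprint is calibrated numerically so that the maximum
# pairwise distance within the displaced vertex set is the requested
# diameter d.
add_protrusion <- function(mesh, d, h0 = 0.35) {
  V <- mesh$V
  R <- mesh$radius
  # widest transverse extent of the dome r(s) = R + h0 + sqrt(rb^2 - s^2)
  # under radial displacement, as a function of the footprint radius rb
  half_width <- function(rb) {
    s <- seq(0, rb, length.out = 400)
    max(s * (R + h0 + sqrt(pmax(rb^2 - s^2, 0))) / R)
  }
  rb <- uniroot(function(z) 2 * half_width(z) - d,
                c(0.05 * d, 1.2 * d))$root
  u <- V / sqrt(rowSums(V^2))
  s <- R * sqrt(pmax(1 - u[, 3]^2, 0))    # transverse distance from +z axis
  sel <- which(u[, 3] > 0 & s <= rb)
  rnew <- R + h0 + sqrt(pmax(rb^2 - s[sel]^2, 0))
  V[sel, ] <- u[sel, , drop = FALSE] * rnew
  mesh$V <- V
  mesh
}
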