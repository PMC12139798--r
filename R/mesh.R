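#' Build a triangulated spherical membrane (icosphere)
#'
#' Starts from a regular icosahedron and applies Loop-style midpoint
#' subdivision, reprojecting vertices onto the sphere after each level.
#' Reference face areas and the reference enclosed volume are recorded from
#' the initial geometry; they define the unstressed state of the membrane's
#' area elasticity and volume penalty.
#'
#' @param radius Sphere radius (um).
#' @param subdivision Number of subdivision levels (0 = icosahedron).
#' @return An object of class `membrane_mesh`: a list with vertex matrix `V`
#'   (n x 3), face index matrix `F` (m x 3, outward-oriented), edge table
#'   `edges` (e x 4: the two edge vertices and the two opposite vertices),
#'   per-face `ref_area`, scalar `ref_volume`, and `radius`.
#' @examples
#' m <- build_icosphere(4, 3)
#' mesh_volume(m$V, m$F) / (4/3 * pi * 4^3)
#' @export
build_icosphere <- function(radius, subdivision = 3) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (subdivision < 0) stop("subdivision must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  storage.mode(F) <- "integer"
  for (lev in seq_len(subdivision)) {
    res <- subdivide_once(V, F)
    V <- res$V
    F <- res$F
    V <- V / sqrt(rowSums(V^2))
  }
  V <- V * radius
  mesh <- structure(list(V = V, F = F), class = "membrane_mesh")
  mesh$edges <- mesh_edges(F)
  mesh$ref_area <- face_areas(V, F)
  mesh$ref_volume <- mesh_volume(V, F)
  mesh$radius <- radius
  mesh$face_adj <- face_adjacency(F)
  mesh$vertex_faces <- vertex_face_index(F, nrow(V))
  mesh
}

vertex_face_index <- function(F, nv) {
  vf <- vector("list", nv)
  for (f in seq_len(nrow(F))) {
    for (k in 1:3) {
      v <- F[f, k]
      vf[[v]] <- c(vf[[v]], f)
    }
  }
  vf
}

subdivide_once <- function(V, F) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  midpoints <- new.env(hash = TRUE)
  newV <- list()
  nextv <- nrow(V)
  getmid <- function(i, j) {
    k <- key(i, j)
    id <- midpoints[[k]]
    if (!is.null(id)) return(id)
    nextv <<- nextv + 1L
    newV[[length(newV) + 1L]] <<- (V[i, ] + V[j, ]) / 2
    midpoints[[k]] <- nextv
    nextv
  }
  newF <- matrix(0L, nrow(F) * 4L, 3L)
  for (f in seq_len(nrow(F))) {
    a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    newF[(f - 1L) * 4L + 1:4, ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(V = rbind(V, do.call(rbind, newV)), F = newF)
}

#' Edge table with opposite vertices
#'
#' For every undirected edge of a closed oriented triangle mesh, returns the
#' two edge vertices `v1, v2` and the opposite vertices `o1` (of the face in
#' which the edge runs v1 -> v2) and `o2` (of the face in which it runs
#' v2 -> v1). Errors if any edge is not shared by exactly two faces.
#'
#' @param F Face index matrix (m x 3).
#' @return Integer matrix (e x 4).
#' @export
mesh_edges <- function(F) {
  m <- nrow(F)
  he_from <- c(F[, 1], F[, 2], F[, 3])
  he_to <- c(F[, 2], F[, 3], F[, 1])
  he_opp <- c(F[, 3], F[, 1], F[, 2])
  key <- paste(pmin(he_from, he_to), pmax(he_from, he_to))
  ord <- order(key)
  key <- key[ord]
  if (any(key[seq(1, length(key), 2)] != key[seq(2, length(key), 2)]) ||
      length(unique(key)) * 2L != length(key)) {
    stop("mesh is not a closed 2-manifold: an edge is not shared by exactly 2 faces")
  }
  from <- he_from[ord]; to <- he_to[ord]; opp <- he_opp[ord]
  i1 <- seq(1, length(key), 2)
  i2 <- i1 + 1L
  # orient so row stores (v1, v2, opp_of_face_with_v1v2, opp_of_other)
  v1 <- from[i1]; v2 <- to[i1]; o1 <- opp[i1]; o2 <- opp[i2]
  if (any(from[i2] != v2 | to[i2] != v1)) {
    stop("inconsistent face orientation: edge traversed twice in same direction")
  }
  cbind(v1 = v1, v2 = v2, o1 = o1, o2 = o2)
}

#' @rdname mesh_geometry
#' @export
face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh geometry helpers
#'
#' `face_areas` returns per-face triangle areas; `mesh_volume` the enclosed
#' (signed, outward-positive) volume; `vertex_normals` area-weighted outward
#' vertex normals; `mean_curvature` the signed discrete mean curvature
#' (positive = locally convex outward) from the cotangent Laplacian.
#'
#' @param V Vertex matrix (n x 3).
#' @param F Face index matrix (m x 3).
#' @name mesh_geometry
#' @export
mesh_volume <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cxx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cxy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cxz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sum(a[, 1] * cxx + a[, 2] * cxy + a[, 3] * cxz) / 6
}

#' @rdname mesh_geometry
#' @export
vertex_normals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      N[, c] <- N[, c] + unname(tapply(fn[, c], factor(F[, k], levels = seq_len(nrow(V))), sum, default = 0))
    }
  }
  N / pmax(sqrt(rowSums(N^2)), 1e-300)
}

#' @rdname mesh_geometry
#' @export
mean_curvature <- function(V, F) {
  n <- nrow(V)
  L <- matrix(0, n, 3)   # accumulated cotangent Laplacian applied to V
  Amix <- numeric(n)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  area <- face_areas(V, F)
  for (cn in corners) {
    i <- F[, cn[1]]; j <- F[, cn[2]]; k <- F[, cn[3]]
    # cotangent at corner i multiplies edge (j,k)
    u <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
    v <- V[k, , drop = FALSE] - V[i, , drop = FALSE]
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    cot <- rowSums(u * v) / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-300)
    d <- V[k, , drop = FALSE] - V[j, , drop = FALSE]
    for (c in 1:3) {
      L[, c] <- L[, c] +
        unname(tapply(0.5 * cot * d[, c], factor(j, levels = seq_len(n)), sum, default = 0)) -
        unname(tapply(0.5 * cot * d[, c], factor(k, levels = seq_len(n)), sum, default = 0))
    }
    Amix <- Amix + unname(tapply(area / 3, factor(i, levels = seq_len(n)), sum, default = 0))
  }
  Hn <- L / (2 * pmax(as.numeric(Amix), 1e-300))
  N <- vertex_normals(V, F)
  -rowSums(Hn * N)
}

#' Validate a membrane mesh
#'
#' Checks the closed-manifold invariants: Euler characteristic 2, every edge
#' shared by exactly two faces with consistent outward orientation, positive
#' enclosed volume.
#'
#' @param mesh A `membrane_mesh`.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  e <- mesh_edges(F)   # errors if non-manifold or inconsistently oriented
  chi <- nrow(V) - nrow(e) + nrow(F)
  if (chi != 2) stop("Euler characteristic is ", chi, ", expected 2")
  if (mesh_volume(V, F) <= 0) stop("enclosed volume must be positive")
  invisible(mesh)
}

#' Monomer budget from actin concentration and membrane volume
#'
#' Number of G-actin monomers corresponding to concentration `C_A` (uM)
#' in the enclosed volume of the membrane, optionally scaled by
#' `actin_scale` (used by the desk-scale configurations).
#'
#' @param C_A Actin concentration in uM.
#' @param mesh A `membrane_mesh`.
#' @param actin_scale Fraction of the nominal budget to use (default 1).
#' @return Integer monomer count.
#' @examples
#' m <- build_icosphere(4, 3)
#' monomer_budget(10, m)   # ~1.6e6 monomers for an 8-um-diameter sphere
#' @export
monomer_budget <- function(C_A, mesh, actin_scale = 1) {
  if (C_A < 0) stop("C_A must be >= 0")
  vol_um3 <- mesh_volume(mesh$V, mesh$F)
  # C_A [umol/L] * 1e-6 [mol/umol] * 6.022e23 [1/mol] * vol [um^3] * 1e-15 [L/um^3]
  round(C_A * 1e-6 * 6.02214076e23 * vol_um3 * 1e-15 * actin_scale)
}
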