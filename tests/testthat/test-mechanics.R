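# Force-field correctness: every term is the exact negative gradient of the
# declared potential (central finite differences), action-reaction holds, and
# zero-temperature relaxation dissipates energy.

fd_sub <- function(pos, sys, p, pairs, rows, membrane_active = TRUE, h = 1e-6) {
  G <- matrix(0, length(rows), 3)
  for (q in seq_along(rows)) {
    i <- rows[q]
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      G[q, c] <- (cortosim:::energy_system(pp, sys, p, pairs, membrane_active) -
                    cortosim:::energy_system(pm, sys, p, pairs, membrane_active)) / (2 * h)
    }
  }
  G
}

check_gradient <- function(state, rows, membrane_active = TRUE, tol = 1e-4) {
  sys <- cortosim:::compile_system(state)
  pairs <- cortosim:::build_pairs(sys, state$params, skin = 0.2)
  f <- cortosim:::eval_forces(sys, state$params, pairs, membrane_active)
  G <- fd_sub(sys$pos, sys, state$params, pairs, rows, membrane_active)
  scale <- max(abs(f$F[rows, , drop = FALSE]), 1e-8)
  expect_lt(max(abs(f$F[rows, , drop = FALSE] + G)) / scale, tol)
  f
}

test_that("straight filament at rest length carries no force", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- make_fixture("single_filament_motor", p)
  st$motors$df$h1_fil <- NA_integer_   # isolate the filament
  st$motors$df$h1_pos <- NA_real_
  f <- net_forces(st, membrane_active = FALSE)
  expect_lt(max(abs(f$fil)), 1e-10)
  expect_equal(f$seg_tension, rep(0, 7), tolerance = 1e-12)
})

test_that("stretched segment obeys Hooke with opposite end forces", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- cortosim:::new_state(p, build_icosphere(2, 2))
  d <- 0.01
  st$x <- rbind(c(0, 0, 0), c(p$seg_len + d, 0, 0))
  st$fil_id <- c(1L, 1L)
  st$seg_rest <- c(p$seg_len, NA)
  st$pool <- 0; st$budget <- p$seg_len * p$monomers_per_um
  f <- net_forces(st, membrane_active = FALSE)
  expect_equal(f$fil[1, 1], p$k_ext * d, tolerance = 1e-10)
  expect_equal(f$fil[2, 1], -p$k_ext * d, tolerance = 1e-10)
  expect_equal(f$seg_tension[1], p$k_ext * d, tolerance = 1e-10)
})

test_that("network forces are exact negative gradients (finite differences)", {
  set.seed(11)
  p <- sim_params(R_mem = 1, mesh_subdiv = 2)
  st <- make_fixture("crosslinked_pair", p)
  st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.02), ncol = 3)
  check_gradient(st, 1:10, membrane_active = FALSE)

  st2 <- make_fixture("single_filament_motor", p)
  st2$x <- st2$x + matrix(rnorm(length(st2$x), sd = 0.02), ncol = 3)
  check_gradient(st2, 1:10, membrane_active = FALSE)
})

test_that("membrane forces are exact negative gradients (finite differences)", {
  set.seed(12)
  p <- sim_params(R_mem = 1, mesh_subdiv = 2, k_area = 100, k_vol = 1000,
                  k_bend_mem = 0.1)
  st <- cortosim:::new_state(p, build_icosphere(1, 1))
  st$mesh$V <- st$mesh$V * (1 + 0.05 * rnorm(nrow(st$mesh$V)))
  check_gradient(st, 1:12)
})

test_that("repulsion force matches the gradient where segments overlap", {
  set.seed(13)
  p <- sim_params(R_mem = 1, mesh_subdiv = 2, rep_range_scale = 20)  # wide range
  st <- make_fixture("crosslinked_pair", p)
  st$acps <- st$acps[0, ]                      # springs off; repulsion only
  st$x[6:10, 2] <- p$acp_rest / 2              # push the filaments together
  st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.005), ncol = 3)
  f <- check_gradient(st, 1:10, membrane_active = FALSE)
  expect_gt(max(abs(f$F[1:10, ])), 0)          # repulsion actually active
})

test_that("internal forces sum to zero (action-reaction)", {
  set.seed(14)
  p <- sim_params(R_mem = 1, mesh_subdiv = 2)
  st <- make_fixture("crosslinked_pair", p)
  st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.03), ncol = 3)
  st$mesh$V <- st$mesh$V * (1 + 0.03 * rnorm(nrow(st$mesh$V)))
  f <- net_forces(st)
  tot <- colSums(rbind(f$fil, f$motors, f$mesh))
  mag <- sum(abs(rbind(f$fil, f$motors, f$mesh)))
  expect_lt(max(abs(tot)), 1e-9 * max(mag, 1))
})

test_that("anchor spring distributes reaction by barycentric weights", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- make_fixture("crosslinked_pair", p)
  # place one anchored cross-linker with the head displaced off the surface
  prj <- cortosim:::project_to_mesh(st$mesh, rbind(c(0.28, 0.07, 0)))
  st$acps$bindable <- TRUE
  st$acps$a_face <- prj$face
  st$acps$a_w1 <- prj$w[1]; st$acps$a_w2 <- prj$w[2]; st$acps$a_w3 <- prj$w[3]
  f <- net_forces(st)
  anch <- which(f$spr_type == "anchor")
  expect_length(anch, 1)
  # total force on the mesh equals the reaction on the anchor spring's B side
  expect_equal(colSums(f$mesh), f$spr_fB[anch, ], tolerance = 1e-9)
  # head coincident with the anchor point -> no force
  fs <- cortosim:::fit_sphere(st$mesh$V)
  tri <- st$mesh$F[prj$face, ]
  pt <- prj$w[1] * st$mesh$V[tri[1], ] + prj$w[2] * st$mesh$V[tri[2], ] +
    prj$w[3] * st$mesh$V[tri[3], ]
  sh <- pt - c((4 - 1) / 2 * p$seg_len / 2, p$acp_rest / 2, 0)
  st2 <- st
  st2$x <- sweep(st$x, 2, -sh)     # translate so arm 1 midpoint sits at anchor
  f2 <- net_forces(st2)
  a2 <- which(f2$spr_type == "anchor")
  len <- sqrt(sum(f2$spr_fB[a2, ]^2))
  expect_lt(abs(f2$spr_tension[a2]) / p$k_anchor, 0.3)  # near the point
})

test_that("zero-temperature relaxation monotonically decreases energy", {
  set.seed(15)
  p <- sim_params(R_mem = 1, mesh_subdiv = 2, kBT = 0, drag_scale = 10)
  st <- make_fixture("crosslinked_pair", p)
  st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.03), ncol = 3)
  e_prev <- potential_energy(st, membrane_active = FALSE)
  for (i in 1:20) {
    st <- langevin_step(st, membrane_active = FALSE)
    e <- potential_energy(st, membrane_active = FALSE)
    expect_lte(e, e_prev + 1e-10)
    e_prev <- e
  }
})

test_that("pre-tensed membrane satisfies the Young-Laplace relation", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 3, k_area = 100, k_vol = 0,
                  k_bend_mem = 0, kBT = 0)
  st <- cortosim:::new_state(p, build_icosphere(2, 3))
  strain <- 0.05
  st$mesh$ref_area <- st$mesh$ref_area / (1 + strain)   # pre-tension
  f <- net_forces(st)
  gamma <- global_tension(st, forces = f)$membrane
  expect_equal(gamma, p$k_area * strain, tolerance = 0.02)
  # net inward pressure from the area elasticity
  nrm <- vertex_normals(st$mesh$V, st$mesh$F)
  P <- -sum(rowSums(f$mesh * nrm)) / sum(face_areas(st$mesh$V, st$mesh$F))
  expect_equal(P, 2 * gamma / 2, tolerance = 0.05 * 2 * gamma / 2)
})
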