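# Observables: cutting-plane tension estimators against construction
# oracles, bleb detection invariances, morphology classification, motor
# orientation angles, density profiles.

# hand-built cortical shell of meridional "springs": n filaments along
# meridians, each segment pre-stretched to carry tension f_t
meridional_shell <- function(p, n_fil = 12, f_t = 10, nseg = 16) {
  R <- p$R_mem * 0.95
  st <- cortosim:::new_state(p, build_icosphere(p$R_mem, p$mesh_subdiv))
  stretch <- f_t / p$k_ext
  xs <- list(); ids <- list(); rests <- list()
  for (q in seq_len(n_fil)) {
    phi <- 2 * pi * (q - 1) / n_fil
    theta <- seq(pi / 2 - 0.5, pi / 2 + 0.5, length.out = nseg + 1)
    pts <- cbind(R * sin(theta) * cos(phi), R * sin(theta) * sin(phi),
                 R * cos(theta))
    # actual arc spacing, declared rest length shorter by the stretch
    seglen <- sqrt(sum((pts[2, ] - pts[1, ])^2))
    xs[[q]] <- pts
    ids[[q]] <- rep(q, nseg + 1)
    rests[[q]] <- c(rep(seglen - stretch, nseg), NA)
  }
  st$x <- do.call(rbind, xs)
  st$fil_id <- unlist(ids)
  st$seg_rest <- unlist(rests)
  st$budget <- sum(st$seg_rest, na.rm = TRUE) * p$monomers_per_um
  st$pool <- 0
  st
}

test_that("global tension recovers a constructed meridional shell exactly", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0, k_area = 0, k_vol = 0,
                  k_bend_mem = 0, k_mem_rep = 0, rep_range_scale = 1e-9)
  f_t <- 10; n_fil <- 12
  st <- meridional_shell(p, n_fil = n_fil, f_t = f_t)
  # equatorial cut (normal z): every filament crosses once, axially aligned
  ten <- global_tension(st, planes = matrix(c(0, 0, 1), 1))
  fs <- cortosim:::fit_sphere(st$mesh$V)
  expect_equal(ten$network, n_fil * f_t / (2 * pi * fs$radius),
               tolerance = 0.02)
  # force-free state measures zero
  st0 <- st
  st0$seg_rest <- ifelse(is.na(st$seg_rest), NA,
                         st$seg_rest + f_t / p$k_ext)
  expect_equal(global_tension(st0, planes = matrix(c(0, 0, 1), 1))$network, 0,
               tolerance = 1e-9)
})

test_that("tension estimator is approximately plane-choice-unbiased", {
  set.seed(41)
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0, k_area = 50)
  st <- meridional_shell(p, n_fil = 24, f_t = 5)
  # 12 random planes; meridional shells only cross near-equatorial planes,
  # so use a uniformly pre-tensed membrane for the homogeneous case
  st$mesh$ref_area <- st$mesh$ref_area / 1.05
  planes <- cortosim:::fibonacci_dirs(12)
  mem <- global_tension(st, planes = planes)$per_plane[, "membrane"]
  expect_lt(sd(mem) / mean(mem), 0.15)
})

test_that("local tension matches global for homogeneous membrane tension", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 3, kBT = 0, k_area = 100)
  st <- cortosim:::new_state(p, build_icosphere(2, 3))
  st$mesh$ref_area <- st$mesh$ref_area / 1.04
  g <- global_tension(st)
  l <- local_tension(st, region = 1:20)
  expect_equal(l$membrane, g$membrane, tolerance = 0.1)
  expect_error(local_tension(st, region = integer(0)), "empty")
})

test_that("local tension sees a locally doubled membrane tension", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 3, kBT = 0, k_area = 100)
  st <- cortosim:::new_state(p, build_icosphere(2, 3))
  st$mesh$ref_area <- st$mesh$ref_area / 1.03
  # double the strain inside a polar cap
  fc <- (st$mesh$V[st$mesh$F[, 1], ] + st$mesh$V[st$mesh$F[, 2], ] +
           st$mesh$V[st$mesh$F[, 3], ]) / 3
  cap <- which(fc[, 3] / sqrt(rowSums(fc^2)) > cos(35 * pi / 180))
  st$mesh$ref_area[cap] <- st$mesh$ref_area[cap] * 1.03 / 1.06
  g <- global_tension(st)
  l <- local_tension(st, region = cap, cap_angle = 25)
  expect_gt(l$membrane / g$membrane, 1.5)
})

test_that("bleb detection is rotation and translation invariant", {
  p <- sim_params(R_mem = 4, mesh_subdiv = 4)
  st <- make_fixture("sphere_with_protrusion", p, d = 2)
  det0 <- detect_blebs(st$mesh, 0.8)
  expect_length(det0, 1)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- st$mesh
  m2$V <- st$mesh$V %*% t(Rz) + matrix(c(1, -2, 0.5), nrow(st$mesh$V), 3,
                                       byrow = TRUE)
  det1 <- detect_blebs(m2, 0.8)
  expect_length(det1, 1)
  expect_equal(det1[[1]]$diameter, det0[[1]]$diameter, tolerance = 1e-9)
  expect_setequal(det1[[1]]$vertices, det0[[1]]$vertices)
})

test_that("bleb detection honours the diameter cutoff and perfect spheres", {
  p <- sim_params(R_mem = 4, mesh_subdiv = 4)
  expect_length(detect_blebs(build_icosphere(4, 3), 0.8), 0)
  st <- make_fixture("sphere_with_protrusion", p, d = 2)
  expect_length(detect_blebs(st$mesh, 0.8), 1)
  expect_equal(detect_blebs(st$mesh, 0.8)[[1]]$diameter, 2, tolerance = 0.1)
  st2 <- make_fixture("sphere_with_protrusion", p, d = 0.5)
  expect_length(detect_blebs(st2$mesh, 0.8), 0)
})

test_that("deformation magnitude is 1 for spheres and exact for ellipsoids", {
  mkV <- function(scale) {
    m <- build_icosphere(5, 3)
    m$V[, 3] <- m$V[, 3] * scale
    m
  }
  snaps <- list(list(V = build_icosphere(5, 3)$V), list(V = mkV(1.2)$V))
  expect_equal(deformation_magnitude(list(list(V = build_icosphere(5, 3)$V))), 1,
               tolerance = 1e-6)
  expect_equal(deformation_magnitude(snaps), 1.2, tolerance = 0.005)
  # rotation invariance of the caliper
  th <- 1.1
  Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  snaps_rot <- list(snaps[[1]], list(V = snaps[[2]]$V %*% t(Ry)))
  expect_equal(deformation_magnitude(snaps_rot), 1.2, tolerance = 0.005)
})

test_that("motor orientation angle matches hand-computed geometry", {
  p <- sim_params(R_mem = 4, mesh_subdiv = 2)
  st <- cortosim:::new_state(p, build_icosphere(4, 2))
  bb <- p$motor_backbone
  # tangential at (3,0,0): backbone along y -> 0 deg
  # radial at (0,3,0): backbone along y -> 90 deg
  # 45 deg backbone at (0,0,3)
  st$motors$ends <- rbind(
    c(3, -bb / 2, 0), c(3, bb / 2, 0),
    c(0, 3 - bb / 2, 0), c(0, 3 + bb / 2, 0),
    c(0, 0, 3) - bb / 2 * c(sqrt(0.5), 0, sqrt(0.5)),
    c(0, 0, 3) + bb / 2 * c(sqrt(0.5), 0, sqrt(0.5)))
  st$motors$df <- data.frame(h1_fil = rep(NA_integer_, 3), h1_pos = NA_real_,
                             h2_fil = NA_integer_, h2_pos = NA_real_,
                             h1_F = 0, h2_F = 0)
  ang <- motor_orientation(st, center = c(0, 0, 0))
  expect_equal(ang, c(0, 90, 45), tolerance = 1e-6)
})

test_that("density profile separates shell from bulk", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- meridional_shell(p, n_fil = 10, f_t = 0)   # all polymer near membrane
  d <- density_profile(st)
  expect_gt(d$ratio, 5)
  # empty state: error-free sentinel
  st0 <- make_fixture("empty_shell", p)
  d0 <- density_profile(st0)
  expect_equal(d0$rho_bulk, 0)
  expect_true(is.na(d0$ratio))
})

test_that("morphology falls back to deformation when no blebs are present", {
  p <- sim_params(R_mem = 5, mesh_subdiv = 3, weak_threshold = 1.05)
  sphere <- build_icosphere(5, 3)
  traj <- structure(list(
    params = p,
    snapshots = list(list(t = 0, V = sphere$V, F = sphere$F,
                          x = matrix(0, 0, 3), fil_id = integer(0))),
    events = data.frame()), class = "cortosim_trajectory")
  expect_equal(classify_morphology(traj), "NoDeformation")
  m <- sphere; m$V[, 3] <- m$V[, 3] * 1.2
  traj$snapshots[[2]] <- list(t = 1, V = m$V, F = m$F, x = matrix(0, 0, 3),
                              fil_id = integer(0))
  expect_equal(classify_morphology(traj), "WeakDeformation")
})
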