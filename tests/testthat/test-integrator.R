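# Overdamped dynamics: deterministic drift, Einstein diffusion, harmonic
# relaxation time, reproducibility of full runs.

test_that("zero force and zero temperature give no displacement", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- make_fixture("single_filament_motor", p)
  st$motors$df$h1_fil <- NA_integer_; st$motors$df$h1_pos <- NA_real_
  x0 <- st$x
  st <- langevin_step(st, membrane_active = FALSE)
  expect_equal(st$x, x0, tolerance = 1e-12)
})

test_that("drift is exactly (F/zeta) dt at zero temperature", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- cortosim:::new_state(p, build_icosphere(2, 2))
  d <- 0.01
  st$x <- rbind(c(0, 0, 0), c(p$seg_len + d, 0, 0))   # stretched segment
  st$fil_id <- c(1L, 1L)
  st$seg_rest <- c(p$seg_len, NA)
  st$budget <- p$seg_len * p$monomers_per_um; st$pool <- 0
  zeta <- 3 * pi * p$eta * p$drag_scale * p$seg_len
  st2 <- langevin_step(st, membrane_active = FALSE)
  expect_equal(st2$x[1, 1], p$k_ext * d / zeta * p$dt, tolerance = 1e-10)
  expect_equal(st2$x[2, 1] - st$x[2, 1], -p$k_ext * d / zeta * p$dt,
               tolerance = 1e-10)
})

test_that("free-point MSD matches the Einstein relation 6 D t", {
  set.seed(31)
  # 100 replicate 2-node filaments with no stretch: centre of mass diffuses
  # with D_com = kBT / (2 zeta_node)
  p <- sim_params(R_mem = 20, mesh_subdiv = 2, k_ext = 1e-9, Lp_actin = 1e-9,
                  d_actin = 1e-9)
  nrep <- 100
  st <- cortosim:::new_state(p, build_icosphere(20, 2))
  base <- 3 * (seq_len(nrep) - 1)
  st$x <- matrix(0, 2 * nrep, 3)
  st$x[seq(1, 2 * nrep, 2), 1] <- base
  st$x[seq(2, 2 * nrep, 2), 1] <- base + p$seg_len
  st$fil_id <- rep(seq_len(nrep), each = 2L)
  st$seg_rest <- rep(c(p$seg_len, NA), nrep)
  st$budget <- nrep * p$seg_len * p$monomers_per_um; st$pool <- 0
  x0 <- st$x
  nstep <- 400
  st <- cortosim:::advance_cycle(st, nstep, membrane_active = FALSE)
  zeta <- 3 * pi * p$eta * p$drag_scale * p$seg_len
  com0 <- (x0[seq(1, 2 * nrep, 2), ] + x0[seq(2, 2 * nrep, 2), ]) / 2
  com1 <- (st$x[seq(1, 2 * nrep, 2), ] + st$x[seq(2, 2 * nrep, 2), ]) / 2
  msd <- mean(rowSums((com1 - com0)^2))
  D_com <- p$kBT / (2 * zeta)
  expect_equal(msd, 6 * D_com * nstep * p$dt, tolerance = 0.10)
})

test_that("harmonic spring relaxes with time constant zeta / k", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0)
  st <- cortosim:::new_state(p, build_icosphere(2, 2))
  d0 <- 0.02
  st$x <- rbind(c(0, 0, 0), c(p$seg_len + d0, 0, 0))
  st$fil_id <- c(1L, 1L)
  st$seg_rest <- c(p$seg_len, NA)
  st$budget <- p$seg_len * p$monomers_per_um; st$pool <- 0
  zeta <- 3 * pi * p$eta * p$drag_scale * p$seg_len
  # relative coordinate relaxes with rate 2k/zeta
  tau <- zeta / (2 * p$k_ext)
  nstep <- 30
  st2 <- cortosim:::advance_cycle(st, nstep, membrane_active = FALSE)
  d1 <- (st2$x[2, 1] - st2$x[1, 1]) - p$seg_len
  expect_equal(d1 / d0, exp(-nstep * p$dt / tau), tolerance = 0.05)
})

test_that("instability (huge displacement) is signalled as an error", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, kBT = 0, dt = 1)
  st <- cortosim:::new_state(p, build_icosphere(2, 2))
  st$x <- rbind(c(0, 0, 0), c(2 * p$seg_len, 0, 0))   # strongly stretched
  st$fil_id <- c(1L, 1L)
  st$seg_rest <- c(p$seg_len, NA)
  st$budget <- p$seg_len * p$monomers_per_um; st$pool <- 0
  expect_error(langevin_step(st, dt = 1, membrane_active = FALSE), "unstable")
})

test_that("identical parameters and seed give bitwise-identical series", {
  p <- scaled_params("shell", t_end = 5, t_assembly = 2, t_activate = 2,
                     actin_scale = 0.12)
  tr1 <- run_simulation(p, seed = 7)
  tr2 <- run_simulation(p, seed = 7)
  expect_identical(tr1$series, tr2$series)
  expect_identical(tr1$state$x, tr2$state$x)
  tr3 <- run_simulation(p, seed = 8)
  expect_false(identical(tr1$series$T_net_global, tr3$series$T_net_global))
})

test_that("a run ending at assembly returns the undeformed assembled state", {
  p <- scaled_params("shell", t_end = 2, t_assembly = 2, t_activate = 2,
                     actin_scale = 0.12)
  tr <- run_simulation(p, seed = 5)
  expect_equal(max(tr$series$t), 2)
  # membrane untouched during assembly
  expect_equal(sqrt(rowSums(tr$state$mesh$V^2)),
               rep(p$R_mem, nrow(tr$state$mesh$V)), tolerance = 1e-9)
  expect_silent(validate_state(tr$state))
})
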