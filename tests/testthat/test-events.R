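# Stochastic kinetics: Bell unbinding statistics, motor stepping statistics,
# severing rule, activation schedule.

test_that("activation schedule is all-or-none at t_activate", {
  p <- sim_params(t_assembly = 5, t_activate = 10, t_end = 20)
  expect_false(activation_schedule(0, p))
  expect_true(activation_schedule(10, p))
  expect_true(activation_schedule(15, p))
})

test_that("Bell unbinding rates have the exact zero-force and e-fold points", {
  p <- sim_params()
  dt <- 1e-4   # small dt: probability ~ rate * dt
  expect_equal(cortosim:::bell_prob(0, p, dt) / dt, p$k_off0, tolerance = 1e-3)
  F_e <- p$kBT / p$r0_bond   # force at which the rate is k_off0 * e
  expect_equal(cortosim:::bell_prob(F_e, p, dt) / dt, p$k_off0 * exp(1),
               tolerance = 1e-3)
})

test_that("ensemble bond survival matches the analytic exponential", {
  # N independent bonds under fixed force F: surviving fraction after t is
  # exp(-rate t) within 3 sigma binomial error
  set.seed(21)
  p <- sim_params(k_off0 = 0.5, r0_bond = 0.001)
  F <- 8
  rate <- p$k_off0 * exp(F * p$r0_bond / p$kBT)
  N <- 4000
  dt <- 0.02
  nstep <- 50       # t = 1 s
  alive <- rep(TRUE, N)
  for (s in seq_len(nstep)) {
    u <- runif(sum(alive))
    alive[alive] <- u >= cortosim:::bell_prob(rep(F, sum(alive)), p, dt)
  }
  t_tot <- nstep * dt
  expected <- exp(-rate * t_tot)
  sigma <- sqrt(expected * (1 - expected) / N)
  expect_lt(abs(mean(alive) - expected), 3 * sigma + 2e-3)
})

test_that("unloaded motor speed matches k_walk0 * step_size", {
  set.seed(22)
  p <- sim_params(k_walk0 = 20, step_size = 0.007)
  dt <- 0.005
  nstep <- 1e4
  pos <- 0
  for (s in seq_len(nstep)) pos <- pos + rpois(1, p$k_walk0 * dt) * p$step_size
  speed <- pos / (nstep * dt)
  expect_equal(speed, p$k_walk0 * p$step_size, tolerance = 0.05)
})

test_that("motor stepping stalls at the ensemble stall force", {
  p <- sim_params()
  f_stall <- p$F_stall * p$heads_per_side
  kw <- function(load) p$k_walk0 * max(0, 1 - load / f_stall)
  expect_equal(kw(0), p$k_walk0)
  expect_equal(kw(f_stall), 0)
  expect_equal(kw(2 * f_stall), 0)
})

test_that("severing splits filaments, returns monomers and logs the event", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, F_sev = 300)
  sl <- p$seg_len
  st <- cortosim:::new_state(p, build_icosphere(2, 2))
  st$x <- cbind(seq(0, by = sl, length.out = 4), 0, 0)
  st$fil_id <- rep(1L, 4)
  st$seg_rest <- c(sl, sl, sl, NA)
  st$budget <- 3 * sl * p$monomers_per_um
  st$pool <- 0
  st$time <- 7
  # tensions [100, 350, 200]: only the middle segment severs
  st2 <- severing_step(st, seg_tension = c(100, 350, 200))
  expect_equal(max(st2$fil_id), 2)
  expect_equal(as.integer(table(st2$fil_id)), c(2L, 2L))
  expect_equal(st2$pool, sl * p$monomers_per_um)
  expect_equal(nrow(st2$events), 1)
  expect_equal(st2$events$t, 7)
  expect_silent(validate_state(st2))
  # below threshold: unchanged
  st3 <- severing_step(st, seg_tension = c(100, 250, 200))
  expect_identical(st3$x, st$x)
  expect_equal(nrow(st3$events), 0)
  # disabled severing never acts
  p_inf <- sim_params(R_mem = 2, mesh_subdiv = 2, F_sev = Inf)
  st$params <- p_inf
  st4 <- severing_step(st, seg_tension = c(1e6, 1e6, 1e6))
  expect_identical(st4$x, st$x)
})

test_that("severing remaps cross-linker arms and unbinds those on the cut", {
  p <- sim_params(R_mem = 2, mesh_subdiv = 2)
  sl <- p$seg_len
  st <- cortosim:::new_state(p, build_icosphere(2, 2))
  st$x <- rbind(cbind(seq(0, by = sl, length.out = 5), 0, 0),
                cbind(seq(0, by = sl, length.out = 5), 0.07, 0))
  st$fil_id <- rep(1:2, each = 5)
  st$seg_rest <- rep(c(rep(sl, 4), NA), 2)
  st$budget <- 8 * sl * p$monomers_per_um
  st$pool <- 0
  # two cross-linkers: one on the cut segment of filament 1, one beyond it
  st$acps <- data.frame(
    bindable = FALSE,
    f1 = c(1L, 1L), p1 = c(1.5 * sl, 3.5 * sl),
    f2 = c(2L, 2L), p2 = c(1.5 * sl, 3.5 * sl),
    a_face = NA_integer_, a_w1 = NA_real_, a_w2 = NA_real_, a_w3 = NA_real_)
  # sever segment 2 (between nodes 2 and 3) of filament 1
  st2 <- severing_step(st, seg_tension = c(0, 400, 0, 0, 0, 0, 0, 0))
  expect_equal(max(st2$fil_id), 3)
  a <- st2$acps
  # first linker straddled the removed segment: that arm unbound
  expect_true(is.na(a$f1[1]))
  expect_false(is.na(a$f2[1]))
  # second linker moved to the distal piece with shifted arc position
  expect_false(is.na(a$f1[2]))
  expect_equal(a$p1[2], 3.5 * sl - 2 * sl, tolerance = 1e-9)
  expect_silent(validate_state(st2))
})

test_that("motors generate no active stepping before activation", {
  set.seed(23)
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, t_assembly = 5, t_activate = 5,
                  t_end = 10, k_off0 = 0, motor_k_off0 = 0)
  st <- make_fixture("single_filament_motor", p)
  st$time <- 1    # before activation
  pos0 <- st$motors$df$h1_pos
  for (i in 1:10) st <- motor_step(st, 0.05)
  expect_equal(st$motors$df$h1_pos, pos0)
  st$time <- 6    # after activation: the head walks
  for (i in 1:40) st <- motor_step(st, 0.05)
  expect_gt(st$motors$df$h1_pos, pos0)
})

test_that("heads reaching the barbed end unbind", {
  set.seed(24)
  p <- sim_params(R_mem = 2, mesh_subdiv = 2, t_activate = 0, t_assembly = 0,
                  t_end = 10, k_walk0 = 2000, k_off0 = 0, motor_k_off0 = 0,
                  k_on = 0)
  st <- make_fixture("single_filament_motor", p)
  st$time <- 1
  for (i in 1:200) st <- motor_step(st, 0.05)
  expect_true(is.na(st$motors$df$h1_fil))
})

test_that("crosslinker kinetics conserves total cross-linker count", {
  set.seed(25)
  p <- scaled_params("shell", t_end = 6, t_assembly = 2, t_activate = 2,
                     actin_scale = 0.15)
  st <- assemble_network(p, "shell")
  st <- couple_to_membrane(st)
  total0 <- nrow(st$acps) + st$acp_free_bindable + st$acp_free_plain
  for (i in 1:10) st <- crosslinker_kinetics_step(st, 0.05)
  expect_equal(nrow(st$acps) + st$acp_free_bindable + st$acp_free_plain, total0)
  expect_silent(validate_state(st))
})
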