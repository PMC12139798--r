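# Analytical bleb-initiation model: saddle-node pressure, detachment tension,
# rupture model, mechanism prediction.

test_that("laplace pressure has the expected forms and limits", {
  p <- theory_params(gamma_c = 0, gamma_m = 2, gamma_m0 = 2, R = 4, R0 = 4)
  expect_equal(laplace_pressure(p), 0)
  p2 <- theory_params(gamma_c = 1000, R = 10)
  expect_equal(laplace_pressure(p2, approximate = TRUE), 200)
  # cortex-dominated limit: full and approximate forms agree to gamma_m/gamma_c
  p3 <- theory_params(gamma_c = 500, gamma_m = 5, gamma_m0 = 5, R = 4, R0 = 4)
  rel <- abs(laplace_pressure(p3) - laplace_pressure(p3, approximate = TRUE)) /
    laplace_pressure(p3, approximate = TRUE)
  expect_lt(rel, 5 / 500 + 1e-12)
  expect_error(laplace_pressure(theory_params(R = -1)), "positive")
})

test_that("bond density equation has the mass-action equilibrium at zero load", {
  # with abundant sites, equilibrium rho_Hb = rho_H rho_A / (rho_A + Km2D);
  # at rho_A = Km2D that is rho_H / 2
  p <- theory_params(rho_H = 10, rho_A = 50, Km2D = 50, rho_Nb = 0)
  # solve rhs = 0 by root finding (independent of the closed form)
  root <- uniroot(function(x) bond_ode_rhs(x, 0, p), c(1e-9, p$rho_H - 1e-9))$root
  analytic <- p$rho_H * p$rho_A / (p$rho_A + p$Km2D + p$rho_H * 0)  # depletion small
  expect_equal(root, p$rho_H / 2, tolerance = 0.15)
  # saturated state relaxes: rhs < 0 at rho_Hb = rho_H
  expect_lt(bond_ode_rhs(p$rho_H - 1e-12, 0, p), 0)
  # singular exponent is signalled
  expect_error(bond_ode_rhs(0, 10, p), "singular")
})

test_that("bond density relaxes to a nearby stable fixed point under small load", {
  p <- theory_params()
  x0 <- uniroot(function(x) bond_ode_rhs(x, 0, p),
                c(0.5 * p$rho_H, p$rho_H - 1e-9))$root
  dP <- 0.05 * critical_pressure(p)
  # forward-Euler integration of the kinetics from the unloaded equilibrium
  x <- x0
  for (i in 1:20000) x <- x + 5e-4 * bond_ode_rhs(x, dP, p)
  expect_gt(x, 0.5 * x0)          # did not collapse
  expect_lt(abs(bond_ode_rhs(x, dP, p)), 1e-6 * p$rho_H)  # settled
})

test_that("critical pressure matches the nondimensional maximization oracle", {
  # independent oracle: dense grid maximization of x ln(A(1-x)/x)
  grid_pstar <- function(logA) {
    x <- seq(1e-6, 1 - 1e-6, length.out = 200001)
    max(x * (logA + log((1 - x) / x)))
  }
  expect_equal(cortosim:::critical_p_star(10), grid_pstar(10), tolerance = 1e-6)
  expect_equal(cortosim:::critical_p_star(10), 7.05, tolerance = 0.01)
  # dimensional scaling
  p <- theory_params(rho_H = 80)
  expect_equal(critical_pressure(p),
               p$kBT * p$rho_H / p$r0 * grid_pstar(log(p$rho_A / p$Km2D)),
               tolerance = 1e-6)
  # degenerate cases
  expect_equal(critical_pressure(theory_params(rho_H = 0)), 0)
  expect_equal(critical_pressure(theory_params(rho_A = 1, Km2D = 2)), 0)
})

test_that("critical pressure agrees with a brute-force fixed-point sweep", {
  # existence of a fixed point of the loaded bond equation on a dense dP grid
  for (lnA in c(4, 8, 12)) {
    p <- theory_params(rho_A = 1000, Km2D = 1000 * exp(-lnA))
    dPs <- critical_pressure(p)
    x <- seq(1e-6, 1 - 1e-6, length.out = 50001)
    dP_of_x <- p$kBT * p$rho_H * x / p$r0 *
      (lnA + log((1 - x) / x))
    expect_equal(dPs, max(dP_of_x), tolerance = 0.01)
  }
})

test_that("p*/lnA is increasing and bracketed on lnA in [5, 12]", {
  lnA <- seq(5, 12, by = 0.5)
  ratio <- vapply(lnA, function(z) cortosim:::critical_p_star(z) / z, 0)
  expect_true(all(diff(ratio) > 0))
  expect_true(all(ratio >= 0.58 & ratio <= 0.75))
})

test_that("detachment tension follows the Laplace relation and is linear in rho_H", {
  p <- theory_params(rho_H = 40)
  expect_equal(critical_detachment_tension(p) / (critical_pressure(p) * p$R),
               0.5, tolerance = 1e-12)
  p2 <- theory_params(rho_H = 80)
  expect_equal(critical_detachment_tension(p2),
               2 * critical_detachment_tension(p), tolerance = 1e-12)
  # closed-form prefactor is half the pressure prefactor
  cf <- critical_detachment_tension(p, closed_form = TRUE)
  expect_equal(cf, 0.35 * p$kBT * p$rho_H * p$R / p$r0 * log(p$rho_A / p$Km2D))
})

test_that("mechanism prediction switches once along each axis", {
  tp <- theory_params()
  rup <- rupture_tension_model()
  expect_equal(predict_mechanism(0, 0.1, tp, rup), "Detachment")
  # fixed R_X: single Detachment -> Rupture switch as R_C grows
  rc <- seq(0.001, 0.4, length.out = 60)
  mech <- vapply(rc, predict_mechanism, "", R_X = 0.08, p = tp, rupture = rup)
  expect_true(all(diff(mech == "Rupture") >= 0))
  expect_true("Detachment" %in% mech && "Rupture" %in% mech)
  # switch point agrees with bisection on the tension difference
  fdiff <- function(r) {
    pp <- tp; pp$rho_H <- r * tp$rho_A
    critical_detachment_tension(pp) - rup(0.08)
  }
  r_star <- uniroot(fdiff, c(1e-4, 0.4))$root
  expect_equal(min(rc[mech == "Rupture"]),
               min(rc[rc > r_star]), tolerance = 1e-9)
  # fixed R_C: single Rupture -> Detachment switch as R_X grows
  rx <- seq(0.02, 0.5, length.out = 60)
  mech2 <- vapply(rx, function(z) predict_mechanism(0.05, z, tp, rup), "")
  expect_true(all(diff(mech2 == "Detachment") >= 0))
  expect_true("Detachment" %in% mech2 && "Rupture" %in% mech2)
})

test_that("phase diagram boundary is monotone and refinement-stable", {
  tp <- theory_params()
  rup <- rupture_tension_model()
  pd <- phase_diagram(sort(c(0.1, seq(0.005, 0.3, length.out = 24))),
                      sort(c(0.1, seq(0.02, 0.5, length.out = 24))), tp, rup)
  # per R_X: the smallest R_C classified Rupture is nondecreasing in R_X
  thr <- vapply(split(pd, pd$R_X), function(d) {
    r <- d$R_C[d$mechanism == "Rupture"]
    if (length(r)) min(r) else Inf
  }, 0)
  expect_true(all(diff(thr[order(as.numeric(names(thr)))]) >= 0))
  # pointwise function: refinement does not change values on shared points
  pd1 <- phase_diagram(0.1, 0.1, tp, rup)
  expect_equal(pd$mechanism[pd$R_C == 0.1 & pd$R_X == 0.1],
               pd1$mechanism[1])
  expect_error(phase_diagram(numeric(0), 0.1), "nonempty")
})

test_that("rupture tension model is nondecreasing and R_C-independent", {
  rup <- rupture_tension_model(slope = 100)
  expect_equal(rup(0.2), 20)
  rx <- seq(0, 1, by = 0.05)
  expect_true(all(diff(rup(rx)) >= 0))
  tab <- rupture_tension_model(table = data.frame(R_X = c(0.1, 0.2, 0.4),
                                                  gamma = c(5, 9, 12)))
  expect_equal(tab(0.2), 9)
  expect_true(all(diff(tab(rx)) >= 0))
})
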