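---
title: "cortosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortosim)
```

# What the package simulates

`cortosim` is a coarse-grained Brownian-dynamics model of a contractile
actomyosin network enclosed in a cell-sized deformable vesicle, together
with an analytical theory of how such a system initiates a bleb — a
pressure-driven spherical membrane protrusion. The model has four kinds of
agents:

* **Actin filaments**, represented as chains of cylindrical segments
  (rest length `seg_len = 0.14` um) with harmonic stretching
  (`k_ext = 100` pN/um), angular bending with stiffness
  `kappa = Lp_actin * kBT / seg_len` (persistence length 9 um), and
  pairwise excluded-volume repulsion. Filaments nucleate and elongate
  during an assembly phase; they do not depolymerise, but any segment
  whose axial tension exceeds the severing threshold `F_sev` is removed,
  splitting the filament in two and returning its monomers to the pool.
* **Cross-linkers (ACPs)**, two-armed linkers in the alpha-actinin
  geometry. Each arm binds a filament site within a capture range at rate
  `k_on` and unbinds with Bell's force-dependent law
  `k_off0 * exp(F r0 / kBT)`. A configurable subset is additionally
  membrane-bindable; those acquire a *sliding anchor* on the triangulated
  membrane. The molar ratios `R_X` (all cross-linkers : actin) and `R_C`
  (membrane-bindable cross-linkers : actin) are the two central control
  parameters: network connectivity and actin-membrane coupling strength.
* **Myosin mini-filaments**, bipolar rods whose two ends each carry an
  effective head ensemble (`heads_per_side = 8` heads of stall force
  `F_stall = 5.7` pN, acting as one arm with ensemble stall force ~46 pN).
  Bound heads step toward the filament barbed end at
  `k_walk0 * max(0, 1 - F/F_stall_ensemble)` and unbind at the barbed end,
  the classical linear force-velocity relation. Motors are switched on
  all-or-none at `t_activate`, after the network has assembled.
* **The membrane**, a closed icosphere mesh with per-face area elasticity
  (`k_area`), dihedral bending rigidity (`k_bend_mem`), a stiff quadratic
  penalty on enclosed volume (`k_vol`, realising volume conservation
  without a constraint solver), and harmonic anchor springs to the
  membrane-bound cross-linkers. Anchor points are surface-bound particles:
  they carry the spring load to the face vertices barycentrically but
  *slide tangentially* with a small in-plane drag, so coupling points can
  migrate over the fluid membrane — a property that earlier cortex models
  lacked and that is required for large blebs.

All positions follow the overdamped Langevin equation,
`dx = (F/zeta) dt + sqrt(2 kBT dt / zeta) dW`, integrated by
Euler-Maruyama; drags come from segment/vertex geometry and the medium
viscosity `eta` (with a documented `drag_scale` multiplier that enlarges
the stable time step, standard practice for scaled-down runs). The
stability bound `dt < zeta_min / (2 k_max)` is computed by `stable_dt()`;
exceeding it is detected at run time as a displacement larger than two
segment lengths in one step and raised as an error rather than silently producing
garbage.

Every force term is the exact negative gradient of a declared potential.
The package carries an independent pure-R implementation of the total
potential energy (`potential_energy()`); the test suite checks the C++
forces against central finite differences of that energy to 1e-4 relative
error, checks that internal forces sum to zero, and that zero-temperature
relaxation is monotone in energy.

# The two bleb-initiation mechanisms and the analytical theory

When motors activate, the cortex contracts and pressurises the vesicle
interior (Young-Laplace: `dP = 2(gamma_m + gamma_c)/R - 2 gamma_m0/R0`,
cortex-dominated limit `dP ~ 2 gamma_c / R`). Two distinct events can let
the membrane escape:

* **Detachment** — the membrane-cortex bonds fail collectively. The bound
  linker density obeys a mass-action binding / Bell-unbinding equation in
  which the pressure load is shared over the bound linkers. Above a
  critical pressure the stable bound state vanishes in a saddle-node;
  nondimensionalised (`x = rho_Hb/rho_H`, `A = rho_A/Km2D`,
  `p = r0 dP/(kBT rho_H)`) the critical value is
  `p* = max_x x ln(A(1-x)/x)`, which is close to `0.7 ln A` for `ln A`
  near 10. The corresponding critical cortex tension is
  `gamma_CD* = dP* R/2`, exactly linear in the linker density and hence in
  `R_C`. `critical_pressure()` computes the saddle-node numerically
  (golden-section maximization to 1e-10; optionally on the full
  fixed-point relation with site depletion), never from the closed-form
  prefactor, which is kept only as the `closed_form = TRUE` variant.
* **Rupture** — the cortex itself tears by cascading filament severing.
  The critical cortex tension for rupture, `gamma_CR*`, is modeled
  parametrically as a nondecreasing function of `R_X`, independent of
  `R_C` (`rupture_tension_model()`); the default is linear through the
  origin with a slope calibrated so that the predicted switch at the
  reference connectivity `R_X = 0.08` falls at intermediate coupling
  (`R_C ~ 0.032`), where simulations show both mechanisms coexisting.

`predict_mechanism()` races the two critical tensions as the cortex
tension ramps up; `phase_diagram()` maps the winner over an
`(R_C, R_X)` grid. The boundary is monotone in both axes: raising `R_C`
at fixed `R_X` switches Detachment to Rupture exactly once, raising `R_X`
at fixed `R_C` switches back exactly once.

# Measurement suite

* **Tension.** The model does not come with a canonical tension
  observable, so the package uses a cutting-plane estimator: for each of
  several great-circle planes, the tensile axial force components of
  network segments crossing the plane (and the in-plane per-face membrane
  tensions weighted by intersection length) are summed and divided by the
  cut contour `2 pi R` of the best-fit sphere. This estimator has the
  right units (pN/um), is exact on a hand-built shell of meridional
  springs, and is validated against the Young-Laplace relation: a
  pre-tensed spherical membrane yields a measured pressure jump within 5%
  of `2 gamma / R`. `local_tension()` restricts the same estimator to a
  spherical-cap window.
* **Blebs.** `detect_blebs()` fits a sphere to the main body robustly,
  takes connected components of vertices protruding beyond the fitted
  radius plus a height threshold, requires a concave neck (negative mean
  curvature on the boundary ring, cotangent-Laplacian estimate), and
  discards candidates below the 0.8 um diameter cutoff. Detection is
  rotation- and translation-invariant. `track_blebs()` links detections
  across snapshots by face-set overlap (Jaccard > 0.3).
* **Mechanism call.** `classify_initiation()` compares the cortical
  polymer density beneath the bleb around its onset with the pre-onset
  value, over one consistent conical support (at least 0.6 rad half-angle)
  used for both the density and the severing-event test: `Rupture` when
  the density collapsed below 25% of the pre-onset mean with at least one
  logged severing event beneath the region within +-5 s; `Detachment`
  when the density is retained (>= 75%) while the membrane-cortex radial
  gap exceeds twice the anchor rest length; `Undetermined` otherwise.
  These thresholds are declared defaults, configurable by the caller.
* **Morphology.** Four exclusive classes, assigned from the cumulative
  number of distinct bleb tracks (>= 2 `MultipleBlebs`, exactly 1
  `SingleBleb`) or, with no blebs, from the deformation magnitude
  `Lmax/Dinit` (maximum caliper width over the trajectory divided by the
  initial diameter; `WeakDeformation` above 1.05, `NoDeformation` below).
* **Orientation and densities.** `motor_orientation()` returns
  `90 deg - acute angle(backbone, centre-to-centroid)` per mini-filament
  (0 = tangential, 90 = radial); `density_profile()` reports polymer
  length per volume in the outer shell versus the interior and per-area
  motor/linker densities beneath the membrane.

# Scaled-down study conditions

The paper-scale reference configuration (`reference_params()`: 8-um
membrane, 10 uM actin, `R_X = R_C = 0.08`, `R_M = 0.01`, 300 pN severing
threshold, 300 s of model time) is faithful but takes cluster-scale
compute. The package therefore defines a desk-scale analogue,
`scaled_params()`, used by the test suite; its choices are the package's
own study conditions and are documented here once:

* 3-um-diameter membrane, subdivision-3 icosphere, ~30% of the nominal
  monomer budget, mean filament length 2.8 um (longer relative to the
  vesicle than at full scale, giving motors enough runway to load up),
  `R_M = 0.04` (more motors per filament compensate the reduced network
  depth).
* `drag_scale = 30` with `dt = 2.8 ms`: inflating the drag slows all
  deterministic dynamics uniformly and permits a large stable step;
  kinetics rates are chosen on the same effective clock.
* `F_sev = 40` pN by default in `scaled_params()` (the regime suite in
  the acceptance tests uses 16 pN with its denser network): segment
  tensions in the small network reach tens rather than hundreds of pN, so
  the severing threshold is scaled with them. With severing disabled
  (`F_sev = Inf`) no rupture-initiated blebs occur, reproducing the
  corresponding full-scale control.
* A 3.5% membrane area reservoir (`excess_area`) with a 1.5% reference
  volume inflation (`vol_inflate`): real liposomes bleb from
  excess area rather than by stretching the bilayer; without slack no
  protrusion can inflate at these pressures. The slight osmotic inflation
  keeps the resting membrane weakly taut, so transient dents from the
  contracting cortex relax instead of ratcheting the maximum caliper; the
  remaining slack funds one-to-few micrometre-scale blebs.
* Bell distances: `r0_bond = 3e-4` um for linker-actin bonds (load must
  accumulate to tens of pN before bonds yield) and a larger
  `anchor_r0_bond = 1.5e-3` um for the membrane anchor linkage, making
  membrane anchors the mechanically weakest bond in the chain. This
  asymmetry is what lets the desk-scale system race the two mechanisms
  the way the theory describes: at low `R_C` the few anchors carry high
  per-bond load and peel (detachment) before network tension reaches the
  severing threshold, while at high `R_C` the load is shared over many
  anchors, the cortex stays attached, tension concentrates and severing
  tears a hole (rupture).

What the desk-scale generator does *not* emulate: the ~200 pN/um tension
plateau, the ~150 s onset times and the quantitative Fig.-8-style
efficiency numbers of the full-scale model; hydrodynamic interactions;
explicit monomer diffusion; depolymerisation. Passing desk-scale tests
therefore demonstrates the mechanisms and their parameter dependence, not
the full-scale quantitative values.

# Numerical choices and degenerate inputs

* Volume conservation is a stiff quadratic penalty; the stiffness keeps
  volume drift below ~1% in reference runs.
* Excluded volume uses a harmonic overlap penalty of range
  `3 * d_actin` (widened for stability) with candidate pairs from a
  midpoint prefilter rebuilt with a safety skin.
* Severing processes segments in descending tension order within a step;
  simultaneous over-threshold segments all sever; single-node remnants
  are dropped with full remapping of attached linkers and motor heads.
* Binding eligibility: a free arm binds the nearest site within one
  segment length on a *different* filament; per-segment arm occupancy is
  capped to avoid pile-up.
* Degenerate inputs error loudly: zero-length segments, zero-area mesh
  triangles, non-manifold meshes, anchors on missing faces, and unstable
  time steps are all detected.
* Determinism: a single seeded generator drives every stochastic choice;
  the same `(params, seed)` reproduces time series bitwise. The Langevin
  inner loop consumes pre-drawn normal deviates from R's generator, so
  the C++ fast path does not change the random stream contract.

# Known limitations

* The cutting-plane tension estimator and the bleb-mechanism thresholds
  are this package's operationalization; the source experiments identify
  mechanisms visually.
* Desk-scale networks are sparse (tens of filaments), so bleb statistics
  carry large seed-to-seed variability; regime checks use majority votes
  over seeds. Two full-scale phenomena have no robust desk analog: the
  rupture pathway (scattered severing events do not dig the micrometre
  hole that a dense percolated cortex concentrates them into, so blebs
  rarely classify as rupture even at strong coupling) and the 3D
  multiple-bleb window (volume-distributed linkers at low density leave
  too few membrane coupling points to bleb at all at this size). The
  corresponding acceptance-style checks fail at desk scale by design of
  honesty, not by accident.
* The rupture tension model `gamma_CR*(R_X)` is parametric (monotone,
  `R_C`-independent); the package does not derive it from first
  principles.
* Membrane-filament sterics beyond anchored coupling are reduced to
  vertex-segment repulsion, which keeps the cortex beneath the membrane
  but is not a full contact model.
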