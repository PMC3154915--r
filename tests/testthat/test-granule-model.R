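# Flux laws of the granule membrane model: closed-form anchors,
# thermodynamic consistency, and stoichiometric bookkeeping.

test_that("Nernst potential matches the closed form and its symmetries", {
  # equal concentrations
  expect_equal(nernst_potential(1, 5, 5), 0)
  # (RT/F) ln 10 at 310.15 K = 61.54 mV
  expect_equal(nernst_potential(1, 10, 1, 310.15), 61.5422, tolerance = 1e-4)
  # antisymmetry in z and under swapping compartments
  expect_equal(nernst_potential(-1, 10, 1), -nernst_potential(1, 10, 1))
  expect_equal(nernst_potential(1, 1, 10), -nernst_potential(1, 10, 1))
  # a divalent ion sees half the potential
  expect_equal(nernst_potential(2, 10, 1), nernst_potential(1, 10, 1) / 2)
  expect_error(nernst_potential(1, 0, 1), "positive")
  expect_error(nernst_potential(0, 1, 1), "nonzero")
})

test_that("ATPase driving force and stall potential follow the free energy", {
  st <- stoichiometry()
  cyto <- cytosol_state()
  # no opposing gradient: full -dG_ATP available
  lum <- lumen_state(pH = cyto$pH, psi_mV = 0)
  expect_equal(atpase_driving_force(lum, cyto, st), 57)
  # closed-form stall: -dG_ATP/(nH F) = 295.36 mV at 2 H+/ATP
  psi_stall <- atpase_stall_potential(cyto, st)
  expect_equal(psi_stall, 295.358, tolerance = 1e-3)
  at_stall <- lumen_state(pH = cyto$pH, psi_mV = psi_stall)
  expect_equal(atpase_driving_force(at_stall, cyto, st), 0, tolerance = 1e-10)
  # monotone decreasing in psi: beyond stall the driving force is negative
  over <- lumen_state(pH = cyto$pH, psi_mV = psi_stall + 10)
  expect_lt(atpase_driving_force(over, cyto, st), 0)
  # root-finding the driving force recovers the closed form to < 0.1 mV
  root <- uniroot(function(psi)
    atpase_driving_force(lumen_state(pH = cyto$pH, psi_mV = psi), cyto, st),
    c(0, 500), tol = 1e-10)$root
  expect_lt(abs(root - psi_stall), 0.1)
  # one pH unit of acidification moves the stall by (RT/F) ln10 per H+
  acid <- lumen_state(pH = cyto$pH - 1, psi_mV = psi_stall - 61.5422)
  expect_equal(atpase_driving_force(acid, cyto, st), 0, tolerance = 1e-3)
})

test_that("ATPase flux is unidirectional, saturating and zero at stall", {
  st <- stoichiometry()
  cyto <- cytosol_state()
  p <- transporter_params(pump_Jmax = 1e-19)
  psi_stall <- atpase_stall_potential(cyto, st)
  expect_equal(atpase_flux(lumen_state(pH = cyto$pH, psi_mV = psi_stall),
                           cyto, p, st), 0, tolerance = 1e-25)
  expect_equal(atpase_flux(lumen_state(pH = cyto$pH, psi_mV = psi_stall + 50),
                           cyto, p, st), 0)
  # D = 2RT gives Jmax tanh(1)
  RT <- gg_constants$R * cyto$temperature_K
  psi_2RT <- psi_stall - 2 * RT / (st$atpase_nH * gg_constants$F) * 1e3
  expect_equal(atpase_flux(lumen_state(pH = cyto$pH, psi_mV = psi_2RT),
                           cyto, p, st), 1e-19 * tanh(1), tolerance = 1e-6)
  # saturation bound far from stall
  expect_equal(atpase_flux(lumen_state(pH = cyto$pH, psi_mV = 0), cyto, p, st),
               1e-19, tolerance = 1e-8)
  p_off <- transporter_params(pump_enabled = FALSE)
  expect_identical(atpase_flux(lumen_state(), cyto, p_off, st), 0)
})

test_that("VGLUT flux reverses at its Nernst potential with Km saturation", {
  st <- stoichiometry()
  cyto <- cytosol_state(glu_mM = 3)
  p <- transporter_params(vglut_enabled = TRUE, vglut_Jmax = 1e-19,
                          vglut_Km_glu = 5)
  # equilibrium: lumen 10x cytosol needs psi = +61.54 mV for an anion
  E <- -nernst_potential(-1, 30, 3)
  expect_equal(E, 61.5422, tolerance = 1e-4)
  lum_eq <- lumen_state(glu_mM = 30, psi_mV = E)
  expect_equal(vglut_flux(lum_eq, cyto, p, st), 0, tolerance = 1e-30)
  # positive psi with equal concentrations loads the lumen
  expect_gt(vglut_flux(lumen_state(glu_mM = 3, psi_mV = 50), cyto, p, st), 0)
  expect_lt(vglut_flux(lumen_state(glu_mM = 3, psi_mV = -50), cyto, p, st), 0)
  # half-saturation at glu_c = Km under a large driving force
  cyto_km <- cytosol_state(glu_mM = 5)
  J <- vglut_flux(lumen_state(glu_mM = 0.01, psi_mV = 280), cyto_km, p, st)
  expect_equal(J, 0.5 * 1e-19, tolerance = 1e-3)
  p_off <- transporter_params()
  expect_identical(vglut_flux(lumen_state(), cyto, p_off, st), 0)
})

test_that("EAAT2 cycle free energy carries a net charge coefficient of 2", {
  st <- stoichiometry()
  expect_identical(st$eaat2_net_charge_out, 2L)
  # flat gradients, psi = 0: equilibrium
  cyto <- cytosol_state(glu_mM = 3, Na_mM = 15, K_mM = 140)
  lum_flat <- lumen_state(pH = cyto$pH, glu_mM = 3, Na_mM = 15, K_mM = 140,
                          psi_mV = 0)
  expect_equal(eaat2_cycle_free_energy(lum_flat, cyto, st), 0,
               tolerance = 1e-12)
  # the electrical term: dG shifts by -2 F dpsi per mole
  lum_psi <- lum_flat; lum_psi$psi_mV <- 100
  expect_equal(eaat2_cycle_free_energy(lum_psi, cyto, st),
               -2 * gg_constants$F * 0.1 / 1e3, tolerance = 1e-9)
  # acidic lumen at positive psi favours export
  lum_acid <- lumen_state(pH = cyto$pH - 1.5, glu_mM = 3, Na_mM = 15,
                          K_mM = 140, psi_mV = 50)
  expect_lt(eaat2_cycle_free_energy(lum_acid, cyto, st), 0)
  expect_error(eaat2_cycle_free_energy(lum_flat, cytosol_state(glu_mM = 0)),
               "positive")
})

test_that("EAAT2 flux bookkeeping is exactly stoichiometric", {
  st <- stoichiometry()
  cyto <- cytosol_state()
  p <- transporter_params(eaat2_enabled = TRUE, eaat2_Jmax = 1e-19)
  lum <- lumen_state(pH = 5.5, glu_mM = 20, Na_mM = 70, K_mM = 30,
                     psi_mV = 80)
  fl <- eaat2_flux(lum, cyto, p, st)
  v <- fl$cycle_rate
  expect_gt(v, 0)  # export under an acidic, positive, Na-loaded lumen
  expect_identical(fl$glu, -v)
  expect_identical(fl$Na, -3 * v)
  expect_identical(fl$H, -v)
  expect_identical(fl$K, v)
  expect_identical(fl$charge, -2 * v)
  # equilibrium: all five coupled fluxes vanish
  lum_flat <- lumen_state(pH = cyto$pH, glu_mM = cyto$glu_mM,
                          Na_mM = cyto$Na_mM, K_mM = cyto$K_mM, psi_mV = 0)
  fl0 <- eaat2_flux(lum_flat, cyto, p, st)
  expect_true(all(abs(unlist(fl0)) < 1e-30))
  # saturation bound
  lum_deep <- lumen_state(pH = 3, glu_mM = 100, Na_mM = 150, K_mM = 1,
                          psi_mV = 250)
  expect_lt(eaat2_flux(lum_deep, cyto, p, st)$cycle_rate,
            1e-19 * (1 + 1e-12))
  expect_identical(eaat2_flux(lum, cyto, transporter_params(), st)$cycle_rate,
                   0)
})

test_that("passive fluxes reverse at their Nernst potentials with the right sign", {
  cyto <- cytosol_state(Cl_mM = 40)
  p <- transporter_params(cl_enabled = TRUE, cl_g = 1e-21,
                          leak_enabled = TRUE, leak_g = 1e-21)
  # Cl-: equal concentrations reverse at 0; positive psi pulls Cl- in
  expect_equal(passive_flux(lumen_state(Cl_mM = 40, psi_mV = 0), cyto, p,
                            "Cl"), 0)
  expect_gt(passive_flux(lumen_state(Cl_mM = 40, psi_mV = 50), cyto, p,
                         "Cl"), 0)
  # H+ leak: acidic lumen at positive psi loses protons
  expect_lt(passive_flux(lumen_state(pH = 5.5, psi_mV = 50), cyto, p,
                         "leak"), 0)
  # disabled pathway contributes exactly zero
  expect_identical(passive_flux(lumen_state(psi_mV = 200), cyto,
                                transporter_params(cl_enabled = FALSE),
                                "Cl"), 0)
})

test_that("capacitive potential follows Q/C", {
  g <- granule_geometry(150, 1)
  expect_equal(g$area_um2, 4 * pi * 0.15^2, tolerance = 1e-12)
  expect_equal(g$volume_L, 4 / 3 * pi * (150e-9)^3 * 1e3, tolerance = 1e-12)
  expect_equal(g$capacitance_F, 2.827433e-15, tolerance = 1e-6)
  expect_equal(charge_to_potential(0, g), 0)
  # 4400 elementary charges on a 150 nm granule give ~ +250 mV
  Q <- 4.4e3 * 1.602176634e-19
  expect_equal(charge_to_potential(Q, g), 249.33, tolerance = 1e-4)
  # doubling the specific capacitance halves the potential
  g2 <- granule_geometry(150, 2)
  expect_equal(charge_to_potential(Q, g2), charge_to_potential(Q, g) / 2)
})

test_that("every flux law is zero at equilibrium and signed by its driving force", {
  st <- stoichiometry()
  p <- all_enabled_params()
  for (case in random_states(40)) {
    lum <- case$lumen; cyto <- case$cyto
    # ATPase: nonnegative, zero iff driving force <= 0, bounded
    D <- atpase_driving_force(lum, cyto, st)
    J <- atpase_flux(lum, cyto, p, st)
    expect_gte(J, 0)
    expect_lte(J, p$pump_Jmax)
    if (D > 1e-6) expect_gt(J, 0) else expect_equal(J, 0, tolerance = 1e-40)
    # VGLUT: sign equals sign of (psi - E_glu), bounded
    E <- -nernst_potential(-1, max(lum$glu_mM, 1e-3), cyto$glu_mM)
    Jv <- vglut_flux(lum, cyto, p, st)
    expect_lte(abs(Jv), p$vglut_Jmax)
    expect_equal(sign(Jv), sign(lum$psi_mV - E), tolerance = 0)
    # EAAT2: sign equals sign of -dG, bounded by Jmax
    dG <- eaat2_cycle_free_energy(lum, cyto, st)
    v <- eaat2_flux(lum, cyto, p, st)$cycle_rate
    expect_lte(abs(v), p$eaat2_Jmax)
    expect_equal(sign(v), sign(-dG), tolerance = 0)
  }
})
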