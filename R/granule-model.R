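#' Granule geometry
#'
#' Builds the fixed geometry of a spherical secretory granule: membrane area,
#' luminal volume and total electrical capacitance, all derived from the
#' radius and the specific membrane capacitance.
#'
#' @param radius_nm granule radius in nm (default 150, i.e. a 300 nm
#'   dense-core granule).
#' @param specific_capacitance_uF_cm2 membrane specific capacitance in
#'   µF/cm² (default 1, the standard biological membrane value).
#' @return An object of class `granule_geometry`: a list with `radius_nm`,
#'   `area_um2`, `volume_L` and `capacitance_F`.
#' @examples
#' g <- granule_geometry(150)
#' g$capacitance_F   # ~2.8e-15 F
#' @export
granule_geometry <- function(radius_nm = 150, specific_capacitance_uF_cm2 = 1) {
  stopifnot(radius_nm > 0, specific_capacitance_uF_cm2 > 0)
  r_m <- radius_nm * 1e-9
  area_m2 <- 4 * pi * r_m^2
  volume_m3 <- (4 / 3) * pi * r_m^3
  structure(list(
    radius_nm = radius_nm,
    specific_capacitance_uF_cm2 = specific_capacitance_uF_cm2,
    area_um2 = area_m2 * 1e12,
    volume_L = volume_m3 * 1e3,
    # µF/cm² -> F/m² is a factor 1e-2
    capacitance_F = specific_capacitance_uF_cm2 * 1e-2 * area_m2
  ), class = "granule_geometry")
}

#' Cytosolic (reservoir) state
#'
#' The cytosol is treated as an infinite reservoir: its composition is held
#' constant for the duration of a simulation.
#'
#' @param pH cytosolic pH.
#' @param glu_mM,Na_mM,K_mM,Cl_mM cytosolic concentrations (mM).
#' @param dG_ATP_kJ free energy of ATP hydrolysis (kJ/mol, negative).
#' @param temperature_K absolute temperature.
#' @return An object of class `cytosol_state`.
#' @export
cytosol_state <- function(pH = 7.2, glu_mM = 3, Na_mM = 15, K_mM = 140,
                          Cl_mM = 40, dG_ATP_kJ = -57, temperature_K = 310.15) {
  stopifnot(glu_mM >= 0, Na_mM >= 0, K_mM >= 0, Cl_mM >= 0,
            dG_ATP_kJ < 0, temperature_K > 0)
  structure(list(pH = pH, glu_mM = glu_mM, Na_mM = Na_mM, K_mM = K_mM,
                 Cl_mM = Cl_mM, dG_ATP_kJ = dG_ATP_kJ,
                 temperature_K = temperature_K),
            class = "cytosol_state")
}

#' Luminal state of the granule
#'
#' Time-varying state of the granule lumen. `psi_mV` is the membrane
#' potential, lumen minus cytosol.
#'
#' @param pH luminal pH.
#' @param glu_mM,Na_mM,K_mM,Cl_mM luminal concentrations (mM).
#' @param psi_mV membrane potential (mV, lumen minus cytosol).
#' @return An object of class `lumen_state`.
#' @export
lumen_state <- function(pH = 7.2, glu_mM = 0.01, Na_mM = 70, K_mM = 30,
                        Cl_mM = 40, psi_mV = 0) {
  stopifnot(glu_mM >= 0, Na_mM >= 0, K_mM >= 0, Cl_mM >= 0,
            is.finite(psi_mV))
  structure(list(pH = pH, glu_mM = glu_mM, Na_mM = Na_mM, K_mM = K_mM,
                 Cl_mM = Cl_mM, psi_mV = psi_mV),
            class = "lumen_state")
}

#' Transporter stoichiometries
#'
#' Fixed integer coupling ratios. The EAAT2-class carrier exports one
#' glutamate anion together with 3 Na+ and 1 H+ while importing 1 K+, so each
#' export cycle removes 2 net positive charges from the lumen.
#'
#' @param atpase_nH_per_ATP protons pumped per ATP hydrolysed (integer >= 1).
#' @return An object of class `stoichiometry`.
#' @export
stoichiometry <- function(atpase_nH_per_ATP = 2) {
  stopifnot(atpase_nH_per_ATP >= 1, atpase_nH_per_ATP == round(atpase_nH_per_ATP))
  s <- list(eaat2_nNa = 3L, eaat2_nH = 1L, eaat2_nK = 1L, eaat2_nGlu = 1L,
            atpase_nH = as.integer(atpase_nH_per_ATP), vglut_zGlu = -1L)
  # net positive charge leaving the lumen per exported glutamate
  s$eaat2_net_charge_out <- s$eaat2_nNa + s$eaat2_nH -
    s$eaat2_nGlu * abs(s$vglut_zGlu) - s$eaat2_nK
  stopifnot(s$eaat2_net_charge_out == 2L)
  structure(s, class = "stoichiometry")
}

#' Maximal rates and conductances of the membrane pathways
#'
#' Each pathway carries an `enabled` flag; a disabled pathway contributes
#' exactly zero flux. Rates are per granule.
#'
#' @param pump_Jmax maximal H+-ATPase proton flux (mol/s).
#' @param vglut_Jmax maximal VGLUT glutamate flux (mol/s).
#' @param vglut_Km_glu cytosolic glutamate Km of VGLUT (mM).
#' @param eaat2_Jmax maximal EAAT2 cycle rate (mol cycles/s).
#' @param eaat2_Km_glu luminal/cytosolic glutamate half-saturation of the
#'   EAAT2 carrier (mM); shuts the carrier off smoothly as its substrate
#'   pool empties.
#' @param cl_g Cl- conductance-like rate (mol/s per mV), default 0.
#' @param leak_g cation (Na+) leak rate (mol/s per mV), default 0.
#' @param pump_enabled,vglut_enabled,eaat2_enabled,cl_enabled,leak_enabled
#'   logical pathway switches.
#' @return An object of class `transporter_params`.
#' @export
transporter_params <- function(pump_Jmax = 5e-20, vglut_Jmax = 5e-20,
                               vglut_Km_glu = 5, eaat2_Jmax = 2e-20,
                               eaat2_Km_glu = 0.5,
                               cl_g = 0, leak_g = 1e-22,
                               pump_enabled = TRUE, vglut_enabled = FALSE,
                               eaat2_enabled = FALSE, cl_enabled = FALSE,
                               leak_enabled = TRUE) {
  stopifnot(pump_Jmax >= 0, vglut_Jmax >= 0, vglut_Km_glu > 0,
            eaat2_Jmax >= 0, eaat2_Km_glu > 0, cl_g >= 0, leak_g >= 0)
  structure(list(pump_Jmax = pump_Jmax, vglut_Jmax = vglut_Jmax,
                 vglut_Km_glu = vglut_Km_glu, eaat2_Jmax = eaat2_Jmax,
                 eaat2_Km_glu = eaat2_Km_glu, cl_g = cl_g, leak_g = leak_g,
                 pump_enabled = pump_enabled, vglut_enabled = vglut_enabled,
                 eaat2_enabled = eaat2_enabled, cl_enabled = cl_enabled,
                 leak_enabled = leak_enabled),
            class = "transporter_params")
}

#' Proton buffering capacity of the lumen
#'
#' @param beta_mM_per_pH mM of protons required to shift luminal pH by one
#'   unit (default 40).
#' @return An object of class `buffer_model`.
#' @export
buffer_model <- function(beta_mM_per_pH = 40) {
  stopifnot(beta_mM_per_pH > 0)
  structure(list(beta_mM_per_pH = beta_mM_per_pH), class = "buffer_model")
}

#' Nernst equilibrium potential
#'
#' Returns (RT/zF)·ln(c_lumen/c_cyto) in mV. Antisymmetric under swapping
#' the two compartments and under the sign of z.
#'
#' @param z integer ionic charge (nonzero).
#' @param c_lumen_mM,c_cyto_mM concentrations on the two sides (mM, > 0).
#' @param temperature_K absolute temperature (default 310.15 K).
#' @return Potential in mV (lumen minus cytosol at equilibrium).
#' @examples
#' nernst_potential(1, 10, 1)    # ~ +61.5 mV at 310.15 K
#' nernst_potential(-1, 10, 1)   # ~ -61.5 mV
#' @export
nernst_potential <- function(z, c_lumen_mM, c_cyto_mM, temperature_K = 310.15) {
  if (z == 0) stop("z must be a nonzero integer charge")
  if (any(c_lumen_mM <= 0) || any(c_cyto_mM <= 0))
    stop("Nernst potential requires strictly positive concentrations")
  1e3 * rt_J(temperature_K) / (z * gg_constants$F) * log(c_lumen_mM / c_cyto_mM)
}

# free [H+] in mM from pH
h_mM <- function(pH) 10^(-pH) * 1e3

#' Net free energy available to the H+-ATPase
#'
#' The pump hydrolyses one ATP to move `atpase_nH` protons into the lumen
#' against the electrochemical proton gradient. Returns
#' \eqn{-\Delta G_{ATP} - n_H (F\psi + RT \ln([H^+]_L/[H^+]_c))} in kJ/mol:
#' positive while pumping is downhill overall, zero at the stall point.
#'
#' @param lumen a [lumen_state()].
#' @param cyto a [cytosol_state()].
#' @param stoich a [stoichiometry()].
#' @return Driving free energy in kJ/mol ATP.
#' @export
atpase_driving_force <- function(lumen, cyto, stoich = stoichiometry()) {
  RT <- rt_J(cyto$temperature_K)
  psi_V <- lumen$psi_mV * 1e-3
  dmuH <- gg_constants$F * psi_V +
    RT * log(h_mM(lumen$pH) / h_mM(cyto$pH))
  (-cyto$dG_ATP_kJ * 1e3 - stoich$atpase_nH * dmuH) / 1e3
}

#' Stall potential of the H+-ATPase
#'
#' The membrane potential at which, for equal luminal and cytosolic pH, the
#' pump's driving force vanishes: \eqn{-\Delta G_{ATP}/(n_H F)}.
#'
#' @inheritParams atpase_driving_force
#' @return Stall potential in mV.
#' @export
atpase_stall_potential <- function(cyto = cytosol_state(),
                                   stoich = stoichiometry()) {
  -cyto$dG_ATP_kJ * 1e3 / (stoich$atpase_nH * gg_constants$F) * 1e3
}

#' H+-ATPase proton flux
#'
#' Unidirectional saturating rate law
#' \eqn{J = J_{max}\,\max(0, \tanh(D/2RT))} with D the driving force from
#' [atpase_driving_force()]. Zero at or beyond stall; bounded by `pump_Jmax`.
#'
#' @inheritParams atpase_driving_force
#' @param params a [transporter_params()].
#' @return Proton flux into the lumen (mol/s).
#' @export
atpase_flux <- function(lumen, cyto, params = transporter_params(),
                        stoich = stoichiometry()) {
  if (!params$pump_enabled) return(0)
  D_J <- atpase_driving_force(lumen, cyto, stoich) * 1e3
  params$pump_Jmax * max(0, tanh(D_J / (2 * rt_J(cyto$temperature_K))))
}

#' VGLUT glutamate flux
#'
#' Electrogenic uniport of glutamate(-) driven by its electrochemical
#' gradient: \eqn{J = J_{max}\,\mathrm{sat}(glu_c)\,\tanh(\Delta G_v/2RT)}
#' with \eqn{\Delta G_v = -zF(\psi - E_{glu})}, z = -1. Positive flux loads
#' the lumen; the law reverses sign with the gradient and is exactly zero at
#' \eqn{\psi = E_{glu}}.
#'
#' @inheritParams atpase_flux
#' @return Glutamate flux into the lumen (mol/s).
#' @export
vglut_flux <- function(lumen, cyto, params = transporter_params(),
                       stoich = stoichiometry()) {
  if (!params$vglut_enabled) return(0)
  RT <- rt_J(cyto$temperature_K)
  # reversal potential in lumen-minus-cytosol convention:
  # E = (RT/zF) ln(c_cyto/c_lumen)
  E_glu <- nernst_potential(stoich$vglut_zGlu, floor_conc(cyto$glu_mM),
                            floor_conc(lumen$glu_mM), cyto$temperature_K)
  dG_v <- -stoich$vglut_zGlu * gg_constants$F * (lumen$psi_mV - E_glu) * 1e-3
  sat <- cyto$glu_mM / (cyto$glu_mM + params$vglut_Km_glu)
  params$vglut_Jmax * sat * tanh(dG_v / (2 * RT))
}

#' Free energy of one EAAT2 export cycle
#'
#' One cycle moves 3 Na+, 1 H+ and 1 glutamate(-) from lumen to cytosol and
#' 1 K+ from cytosol to lumen, i.e. 2 net positive charges leave the lumen.
#' Returns the cycle \eqn{\Delta G} in kJ/mol exported glutamate; negative
#' means export is thermodynamically favourable.
#'
#' @inheritParams atpase_driving_force
#' @return kJ/mol per exported glutamate.
#' @export
eaat2_cycle_free_energy <- function(lumen, cyto, stoich = stoichiometry()) {
  if (cyto$Na_mM <= 0 || cyto$K_mM <= 0 || cyto$glu_mM <= 0)
    stop("EAAT2 cycle free energy requires positive coupled-ion concentrations")
  RT <- rt_J(cyto$temperature_K)
  psi_V <- lumen$psi_mV * 1e-3
  dG <- RT * (
    stoich$eaat2_nNa * log(cyto$Na_mM / floor_conc(lumen$Na_mM)) +
    stoich$eaat2_nH  * log(h_mM(cyto$pH) / h_mM(lumen$pH)) +
    stoich$eaat2_nGlu * log(floor_conc(cyto$glu_mM) / floor_conc(lumen$glu_mM)) +
    stoich$eaat2_nK  * log(floor_conc(lumen$K_mM) / cyto$K_mM)
  ) - stoich$eaat2_net_charge_out * gg_constants$F * psi_V
  dG / 1e3
}

#' EAAT2 coupled flux
#'
#' Reversible saturating rate law
#' \eqn{v = J_{max}\,\mathrm{sat}(glu)\,\tanh(-\Delta G_{cycle}/2RT)} with the
#' saturation factor taken on the substrate-donor side (luminal glutamate in
#' export mode, cytosolic in import mode). Returns the full stoichiometric
#' bookkeeping: per cycle rate v (export positive), the species fluxes into
#' the lumen are glu = -v, Na = -3v, H = -v, K = +v, and the luminal charge
#' flux is -2v.
#'
#' @inheritParams atpase_flux
#' @return A list with elements `cycle_rate` (mol/s, export positive) and
#'   `glu`, `Na`, `H`, `K` (mol/s into the lumen) and `charge` (mol charge/s
#'   into the lumen).
#' @export
eaat2_flux <- function(lumen, cyto, params = transporter_params(),
                       stoich = stoichiometry()) {
  zero <- list(cycle_rate = 0, glu = 0, Na = 0, H = 0, K = 0, charge = 0)
  if (!params$eaat2_enabled) return(zero)
  RT <- rt_J(cyto$temperature_K)
  dG_J <- eaat2_cycle_free_energy(lumen, cyto, stoich) * 1e3
  raw <- tanh(-dG_J / (2 * RT))
  sat <- if (raw >= 0) {
    lumen$glu_mM / (lumen$glu_mM + params$eaat2_Km_glu)
  } else {
    cyto$glu_mM / (cyto$glu_mM + params$eaat2_Km_glu)
  }
  v <- params$eaat2_Jmax * sat * raw
  list(cycle_rate = v,
       glu = -stoich$eaat2_nGlu * v,
       Na  = -stoich$eaat2_nNa * v,
       H   = -stoich$eaat2_nH * v,
       K   = +stoich$eaat2_nK * v,
       charge = -stoich$eaat2_net_charge_out * v)
}

#' Passive conductive flux
#'
#' Linear conductance law for a passive pathway. The species flux into the
#' lumen is \eqn{-z\,g\,(\psi - E)}: at a lumen-positive potential above the
#' reversal, anions (Cl-) flow in and cations (the leak species, H+) flow
#' out. Disabled pathways contribute exactly zero.
#'
#' @inheritParams atpase_flux
#' @param species `"Cl"` or `"leak"` (the passive H+ leak of the membrane).
#' @return Species flux into the lumen (mol/s).
#' @export
passive_flux <- function(lumen, cyto, params = transporter_params(),
                         species = c("Cl", "leak")) {
  species <- match.arg(species)
  if (species == "Cl") {
    if (!params$cl_enabled || params$cl_g == 0) return(0)
    z <- -1
    g <- params$cl_g
    E <- nernst_potential(z, floor_conc(cyto$Cl_mM), floor_conc(lumen$Cl_mM),
                          cyto$temperature_K)
  } else {
    if (!params$leak_enabled || params$leak_g == 0) return(0)
    z <- +1
    g <- params$leak_g
    E <- nernst_potential(z, h_mM(cyto$pH), h_mM(lumen$pH),
                          cyto$temperature_K)
  }
  -z * g * (lumen$psi_mV - E)
}

#' Convert cumulative moved charge to membrane potential
#'
#' The granule has no resting conductance, so its potential is purely
#' capacitive: \eqn{\psi = Q/C}.
#'
#' @param charge_C cumulative charge moved into the lumen (coulombs).
#' @param geometry a [granule_geometry()].
#' @return Membrane potential in mV.
#' @examples
#' g <- granule_geometry(150)
#' charge_to_potential(4.4e3 * 1.602176634e-19, g)  # ~ +250 mV
#' @export
charge_to_potential <- function(charge_C, geometry = granule_geometry()) {
  charge_C / geometry$capacitance_F * 1e3
}
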