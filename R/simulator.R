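#' Define a granule-energetics scenario
#'
#' The three named scenarios differ only in which transporters are enabled:
#' `"atpase_only"` (the vacuolar H+-ATPase as the sole pathway),
#' `"atpase_vglut"` (ATPase + VGLUT) and `"atpase_vglut_eaat2"` (ATPase +
#' VGLUT + EAAT2). `"custom"` takes the pathway flags from `params` as given.
#'
#' @param name scenario name.
#' @param params a [transporter_params()]; for the named scenarios its
#'   `*_enabled` flags are overwritten by the scenario definition.
#' @param geometry a [granule_geometry()].
#' @param cyto a [cytosol_state()].
#' @param lumen0 initial [lumen_state()].
#' @param stoich a [stoichiometry()].
#' @param buffer a [buffer_model()].
#' @param t_end simulated time (s, default 300).
#' @param n_out number of output points (default 1000).
#' @param track_cations if `FALSE` (default) luminal Na+ and K+ are held at
#'   their initial values (reservoir treatment, mirroring the cytosol); if
#'   `TRUE` they are integrated dynamically with only the modelled pathways.
#'   See the methods vignette for the rationale.
#' @return An object of class `granule_scenario`.
#' @export
granule_scenario <- function(name = c("atpase_only", "atpase_vglut",
                                      "atpase_vglut_eaat2", "custom"),
                             params = transporter_params(),
                             geometry = granule_geometry(),
                             cyto = cytosol_state(),
                             lumen0 = lumen_state(),
                             stoich = stoichiometry(),
                             buffer = buffer_model(),
                             t_end = 300, n_out = 1000,
                             track_cations = FALSE) {
  name <- match.arg(name)
  stopifnot(t_end >= 0, n_out >= 1)
  if (name != "custom") {
    params$pump_enabled  <- TRUE
    params$vglut_enabled <- name %in% c("atpase_vglut", "atpase_vglut_eaat2")
    params$eaat2_enabled <- name == "atpase_vglut_eaat2"
  }
  structure(list(name = name, params = params, geometry = geometry,
                 cyto = cyto, lumen0 = lumen0, stoich = stoich,
                 buffer = buffer, t_end = t_end, n_out = n_out,
                 track_cations = track_cations),
            class = "granule_scenario")
}

# assemble a lumen_state from the ODE state vector; tiny negative
# concentration excursions from the integrator are clipped to zero (the
# flux laws apply the documented floor inside their log terms anyway)
state_to_lumen <- function(y, geometry) {
  lumen_state(pH = y[["pH"]], glu_mM = max(0, y[["glu"]]),
              Na_mM = max(0, y[["Na"]]), K_mM = max(0, y[["K"]]),
              Cl_mM = max(0, y[["Cl"]]),
              psi_mV = charge_to_potential(y[["Q"]], geometry))
}

# all pathway fluxes (mol/s into the lumen) at one state
granule_fluxes <- function(lumen, cyto, params, stoich) {
  ea <- eaat2_flux(lumen, cyto, params, stoich)
  pump <- atpase_flux(lumen, cyto, params, stoich)
  vg <- vglut_flux(lumen, cyto, params, stoich)
  cl <- passive_flux(lumen, cyto, params, "Cl")
  lk <- passive_flux(lumen, cyto, params, "leak")
  list(pump_H = pump, vglut_glu = vg, eaat2 = ea, cl_Cl = cl, leak_H = lk,
       net = list(H  = pump + ea$H + lk,
                  glu = vg + ea$glu,
                  Na = ea$Na,
                  K  = ea$K,
                  Cl = cl))
}

#' Time derivatives of the granule state
#'
#' Right-hand side of the granule ODE system. The integrated states are the
#' cumulative moved charge `Q` (C; the potential is recomputed from it
#' algebraically), luminal pH, and luminal glutamate, Na+, K+ and Cl- (mM).
#' Concentration derivatives are net species flux over luminal volume; the
#' pH derivative is the net proton influx converted through the buffering
#' capacity; the charge derivative is \eqn{F \sum_i z_i J_i}.
#'
#' @param t time (s, unused; the system is autonomous).
#' @param y named state vector `c(Q, pH, glu, Na, K, Cl)`.
#' @param parms list with elements `params`, `geometry`, `cyto`, `stoich`,
#'   `buffer`, `track_cations` (as assembled by [granule_scenario()]).
#' @return A list whose first element is the derivative vector, as required
#'   by [deSolve::lsoda()].
#' @export
granule_derivatives <- function(t, y, parms) {
  lumen <- state_to_lumen(y, parms$geometry)
  fl <- granule_fluxes(lumen, parms$cyto, parms$params, parms$stoich)
  net <- fl$net
  if (any(!is.finite(unlist(net))))
    stop("non-finite flux at t = ", t, "; state: ",
         paste(sprintf("%s=%.6g", names(y), y), collapse = ", "))
  V <- parms$geometry$volume_L
  to_mM_s <- function(J_mol_s) 1e3 * J_mol_s / V
  dQ <- gg_constants$F * (net$H + net$Na + net$K - net$glu - net$Cl)
  dpH <- -to_mM_s(net$H) / parms$buffer$beta_mM_per_pH
  dglu <- to_mM_s(net$glu)
  if (parms$track_cations) {
    dNa <- to_mM_s(net$Na)
    dK  <- to_mM_s(net$K)
  } else {
    dNa <- 0
    dK  <- 0
  }
  dCl <- to_mM_s(net$Cl)
  list(c(Q = dQ, pH = dpH, glu = dglu, Na = dNa, K = dK, Cl = dCl))
}

#' Integrate a granule scenario through time
#'
#' Stiff-capable adaptive integration (lsoda) of the granule flux model.
#' Deterministic given its inputs. The returned trajectory carries the
#' membrane potential, luminal free [H+], all tracked concentrations and the
#' instantaneous pathway fluxes at every output point, plus a steady-state
#' summary (mean over the final 10% of the run and a convergence flag that
#' is `TRUE` when every relative derivative is below `1e-6`/s there).
#'
#' @param scenario a [granule_scenario()].
#' @param rtol,atol integrator tolerances (relative default 1e-8).
#' @return An object of class `granule_trajectory`: a data.frame with one
#'   row per output time and attributes `steady_state` (named list of
#'   last-window means plus `converged`) and `scenario`.
#' @export
simulate_granule <- function(scenario, rtol = 1e-8, atol = 1e-12) {
  sc <- scenario
  y0 <- c(Q = sc$geometry$capacitance_F * sc$lumen0$psi_mV * 1e-3,
          pH = sc$lumen0$pH, glu = sc$lumen0$glu_mM, Na = sc$lumen0$Na_mM,
          K = sc$lumen0$K_mM, Cl = sc$lumen0$Cl_mM)
  parms <- sc[c("params", "geometry", "cyto", "stoich", "buffer",
                "track_cations")]
  if (sc$t_end == 0) {
    out <- matrix(c(0, y0), nrow = 1,
                  dimnames = list(NULL, c("time", names(y0))))
  } else {
    times <- seq(0, sc$t_end, length.out = sc$n_out + 1)
    atol_v <- c(Q = 1e-24, pH = atol, glu = atol, Na = atol, K = atol,
                Cl = atol)
    out <- deSolve::lsoda(y0, times, granule_derivatives, parms,
                          rtol = rtol, atol = atol_v, maxsteps = 50000)
    diagn <- attr(out, "istate")
    if (nrow(out) < length(times))
      stop("integration failed at t = ", out[nrow(out), "time"],
           " (step-size collapse); last state: ",
           paste(sprintf("%s=%.6g", colnames(out)[-1], out[nrow(out), -1]),
                 collapse = ", "))
  }
  traj <- as.data.frame(out)
  traj$psi_mV <- charge_to_potential(traj$Q, sc$geometry)
  traj$H_mM <- h_mM(traj$pH)
  flux_rows <- lapply(seq_len(nrow(traj)), function(i) {
    y <- c(Q = traj$Q[i], pH = traj$pH[i], glu = traj$glu[i],
           Na = traj$Na[i], K = traj$K[i], Cl = traj$Cl[i])
    lum <- state_to_lumen(y, sc$geometry)
    fl <- granule_fluxes(lum, sc$cyto, sc$params, sc$stoich)
    c(J_pump_H = fl$pump_H, J_vglut_glu = fl$vglut_glu,
      J_eaat2_cycle = fl$eaat2$cycle_rate, J_cl_Cl = fl$cl_Cl,
      J_leak_H = fl$leak_H)
  })
  traj <- cbind(traj, do.call(rbind, flux_rows))

  win <- traj$time >= sc$t_end * 0.9
  if (!any(win)) win <- rep(TRUE, nrow(traj))
  ss <- list(psi_mV = mean(traj$psi_mV[win]), pH = mean(traj$pH[win]),
             H_mM = mean(traj$H_mM[win]), glu_mM = mean(traj$glu[win]),
             Na_mM = mean(traj$Na[win]), K_mM = mean(traj$K[win]),
             Cl_mM = mean(traj$Cl[win]))
  yend <- c(Q = traj$Q[nrow(traj)], pH = traj$pH[nrow(traj)],
            glu = traj$glu[nrow(traj)], Na = traj$Na[nrow(traj)],
            K = traj$K[nrow(traj)], Cl = traj$Cl[nrow(traj)])
  dend <- granule_derivatives(sc$t_end, yend, parms)[[1]]
  scale <- pmax(abs(yend), c(Q = 1e-18, pH = 1, glu = 1, Na = 1, K = 1,
                             Cl = 1))
  ss$max_rel_rate <- max(abs(dend) / scale)
  ss$converged <- ss$max_rel_rate < 1e-6
  structure(traj, steady_state = ss, scenario = sc,
            class = c("granule_trajectory", "data.frame"))
}

#' Steady-state summary of a trajectory
#'
#' @param traj a `granule_trajectory` from [simulate_granule()].
#' @return Named list of last-window means and the convergence flag.
#' @export
steady_state <- function(traj) attr(traj, "steady_state")

#' Run the three published transporter-complement scenarios
#'
#' Integrates the ATPase-only, ATPase+VGLUT and ATPase+VGLUT+EAAT2 scenarios
#' with a shared parameter set and summarises their steady states, together
#' with the qualitative ordering checks the model is expected to satisfy:
#' the membrane potential falls and the luminal [H+] rises as VGLUT and then
#' EAAT2 are added, and EAAT2 strongly depletes luminal glutamate.
#'
#' @param params shared [transporter_params()] (pathway flags are set per
#'   scenario).
#' @param t_end,n_out integration window and output grid.
#' @param ... further arguments passed to [granule_scenario()].
#' @return A list with `trajectories` (named list of three trajectories),
#'   `summary` (data.frame of steady-state psi, [H+] and glutamate) and
#'   `orderings` (named logical vector).
#' @export
run_published_scenarios <- function(params = transporter_params(),
                                    t_end = 300, n_out = 1000, ...) {
  names <- c("atpase_only", "atpase_vglut", "atpase_vglut_eaat2")
  trajs <- lapply(names, function(nm)
    simulate_granule(granule_scenario(nm, params = params, t_end = t_end,
                                      n_out = n_out, ...)))
  names(trajs) <- names
  ss <- lapply(trajs, steady_state)
  summary <- data.frame(
    scenario = names,
    psi_mV = vapply(ss, `[[`, 0, "psi_mV"),
    pH = vapply(ss, `[[`, 0, "pH"),
    H_mM = vapply(ss, `[[`, 0, "H_mM"),
    glu_mM = vapply(ss, `[[`, 0, "glu_mM"),
    converged = vapply(ss, `[[`, TRUE, "converged"),
    row.names = NULL
  )
  ord <- c(
    psi_decreasing = summary$psi_mV[1] > summary$psi_mV[2] &&
      summary$psi_mV[2] > summary$psi_mV[3],
    H_increasing = summary$H_mM[3] > summary$H_mM[2] &&
      summary$H_mM[2] > summary$H_mM[1],
    glu_depleted_by_eaat2 = summary$glu_mM[2] > 10 * summary$glu_mM[3],
    atpase_only_no_accumulation =
      abs(summary$pH[1] - trajs[[1]]$pH[1]) < 0.05 &&
      summary$glu_mM[1] < 10 * trajs[[1]]$glu[1] + 0.1
  )
  list(trajectories = trajs, summary = summary, orderings = ord)
}
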