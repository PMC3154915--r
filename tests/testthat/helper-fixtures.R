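# Shared fixtures: small hand-built sections and random model states.

# a minimal section with one granule at the origin and one SLMV on the
# x-axis, inside a large profile so nothing else interferes
toy_section <- function(granule_r = 150, slmv_x = 1500, slmv_r = 20,
                        profile_area_um2 = 25) {
  sec <- em_geometry(n_granules = 0, n_slmv = 0, n_mito = 0,
                     profile_area_um2 = profile_area_um2, seed = 1)
  sec$granules <- data.frame(x = 0, y = 0, r = granule_r)
  sec$slmv <- data.frame(x = slmv_x, y = 0, r = slmv_r)
  sec
}

# random-but-physical lumen/cytosol state pairs for property tests
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(
      lumen = lumen_state(pH = runif(1, 4, 8), glu_mM = runif(1, 0.01, 150),
                          Na_mM = runif(1, 1, 150), K_mM = runif(1, 1, 150),
                          Cl_mM = runif(1, 1, 150),
                          psi_mV = runif(1, -150, 300)),
      cyto = cytosol_state(pH = runif(1, 6.8, 7.6), glu_mM = runif(1, 0.5, 10),
                           Na_mM = runif(1, 5, 30), K_mM = runif(1, 100, 160),
                           Cl_mM = runif(1, 10, 60))
    )
  })
}

all_enabled_params <- function(...) {
  transporter_params(vglut_enabled = TRUE, eaat2_enabled = TRUE,
                     cl_enabled = TRUE, cl_g = 1e-22, ...)
}
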