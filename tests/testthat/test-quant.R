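# Quantification pipeline: the 30-nm assignment rule, grid-point areas,
# background subtraction, ratio statistics and calibration inversion.

test_that("the 30-nm rule assigns particles with boundary-inclusive bands", {
  sec <- toy_section(granule_r = 150, slmv_x = 1500, slmv_r = 20)
  pts <- data.frame(
    x = c(0,      # granule centre -> core
          150 + 29,  # 29 nm outside the granule border -> membrane
          150 + 31,  # 31 nm outside -> cytosol
          150 - 29,  # 29 nm inside the border -> membrane
          1500 + 20 + 29,  # 29 nm outside the SLMV border -> SLMV
          1500 + 20 + 31,  # 31 nm outside -> cytosol
          700),   # open cytosol
    y = 0)
  lab <- em_classify(sec, pts$x, pts$y)
  expect_identical(lab, c("granule_core", "granule_membrane", "cytosol",
                          "granule_membrane", "slmv", "cytosol", "cytosol"))
  # plasma membrane band, both sides of the border
  R <- sec$profile_radius_nm
  expect_identical(em_classify(sec, c(R - 29, R + 29, R + 31), c(0, 0, 0)),
                   c("plasma_membrane", "plasma_membrane", "resin"))
  expect_error(em_classify(sec, sec$bounds_halfwidth_nm + 1, 0), "bounds")
})

test_that("assignment reproduces generator provenance on background-free patterns", {
  acc <- vapply(1:5, function(s) {
    sec <- em_geometry(seed = 60 + s)
    spec <- em_label_spec("glutamate",
      c(granule_core = 25, granule_membrane = 25, slmv = 60, cytosol = 25,
        mito_matrix = 20, mito_membrane = 10, plasma_membrane = 8))
    p <- em_particles(sec, spec, seed = 160 + s)
    a <- assign_particles(sec, p)
    mean(a$compartment == a$true_compartment)
  }, 0)
  expect_true(all(acc >= 0.99))
})

test_that("grid-point areas converge to the analytic areas", {
  # isolated circle of radius 300 nm (granule core region)
  sec <- toy_section(granule_r = 330, slmv_x = 2000)
  analytic <- pi * 0.3^2
  err <- vapply(c(80, 10, 5), function(s) {
    est <- estimate_areas(sec, grid_spacing_nm = s)
    a <- est$area_um2[est$compartment == "granule_core"]
    abs(a - analytic) / analytic
  }, 0)
  expect_lt(err[2], 0.02)   # < 2% at 10 nm spacing
  expect_lt(err[3], 0.01)
  expect_lt(err[3], err[1] + 1e-9)  # finer grids do not get worse
  # analytic method short-circuits the lattice
  est_a <- estimate_areas(sec, method = "analytic")
  expect_equal(est_a$area_um2, est_a$area_analytic_um2)
})

test_that("densities subtract the right background stream without clipping", {
  sec <- toy_section()
  areas <- estimate_areas(sec, method = "analytic")
  # an empty pattern gives net = -background everywhere, flagged
  empty <- data.frame(x = numeric(0), y = numeric(0))
  empty$compartment <- character(0)
  tab0 <- compute_densities(empty, areas, background_model(),
                            "amino_acid")
  nonempty <- tab0$area_um2 > 0
  expect_true(all(tab0$net_density[nonempty] == -1.7))
  expect_true(all(tab0$negative_net[nonempty]))
  # observed 21.4 /um^2 with resin background 1.7 nets 19.7
  a_cyt <- areas$area_um2[areas$compartment == "cytosol"]
  n <- round(21.4 * a_cyt)
  set.seed(1)
  pts <- as.data.frame(matrix(0, n, 2, dimnames = list(NULL, c("x", "y"))))
  pts$compartment <- "cytosol"
  tab <- compute_densities(pts, areas, background_model(), "amino_acid")
  cyt <- tab[tab$compartment == "cytosol", ]
  expect_equal(cyt$net_density, n / a_cyt - 1.7, tolerance = 1e-12)
  expect_equal(cyt$net_density, 19.7, tolerance = 0.05)
  # protein antigens use membrane vs matrix background streams
  tabp <- compute_densities(pts, areas, background_model(), "protein")
  expect_equal(tabp$net_density[tabp$compartment == "granule_membrane"],
               -3.7)
  expect_equal(tabp$net_density[tabp$compartment == "granule_core"], -4.9)
  # zero area with nonzero count is an error
  bad <- areas; bad$area_um2[bad$compartment == "cytosol"] <- 0
  expect_error(compute_densities(pts, bad, background_model(),
                                 "amino_acid"), "zero area")
})

test_that("Mann-Whitney U comparisons are exact for small samples", {
  # identical groups: p = 1
  expect_equal(mwu_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 1)
  # completely separated 4 vs 4: exact two-tailed p = 2/70
  expect_equal(mwu_test(c(1, 2, 3, 4), c(5, 6, 7, 8))$p, 2 / 70,
               tolerance = 1e-12)
  expect_equal(mwu_test(1:4, 5:8)$U, 0)
})

test_that("ratio statistics summarise per-cell ratios and compare groups", {
  run_a <- em_run_preset("rat_alpha_glutamate", n_cells = 5, seed = 3)
  run_b <- em_run_preset("rat_beta_glutamate", n_cells = 5, seed = 4)
  rs <- ratio_stats(c(run_a$tables, run_b$tables),
                    rep(c("alpha", "beta"), each = 5))
  expect_equal(nrow(rs$cells), 10)
  # alpha granule/cytosol ratio > 1, beta < 1, SLMV >> granule in both
  m <- function(g, r) rs$summary$mean[rs$summary$group == g &
                                      rs$summary$ratio == r]
  expect_gt(m("alpha", "sg_cyto"), 1)
  expect_lt(m("beta", "sg_cyto"), 1)
  expect_gt(m("alpha", "slmv_cyto"), m("alpha", "sg_cyto"))
  expect_gt(m("beta", "slmv_cyto"), m("beta", "sg_cyto"))
  # the group comparison detects the alpha/beta ratio difference
  p_sg <- rs$tests$p[rs$tests$ratio == "sg_cyto"]
  expect_lt(p_sg, 0.05)
})

test_that("calibration curves invert densities to concentrations", {
  # exact two-point line through the origin: slope 10, density 20 -> 2 mM
  ser <- data.frame(conc_mM = c(0, 3), density = c(0, 30))
  cur <- calibrate_concentration(ser)
  expect_equal(cur$slope, 10, tolerance = 1e-12)
  expect_equal(cur$intercept, 0)
  expect_equal(estimate_mM(cur, 20)$conc_mM, 2, tolerance = 1e-12)
  # a clearly nonzero intercept is kept
  set.seed(9)
  x <- rep(0:4, each = 6)
  y <- 5 + 8 * x + rnorm(30, sd = 0.5)
  cur2 <- calibrate_concentration(data.frame(conc_mM = x, density = y))
  expect_identical(cur2$inversion, "with_intercept")
  est <- estimate_mM(cur2, 5 + 8 * 2.5)
  expect_equal(est$conc_mM, 2.5, tolerance = 0.1)
  expect_true(est$lo_mM < est$conc_mM & est$conc_mM < est$hi_mM)
  # negative densities cannot go through an origin-anchored inverse
  expect_error(estimate_mM(cur, -1), "negative")
})

test_that("the density estimator is unbiased for every compartment class", {
  # small sections for speed; 200 seeds; analytic areas isolate the
  # counting/subtraction chain
  spec_int <- c(granule_core = 33.6, granule_membrane = 33.6, slmv = 100,
                cytosol = 21.1, mito_matrix = 21.1)
  ps <- em_label_spec("glutamate", spec_int, background = 1.7)
  cps <- c("secretory_granule", "slmv", "cytosol", "mito_matrix")
  truth <- c(33.6, 100, 21.1, 21.1)
  nets <- t(vapply(1:200, function(s) {
    sec <- em_geometry(n_granules = 8, n_slmv = 4, n_mito = 1,
                       profile_area_um2 = 10, seed = 300 + s)
    p <- em_particles(sec, ps, seed = 7300 + s)
    tab <- quantify_section(sec, p, area_method = "analytic")
    vapply(cps, function(cp) tab$net_density[tab$compartment == cp], 0)
  }, setNames(numeric(4), cps)))
  for (i in seq_along(cps)) {
    se <- sd(nets[, i]) / sqrt(nrow(nets))
    expect_lt(abs(mean(nets[, i]) - truth[i]), 2 * se)
  }
})
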