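# evaluate `code` under a temporary RNG state seeded with `seed`
# (NULL seed = use the current RNG stream)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# names of the areal/membrane compartments a section can contain
EM_COMPARTMENTS <- c("slmv", "granule_membrane", "granule_core",
                     "plasma_membrane", "mito_membrane", "mito_matrix",
                     "cytosol", "resin")

#' Generate a synthetic cell-profile geometry
#'
#' Builds one synthetic ultrathin-section cell profile: a circular cell
#' bounded by its plasma membrane, containing circular secretory granules
#' (dense core plus a 60 nm limiting-membrane band, i.e. 30 nm to either
#' side of the granule border), synaptic-like microvesicles (SLMVs, ~40 nm),
#' and mitochondria (matrix plus outer-membrane band), surrounded by a rim
#' of empty resin. Shapes are placed by rejection sampling so that no two
#' 30 nm-extended footprints overlap; all compartment areas are therefore
#' available in closed form for oracle tests.
#'
#' @param cell_type `"alpha"` or `"beta"`.
#' @param condition `"rat"`, `"mouse_wt"` or `"mouse_ko"`.
#' @param n_granules,n_slmv,n_mito shape counts (defaults 30/15/3).
#' @param profile_area_um2 cell profile area (µm², default 25).
#' @param granule_diam_nm,slmv_diam_nm,mito_diam_nm diameter ranges (nm)
#'   from which shape diameters are drawn uniformly.
#' @param resin_margin_nm width of the empty-resin rim beyond the plasma
#'   membrane band (nm).
#' @param seed integer seed making the layout reproducible; `NULL` uses the
#'   current RNG stream.
#' @param max_tries placement attempts per shape before giving up.
#' @return An object of class `em_section`: shape tables in nm plus derived
#'   analytic areas (see [em_area_table()]).
#' @export
em_geometry <- function(cell_type = c("beta", "alpha"),
                        condition = c("rat", "mouse_wt", "mouse_ko"),
                        n_granules = 30, n_slmv = 15, n_mito = 3,
                        profile_area_um2 = 25,
                        granule_diam_nm = c(250, 350),
                        slmv_diam_nm = c(35, 45),
                        mito_diam_nm = c(500, 800),
                        resin_margin_nm = 400,
                        seed = NULL, max_tries = 2000) {
  cell_type <- match.arg(cell_type)
  condition <- match.arg(condition)
  stopifnot(n_granules >= 0, n_slmv >= 0, n_mito >= 0, profile_area_um2 > 0)
  R <- sqrt(profile_area_um2 / pi) * 1e3   # profile radius, nm
  hw <- 30                                  # membrane band half-width, nm
  with_seed(seed, {
    placed <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    place <- function(n, diam_range) {
      out <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
      for (i in seq_len(n)) {
        r <- runif(1, diam_range[1], diam_range[2]) / 2
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          # keep the 30 nm-extended footprint clear of the plasma-membrane band
          rmax <- R - hw - (r + hw) - 10
          if (rmax <= 0) break
          d0 <- sqrt(runif(1)) * rmax
          th <- runif(1, 0, 2 * pi)
          x <- d0 * cos(th); y <- d0 * sin(th)
          if (nrow(placed) == 0 ||
              all(sqrt((placed$x - x)^2 + (placed$y - y)^2) >
                  placed$r + r + 2 * hw + 10)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place shape (radius ", round(r),
                      " nm) after ", max_tries, " tries; reduce counts ",
                      "or enlarge the profile")
        out <- rbind(out, data.frame(x = x, y = y, r = r))
        placed <<- rbind(placed, data.frame(x = x, y = y, r = r))
      }
      out
    }
    # mitochondria first (largest), then granules, then SLMVs
    mito <- place(n_mito, mito_diam_nm)
    granules <- place(n_granules, granule_diam_nm)
    slmv <- place(n_slmv, slmv_diam_nm)
    structure(list(cell_type = cell_type, condition = condition,
                   profile_radius_nm = R, membrane_halfwidth_nm = hw,
                   bounds_halfwidth_nm = R + hw + resin_margin_nm,
                   granules = granules, slmv = slmv, mito = mito),
              class = "em_section")
  })
}

#' Analytic compartment areas of a synthetic section
#'
#' Closed-form areas (µm²) of every compartment in an [em_geometry()]
#' section. Membrane compartments are 60 nm bands (30 nm to either side of
#' the border), so their area equals trace length x 60 nm exactly. The SLMV
#' compartment includes the 30 nm counting halo around each vesicle.
#'
#' @param section an `em_section`.
#' @return data.frame with columns `compartment` and `area_um2`.
#' @export
em_area_table <- function(section) {
  hw <- section$membrane_halfwidth_nm
  nm2_to_um2 <- 1e-6
  disc <- function(r) pi * r^2
  core_a <- function(df) sum(disc(pmax(df$r - hw, 0)))
  band_a <- function(df) sum(disc(df$r + hw) - disc(pmax(df$r - hw, 0)))
  foot_a <- function(df) sum(disc(df$r + hw))
  R <- section$profile_radius_nm
  B <- section$bounds_halfwidth_nm
  areas <- c(
    slmv = foot_a(section$slmv),
    granule_membrane = band_a(section$granules),
    granule_core = core_a(section$granules),
    plasma_membrane = disc(R + hw) - disc(R - hw),
    mito_membrane = band_a(section$mito),
    mito_matrix = core_a(section$mito),
    cytosol = disc(R - hw) - foot_a(section$granules) -
      foot_a(section$slmv) - foot_a(section$mito),
    resin = (2 * B)^2 - disc(R + hw)
  ) * nm2_to_um2
  data.frame(compartment = names(areas), area_um2 = unname(areas))
}

#' Classify points into section compartments
#'
#' Applies the counting rule used throughout the quantification pipeline:
#' a point belongs to an SLMV when it lies within `halfwidth` (30 nm) of the
#' vesicle's outer border (inclusive); to a membrane (plasma, granule
#' limiting, mitochondrial outer) when within 30 nm on either side of the
#' membrane trace; otherwise to the areal compartment containing it.
#' Precedence for ambiguous points: SLMV halo, then membrane bands, then
#' granule core, then mitochondrion, then cytosol.
#'
#' @param section an `em_section`.
#' @param x,y point coordinates (nm, section-centred).
#' @param halfwidth membrane band half-width (nm, default the section's).
#' @return Character vector of compartment labels.
#' @export
em_classify <- function(section, x, y, halfwidth = NULL) {
  hw <- if (is.null(halfwidth)) section$membrane_halfwidth_nm else halfwidth
  stopifnot(hw > 0, length(x) == length(y))
  R <- section$profile_radius_nm
  B <- section$bounds_halfwidth_nm
  if (any(abs(x) > B | abs(y) > B))
    stop("point outside the section bounds")
  n <- length(x)
  d0 <- sqrt(x^2 + y^2)
  lab <- rep("cytosol", n)
  lab[d0 > R + hw] <- "resin"
  lab[abs(d0 - R) <= hw] <- "plasma_membrane"
  assign_circles <- function(lab, df, inner_lab, band_lab) {
    for (i in seq_len(nrow(df))) {
      sel <- which(abs(x - df$x[i]) <= df$r[i] + hw &
                   abs(y - df$y[i]) <= df$r[i] + hw)
      if (!length(sel)) next
      d <- sqrt((x[sel] - df$x[i])^2 + (y[sel] - df$y[i])^2)
      if (!is.null(inner_lab)) lab[sel[d < df$r[i] - hw]] <- inner_lab
      lab[sel[abs(d - df$r[i]) <= hw]] <- band_lab
      if (is.null(inner_lab)) lab[sel[d <= df$r[i] + hw]] <- band_lab
    }
    lab
  }
  # overwrite in increasing precedence
  lab <- assign_circles(lab, section$mito, "mito_matrix", "mito_membrane")
  lab <- assign_circles(lab, section$granules, "granule_core",
                        "granule_membrane")
  lab <- assign_circles(lab, section$slmv, NULL, "slmv")
  lab
}

#' Label specification for immunogold simulation
#'
#' Per-compartment true net labelling intensities (gold particles/µm²) plus
#' a uniform background intensity applied over the whole section (resin
#' included), emulating nonspecific antibody binding.
#'
#' @param antigen antigen name (free text, e.g. `"glutamate"`, `"EAAT2"`).
#' @param intensities named numeric vector of net intensities (/µm²); names
#'   must be compartments from `EM_COMPARTMENTS` (resin excluded —
#'   by definition empty resin carries only background). Unnamed
#'   compartments get 0.
#' @param background uniform background intensity (/µm²).
#' @param size_nm gold particle size class (10 or 15 nm, for double
#'   labelling).
#' @return An object of class `em_label_spec`.
#' @export
em_label_spec <- function(antigen, intensities, background = 0,
                          size_nm = 15) {
  stopifnot(all(intensities >= 0), background >= 0,
            all(names(intensities) %in% setdiff(EM_COMPARTMENTS, "resin")))
  full <- setNames(numeric(length(EM_COMPARTMENTS)), EM_COMPARTMENTS)
  full[names(intensities)] <- intensities
  structure(list(antigen = antigen, intensities = full,
                 background = background, size_nm = size_nm),
            class = "em_label_spec")
}

# uniform samplers over the primitive shapes (coordinates in nm)
runif_disc <- function(n, x0, y0, r) {
  d <- r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  cbind(x = x0 + d * cos(th), y = y0 + d * sin(th))
}
runif_annulus <- function(n, x0, y0, r1, r2) {
  d <- sqrt(runif(n, r1^2, r2^2)); th <- runif(n, 0, 2 * pi)
  cbind(x = x0 + d * cos(th), y = y0 + d * sin(th))
}

# sample n points uniformly over one compartment class by rejection
sample_compartment <- function(section, compartment, n) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  hw <- section$membrane_halfwidth_nm
  R <- section$profile_radius_nm
  B <- section$bounds_halfwidth_nm
  per_shape <- function(df, fun, weight) {
    if (nrow(df) == 0) return(cbind(x = numeric(0), y = numeric(0)))
    k <- as.vector(stats::rmultinom(1, n, weight))
    do.call(rbind, lapply(seq_len(nrow(df)), function(i) fun(k[i], i)))
  }
  switch(compartment,
    granule_core = per_shape(section$granules, function(k, i)
      runif_disc(k, section$granules$x[i], section$granules$y[i],
                 max(section$granules$r[i] - hw, 0)),
      pmax(section$granules$r - hw, 0)^2),
    granule_membrane = per_shape(section$granules, function(k, i)
      runif_annulus(k, section$granules$x[i], section$granules$y[i],
                    max(section$granules$r[i] - hw, 0),
                    section$granules$r[i] + hw),
      (section$granules$r + hw)^2 - pmax(section$granules$r - hw, 0)^2),
    slmv = per_shape(section$slmv, function(k, i)
      runif_disc(k, section$slmv$x[i], section$slmv$y[i],
                 section$slmv$r[i] + hw),
      (section$slmv$r + hw)^2),
    mito_matrix = per_shape(section$mito, function(k, i)
      runif_disc(k, section$mito$x[i], section$mito$y[i],
                 max(section$mito$r[i] - hw, 0)),
      pmax(section$mito$r - hw, 0)^2),
    mito_membrane = per_shape(section$mito, function(k, i)
      runif_annulus(k, section$mito$x[i], section$mito$y[i],
                    max(section$mito$r[i] - hw, 0), section$mito$r[i] + hw),
      (section$mito$r + hw)^2 - pmax(section$mito$r - hw, 0)^2),
    plasma_membrane = runif_annulus(n, 0, 0, R - hw, R + hw),
    cytosol = {
      pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
      while (nrow(pts) < n) {
        cand <- runif_disc(2 * (n - nrow(pts)) + 10, 0, 0, R - hw)
        keep <- em_classify(section, cand[, 1], cand[, 2]) == "cytosol"
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts[seq_len(n), , drop = FALSE]
    },
    resin = {
      pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
      while (nrow(pts) < n) {
        m <- 2 * (n - nrow(pts)) + 10
        cand <- cbind(x = runif(m, -B, B), y = runif(m, -B, B))
        keep <- sqrt(cand[, 1]^2 + cand[, 2]^2) > R + hw
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts[seq_len(n), , drop = FALSE]
    },
    stop("unknown compartment: ", compartment)
  )
}

#' Simulate an immunogold particle pattern over a section
#'
#' Compartment-wise homogeneous Poisson labelling: each compartment receives
#' `Poisson(intensity x area)` particles placed uniformly within it, and the
#' whole section (resin included) additionally receives uniform background
#' at the spec's background intensity. Every particle carries its true
#' generating compartment (`"background"` for background particles) so
#' assignment can be scored exactly in oracle tests.
#'
#' @param section an [em_geometry()] section.
#' @param spec an [em_label_spec()].
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return data.frame of class `em_particles`: `x`, `y` (nm), `antigen`,
#'   `size_nm`, `true_compartment`.
#' @export
em_particles <- function(section, spec, seed = NULL) {
  stopifnot(inherits(section, "em_section"), inherits(spec, "em_label_spec"))
  with_seed(seed, {
    areas <- em_area_table(section)
    rows <- lapply(areas$compartment, function(cp) {
      lam <- spec$intensities[[cp]] * areas$area_um2[areas$compartment == cp]
      n <- if (lam > 0) stats::rpois(1, lam) else 0L
      pts <- sample_compartment(section, cp, n)
      if (nrow(pts) == 0) return(NULL)
      data.frame(x = pts[, 1], y = pts[, 2], antigen = spec$antigen,
                 size_nm = spec$size_nm, true_compartment = cp)
    })
    B <- section$bounds_halfwidth_nm
    n_bg <- stats::rpois(1, spec$background * (2 * B)^2 * 1e-6)
    bg <- if (n_bg > 0)
      data.frame(x = runif(n_bg, -B, B), y = runif(n_bg, -B, B),
                 antigen = spec$antigen, size_nm = spec$size_nm,
                 true_compartment = "background")
    out <- do.call(rbind, c(rows, list(bg)))
    if (is.null(out))
      out <- data.frame(x = numeric(0), y = numeric(0),
                        antigen = character(0), size_nm = numeric(0),
                        true_compartment = character(0))
    rownames(out) <- NULL
    class(out) <- c("em_particles", "data.frame")
    out
  })
}

#' Printed-value presets for the labelling experiments
#'
#' Encodes the published per-compartment net glutamate labelling densities
#' for rat alpha- and beta-cells and for wild-type and EAAT2-knockout mouse
#' beta-cells, together with the empty-resin background rate, plus
#' representative presets for the two protein antigens (whose granule
#' intensities were shown graphically; only their background rates are
#' printed and pinned here). Intensities are gold particles/µm².
#'
#' @param name one of `"rat_alpha_glutamate"`, `"rat_beta_glutamate"`,
#'   `"mouse_wt_glutamate"`, `"mouse_ko_glutamate"`, `"rat_beta_vglut3"`,
#'   `"rat_beta_eaat2"`.
#' @return A list with elements `label` (an [em_label_spec()]), `geometry`
#'   (argument list for [em_geometry()]) and `antigen_class`
#'   (`"amino_acid"` or `"protein"`).
#' @export
em_preset <- function(name = c("rat_alpha_glutamate", "rat_beta_glutamate",
                               "mouse_wt_glutamate", "mouse_ko_glutamate",
                               "rat_beta_vglut3", "rat_beta_eaat2")) {
  name <- match.arg(name)
  rat_geom  <- list(n_granules = 30, n_slmv = 15, n_mito = 3)
  mouse_geom <- list(n_granules = 45, n_slmv = 15, n_mito = 3)
  glu <- function(sg, cyto, slmv = 100)
    em_label_spec("glutamate", c(granule_core = sg, granule_membrane = sg,
                                 slmv = slmv, cytosol = cyto,
                                 mito_matrix = cyto),
                  background = 1.7)
  switch(name,
    rat_alpha_glutamate = list(
      label = glu(33.6, 21.1),
      geometry = c(rat_geom, cell_type = "alpha", condition = "rat"),
      antigen_class = "amino_acid"),
    rat_beta_glutamate = list(
      label = glu(19.7, 30.2),
      geometry = c(rat_geom, cell_type = "beta", condition = "rat"),
      antigen_class = "amino_acid"),
    mouse_wt_glutamate = list(
      label = glu(9.0, 12.2, slmv = 60),
      geometry = c(mouse_geom, cell_type = "beta", condition = "mouse_wt"),
      antigen_class = "amino_acid"),
    mouse_ko_glutamate = list(
      label = glu(17.7, 10.5, slmv = 60),
      geometry = c(mouse_geom, cell_type = "beta", condition = "mouse_ko"),
      antigen_class = "amino_acid"),
    rat_beta_vglut3 = list(
      label = em_label_spec("VGLUT3",
        c(granule_membrane = 25, slmv = 40, granule_core = 3,
          cytosol = 1, plasma_membrane = 2,
          mito_membrane = 1.3, mito_matrix = 2.7), background = 0.5),
      geometry = c(rat_geom, cell_type = "beta", condition = "rat"),
      antigen_class = "protein"),
    rat_beta_eaat2 = list(
      label = em_label_spec("EAAT2",
        c(granule_membrane = 30, granule_core = 20, slmv = 2,
          cytosol = 1, plasma_membrane = 1,
          mito_membrane = 3.7, mito_matrix = 4.9), background = 0.5),
      geometry = c(rat_geom, cell_type = "beta", condition = "rat"),
      antigen_class = "protein")
  )
}

#' Generate a calibration test-section series
#'
#' Emulates ultrathin test sections containing known fixed amino-acid
#' concentrations: the expected labelling density is linear in
#' concentration (`intercept + slope x conc`), and each section's observed
#' density is a Poisson count over its area.
#'
#' @param conc_mM vector of known concentrations (>= 2 distinct values).
#' @param slope particles/µm² per mM.
#' @param intercept particles/µm² at zero concentration.
#' @param area_um2 area counted per test section.
#' @param seed integer seed.
#' @return data.frame of class `em_calibration_series` with columns
#'   `conc_mM`, `count`, `area_um2`, `density`.
#' @export
em_calibration <- function(conc_mM, slope, intercept = 0, area_um2 = 10,
                           seed = NULL) {
  stopifnot(length(unique(conc_mM)) >= 2, all(conc_mM >= 0), slope >= 0,
            intercept >= 0, area_um2 > 0)
  with_seed(seed, {
    lam <- (intercept + slope * conc_mM) * area_um2
    count <- stats::rpois(length(lam), lam)
    out <- data.frame(conc_mM = conc_mM, count = count,
                      area_um2 = area_um2, density = count / area_um2)
    class(out) <- c("em_calibration_series", "data.frame")
    out
  })
}

#' Write / read a synthetic section as JSON
#'
#' One JSON document per section: geometry (shape centres and radii, nm)
#' plus the particle table. Deterministic round trip.
#'
#' @param section an `em_section`.
#' @param particles an `em_particles` data.frame (optional).
#' @param path output file.
#' @return `path`, invisibly (writer); a list with `section` and
#'   `particles` (reader).
#' @export
write_em_section <- function(section, particles = NULL, path) {
  doc <- list(
    cell_type = section$cell_type, condition = section$condition,
    profile_radius_nm = section$profile_radius_nm,
    membrane_halfwidth_nm = section$membrane_halfwidth_nm,
    bounds_halfwidth_nm = section$bounds_halfwidth_nm,
    granules = section$granules, slmv = section$slmv, mito = section$mito,
    particles = particles
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_em_section
#' @export
read_em_section <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(d) if (length(d)) as.data.frame(d) else
    data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  section <- structure(list(
    cell_type = doc$cell_type, condition = doc$condition,
    profile_radius_nm = doc$profile_radius_nm,
    membrane_halfwidth_nm = doc$membrane_halfwidth_nm,
    bounds_halfwidth_nm = doc$bounds_halfwidth_nm,
    granules = as_df(doc$granules), slmv = as_df(doc$slmv),
    mito = as_df(doc$mito)), class = "em_section")
  particles <- if (!is.null(doc$particles)) {
    p <- as.data.frame(doc$particles)
    class(p) <- c("em_particles", "data.frame")
    p
  }
  list(section = section, particles = particles)
}
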