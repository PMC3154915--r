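#' Particle/grid-point counting rule
#'
#' The inclusion rule used for counting: particles (and area grid points)
#' belong to an SLMV when within `slmv_halo` nm of its outer border
#' (boundary inclusive), and to a membrane when within `membrane_halfwidth`
#' nm on either side of the membrane trace.
#'
#' @param membrane_halfwidth nm (default 30).
#' @param slmv_halo nm (default 30).
#' @return An object of class `assignment_rule`.
#' @export
assignment_rule <- function(membrane_halfwidth = 30, slmv_halo = 30) {
  stopifnot(membrane_halfwidth > 0, slmv_halo > 0)
  structure(list(membrane_halfwidth = membrane_halfwidth,
                 slmv_halo = slmv_halo), class = "assignment_rule")
}

#' Assign gold particles to compartments
#'
#' Labels every particle with exactly one compartment under the counting
#' rule, with precedence SLMV halo > membrane bands > granule core >
#' mitochondrion > cytosol for ambiguous positions.
#'
#' @param section an `em_section`.
#' @param particles an `em_particles` data.frame.
#' @param rule an [assignment_rule()].
#' @return `particles` with an added `compartment` column.
#' @export
assign_particles <- function(section, particles, rule = assignment_rule()) {
  stopifnot(inherits(section, "em_section"))
  particles$compartment <- em_classify(section, particles$x, particles$y,
                                       halfwidth = rule$membrane_halfwidth)
  particles
}

#' Estimate compartment areas by point counting
#'
#' Stereological area estimation: a square lattice of grid points (spacing
#' `grid_spacing_nm`, offset half a spacing from the section corner) is
#' classified with the same counting rule as the particles, and each
#' compartment's area is `points x spacing²`. The analytic areas are
#' returned alongside for oracle comparison; `method = "analytic"` skips the
#' lattice and uses them directly.
#'
#' @param section an `em_section`.
#' @param grid_spacing_nm lattice spacing (nm, default 10).
#' @param rule an [assignment_rule()].
#' @param method `"grid"` or `"analytic"`.
#' @return data.frame with `compartment`, `area_um2` (the estimate in use)
#'   and `area_analytic_um2`.
#' @export
estimate_areas <- function(section, grid_spacing_nm = 10,
                           rule = assignment_rule(),
                           method = c("grid", "analytic")) {
  method <- match.arg(method)
  stopifnot(grid_spacing_nm > 0)
  analytic <- em_area_table(section)
  if (method == "analytic") {
    return(data.frame(compartment = analytic$compartment,
                      area_um2 = analytic$area_um2,
                      area_analytic_um2 = analytic$area_um2))
  }
  B <- section$bounds_halfwidth_nm
  s <- grid_spacing_nm
  g <- seq(-B + s / 2, B, by = s)
  grid <- expand.grid(x = g, y = g)
  lab <- em_classify(section, grid$x, grid$y,
                     halfwidth = rule$membrane_halfwidth)
  counts <- table(factor(lab, levels = analytic$compartment))
  data.frame(compartment = analytic$compartment,
             area_um2 = as.numeric(counts) * s^2 * 1e-6,
             area_analytic_um2 = analytic$area_um2)
}

#' Background labelling model
#'
#' Reference background densities used for correction: membrane-bound
#' antigens are corrected with the density measured over mitochondrial
#' outer membranes, areal antigens with the mitochondrial matrix density,
#' and amino acids (which label everywhere, including resin) with the
#' empty-resin density. Defaults are the published glutamate/protein
#' background rates.
#'
#' @param membrane,matrix,resin background densities (particles/µm²).
#' @return An object of class `background_model`.
#' @export
background_model <- function(membrane = 3.7, matrix = 4.9, resin = 1.7) {
  stopifnot(membrane >= 0, matrix >= 0, resin >= 0)
  structure(list(membrane = membrane, matrix = matrix, resin = resin),
            class = "background_model")
}

# which background stream applies to each compartment for a given antigen
# class ("amino_acid": resin everywhere; "protein": membrane vs matrix)
background_for <- function(compartment, background, antigen_class) {
  if (antigen_class == "amino_acid") {
    return(rep(background$resin, length(compartment)))
  }
  membrane_like <- c("granule_membrane", "plasma_membrane", "slmv",
                     "mito_membrane")
  ifelse(compartment %in% membrane_like, background$membrane,
         background$matrix)
}

#' Background-corrected particle densities
#'
#' Raw density is count/area per compartment; net density subtracts the
#' applicable background stream (no clipping: negative net densities are
#' preserved and flagged). A pooled `secretory_granule` row (core plus
#' limiting membrane) is appended, since amino-acid labelling is reported
#' over whole granules.
#'
#' @param assigned particle table from [assign_particles()].
#' @param areas area table from [estimate_areas()].
#' @param background a [background_model()].
#' @param antigen_class `"amino_acid"` or `"protein"`.
#' @return data.frame of class `density_table`: `compartment`, `count`,
#'   `area_um2`, `raw_density`, `net_density`, `negative_net`.
#' @export
compute_densities <- function(assigned, areas,
                              background = background_model(),
                              antigen_class = c("amino_acid", "protein")) {
  antigen_class <- match.arg(antigen_class)
  counts <- table(factor(assigned$compartment, levels = areas$compartment))
  if (any(areas$area_um2 <= 0 & as.numeric(counts) > 0))
    stop("compartment with zero area but nonzero particle count")
  tab <- data.frame(compartment = areas$compartment,
                    count = as.numeric(counts),
                    area_um2 = areas$area_um2)
  sg <- tab$compartment %in% c("granule_core", "granule_membrane")
  pooled <- data.frame(compartment = "secretory_granule",
                       count = sum(tab$count[sg]),
                       area_um2 = sum(tab$area_um2[sg]))
  tab <- rbind(tab, pooled)
  tab$raw_density <- ifelse(tab$area_um2 > 0, tab$count / tab$area_um2, NA)
  bg <- background_for(tab$compartment, background, antigen_class)
  bg[tab$compartment == "secretory_granule"] <-
    background_for("granule_core", background, antigen_class)
  tab$net_density <- tab$raw_density - bg
  tab$negative_net <- !is.na(tab$net_density) & tab$net_density < 0
  class(tab) <- c("density_table", "data.frame")
  tab
}

#' Quantify one synthetic cell end to end
#'
#' Convenience wrapper running assignment, area estimation and background
#' correction for one section/pattern pair.
#'
#' @param section an `em_section`.
#' @param particles an `em_particles` table.
#' @param rule an [assignment_rule()].
#' @param background a [background_model()].
#' @param antigen_class `"amino_acid"` or `"protein"`.
#' @param area_method `"analytic"` or `"grid"`.
#' @param grid_spacing_nm lattice spacing when `area_method = "grid"`.
#' @return A `density_table`.
#' @export
quantify_section <- function(section, particles, rule = assignment_rule(),
                             background = background_model(),
                             antigen_class = "amino_acid",
                             area_method = "grid", grid_spacing_nm = 10) {
  assigned <- assign_particles(section, particles, rule)
  areas <- estimate_areas(section, grid_spacing_nm, rule,
                          method = area_method)
  compute_densities(assigned, areas, background, antigen_class)
}

# per-cell compartment ratio from one density table
cell_ratio <- function(tab, num, den = "cytosol") {
  nd <- function(cp) tab$net_density[tab$compartment == cp]
  d <- nd(den)
  if (length(d) != 1 || is.na(d) || d <= 0) return(NA_real_)
  nd(num) / d
}

#' Ratio summaries and group comparisons
#'
#' Computes per-cell granule/cytosol and SLMV/cytosol net-density ratios,
#' group summaries (mean, SD, SEM, n) and two-tailed Mann-Whitney U
#' comparisons between groups (exact for small samples, normal
#' approximation for larger ones, via [stats::wilcox.test()]). Cells whose
#' cytosolic net density is not positive have undefined ratios and are
#' excluded with a warning.
#'
#' @param tables list of per-cell `density_table`s.
#' @param groups character/factor of group membership, one per cell.
#' @return A list with `cells` (per-cell ratio table), `summary` (per
#'   group x ratio) and `tests` (pairwise MWU results per ratio).
#' @export
ratio_stats <- function(tables, groups = rep("all", length(tables))) {
  stopifnot(length(tables) == length(groups))
  cells <- do.call(rbind, lapply(seq_along(tables), function(i) {
    data.frame(cell = i, group = as.character(groups[i]),
               sg_cyto = cell_ratio(tables[[i]], "secretory_granule"),
               slmv_cyto = cell_ratio(tables[[i]], "slmv"))
  }))
  if (anyNA(cells$sg_cyto))
    warning(sum(is.na(cells$sg_cyto)),
            " cell(s) with non-positive cytosolic net density excluded")
  ratios <- c("sg_cyto", "slmv_cyto")
  summ <- do.call(rbind, lapply(split(cells, cells$group), function(d) {
    do.call(rbind, lapply(ratios, function(rn) {
      v <- d[[rn]][!is.na(d[[rn]])]
      data.frame(group = d$group[1], ratio = rn, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 sem = stats::sd(v) / sqrt(length(v)))
    }))
  }))
  rownames(summ) <- NULL
  gl <- unique(cells$group)
  tests <- NULL
  if (length(gl) >= 2) {
    pairs <- utils::combn(gl, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(ratios, function(rn) {
        x <- cells[[rn]][cells$group == pr[1]]
        y <- cells[[rn]][cells$group == pr[2]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) return(NULL)
        wt <- mwu_impl(x, y)
        data.frame(group1 = pr[1], group2 = pr[2], ratio = rn,
                   U = unname(wt$statistic), p = wt$p.value,
                   method = wt$method)
      }))
    }))
  }
  list(cells = cells, summary = summ, tests = tests)
}

#' Two-tailed Mann-Whitney U test
#'
#' Thin wrapper exposing the group-comparison test used throughout the
#' pipeline: exact when both samples are small (n <= 20) and tie-free,
#' normal approximation otherwise.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p`.
#' @export
mwu_test <- function(x, y) {
  wt <- mwu_impl(x, y)
  list(U = unname(wt$statistic), p = wt$p.value)
}

# exact only when both samples are small and tie-free (the exact null
# distribution is undefined under ties); otherwise normal approximation
mwu_impl <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  stats::wilcox.test(x, y, alternative = "two.sided",
                     exact = length(x) <= 20 && length(y) <= 20 && !ties)
}

#' Fit a density-to-concentration calibration curve
#'
#' Least-squares linear fit of labelling density against known test-section
#' concentration. Both the full fit and the through-origin fit are
#' computed; the through-origin fit is used for inversion when the fitted
#' intercept is not statistically distinguishable from zero (p > 0.05),
#' unless `force` picks one.
#'
#' @param series an [em_calibration()] data.frame (columns `conc_mM`,
#'   `density`).
#' @param force `NULL`, `"with_intercept"` or `"through_origin"`.
#' @return An object of class `em_calibration_curve`: `slope`, `intercept`,
#'   fit objects, and the choice in `inversion`.
#' @export
calibrate_concentration <- function(series, force = NULL) {
  stopifnot(nrow(series) >= 2, length(unique(series$conc_mM)) >= 2)
  fit <- stats::lm(density ~ conc_mM, data = series)
  fit0 <- stats::lm(density ~ conc_mM - 1, data = series)
  # an exact 2-point fit has no residual df; treat its intercept p as NA
  ic_p <- suppressWarnings(
    summary(fit)$coefficients["(Intercept)", "Pr(>|t|)"])
  inversion <- if (!is.null(force)) {
    match.arg(force, c("with_intercept", "through_origin"))
  } else if (is.finite(ic_p) && ic_p <= 0.05) "with_intercept"
  else "through_origin"
  use <- if (inversion == "with_intercept") fit else fit0
  co <- stats::coef(use)
  structure(list(
    slope = unname(co[["conc_mM"]]),
    intercept = if (inversion == "with_intercept")
      unname(co[["(Intercept)"]]) else 0,
    intercept_p = ic_p, inversion = inversion,
    fit = fit, fit_through_origin = fit0,
    sigma = suppressWarnings(summary(use)$sigma)),
    class = "em_calibration_curve")
}

#' Estimate concentration from a net labelling density
#'
#' Inverse prediction through the calibration line with a delta-method
#' standard error (combining residual scatter of a new observation with the
#' slope/intercept uncertainty).
#'
#' @param curve an [calibrate_concentration()] curve.
#' @param net_density net labelling density (particles/µm²).
#' @return data.frame with `net_density`, `conc_mM`, `se_mM`, `lo_mM`,
#'   `hi_mM` (95% interval).
#' @export
estimate_mM <- function(curve, net_density) {
  stopifnot(inherits(curve, "em_calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive to invert")
  if (curve$inversion == "through_origin" && any(net_density < 0))
    stop("cannot invert a negative density through an origin-anchored curve")
  x0 <- (net_density - curve$intercept) / curve$slope
  use <- if (curve$inversion == "with_intercept") curve$fit
         else curve$fit_through_origin
  # a saturated (exact) fit has no residual scatter; vcov still warns
  V <- suppressWarnings(stats::vcov(use))
  g <- if (curve$inversion == "with_intercept") {
    # d x0/d(intercept), d x0/d(slope)
    rbind(-1 / curve$slope, -x0 / curve$slope)
  } else rbind(-x0 / curve$slope)
  var_fit <- colSums(g * (V %*% g))
  se <- sqrt(var_fit + (curve$sigma / curve$slope)^2)
  data.frame(net_density = net_density, conc_mM = x0, se_mM = se,
             lo_mM = x0 - 1.96 * se, hi_mM = x0 + 1.96 * se)
}
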