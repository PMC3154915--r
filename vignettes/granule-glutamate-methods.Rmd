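---
title: "Methods: granule energetics and immunogold quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granule energetics and immunogold quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulegold)
```

`granulegold` implements two computational pipelines around the biology of
glutamate handling by endocrine secretory granules: a biophysical model of
the granule membrane's energetics, and a synthetic-data-driven
re-implementation of quantitative immunogold cytochemistry. This vignette
is the package's account of both methods: the models, their assumptions,
the tunable parameters, and the places where a design choice was genuinely
open.

## 1. The granule energetics model

### The physical picture

Insulin-containing secretory granules carry a vacuolar H⁺-ATPase that
pumps protons into the lumen. Because the granule membrane is tiny
(capacitance ~3 fF for a 150 nm-radius granule) and essentially
non-conductive, moving only a few thousand elementary charges polarizes it
by hundreds of millivolts. The pump therefore self-limits: with no other
pathway, the membrane potential ψ (lumen minus cytosol) rises until the
pump's free energy is exhausted — the *stall potential*
\(\psi_{stall} = -\Delta G_{ATP}/(n_H F)\), ≈ +295 mV for 2 H⁺/ATP and
\(\Delta G_{ATP} = -57\) kJ/mol — and essentially no protons or metabolites
accumulate.

A vesicular glutamate transporter (VGLUT) changes this: glutamate⁻ influx
is a counter-charge that discharges ψ, letting the pump continue, so both
H⁺ and glutamate accumulate. An EAAT2-class carrier in the granule
membrane runs in export mode (3 Na⁺ + 1 H⁺ + glutamate⁻ out, 1 K⁺ in; net
2 positive charges leave per cycle), which removes accumulated glutamate
and provides further counter-charge: the potential falls further while
acidification deepens. Those three transporter complements —
`atpase_only`, `atpase_vglut`, `atpase_vglut_eaat2` — are the package's
named scenarios.

### Rate laws

Published descriptions of this system fix the stoichiometries and the
qualitative behaviour but not the transporter kinetics. We therefore use
the minimal thermodynamically consistent saturating law

\[ J = J_{max} \tanh\!\left(\frac{\Delta G}{2RT}\right), \]

clipped to be unidirectional for the ATPase
(\(J = J_{max}\max(0,\tanh(D/2RT))\)), where \(\Delta G\) (or \(D\)) is the
driving free energy of the pathway. Any rate law that (i) vanishes exactly
at thermodynamic equilibrium, (ii) has the sign of its driving force
everywhere, and (iii) saturates at a finite \(J_{max}\) reproduces the
same qualitative results; the tanh form is the simplest such choice. VGLUT
additionally carries a cytosolic-substrate Michaelis factor
\(glu_c/(glu_c + K_m)\), and the EAAT2 law a donor-side glutamate factor
\(glu/(glu + K_m)\) so the carrier shuts off smoothly as its substrate
pool empties (without it, the numerical concentration floor would become
load-bearing as \(glu_L \to 0\)).

Passive pathways (a Cl⁻ channel and a proton leak) follow the linear
conductance law: species flux into the lumen \(= -z\,g\,(\psi - E)\),
with \(E = (RT/zF)\ln(c_{cyto}/c_{lumen})\) the reversal potential in the
lumen-minus-cytosol convention. At a lumen-positive ψ above reversal this
carries anions in and cations out, as it must. The exported helper
`nernst_potential(z, c_lumen, c_cyto)` returns
\((RT/zF)\ln(c_{lumen}/c_{cyto})\) — note that the reversal potential of a
species is that expression with the *arguments swapped*.

### State variables and integration

The integrated states are the cumulative moved charge \(Q\) (ψ is always
recomputed algebraically as \(Q/C\), so charge and potential cannot
drift apart), luminal pH, and luminal glutamate, Na⁺, K⁺ and Cl⁻.
Net proton flux is converted to pH through a buffering capacity β
(default 40 mM/pH); concentration derivatives are flux over luminal
volume. Integration uses `deSolve::lsoda` (adaptive, stiff-capable,
relative tolerance 1e-8, per-state absolute tolerances). The steady-state
summary is the mean over the final 10% of the run, with a convergence
flag (`TRUE` when all relative derivatives are below 1e-6/s at the end
point) exposed rather than silently trusted.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| radius | 150 nm | granule radius (300 nm dense-core granule) |
| specific capacitance | 1 µF/cm² | standard membrane value |
| β | 40 mM/pH | luminal proton buffering |
| T | 310.15 K | body temperature |
| ΔG_ATP | −57 kJ/mol | free energy of ATP hydrolysis |
| n_H | 2 | H⁺ pumped per ATP (stall ≈ +295 mV) |
| pH_c | 7.2; glu_c 3 mM; Na_c 15; K_c 140; Cl_c 40 mM | cytosol (fixed reservoir) |
| initial lumen | pH 7.2, glu 0.01, Na 70, K 30, Cl 40 mM, ψ 0 | pre-activation granule |
| pump/VGLUT J_max | 5e-20 mol/s | ~30,000 molecules/s per granule: tens of transporter copies at typical turnover |
| EAAT2 J_max | 2e-20 mol/s | same reasoning, fewer copies |
| VGLUT K_m | 5 mM; EAAT2 K_m | 0.5 mM | substrate half-saturation |
| H⁺ leak g | 1e-22 mol/s/mV | small passive proton permeability |
| Cl⁻ conductance | 0 (disabled) | optional counter-charge pathway |
| t_end | 300 s, 1000 output points | integration window |

The cytosolic glutamate concentration (3 mM) is anchored to the measured
low-mM cytosolic level; luminal Na⁺ is set high because secretory granules
are known to contain substantial sodium. All defaults are overridable per
key, and round-trip through YAML configuration files
(`write_scenario_config()` / `read_scenario_config()`).

### Two deliberate modelling choices

**Fixed luminal cation gradients.** By default luminal Na⁺ and K⁺ are held
at their initial values (`track_cations = FALSE`), extending the
infinite-reservoir treatment of the cytosol to the granule's cation
content. The reason is quantitative: with only the EAAT2 carrier moving
Na⁺, a 70 mM luminal store supports at most ~23 mM-equivalents of
glutamate export before the carrier stalls — after which VGLUT refills the
lumen and the EAAT2 scenario converges back toward the VGLUT-only state,
contradicting the central observation that sustained EAAT2 activity keeps
granule glutamate *much* lower. No passive pathway can resupply Na⁺ (a
lumen-positive ψ drives cations out), so sustained export requires
treating the granule's cation pool as buffered by processes outside this
model. Setting `track_cations = TRUE` restores full dynamic tracking for
anyone studying the store-limited regime.

**A small default H⁺ leak.** Without any proton re-entry pathway the
EAAT2 scenario has no steady state at all: the carrier keeps removing
charge, the pump keeps acidifying, and luminal pH falls without bound. A
small passive H⁺ leak (1e-22 mol/s/mV) is the minimal physical brake. It
costs the ATPase-only scenario a few mV (steady ψ ≈ +278 rather than
+294 mV, still far above +200 mV).

### Known limitations

With the fixed cation gradients, the EAAT2 scenario's 300-s state
overshoots: the membrane potential ends mildly *negative* (~−120 mV) and
the lumen far more acidic than real granules (which sit near pH 5). Real
granules limit this through finite cation stores, larger buffering and
H⁺-coupled exchangers not modelled here. The package's claims — and its
tests — are therefore about the *orderings* across transporter
complements (ψ decreasing, [H⁺] increasing, glutamate strongly depleted
by EAAT2, all robust to ±50% one-at-a-time rate perturbations), not about
absolute axis values, which the source data do not constrain. There is no
osmotic volume dynamics, no Donnan binding to the dense core, and no
kinetic detail of transporter conformational cycles.

## 2. Synthetic immunogold sections

`em_geometry()` builds a circular cell profile (default 25 µm²) with
circular secretory granules (diameters 250–350 nm; a 60 nm limiting-
membrane band spans 30 nm to either side of the border), ~40 nm SLMVs,
mitochondria (matrix + outer-membrane band), a plasma-membrane band, and
an empty-resin rim. Shapes are placed by rejection sampling so their
30 nm-extended footprints never overlap: every compartment area is then
available in closed form, which is what makes exact oracle tests of the
pipeline possible. Counts per profile (30 granules for the rat presets,
45 for the mouse presets, 15 SLMVs, 3 mitochondria) are defaults chosen
to make the published cell-to-cell standard deviations plausible; none of
these layout quantities were published.

`em_particles()` implements the declared noise model: per-compartment
*homogeneous Poisson* labelling (count ~ Poisson(intensity × area),
positions uniform within the compartment), superposed with a uniform
background over the entire section — the sampling model that
particle-density statistics implicitly assume. Every particle carries its
true generating compartment so that the assignment rule can be scored
exactly. Presets encode the published net intensities (gold
particles/µm²): rat α granules 33.6 / cytosol 21.1; rat β granules 19.7 /
cytosol 30.2; mouse wild-type granules 9.0 / cytosol 12.2; mouse EAAT2-KO
granules 17.7 / cytosol 10.5; empty-resin background 1.7; protein
backgrounds 3.7/1.3 (mitochondrial outer membrane) and 4.9/2.7 (matrix).
Quantities that were published only graphically (SLMV glutamate, protein
granule intensities) use representative defaults: SLMV glutamate is set
to 100/µm², which reproduces the strong SLMV ≫ granule inequality without
pinning an unpublished number. Mitochondrial glutamate is set equal to
cytosolic (mitochondria are a background reference only for the protein
antigens, not for amino acids).

`em_calibration()` emulates the test-section calibration: sections of
known glutamate concentration with expected density linear in
concentration and Poisson counting noise.

## 3. The quantification pipeline

* **Assignment (30 nm rule).** A particle belongs to an SLMV when its
  centre lies within 30 nm of the vesicle's outer border (inclusive), and
  to a membrane when within 30 nm on either side of the membrane trace.
  Precedence for ambiguous positions — SLMV halo over membrane bands over
  granule core over mitochondrion over cytosol — is not specified by the
  source counting protocol; it is isolated in one function
  (`em_classify()`) and documented here. The generator's geometry keeps
  footprints disjoint, so in synthetic data the precedence almost never
  fires.
* **Areas.** Stereological point counting: a square lattice (default
  10 nm spacing, half-spacing offset) is classified with the same rule,
  and area = points × spacing². The estimate converges to the analytic
  area as spacing → 0 (error below 2% at 10 nm for granule-sized discs);
  the analytic areas are always exposed for oracle comparison, and
  `area_method = "analytic"` uses them directly.
* **Densities.** Raw density = count/area; net density subtracts the
  applicable background stream — empty resin for amino-acid antigens,
  mitochondrial outer membrane for membrane-bound protein antigens,
  mitochondrial matrix for areal protein antigens. Membrane densities use
  the 60 nm band area (trace length × 60 nm) as denominator so all
  densities share /µm² units. Negative net densities are *preserved and
  flagged*, never clipped — clipping would bias every summary upward. A
  pooled `secretory_granule` row (core + limiting membrane) matches how
  amino-acid labelling is reported over whole granules.
* **Statistics.** Per-cell granule/cytosol and SLMV/cytosol ratios;
  group summaries as mean ± SD (per-cell designs) or per-animal means
  with across-animal SEM (the mouse design); two-tailed Mann–Whitney U
  comparisons via `stats::wilcox.test` — exact for tie-free samples up to
  n = 20, normal approximation otherwise. Note the distinction between
  the mean of per-cell ratios and the ratio of mean densities: both are
  reported, because they genuinely differ (for the rat presets,
  19.7/30.2 ≈ 0.65 as a ratio of means, while the mean per-cell ratio is
  slightly higher).
* **Calibration.** Least-squares fit of density against known test-section
  concentration, with both a full and a through-origin fit; the
  through-origin fit is used for inversion when the intercept is not
  statistically distinguishable from zero. Inverse prediction carries a
  delta-method standard error. Anchoring the curve so that the measured
  β-cytosol density reads 3 mM places the β-granule estimate near 2 mM —
  the low-mM bracket reported for these compartments.

## 4. What the synthetic tests do and do not show

The generator emulates exactly the statistical structure the pipeline
assumes: homogeneous Poisson labelling within geometrically ideal
(circular, non-overlapping) compartments, uniform background, and a
linear calibration response. Passing tests therefore demonstrate that the
*estimators are correct* — assignment matches provenance, densities are
recovered without bias at the published intensities and sample sizes, and
printed inequalities are reproduced in direction. They do not validate
the biological assumptions themselves: real sections have irregular
compartments, spatially correlated labelling, section-thickness effects
and antibody accessibility gradients that no coordinate-level simulation
captures. Likewise the chosen problem sizes (5 cells of ~30 granules for
the rat presets; 4 animals × 5 cells of ~45 granules for the mouse
presets, matching the ~119/179-granule published sample scale) make the
recovery precision a few percent; they are analysis choices, not
measured quantities.

## 5. Numerical choices

* Concentration floor 1e-3 mM inside all log terms; steady states above
  the floor are unaffected (tested).
* Integrator: `lsoda`, rtol 1e-8, atol 1e-24 for charge (coulombs) and
  1e-12 for concentrations; charge integrated, potential derived.
* Tiny negative concentration excursions from the integrator are clipped
  to zero when states are rebuilt; flux laws never see negative input.
* Grid areas use a half-spacing lattice offset so no lattice line
  coincides with a shape boundary.
* The exact Mann–Whitney null distribution is undefined under ties; tied
  samples fall back to the normal approximation.
* Random layouts retry placement up to `max_tries` and then fail loudly
  rather than degrade packing silently.
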