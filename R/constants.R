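#' Physical constants used throughout the package
#'
#' Faraday constant (C/mol), molar gas constant (J/mol/K) and the Avogadro
#' number. All unit conversions in the package funnel through these values.
#'
#' @format A named list with elements `F` (96485.332 C/mol), `R`
#'   (8.31446 J/mol/K) and `NA_` (6.02214076e23 /mol).
#' @export
gg_constants <- list(
  F   = 96485.33212,
  R   = 8.314462618,
  NA_ = 6.02214076e23
)

# RT in J/mol at temperature T (K)
rt_J <- function(T) gg_constants$R * T

# concentration floor (mM) applied inside log terms; see vignette
CONC_FLOOR_MM <- 1e-3

floor_conc <- function(c_mM) pmax(c_mM, CONC_FLOOR_MM)
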