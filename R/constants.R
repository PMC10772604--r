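#' Physical constants used throughout the package
#'
#' @format A list with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, 8.617333262e-5 eV/K (CODATA).}
#'   \item{p_atm}{Sea-surface atmospheric O2 partial pressure, 0.21 atm.}
#' }
#' @export
mi_constants <- list(
  k_B   = 8.617333262e-5,
  p_atm = 0.21
)

# internal shorthands
.kB <- mi_constants$k_B
.T0K <- 273.15
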