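#' Construct a set of active hypoxia tolerance traits
#'
#' Bundles the three diagnosed traits of a species: active hypoxia tolerance
#' `A_eco` (1/atm), its temperature sensitivity `E_eco_ref` (eV) evaluated at
#' the reference temperature, and the slope `dEdT` (eV/degC) that lets the
#' effective activation energy vary linearly with temperature.
#'
#' @param A_eco Active hypoxia tolerance, 1/atm; must be > 0. Its reciprocal
#'   is the minimum viable pO2 for an ecologically active population at
#'   `T_ref`.
#' @param E_eco_ref Temperature sensitivity of active hypoxia tolerance at
#'   `T_ref`, eV.
#' @param dEdT Slope of the effective activation energy with temperature,
#'   eV/degC. Non-negative by default; set `allow_negative_dEdT = TRUE` to
#'   relax.
#' @param T_ref Reference temperature, degC (default 15).
#' @param species_id Optional species identifier.
#' @param allow_negative_dEdT Permit `dEdT < 0`.
#' @return An object of class `"trait_set"` (a named list).
#' @examples
#' tr <- trait_set(A_eco = 10, E_eco_ref = 0.4)
#' po2_act(tr, T = 25)
#' @export
trait_set <- function(A_eco, E_eco_ref, dEdT = 0, T_ref = 15,
                      species_id = NA_character_,
                      allow_negative_dEdT = FALSE) {
  stopifnot(length(A_eco) == 1L, length(E_eco_ref) == 1L,
            length(dEdT) == 1L, length(T_ref) == 1L)
  if (!is.finite(A_eco) || A_eco <= 0)
    stop("A_eco must be finite and > 0, got ", A_eco)
  if (!is.finite(E_eco_ref)) stop("E_eco_ref must be finite")
  if (!is.finite(dEdT)) stop("dEdT must be finite")
  if (!is.finite(T_ref)) stop("T_ref must be finite")
  if (dEdT < 0 && !allow_negative_dEdT)
    stop("dEdT < 0; set allow_negative_dEdT = TRUE to permit")
  structure(
    list(species_id = species_id, A_eco = A_eco, E_eco_ref = E_eco_ref,
         dEdT = dEdT, T_ref = T_ref),
    class = "trait_set"
  )
}

#' @export
print.trait_set <- function(x, ...) {
  cat("Active hypoxia tolerance traits",
      if (!is.na(x$species_id)) paste0("[", x$species_id, "]"), "\n")
  cat(sprintf("  A_eco     = %.4g atm^-1\n", x$A_eco))
  cat(sprintf("  E_eco_ref = %.4g eV at T_ref = %g degC\n",
              x$E_eco_ref, x$T_ref))
  cat(sprintf("  dEdT      = %.4g eV/degC\n", x$dEdT))
  invisible(x)
}

as_trait_set <- function(x) {
  if (inherits(x, "trait_set")) return(x)
  trait_set(A_eco = x$A_eco, E_eco_ref = x$E_eco_ref,
            dEdT = if (is.null(x$dEdT)) 0 else x$dEdT,
            T_ref = if (is.null(x$T_ref)) 15 else x$T_ref,
            species_id = if (is.null(x$species_id)) NA_character_
                         else x$species_id,
            allow_negative_dEdT = TRUE)
}

#' Arrhenius temperature-scaling factor
#'
#' `exp(-E/k_B * (1/T_K - 1/Tref_K))` with temperatures in Kelvin. The factor
#' equals 1 at `T = T_ref`, increases with temperature when `E > 0` and
#' decreases when `E < 0`. It scales any rate (or ratio of rates) with
#' effective activation energy `E` relative to its value at the reference
#' temperature.
#'
#' @param E Activation energy, eV. Vectorised.
#' @param T_C Temperature, degC. Vectorised.
#' @param T_ref Reference temperature, degC.
#' @return Dimensionless factor(s).
#' @examples
#' arrhenius_factor(0.4, T_C = 25, T_ref = 15)  # ~1.716
#' @export
arrhenius_factor <- function(E, T_C, T_ref = 15) {
  if (any(!is.finite(E))) stop("non-finite activation energy E")
  if (any(!is.finite(T_C)) || any(!is.finite(T_ref)))
    stop("non-finite temperature")
  if (any(T_C <= -.T0K) || any(T_ref <= -.T0K))
    stop("temperature at or below absolute zero")
  exp(-E / .kB * (1 / (T_C + .T0K) - 1 / (T_ref + .T0K)))
}

#' Effective activation energy at a given temperature
#'
#' The effective temperature sensitivity of active hypoxia tolerance is
#' modelled as a linear function of temperature,
#' `E(T) = E_eco_ref + dEdT * (T - T_ref)`, which parameterises the
#' multi-step nature of organismal O2 supply with a single extra slope.
#'
#' @param traits A [trait_set()].
#' @param T_C Temperature, degC. Vectorised.
#' @return Effective activation energy, eV.
#' @export
effective_E <- function(traits, T_C) {
  traits <- as_trait_set(traits)
  if (any(!is.finite(T_C))) stop("non-finite temperature")
  traits$E_eco_ref + traits$dEdT * (T_C - traits$T_ref)
}

#' Minimum viable pO2 for an ecologically active population
#'
#' The temperature-dependent lower pO2 threshold,
#' `pO2_act(T) = (1/A_eco) * f(E(T), T)`, below which the Metabolic Index
#' falls under 1 and sustained ecological activity is not viable.
#'
#' @inheritParams effective_E
#' @return Threshold pO2, atm. Vectorised over `T_C`.
#' @examples
#' po2_act(trait_set(A_eco = 1/0.21, E_eco_ref = 0.3), T_C = 15)  # 0.21 atm
#' @export
po2_act <- function(traits, T_C) {
  traits <- as_trait_set(traits)
  (1 / traits$A_eco) *
    arrhenius_factor(effective_E(traits, T_C), T_C, traits$T_ref)
}

#' Metabolic Index relative to the active threshold
#'
#' Ratio of ambient O2 supply potential to the O2 demand of sustained
#' ecological activity: `Phi = A_eco * pO2 / f(E(T), T)`. Values at or above
#' 1 mark metabolically viable habitat; `Phi` equals 1 exactly at
#' `pO2 = po2_act(traits, T)`. Because the diagnosed tolerance already folds
#' in the critical activity ratio (`A_eco = A_o / Phi_crit`), this index is
#' the classical metabolic index normalised by `Phi_crit`.
#'
#' @param pO2 Ambient O2 partial pressure, atm; must be >= 0. Vectorised.
#' @inheritParams effective_E
#' @return Dimensionless index, vectorised over `pO2`/`T_C`.
#' @export
metabolic_index <- function(pO2, T_C, traits) {
  traits <- as_trait_set(traits)
  if (any(!is.finite(pO2)) || any(pO2 < 0))
    stop("pO2 must be finite and >= 0")
  traits$A_eco * pO2 /
    arrhenius_factor(effective_E(traits, T_C), T_C, traits$T_ref)
}

#' Compose the active temperature sensitivity from its components
#'
#' `E_eco = E_d - E_s + E_phicrit`: the activation energy of metabolic O2
#' demand, minus that of physiological O2 supply, plus the temperature
#' sensitivity of the sustained-to-resting metabolic rate ratio.
#'
#' @param E_d Demand activation energy, eV.
#' @param E_s Supply activation energy, eV.
#' @param E_phicrit Temperature sensitivity of Phi_crit, eV (default 0,
#'   i.e. activity costs scale like resting costs).
#' @return `E_eco`, eV.
#' @examples
#' compose_E_eco(0.7, 0.4, -0.1)  # 0.2
#' @export
compose_E_eco <- function(E_d, E_s, E_phicrit = 0) {
  if (any(!is.finite(c(E_d, E_s, E_phicrit))))
    stop("all components must be finite")
  E_d - E_s + E_phicrit
}

#' Active hypoxia tolerance from resting traits
#'
#' Computes `A_eco` from exactly one of three equivalent parameterisations:
#' resting tolerance `A_o` (`A_eco = A_o / Phi_crit`), resting vulnerability
#' `V_h` (`A_eco = 1 / (V_h * Phi_crit)`), or the supply/demand coefficients
#' (`A_eco = alpha_S / (alpha_D * Phi_crit)`).
#'
#' @param Phi_crit Ratio of sustained to resting metabolic rate, >= 1 in
#'   physiologically meaningful cases (1 means no active cost).
#' @param A_o Resting hypoxia tolerance, 1/atm.
#' @param V_h Resting hypoxia vulnerability, atm (`A_o = 1/V_h`).
#' @param alpha_S,alpha_D O2 supply efficacy and resting demand coefficients
#'   (must be supplied together).
#' @param strict Error (rather than warn) when `Phi_crit < 1`.
#' @return `A_eco`, 1/atm.
#' @examples
#' aeco_from_components(Phi_crit = 3, A_o = 15)  # 5
#' @export
aeco_from_components <- function(Phi_crit, A_o = NULL, V_h = NULL,
                                 alpha_S = NULL, alpha_D = NULL,
                                 strict = FALSE) {
  routes <- c(!is.null(A_o), !is.null(V_h),
              !is.null(alpha_S) || !is.null(alpha_D))
  if (sum(routes) != 1L)
    stop("supply exactly one of A_o, V_h, or (alpha_S, alpha_D)")
  if (any(!is.finite(Phi_crit)))
    stop("Phi_crit must be finite")
  if (any(Phi_crit < 1)) {
    msg <- "Phi_crit < 1: sustained metabolic rate below resting"
    if (strict) stop(msg) else warning(msg)
  }
  if (any(Phi_crit == 0)) stop("Phi_crit must be non-zero")
  if (!is.null(A_o)) return(A_o / Phi_crit)
  if (!is.null(V_h)) {
    if (any(V_h == 0)) stop("V_h must be non-zero")
    return(1 / (V_h * Phi_crit))
  }
  if (is.null(alpha_S) || is.null(alpha_D))
    stop("alpha_S and alpha_D must be supplied together")
  if (any(alpha_D == 0)) stop("alpha_D must be non-zero")
  alpha_S / (alpha_D * Phi_crit)
}
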