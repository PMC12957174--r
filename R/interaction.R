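## interaction_kinetics: the three inhibition mechanisms coupling
## perpetrators to victims, exposed as pure functions.  The ODE engine uses
## the same arithmetic internally (see pbpk_rhs); these entry points are the
## quantitative definition of each mechanism and serve as analytic oracles.

#' Competitive inhibition factor on the apparent Km
#'
#' `Km_apparent = Km * (1 + sum(Cu_I / Ki))` across all competitive
#' inhibitors of an enzyme.  Returns the multiplier.  At substrate
#' concentrations well below Km the metabolic rate scales as 1/factor.
#'
#' @param Cu_inhibitor unbound inhibitor concentration(s), umol/L.
#' @param Ki inhibition constant(s), umol/L (recycled against
#'   `Cu_inhibitor`).
#' @return dimensionless factor >= 1.
#' @export
competitive_rate_factor <- function(Cu_inhibitor, Ki) {
  if (any(Cu_inhibitor < 0) || any(Ki <= 0))
    abort_validation("Cu_inhibitor must be >= 0 and Ki > 0")
  1 + sum(Cu_inhibitor / Ki)
}

#' Enzyme-pool dynamics under mechanism-based inactivation
#'
#' `dE/dt = kdeg * (1 - E) - kinact * Cu / (KI + Cu) * E` for the active
#' enzyme fraction `E` (baseline 1).  Integrated alongside the PBPK state
#' by the engine.
#'
#' @param E_frac active enzyme fraction in \[0, 1\].
#' @param Cu_inhibitor unbound inactivator concentration, umol/L.
#' @param KI half-maximal inactivation concentration, umol/L.
#' @param kinact maximal inactivation rate, 1/h.
#' @param kdeg enzyme degradation/resynthesis rate, 1/h.
#' @return dE/dt, 1/h.
#' @export
tdi_enzyme_dynamics <- function(E_frac, Cu_inhibitor, KI, kinact, kdeg) {
  if (any(E_frac < 0) || any(E_frac > 1))
    abort_validation("E_frac must lie in [0, 1]", "E_frac")
  kdeg * (1 - E_frac) - kinact * Cu_inhibitor / (KI + Cu_inhibitor) * E_frac
}

#' Steady-state active fraction under constant inactivator exposure
#'
#' Closed form of [tdi_enzyme_dynamics()] at equilibrium:
#' `E_ss = kdeg / (kdeg + kinact * I / (KI + I))`.
#'
#' @inheritParams tdi_enzyme_dynamics
#' @export
tdi_steady_state <- function(Cu_inhibitor, KI, kinact, kdeg) {
  lam <- kinact * Cu_inhibitor / (KI + Cu_inhibitor)
  kdeg / (kdeg + lam)
}

#' Reversible MAO-A coupling multiplier
#'
#' Apparent MAO-A clearance under unbound harmine:
#' `CL_apparent = CL / (1 + Cu_HRM / Ki)`; the returned multiplier is
#' applied to the MAO-A intrinsic clearances in gut wall and liver.
#'
#' @param Cu_HRM unbound harmine concentration at the site, umol/L.
#' @param Ki_MAOA reversible MAO-A inhibition constant, umol/L.
#' @return multiplier in (0, 1].
#' @export
maoa_coupling <- function(Cu_HRM, Ki_MAOA) {
  if (any(Cu_HRM < 0) || any(Ki_MAOA <= 0))
    abort_validation("Cu_HRM must be >= 0 and Ki_MAOA > 0")
  1 / (1 + Cu_HRM / Ki_MAOA)
}
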