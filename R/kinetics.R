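#' Convert light intensity to photon flux
#'
#' Unit bridge between the conventional light-intensity scale
#' (umol photons m^-2 s^-1) and an absolute photon flux
#' (photons m^-2 s^-1), so that an absorption cross-section in nm^2 times
#' the flux yields a per-second excitation rate.
#'
#' @param I Light intensity (umol photons m^-2 s^-1); vectorized.
#' @return Photon flux in photons m^-2 s^-1 (`I * 1e-6 *` Avogadro's number).
#' @examples
#' photon_flux(1)   # one micromole of photons
#' photon_flux(440)
#' @export
photon_flux <- function(I) {
  if (!is.numeric(I) || any(is.na(I)) || any(I < 0)) {
    abort("light intensity must be non-negative")
  }
  I * 1e-6 * .avogadro
}

# per-unit excitation, energy-conversion and damage rates of the two-state
# photosynthetic-unit cycle; returns per-PSU rates in s^-1
psu_unit_rates <- function(params, I) {
  kexc <- params$sigma * 1e-18 * photon_flux(I)
  if (kexc + params$tau <= 0) {
    return(list(kexc = 0, eps = 0, delta = 0, excited = 0))
  }
  excited <- kexc / (kexc + params$tau)
  eps <- params$tau * excited            # energy output per PSU
  target <- switch(params$damage_target,
                   excited = excited,
                   ground = 1 - excited)
  delta <- params$kd * kexc * target     # damage probability flux per PSU
  list(kexc = kexc, eps = eps, delta = delta, excited = excited)
}

#' Photosynthetic-unit fluxes
#'
#' Quasi-steady-state fluxes of the two-state photosynthetic-unit (PSU)
#' cycle: units in the ground state absorb photons with per-unit rate
#' `sigma * photon_flux(I)` and excited units relax with turnover rate `tau`,
#' delivering one unit of cellular energy per relaxation. At quasi-steady
#' state the absorption flux `v1` equals the energy-production flux `v2 =
#' P * tau * k_exc / (k_exc + tau)`, which saturates at `tau * P`.
#' Photodamage `vi` removes PSU mass with probability `kd` per damaging
#' excitation; by default damaging excitations are those arriving at already
#' excited (busy) units, so `vi` keeps increasing with light after `v2` has
#' saturated -- the mechanism behind photoinhibition.
#'
#' @param P_conc Photosynthetic-unit concentration (any amount unit; the
#'   returned fluxes are per the same unit).
#' @param I Light intensity (umol photons m^-2 s^-1).
#' @param params A [model_parameters()] object.
#' @return A tibble with columns `v1`, `v2`, `vi` (fluxes, s^-1 times the
#'   unit of `P_conc`), `k_exc` (per-unit excitation rate, s^-1) and
#'   `excited_fraction`.
#' @examples
#' psu_rates(1, I = 440, params = model_parameters())
#' @export
psu_rates <- function(P_conc, I, params = model_parameters()) {
  if (any(P_conc < 0)) abort("`P_conc` must be >= 0")
  u <- psu_unit_rates(params, I)
  tibble(
    v1 = u$eps * P_conc,
    v2 = u$eps * P_conc,
    vi = u$delta * P_conc,
    k_exc = u$kexc,
    excited_fraction = u$excited
  )
}
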