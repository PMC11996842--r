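#' Physical constants (CODATA, overridable)
#'
#' SI values of the constants used by the observer-thermodynamics
#' calculators. Any of them can be overridden — e.g. `k_B = 1` — which keeps
#' the closed forms cleanly testable with toy units.
#'
#' @param k_B Boltzmann constant (J/K).
#' @param hbar Reduced Planck constant (J s).
#' @param G Gravitational constant (m^3 kg^-1 s^-2).
#' @param c Speed of light (m/s).
#' @return Named list of class `physical_constants`.
#' @export
physical_constants <- function(k_B = 1.380649e-23, hbar = 1.054571817e-34,
                               G = 6.67430e-11, c = 299792458) {
  stopifnot(k_B > 0, hbar > 0, G > 0, c > 0)
  structure(list(k_B = k_B, hbar = hbar, G = G, c = c),
            class = "physical_constants")
}

#' Landauer minimum erasure energy
#'
#' The minimum free energy to erase or irreversibly record one bit at
#' temperature `T`: `ln(2) k_B T`.
#'
#' @param T_kelvin Temperature in kelvin, `> 0`.
#' @param const A [physical_constants()] list.
#' @return Energy in joules.
#' @export
#' @examples
#' landauer_min_energy(300) # ~2.87e-21 J
landauer_min_energy <- function(T_kelvin, const = physical_constants()) {
  if (any(T_kelvin <= 0)) qcog_abort("temperature must be > 0", "qcog_domain_error")
  log(2) * const$k_B * T_kelvin
}

#' Energy of one yes/no question
#'
#' The Hamiltonian scale of a one-bit interrogation, `H = beta k_B T` per
#' bit, with `beta >= ln(2)` allowing for practical inefficiencies; at
#' `beta = ln(2)` it coincides exactly with the Landauer bound. Values of
#' `beta` below `ln(2)` are physically sub-Landauer and produce a warning.
#'
#' @param beta Dimensionless efficiency factor.
#' @param T_kelvin Temperature in kelvin.
#' @param const A [physical_constants()] list.
#' @return Energy in joules.
#' @export
question_energy <- function(beta, T_kelvin, const = physical_constants()) {
  if (any(beta < log(2))) {
    warning("beta < ln(2): below the Landauer limit", call. = FALSE)
  }
  beta * const$k_B * T_kelvin
}

#' Schwarzschild and Bekenstein-Hawking quantities of a mass
#'
#' Closed forms for a non-rotating, uncharged black hole of mass `M`:
#' horizon radius `R_s = 2 G M / c^2`, horizon area `A = 4 pi R_s^2`, and
#' entropy computed two ways — the mass form `S = 4 pi G k_B M^2 / (hbar c)`
#' and the area form `S = k_B c^3 A / (4 G hbar)` — which must agree to
#' 1e-10 relative (an internal consistency check performed on every call).
#'
#' @param M Mass in kg, `> 0`.
#' @param const A [physical_constants()] list.
#' @return A tibble with columns `mass`, `radius_m`, `area_m2`,
#'   `entropy_J_per_K`.
#' @export
#' @examples
#' black_hole_quantities(1.989e30) # one solar mass: R_s ~ 2.95 km
black_hole_quantities <- function(M, const = physical_constants()) {
  if (any(M <= 0)) qcog_abort("mass must be > 0", "qcog_domain_error")
  r_s <- 2 * const$G * M / const$c^2
  area <- 4 * pi * r_s^2
  s_mass <- const$k_B * 4 * pi * const$G * M^2 / (const$hbar * const$c)
  s_area <- const$k_B * const$c^3 * area / (4 * const$G * const$hbar)
  rel <- abs(s_mass - s_area) / s_mass
  if (any(rel > 1e-10)) {
    qcog_abort("entropy closed forms disagree beyond 1e-10 relative", "qcog_contract_error")
  }
  tibble::tibble(mass = M, radius_m = r_s, area_m2 = area,
                 entropy_J_per_K = s_mass)
}

#' Fitness-beats-truth probability
#'
#' Probability that a fitness-tuned perceptual strategy outcompetes a
#' veridical one as a function of the number of distinct perceptual states
#' `n`: `(n - 3) / (n - 1)`. The ratio is 0 at the `n = 3` boundary,
#' strictly increasing, and tends to 1 as the perceptual space grows —
#' truth-tracking perception is driven out in rich perceptual spaces.
#'
#' @param n_states Integer number of perceptual states, `>= 3`.
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' fbt_probability(4) # 1/3
fbt_probability <- function(n_states) {
  if (any(n_states < 3)) {
    qcog_abort("fitness-beats-truth ratio requires n_states >= 3", "qcog_domain_error")
  }
  (n_states - 3) / (n_states - 1)
}
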