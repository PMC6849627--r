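#' Potential evapotranspiration from mean annual temperature
#'
#' Annual atmospheric water demand as a smooth, nondecreasing function of
#' mean annual temperature, using the cubic evaporative-demand form of
#' Turc's annual water-balance family:
#' \deqn{PET(T) = \max\{0,\; 300 + 25T + 0.05T^3\}\ \mathrm{mm\,yr^{-1}}}
#' The derivative \eqn{25 + 0.15T^2} is positive everywhere, demand
#' vanishes for very cold climates (below about -10.7 degC), and at the
#' default site temperature of 5.1 degC the demand is ~434 mm/yr, a
#' realistic upland-blanket-bog value.
#'
#' @param temp_c mean annual air temperature, degC.
#' @return potential evapotranspiration, mm/year.
#' @export
pet <- function(temp_c) {
  stopifnot(is.numeric(temp_c), all(is.finite(temp_c)))
  pmax(0, 300 + 25 * temp_c + 0.05 * temp_c^3)
}

#' Net primary production from potential evapotranspiration
#'
#' Saturating-exponential production curve of the Lieth
#' evapotranspiration-productivity family,
#' \deqn{NPP = c_f \cdot 3000\,[1 - e^{-0.0009695\,(PET - 20)}]}
#' in g dry matter m-2 yr-1 converted to carbon with \eqn{c_f = 0.475} g C
#' per g dry matter, clamped at zero below the 20 mm intercept.  A
#' management multiplier (burning) scales the result; plant-functional-type
#' composition does not alter the total here (bog communities converge in
#' annual production) but governs litter quality downstream.
#'
#' @param pet_mm potential evapotranspiration, mm/year.
#' @param pfts optional [pft_composition()] result (unused for the total;
#'   accepted so callers can pass the year's community through).
#' @param multiplier management multiplier in \[0, 1\] (1 = unmanaged;
#'   0.01 in a burn year).
#' @return net primary production, g C m-2 yr-1.
#' @export
npp <- function(pet_mm, pfts = NULL, multiplier = 1) {
  stopifnot(all(is.finite(pet_mm)), all(pet_mm >= 0))
  if (any(multiplier < 0 | multiplier > 1)) abort("`multiplier` must lie in [0, 1].")
  base <- 0.475 * 3000 * (1 - exp(-0.0009695 * pmax(0, pet_mm - 20)))
  base * multiplier
}
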