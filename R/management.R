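#' Grouse-moor management schedule
#'
#' Dated burn-rotation and grip-drainage parameters for a managed blanket
#' bog.  Defaults describe a formal shooting estate of the northern
#' Pennines: rotational burning 1851-1950 on a 20-year return interval,
#' reducing NPP to 1% in the burnt year with sigmoidal recovery to 100% by
#' 5 or 10 years and routing 5% of the burnt biomass carbon to an inert
#' charcoal pool; grips installed in 1831, held at optimum efficiency for
#' 25 years, declining linearly to 60% over the next 15 years, renewed to
#' optimum in 1871 and held until 1905, then declining linearly to 0% by
#' 1955, lowering the water table by 5 cm at full efficiency.  Grazing is
#' a no-op above 450 m elevation.
#'
#' @param burn_start,burn_end first and last possible burn years.
#' @param rotation burn return interval, years.
#' @param recovery_years years for NPP to recover to 100% after a burn
#'   (5 or 10 in the standard scenarios).
#' @param burn_npp_floor NPP multiplier in the burnt year (0.01 = 1%).
#' @param charcoal_fraction fraction of burnt biomass carbon becoming
#'   inert charcoal (0.05 = 5%).
#' @param drain_install grip installation year.
#' @param drain_renewal renewal year (efficiency jumps back to optimum).
#' @param drain_optimum_until last year of the post-renewal optimum.
#' @param drain_zero_by year by which efficiency reaches 0.
#' @param optimum_span,decline_span years at optimum and declining after
#'   installation.
#' @param decline_floor efficiency reached at the end of the first decline.
#' @param drain_depth water-table lowering at full efficiency, cm.
#' @param burning,drainage logical switches for the two interventions.
#' @param elevation_m site elevation; grazing is insignificant above
#'   `grazing_limit_m` and no grazing effect is modelled there.
#' @param grazing_limit_m elevation above which grazing is a no-op (450 m).
#' @return list of class `scenario_schedule`.
#' @export
scenario_schedule <- function(burn_start = 1851, burn_end = 1950, rotation = 20,
                              recovery_years = 10, burn_npp_floor = 0.01,
                              charcoal_fraction = 0.05,
                              drain_install = 1831, drain_renewal = 1871,
                              drain_optimum_until = 1905, drain_zero_by = 1955,
                              optimum_span = 25, decline_span = 15,
                              decline_floor = 0.60, drain_depth = 5,
                              burning = TRUE, drainage = TRUE,
                              elevation_m = 550, grazing_limit_m = 450) {
  if (burn_start > burn_end) abort("`burn_start` must be <= `burn_end`.")
  if (rotation < 1) abort("`rotation` must be >= 1.")
  fracs <- c(burn_npp_floor, charcoal_fraction, decline_floor)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1].")
  if (!(drain_install < drain_renewal && drain_renewal < drain_zero_by)) {
    abort("need drain_install < drain_renewal < drain_zero_by.")
  }
  structure(list(burn_start = burn_start, burn_end = burn_end, rotation = rotation,
                 recovery_years = recovery_years, burn_npp_floor = burn_npp_floor,
                 charcoal_fraction = charcoal_fraction,
                 drain_install = drain_install, drain_renewal = drain_renewal,
                 drain_optimum_until = drain_optimum_until,
                 drain_zero_by = drain_zero_by,
                 optimum_span = optimum_span, decline_span = decline_span,
                 decline_floor = decline_floor, drain_depth = drain_depth,
                 burning = burning, drainage = drainage,
                 elevation_m = elevation_m, grazing_limit_m = grazing_limit_m),
            class = "scenario_schedule")
}

#' Named management scenario presets
#'
#' The five standard contrasts: `"no_shoot"` (unmanaged), `"burn_drain_10"`
#' and `"burn_drain_5"` (burning plus drainage, 10- or 5-year NPP
#' recovery), `"burn_only_10"` and `"burn_only_5"` (burning without
#' drainage).
#'
#' @param name scenario name.
#' @return a [scenario_schedule()], or `NULL` for `"no_shoot"`.
#' @export
scenario_preset <- function(name = c("no_shoot", "burn_drain_10", "burn_drain_5",
                                     "burn_only_10", "burn_only_5")) {
  name <- match.arg(name)
  switch(name,
    no_shoot = NULL,
    burn_drain_10 = scenario_schedule(recovery_years = 10),
    burn_drain_5 = scenario_schedule(recovery_years = 5),
    burn_only_10 = scenario_schedule(recovery_years = 10, drainage = FALSE),
    burn_only_5 = scenario_schedule(recovery_years = 5, drainage = FALSE)
  )
}

#' Burn years of a schedule
#'
#' @param s [scenario_schedule()].
#' @return integer vector `burn_start, burn_start + rotation, ... <= burn_end`
#'   (empty if burning is switched off).
#' @export
burn_years <- function(s) {
  if (!s$burning) return(integer(0))
  seq(s$burn_start, s$burn_end, by = s$rotation)
}

#' NPP multiplier after a burn
#'
#' 1% of normal NPP in the burnt year, recovering along a sigmoid
#' (logistic with midpoint at half the recovery span, pinned exactly to the
#' floor at year 0 and to 1 at and beyond `recovery_years`).
#'
#' @param years_since_burn nonnegative integer(s).
#' @param s [scenario_schedule()].
#' @return multiplier(s) in `[burn_npp_floor, 1]`, nondecreasing.
#' @export
npp_multiplier <- function(years_since_burn, s = scenario_schedule()) {
  if (any(years_since_burn < 0)) abort("`years_since_burn` must be >= 0.")
  R <- s$recovery_years
  g <- function(t) 1 / (1 + exp(-(t - R / 2) / (R / 8)))
  v <- s$burn_npp_floor +
    (1 - s$burn_npp_floor) * (g(years_since_burn) - g(0)) / (g(R) - g(0))
  ifelse(years_since_burn >= R, 1, pmin(1, pmax(s$burn_npp_floor, v)))
}

#' Charcoal input from a burn
#'
#' @param burned_npp_c burnt biomass carbon, g C m-2 (>= 0).
#' @param s [scenario_schedule()].
#' @return carbon routed to the inert charcoal pool, g C m-2
#'   (`charcoal_fraction` of the burnt mass).
#' @export
charcoal_input <- function(burned_npp_c, s = scenario_schedule()) {
  if (any(burned_npp_c < 0)) abort("`burned_npp_c` must be >= 0.")
  s$charcoal_fraction * burned_npp_c
}

#' Grip drainage efficiency in a given year
#'
#' Piecewise-linear on integer years: optimum (1.0) from installation for
#' `optimum_span` years, declining linearly to `decline_floor` in the last
#' year before renewal, an instantaneous jump back to optimum at renewal,
#' optimum until `drain_optimum_until`, then linear decline to 0 at
#' `drain_zero_by`; 0 outside the installed period.
#'
#' @param year calendar year(s).
#' @param s [scenario_schedule()].
#' @return efficiency fraction(s) in `[0, 1]`.
#' @export
drain_efficiency <- function(year, s = scenario_schedule()) {
  if (!s$drainage) return(rep(0, length(year)))
  opt1_end <- s$drain_install + s$optimum_span - 1          # last optimum year
  vapply(year, function(y) {
    if (y < s$drain_install || y > s$drain_zero_by) return(0)
    if (y <= opt1_end) return(1)
    if (y < s$drain_renewal) {
      # linear from 1.0 (last optimum year) to decline_floor in the year
      # immediately before renewal
      f <- (y - opt1_end) / (s$drain_renewal - 1 - opt1_end)
      return(1 - (1 - s$decline_floor) * f)
    }
    if (y <= s$drain_optimum_until) return(1)
    max(0, 1 - (y - s$drain_optimum_until) / (s$drain_zero_by - s$drain_optimum_until))
  }, numeric(1))
}

#' Apply drainage to a water table
#'
#' @param wtd natural water-table depth, cm.
#' @param year calendar year.
#' @param s [scenario_schedule()].
#' @return deepened water table `wtd + drain_depth * drain_efficiency(year)`.
#' @export
apply_drainage <- function(wtd, year, s = scenario_schedule()) {
  wtd + s$drain_depth * drain_efficiency(year, s)
}
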