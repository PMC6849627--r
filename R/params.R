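#' Hydrological parameters
#'
#' @param sy specific yield (fraction, default 0.02, clay-type bedrock
#'   interface).  Used as a floor on the air-filled storage fraction when
#'   converting water gains/losses to water-table movement; with the default
#'   pore-space law (which is >= 0.2 everywhere) the floor is not binding.
#' @param hc hydraulic conductivity into the bedrock, cm/year (default 0.1,
#'   unweathered clay).
#' @param pore_a,pore_b constants of the air-filled pore-space law
#'   `min(1, pore_a * exp(pore_b * d^2))`, d in metres above the water table.
#' @param runoff_threshold water-table depth (cm) above which (i.e. wetter
#'   than which) excess water is shed as runoff within the year (default 0,
#'   the peat surface: high water tables lead to higher runoff).
#' @param runoff_coef fraction of the excess shed per year (default 1:
#'   blanket bogs on slopes shed surface water within the season).
#' @param standing_water_cap deepest standing water tracked, cm (default
#'   -10; anything wetter is shed as runoff).
#' @param dry_season_pet_frac share of annual PET demand drawn from
#'   water-table storage during the dry season (default 0.10).
#' @param dry_season_recharge_frac share of annual precipitation that
#'   recharges the water table during the dry season (default 0.017).
#'   Together with `dry_season_pet_frac` this sets the within-year
#'   drawdown that the reported annual-mean water table reflects; the
#'   defaults are calibrated so an unmanaged run under the default climate
#'   reproduces the observed blanket-bog regime of mean annual WTD ~4.4 cm
#'   with interannual sd ~1.8 cm.
#' @return list of class `hydro_params`.
#' @export
hydro_params <- function(sy = 0.02, hc = 0.1, pore_a = 0.2, pore_b = 1.6,
                         runoff_threshold = 0, runoff_coef = 1,
                         standing_water_cap = -10,
                         dry_season_pet_frac = 0.10,
                         dry_season_recharge_frac = 0.017) {
  if (sy <= 0 || sy >= 1) abort("`sy` must lie in (0, 1).")
  if (hc < 0) abort("`hc` must be >= 0.")
  if (runoff_coef < 0 || runoff_coef > 1) abort("`runoff_coef` must lie in [0, 1].")
  structure(list(sy = sy, hc = hc, pore_a = pore_a, pore_b = pore_b,
                 runoff_threshold = runoff_threshold, runoff_coef = runoff_coef,
                 standing_water_cap = standing_water_cap,
                 dry_season_pet_frac = dry_season_pet_frac,
                 dry_season_recharge_frac = dry_season_recharge_frac),
            class = "hydro_params")
}

#' Decomposition parameters
#'
#' Annual discrete fractional decay per litter-quality pool: a cohort mass
#' fraction above the water table loses `min(1, k * fT)` of each pool per
#' year, and below the water table `anoxic_ratio` times that, where
#' `fT = q10^((T - tref)/10)`.  Discrete annual rates (rather than
#' within-year exponential integration) keep the anoxic:oxic first-year
#' loss ratio exactly equal to `anoxic_ratio`.
#'
#' @param k_pools named aerobic rate constants (/year) for the four litter
#'   quality pools (fast, mid, slow, humic).
#' @param q10 temperature sensitivity (default 2).
#' @param tref reference temperature, degC (default 10).
#' @param anoxic_ratio anaerobic:aerobic rate multiplier (default 0.035;
#'   literature range 0.025-0.0625 accepted).
#' @param ch4_fraction_anoxic fraction of anoxic carbon loss emitted as
#'   CH4 (remainder as CO2; default 0.5).
#' @param ch4_oxidation_rate first-order methane oxidation constant, per cm
#'   of oxic peat transited per year (default 0.05; see the methods
#'   vignette for the basis of this rate).
#' @param ebullition_fraction share of produced CH4 escaping as bubbles,
#'   bypassing oxidation (default 0.15).
#' @param pmt_coef plant-mediated-transport efficiency per unit sedge+rush
#'   cover (default 1).
#' @return list of class `decomp_params`.
#' @export
decomp_params <- function(k_pools = c(fast = 0.6, mid = 0.25, slow = 0.06, humic = 0.004),
                          q10 = 2, tref = 10, anoxic_ratio = 0.035,
                          ch4_fraction_anoxic = 0.10,
                          ch4_oxidation_rate = 0.05,
                          ebullition_fraction = 0.10,
                          pmt_coef = 0.5) {
  if (any(k_pools <= 0)) abort("pool rate constants must be > 0.")
  if (anoxic_ratio <= 0 || anoxic_ratio >= 1) abort("`anoxic_ratio` must lie in (0, 1).")
  if (ch4_fraction_anoxic < 0 || ch4_fraction_anoxic > 1) {
    abort("`ch4_fraction_anoxic` must lie in [0, 1].")
  }
  structure(list(k_pools = k_pools, q10 = q10, tref = tref,
                 anoxic_ratio = anoxic_ratio,
                 ch4_fraction_anoxic = ch4_fraction_anoxic,
                 ch4_oxidation_rate = ch4_oxidation_rate,
                 ebullition_fraction = ebullition_fraction,
                 pmt_coef = pmt_coef),
            class = "decomp_params")
}

#' Full simulator parameter set
#'
#' @param hydro [hydro_params()].
#' @param decomp [decomp_params()].
#' @param bd_surface,bd_deep,bd_efold bulk-density compaction rule: cohort
#'   bulk density (g/cm3) rises from `bd_surface` toward `bd_deep` with
#'   e-folding age `bd_efold` years.
#' @param c_fraction carbon fraction of litter dry matter (default 0.475).
#' @param erosion_rate proportional annual carbon loss to erosion (default
#'   0: erosion is a stub retained for budget bookkeeping).
#' @return list of class `peat_params`.
#' @export
peat_params <- function(hydro = hydro_params(), decomp = decomp_params(),
                        bd_surface = 0.04, bd_deep = 0.14, bd_efold = 100,
                        c_fraction = 0.475, erosion_rate = 0) {
  structure(list(hydro = hydro, decomp = decomp,
                 bd_surface = bd_surface, bd_deep = bd_deep, bd_efold = bd_efold,
                 c_fraction = c_fraction, erosion_rate = erosion_rate),
            class = "peat_params")
}

#' Read simulator parameters from a YAML config file
#'
#' Keys are namespaced as `hydro.*`, `decomp.*` and top-level simulator
#' keys, e.g. `hydro: {sy: 0.02, hc: 0.1}`, `decomp: {anoxic_ratio: 0.035}`.
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return [peat_params()] object.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs needs the 'yaml' package.")
  }
  cfg <- yaml::read_yaml(path)
  take <- function(block, fn) {
    args <- cfg[[block]] %||% list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) abort(paste0("unknown ", block, " keys: ", paste(bad, collapse = ", ")))
    do.call(fn, args)
  }
  top <- cfg[setdiff(names(cfg), c("hydro", "decomp"))]
  bad <- setdiff(names(top), names(formals(peat_params)))
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  do.call(peat_params, c(list(hydro = take("hydro", hydro_params),
                              decomp = take("decomp", decomp_params)), top))
}
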