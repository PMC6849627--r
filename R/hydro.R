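#' Bedrock drainage loss
#'
#' Annual loss of water from the peat column into the underlying bedrock,
#' `hc` times the saturated-thickness fraction of the column, in cm of
#' water per year.  With the near-impermeable default conductivity
#' (0.1 cm/year, unweathered clay) the loss is a minor term of the water
#' balance, as intended for blanket peat over tight bedrock.
#'
#' @param wtd water-table depth, cm.
#' @param hydro [hydro_params()].
#' @param total_depth peat column depth, cm (default `Inf`, i.e. a fully
#'   saturated deep column).
#' @return water loss, cm/year (0 when `hc = 0`).
#' @export
bedrock_drainage <- function(wtd, hydro = hydro_params(), total_depth = Inf) {
  if (hydro$hc == 0) return(0)
  if (is.infinite(total_depth)) return(hydro$hc)
  if (total_depth <= 0) return(0)
  sat <- (total_depth - min(max(wtd, 0), total_depth)) / total_depth
  hydro$hc * sat
}

#' Annual water-table update
#'
#' Annual bucket balance on the storage implied by the air-filled
#' pore-space law: precipitation less evapotranspiration and bedrock
#' drainage changes the storage deficit; water in excess of the
#' field-capacity threshold is shed as runoff (high water tables lead to
#' higher runoff), and standing water is capped.  The reported annual-mean
#' water table adds a within-year dry-season drawdown,
#' `max(0, beta * PET - rho * P)` cm of water converted to depth through
#' the same storage function, which refills from the winter surplus and so
#' does not enter the annual ledger.  The ledger closes exactly:
#' `precip - aet - runoff - drainage = deficit(end) - deficit(start)`.
#'
#' @param column a `peat_column` or any list with elements `wtd` (cm, the
#'   end-of-previous-year water table) and `total_depth` (cm).
#' @param precip_mm,pet_mm annual precipitation and potential
#'   evapotranspiration, mm.
#' @param hydro [hydro_params()].
#' @return list with `wtd` (end-of-year, cm), `wtd_mean` (annual mean, cm),
#'   and the ledger terms `precip_cm`, `aet_cm`, `runoff_cm`,
#'   `drainage_cm`, `deficit_start`, `deficit_end` (all cm of water).
#' @export
update_water_table <- function(column, precip_mm, pet_mm, hydro = hydro_params()) {
  stopifnot(precip_mm >= 0, pet_mm >= 0)
  w0 <- column$wtd
  total_depth <- column$total_depth
  maps <- deficit_maps(hydro$pore_a, hydro$pore_b)
  P <- precip_mm / 10
  E <- pet_mm / 10
  d0 <- maps$fwd(w0)
  dmax <- if (is.finite(total_depth)) maps$fwd(total_depth) else Inf

  aet <- min(E, max(0, P + (dmax - d0)))          # water-limited ET
  drain <- min(bedrock_drainage(w0, hydro, total_depth),
               max(0, P - aet + (dmax - d0)))
  d1 <- d0 - (P - aet - drain)

  runoff <- 0
  d_thr <- maps$fwd(hydro$runoff_threshold)
  if (d1 < d_thr) {
    shed <- hydro$runoff_coef * (d_thr - d1)
    runoff <- runoff + shed
    d1 <- d1 + shed
  }
  d_cap <- maps$fwd(hydro$standing_water_cap)
  if (d1 < d_cap) {                               # hard cap on standing water
    runoff <- runoff + (d_cap - d1)
    d1 <- d_cap
  }
  wtd_end <- maps$inv(d1)
  if (is.finite(total_depth)) wtd_end <- min(wtd_end, total_depth)

  drawdown <- max(0, hydro$dry_season_pet_frac * E - hydro$dry_season_recharge_frac * P)
  wtd_mean <- maps$inv(d1 + drawdown)
  if (is.finite(total_depth)) wtd_mean <- min(wtd_mean, total_depth)

  list(wtd = wtd_end, wtd_mean = wtd_mean,
       precip_cm = P, aet_cm = aet, runoff_cm = runoff, drainage_cm = drain,
       deficit_start = d0, deficit_end = d1)
}
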