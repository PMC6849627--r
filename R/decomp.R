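#' Annual decomposition of the peat column
#'
#' Each cohort's litter-quality pools decay by the discrete annual fraction
#' `min(1, k * fT)` for the mass fraction above the water table (oxic) and
#' `anoxic_ratio` times that below it (anoxic), with the shared temperature
#' modifier `fT = q10^((T - tref)/10)`.  The mass fraction of a cohort
#' above the water table is its thickness fraction above.  Anoxic carbon
#' loss is partitioned into CH4 (`ch4_fraction_anoxic`) and CO2; oxic loss
#' is all CO2.  Charcoal (`inert`) never decays.
#'
#' @param column a `peat_column` (see [peat_column()]); cohorts are stored
#'   deepest (oldest) first.
#' @param wtd water-table depth used for the oxic/anoxic split, cm.
#' @param temp_c mean annual temperature, degC.
#' @param params [decomp_params()].
#' @return list with `co2` (g C m-2, from oxic loss plus the CO2 share of
#'   anoxic loss), `ch4_produced` (g C m-2), `loss_by_cohort` (g C m-2 per
#'   cohort), `oxic_loss`, `anoxic_loss`, and the updated `pools` matrix
#'   (active cohorts only).
#' @export
decompose <- function(column, wtd, temp_c, params = decomp_params()) {
  n <- column$n %||% nrow(column$pools)
  pools <- column$pools[seq_len(n), , drop = FALSE]
  if (n == 0) {
    return(list(co2 = 0, ch4_produced = 0, loss_by_cohort = numeric(0),
                oxic_loss = 0, anoxic_loss = 0, pools = pools))
  }
  fT <- params$q10^((temp_c - params$tref) / 10)
  r <- pmin(1, params$k_pools * fT)              # annual fractional loss, oxic
  th <- column$thickness[seq_len(n)]
  csum <- cumsum(th)
  top <- csum[n] - csum                          # depth of each cohort's top
  frac_ox <- pmin(1, pmax(0, (wtd - top) / th))
  frac_ox[th == 0] <- as.numeric(wtd >= top[th == 0])

  loss_ox <- pools * (frac_ox %o% r)
  loss_an <- pools * ((1 - frac_ox) %o% (r * params$anoxic_ratio))
  oxic_loss <- sum(loss_ox)
  anoxic_loss <- sum(loss_an)
  ch4 <- anoxic_loss * params$ch4_fraction_anoxic
  co2 <- oxic_loss + anoxic_loss * (1 - params$ch4_fraction_anoxic)
  list(co2 = co2, ch4_produced = ch4,
       loss_by_cohort = rowSums(loss_ox + loss_an),
       oxic_loss = oxic_loss, anoxic_loss = anoxic_loss,
       pools = pools - loss_ox - loss_an)
}

#' Methane transport, oxidation and net emission
#'
#' Produced CH4 leaves the peat by three routes: plant-mediated transport
#' through sedge and rush aerenchyma and ebullition both bypass the oxic
#' layer, while the diffusive remainder is oxidized first-order along its
#' transit of the oxic zone, `exp(-k_ox * max(wtd, 0))`.  With standing
#' water there is no oxic layer and the net flux equals production;
#' oxidized CH4-carbon is emitted as CO2 by the caller.
#'
#' @param ch4_produced CH4 production, g C m-2 yr-1 (>= 0).
#' @param wtd water-table depth, cm.
#' @param pfts named PFT fraction vector (see [pft_composition()]); only
#'   the sedge and rush shares matter here.
#' @param params [decomp_params()].
#' @return net CH4 emission, g C m-2 yr-1, in `[0, ch4_produced]`.
#' @export
methane_transport <- function(ch4_produced, wtd, pfts, params = decomp_params()) {
  if (ch4_produced < 0) abort("`ch4_produced` must be >= 0.")
  if (ch4_produced == 0) return(0)
  bypass <- min(1, params$pmt_coef * (pfts[["sedge"]] + pfts[["rush"]]) +
                  params$ebullition_fraction)
  survive <- exp(-params$ch4_oxidation_rate * max(wtd, 0))
  unname(ch4_produced * (bypass + (1 - bypass) * survive))
}
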