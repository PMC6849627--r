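#' Create an (initially empty) peat column state
#'
#' The column is an ordered stack of annual litter cohorts (stored deepest,
#' i.e. oldest, first), each with four litter-quality carbon pools plus an
#' inert charcoal pool.  Cohort thickness follows from dry mass and an
#' age-dependent bulk density, so the column compacts as it ages.  For
#' multi-millennial runs, cohorts long buried below the deepest water
#' table are pooled into coarser blocks (their fractional decay is
#' identical, so pooling conserves carbon exactly and only coarsens the
#' depth discretization of old peat).
#'
#' @param year0 calendar year before the first simulated year.
#' @param params [peat_params()].
#' @return list of class `peat_column`: `pools` (cohorts x 4 pools, g C
#'   m-2), `inert` (g C m-2), `birth_year`, `thickness` (cm),
#'   `total_depth` (cm), `n` (active cohorts), `wtd` (end-of-year water
#'   table, cm), `year`.
#' @export
peat_column <- function(year0 = 0, params = peat_params()) {
  col <- list(pools = matrix(numeric(0), 0, 4,
                             dimnames = list(NULL, names(params$decomp$k_pools))),
              inert = numeric(0), birth_year = numeric(0),
              thickness = numeric(0), total_depth = 0, n = 0L,
              wtd = 0, year = year0)
  structure(col, class = "peat_column")
}

cohort_bulk_density <- function(age, params) {
  params$bd_surface + (params$bd_deep - params$bd_surface) * (1 - exp(-age / params$bd_efold))
}

refresh_thickness <- function(column, params) {
  n <- column$n
  if (n == 0) {
    column$thickness <- numeric(0)
    column$total_depth <- 0
    return(column)
  }
  i <- seq_len(n)
  mass_dm <- (rowSums(column$pools[i, , drop = FALSE]) + column$inert[i]) /
    params$c_fraction
  bd <- cohort_bulk_density(column$year - column$birth_year[i], params)
  column$thickness[i] <- mass_dm / (bd * 1e4)   # g m-2 over g cm-3 * cm2 m-2
  column$total_depth <- sum(column$thickness[i])
  column
}

# grow cohort arrays geometrically so appending is amortized O(1)
ensure_capacity <- function(column, extra) {
  need <- column$n + extra
  cap <- nrow(column$pools)
  if (need <= cap) return(column)
  newcap <- max(need, 64L, 2L * cap)
  pools <- matrix(0, newcap, 4, dimnames = dimnames(column$pools))
  pools[seq_len(column$n), ] <- column$pools[seq_len(column$n), , drop = FALSE]
  column$pools <- pools
  pad <- function(v) c(v[seq_len(column$n)], numeric(newcap - column$n))
  column$inert <- pad(column$inert)
  column$birth_year <- pad(column$birth_year)
  column$thickness <- pad(column$thickness)
  column
}

# pool deeply buried cohorts into blocks; exact for carbon (shared decay
# factors under full anoxia), approximate only in the bulk-density age
merge_old_cohorts <- function(column, young_keep = 250L, block = 25L) {
  # rows 1..n oldest first; keep the youngest `young_keep` annual cohorts
  while (TRUE) {
    ages <- column$year - column$birth_year[seq_len(column$n)]
    young <- sum(ages < young_keep)
    old <- column$n - young
    if (old < 2L * block) break
    i <- seq_len(block)                # the `block` oldest rows
    mass <- rowSums(column$pools[i, , drop = FALSE]) + column$inert[i]
    w <- if (sum(mass) > 0) mass / sum(mass) else rep(1 / block, block)
    merged_pools <- colSums(column$pools[i, , drop = FALSE])
    merged_inert <- sum(column$inert[i])
    merged_birth <- sum(w * column$birth_year[i])
    keep <- seq.int(block + 1L, column$n)
    n_new <- length(keep) + 1L
    column$pools[seq_len(n_new), ] <- rbind(merged_pools,
                                            column$pools[keep, , drop = FALSE])
    column$inert[seq_len(n_new)] <- c(merged_inert, column$inert[keep])
    column$birth_year[seq_len(n_new)] <- c(merged_birth, column$birth_year[keep])
    column$n <- n_new
  }
  column
}

# one annual step on the mutable state list; returns a plain named vector
step_year_core <- function(state, year, temp_c, precip_mm, params, schedule) {
  col <- state$column
  if (year != col$year + 1) {
    abort(paste0("climate year ", year, " does not follow simulated year ",
                 col$year, "; the series must be contiguous."))
  }
  col$year <- year
  col <- refresh_thickness(col, params)   # compaction with one more year of age
  depth_prev <- state$depth_prev %||% col$total_depth

  pet_mm <- pet(temp_c)
  hyd <- update_water_table(col, precip_mm, pet_mm, params$hydro)
  col$wtd <- hyd$wtd

  offset <- 0
  if (!is.null(schedule) && schedule$drainage) {
    offset <- schedule$drain_depth * drain_efficiency(year, schedule)
  }
  wtd_use <- min(hyd$wtd_mean + offset, col$total_depth)

  hist <- c(state$wtd_history, wtd_use)
  pfts <- pft_composition(hist)

  dec <- decompose(col, wtd_use, temp_c, params$decomp)
  col$pools[seq_len(col$n), ] <- dec$pools
  ch4_net <- methane_transport(dec$ch4_produced, wtd_use, pfts, params$decomp)
  co2 <- dec$co2 + (dec$ch4_produced - ch4_net)   # oxidized CH4 emitted as CO2

  erosion <- 0
  if (params$erosion_rate > 0) {
    i <- seq_len(col$n)
    erosion <- params$erosion_rate * (sum(col$pools[i, ]) + sum(col$inert[i]))
    keep <- 1 - params$erosion_rate
    col$pools[i, ] <- col$pools[i, ] * keep
    col$inert[i] <- col$inert[i] * keep
  }

  mult <- 1
  charcoal <- 0
  if (!is.null(schedule) && schedule$burning) {
    burns <- burn_years(schedule)
    past <- burns[burns <= year]
    if (length(past)) {
      ys <- year - max(past)
      mult <- npp_multiplier(ys, schedule)
      if (ys == 0) {
        potential <- npp(pet_mm, pfts, 1)
        charcoal <- charcoal_input(potential * (1 - mult), schedule)
      }
    }
  }
  realized <- npp(pet_mm, pfts, mult)
  litter <- realized * as.numeric(pfts %*% litter_allocation())

  col <- ensure_capacity(col, 1L)
  col$n <- col$n + 1L
  col$pools[col$n, ] <- litter
  col$inert[col$n] <- charcoal
  col$birth_year[col$n] <- year
  col <- merge_old_cohorts(col)
  col <- refresh_thickness(col, params)

  i <- seq_len(col$n)
  stock <- sum(col$pools[i, ]) + sum(col$inert[i])
  litter_in <- realized + charcoal
  out <- c(
    year = year, temp_c = temp_c, precip_mm = precip_mm, pet_mm = pet_mm,
    mean_wtd = wtd_use, wtd_end = col$wtd, wtd_natural = hyd$wtd_mean,
    npp = realized, litter_in = litter_in, charcoal_in = charcoal,
    co2_flux = co2, ch4_produced = dec$ch4_produced, ch4_net = ch4_net,
    erosion = erosion,
    soil_c_budget = litter_in - co2 - ch4_net - erosion,
    c_stock = stock,
    peat_increment = col$total_depth - depth_prev,
    total_depth = col$total_depth,
    aet_cm = hyd$aet_cm, runoff_cm = hyd$runoff_cm,
    drainage_cm = hyd$drainage_cm, precip_cm = hyd$precip_cm,
    deficit_start = hyd$deficit_start, deficit_end = hyd$deficit_end,
    sphagnum = pfts[["sphagnum"]], sedge = pfts[["sedge"]],
    shrub = pfts[["shrub"]]
  )
  state$column <- col
  state$wtd_history <- tail(hist, 5)
  state$depth_prev <- col$total_depth
  list(state = state, out = out)
}

#' Advance the simulation by one year
#'
#' One annual timestep: potential evapotranspiration from temperature, the
#' water-table bucket update, management drainage offset, vegetation from
#' the 5-year water-table average, decomposition and methane transport,
#' then litter input as a new cohort (NPP scaled by any burn multiplier,
#' with charcoal routed to the inert pool in burn years) and recompaction.
#'
#' @param state simulation state: list with `column` ([peat_column()]) and
#'   `wtd_history` (annual mean WTDs, most recent last; may be empty).
#' @param year,temp_c,precip_mm the climate year to simulate.
#' @param params [peat_params()].
#' @param schedule a [scenario_schedule()] or `NULL` for no management.
#' @return list with the updated `state` and a one-row `output` tibble
#'   (year, mean/end WTD, NPP, CO2 flux, net CH4, peat increment, soil C
#'   budget and the water/carbon ledger terms).
#' @export
step_year <- function(state, year, temp_c, precip_mm,
                      params = peat_params(), schedule = NULL) {
  stp <- step_year_core(state, year, temp_c, precip_mm, params, schedule)
  list(state = stp$state, output = tibble::as_tibble(as.list(stp$out)))
}

#' Run the peatland simulator over a climate series
#'
#' Deterministic given its inputs; multi-millennial series run in seconds.
#' Starts from an empty column (peat initiation) unless an `init` state
#' from a previous run (spin-up) is supplied.
#'
#' @param climate tibble with `year`, `temp_c`, `precip_mm` (contiguous
#'   years), e.g. from [gen_climate()].
#' @param params [peat_params()].
#' @param schedule [scenario_schedule()], a [scenario_preset()] name, or
#'   `NULL` (unmanaged).
#' @param init optional state from a previous simulation (its `$state`),
#'   to continue a spin-up run.
#' @return object of class `peat_simulation`: list with `annual` (tibble of
#'   yearly outputs), `column` (final [peat_column()]), `state` (for
#'   continuation), `params`, `schedule`.
#' @examples
#' clim <- gen_climate(60, seed = 1, start_year = 1)
#' sim <- simulate_peatland(clim)
#' tidy(sim)
#' @export
simulate_peatland <- function(climate, params = peat_params(),
                              schedule = NULL, init = NULL) {
  check_climate(climate)
  if (is.character(schedule)) schedule <- scenario_preset(schedule)
  state <- init %||% list(column = peat_column(climate$year[1] - 1, params),
                          wtd_history = numeric(0))
  if (state$column$year != climate$year[1] - 1) {
    abort(paste0("initial state ends in year ", state$column$year,
                 " but climate starts in ", climate$year[1], "."))
  }
  n <- nrow(climate)
  rows <- NULL
  for (i in seq_len(n)) {
    stp <- step_year_core(state, climate$year[i], climate$temp_c[i],
                          climate$precip_mm[i], params, schedule)
    state <- stp$state
    if (is.null(rows)) {
      rows <- matrix(NA_real_, n, length(stp$out),
                     dimnames = list(NULL, names(stp$out)))
    }
    rows[i, ] <- stp$out
  }
  structure(list(annual = tibble::as_tibble(as.data.frame(rows)),
                 column = state$column,
                 state = state, params = params, schedule = schedule),
            class = "peat_simulation")
}

#' @export
print.peat_simulation <- function(x, ...) {
  a <- x$annual
  cat("<peat_simulation> ", nrow(a), " years (", min(a$year), "-", max(a$year),
      ")\n", sep = "")
  cat(sprintf("  final depth %.1f cm, C stock %.0f g C m-2\n",
              x$column$total_depth, tail(a$c_stock, 1)))
  cat(sprintf("  mean WTD %.1f cm | NPP %.0f | CO2 %.0f | net CH4 %.1f g C m-2 yr-1\n",
              mean(a$mean_wtd), mean(a$npp), mean(a$co2_flux), mean(a$ch4_net)))
  invisible(x)
}
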