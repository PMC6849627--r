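#' Pair reconstruction samples with simulated years
#'
#' Each dated reconstruction sample is matched to the simulated annual mean
#' water table of the year minimizing the age difference, within a
#' tolerance of one year.  Reconstruction ages are rounded to the nearest
#' calendar year first; an exact-year match is preferred, and a sample
#' falling exactly between two available model years is paired with the
#' average of the two.  Unmatched samples are dropped and counted.
#'
#' @param model_annual tibble of simulator output (columns `year`,
#'   `mean_wtd`), e.g. `sim$annual`.
#' @param recon data frame with `age_yr` (calendar year, fractional
#'   allowed) and `wtd_pred` columns.
#' @param tolerance maximum |age difference| in years (default 1).
#' @return tibble of class `wtd_pairs` with `year`, `wtd_recon`,
#'   `wtd_model`; attribute `n_dropped` counts unmatched samples.
#' @export
pair_years <- function(model_annual, recon, tolerance = 1) {
  if (nrow(model_annual) == 0 || nrow(recon) == 0) abort("both series must be nonempty.")
  if (!all(c("age_yr", "wtd_pred") %in% names(recon))) {
    abort("recon needs columns age_yr and wtd_pred.")
  }
  yrs <- model_annual$year
  rows <- purrr::pmap(list(round(recon$age_yr), recon$wtd_pred), function(a, w) {
    dd <- abs(yrs - a)
    if (min(dd) > tolerance) return(NULL)
    hit <- which(dd == min(dd))
    tibble::tibble(year = a, wtd_recon = w,
                   wtd_model = mean(model_annual$mean_wtd[hit]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no reconstruction sample pairs with a model year.")
  structure(out, class = c("wtd_pairs", class(out)),
            n_dropped = nrow(recon) - nrow(out))
}

#' Fit the proxy-model offset regression
#'
#' Ordinary least squares of the simulated water table on the reconstructed
#' water table over the paired years.  The fitted line is the offset
#' correction mapping proxy predictions onto the model scale.
#'
#' @param pairs a [pair_years()] tibble (or any data frame with
#'   `wtd_recon`, `wtd_model`; >= 3 rows).
#' @return object of class `offset_regression`: `slope`, `intercept`,
#'   `r2`, `n_pairs` and the underlying `lm` fit.
#' @export
fit_offset <- function(pairs) {
  if (nrow(pairs) < 3) abort("need at least 3 pairs.")
  if (var(pairs$wtd_recon) == 0) abort("zero variance in the reconstructed WTD.")
  fit <- lm(wtd_model ~ wtd_recon, data = pairs)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = cor(pairs$wtd_recon, pairs$wtd_model)^2,
                 n_pairs = nrow(pairs), fit = fit),
            class = "offset_regression")
}

#' @export
print.offset_regression <- function(x, ...) {
  cat(sprintf("<offset_regression> WTD_model = %.3f * WTD_recon %+.3f (r2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_pairs))
  invisible(x)
}

#' Apply an offset correction to a reconstruction
#'
#' Replaces each reconstructed value by `slope * x + intercept`; standard
#' errors, if present, are scaled by |slope|.  Refitting corrected values
#' against the model on the training pairs returns slope 1, intercept 0
#' (the usual least-squares projection property).
#'
#' @param recon data frame with `wtd_pred` (and optionally `se_boot`).
#' @param reg an [fit_offset()] result.
#' @return `recon` with `wtd_pred` corrected and the raw series kept as
#'   `wtd_raw`.
#' @export
apply_offset <- function(recon, reg) {
  recon$wtd_raw <- recon$wtd_pred
  recon$wtd_pred <- reg$slope * recon$wtd_pred + reg$intercept
  if ("se_boot" %in% names(recon)) recon$se_boot <- abs(reg$slope) * recon$se_boot
  recon
}

#' Summarize simulator output over a period
#'
#' Mean and sample standard deviation (n-1 denominator) of water table,
#' fluxes, peat increment and soil carbon budget over the years of a
#' period.  A single-year period reports sd 0 with `sd_defined = FALSE`.
#'
#' @param annual simulator annual tibble.
#' @param period length-2 numeric `c(first, last)` calendar years,
#'   inclusive.
#' @return one-row tibble of class `period_summary` with `*_mean` and
#'   `*_sd` columns for `wtd`, `co2`, `ch4`, `increment`, `budget`, plus
#'   `period_start`, `period_end`, `n_years`, `sd_defined`.
#' @export
period_summary <- function(annual, period) {
  sel <- dplyr::filter(annual, .data$year >= period[1], .data$year <= period[2])
  if (nrow(sel) == 0) abort("no simulated years inside the period.")
  one <- nrow(sel) == 1
  s <- function(v) if (one) 0 else sd(v)
  tibble::new_tibble(tibble::tibble(
    period_start = period[1], period_end = period[2], n_years = nrow(sel),
    sd_defined = !one,
    wtd_mean = mean(sel$mean_wtd), wtd_sd = s(sel$mean_wtd),
    co2_mean = mean(sel$co2_flux), co2_sd = s(sel$co2_flux),
    ch4_mean = mean(sel$ch4_net), ch4_sd = s(sel$ch4_net),
    increment_mean = mean(sel$peat_increment), increment_sd = s(sel$peat_increment),
    budget_mean = mean(sel$soil_c_budget), budget_sd = s(sel$soil_c_budget)
  ), class = "period_summary")
}

#' Difference two period summaries (scenario contrast)
#'
#' Per-variable differences of means, A minus B, for
#' managed-versus-unmanaged contrasts over a common period.
#'
#' @param summary_a,summary_b [period_summary()] rows over the same period.
#' @return one-row tibble of `*_diff` columns.
#' @export
scenario_diff <- function(summary_a, summary_b) {
  if (summary_a$period_start != summary_b$period_start ||
      summary_a$period_end != summary_b$period_end) {
    abort("period summaries cover different periods.")
  }
  tibble::tibble(
    period_start = summary_a$period_start, period_end = summary_a$period_end,
    wtd_diff = summary_a$wtd_mean - summary_b$wtd_mean,
    co2_diff = summary_a$co2_mean - summary_b$co2_mean,
    ch4_diff = summary_a$ch4_mean - summary_b$ch4_mean,
    increment_diff = summary_a$increment_mean - summary_b$increment_mean,
    budget_diff = summary_a$budget_mean - summary_b$budget_mean
  )
}
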