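#' Generate a synthetic annual climate series
#'
#' Draws independent normal interannual deviates around stationary means
#' (optionally with a linear temperature trend and AR(1) persistence), the
#' statistical structure the simulator assumes of its driver.  Defaults are
#' calibrated to a northern-England blanket-bog site: mean annual temperature
#' about 5.1 degC and annual precipitation around 2,000 mm.  Precipitation is
#' truncated at zero.
#'
#' @param n_years number of years (>= 1).
#' @param mean_temp,mean_precip long-run means (degC, mm/year).
#' @param temp_sd,precip_sd interannual standard deviations (degC, mm/year).
#' @param trend_temp linear temperature trend, degC per century (default 0).
#' @param ar1 AR(1) coefficient for both variables' anomalies (default 0,
#'   i.e. independent years; the field rarely has strong annual persistence).
#' @param start_year calendar year of the first row.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return tibble with columns `year`, `temp_c`, `precip_mm`.
#' @examples
#' gen_climate(10, seed = 1)
#' @export
gen_climate <- function(n_years,
                        mean_temp = 5.1, mean_precip = 2000,
                        temp_sd = 0.6, precip_sd = 200,
                        trend_temp = 0, ar1 = 0,
                        start_year = 1, seed = NULL) {
  if (!is.numeric(n_years) || length(n_years) != 1 || n_years < 1) {
    abort("`n_years` must be a single number >= 1.")
  }
  if (precip_sd < 0 || temp_sd < 0) abort("standard deviations must be >= 0.")
  if (abs(ar1) >= 1) abort("`ar1` must lie in (-1, 1).")
  n_years <- as.integer(n_years)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  draw <- function(sd) {
    z <- rnorm(n_years, 0, sd)
    if (ar1 != 0 && n_years > 1) {
      # stationary AR(1) with the requested marginal sd
      z <- as.numeric(stats::filter(z * sqrt(1 - ar1^2), ar1, method = "recursive",
                                    init = z[1]))
    }
    z
  }
  yrs <- seq.int(start_year, length.out = n_years)
  temp <- mean_temp + trend_temp * (yrs - yrs[1]) / 100 + draw(temp_sd)
  precip <- pmax(0, mean_precip + draw(precip_sd))
  tibble::tibble(year = yrs, temp_c = temp, precip_mm = precip)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

check_climate <- function(climate) {
  need <- c("year", "temp_c", "precip_mm")
  if (!all(need %in% names(climate))) {
    abort("climate must have columns year, temp_c, precip_mm.")
  }
  if (nrow(climate) == 0) abort("climate series is empty.")
  dy <- diff(climate$year)
  if (length(dy) && any(dy != 1)) {
    gap <- climate$year[which(dy != 1)[1]]
    abort(paste0("climate years must be contiguous; gap after year ", gap, "."))
  }
  if (any(climate$precip_mm < 0)) abort("precipitation must be >= 0.")
  invisible(climate)
}

#' Read or write a climate series as delimited text
#'
#' The on-disk format is a plain CSV with header `year,temp_c,precip_mm`.
#'
#' @param path file path.
#' @param climate tibble as returned by [gen_climate()].
#' @return `read_climate()` returns the climate tibble; `write_climate()`
#'   returns `climate` invisibly.
#' @export
read_climate <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_climate(out)
  tibble::as_tibble(out)
}

#' @rdname read_climate
#' @export
write_climate <- function(climate, path) {
  check_climate(climate)
  readr::write_csv(climate, path)
  invisible(climate)
}
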