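#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-component table of a
#' fitted object (taxon coefficients, regression terms, age-model anchors,
#' annual simulator output) and `glance()` a one-row model summary.
#'
#' @param x a `wa_tol`, `offset_regression`, `age_depth_model` or
#'   `peat_simulation` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy wa_tol
#' @export
tidy.wa_tol <- function(x, ...) x$taxa

#' @rdname tidiers
#' @method glance wa_tol
#' @export
glance.wa_tol <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$taxa), n_samples = length(x$training$wtd_obs),
                 deshrink_b0 = x$b0, deshrink_b1 = x$b1, rmse = x$rmse)
}

#' @rdname tidiers
#' @method tidy offset_regression
#' @export
tidy.offset_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "wtd_recon"),
                 estimate = c(x$intercept, x$slope),
                 std.error = summary(x$fit)$coefficients[, "Std. Error"])
}

#' @rdname tidiers
#' @method glance offset_regression
#' @export
glance.offset_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r2, n_pairs = x$n_pairs)
}

#' @rdname tidiers
#' @method tidy age_depth_model
#' @export
tidy.age_depth_model <- function(x, ...) x$anchors

#' @rdname tidiers
#' @method tidy peat_simulation
#' @export
tidy.peat_simulation <- function(x, ...) x$annual

#' @rdname tidiers
#' @method glance peat_simulation
#' @export
glance.peat_simulation <- function(x, ...) {
  a <- x$annual
  tibble::tibble(
    n_years = nrow(a), final_depth_cm = x$column$total_depth,
    final_c_stock = dplyr::last(a$c_stock),
    mean_wtd = mean(a$mean_wtd), mean_npp = mean(a$npp),
    mean_co2 = mean(a$co2_flux), mean_ch4 = mean(a$ch4_net),
    mean_budget = mean(a$soil_c_budget)
  )
}
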