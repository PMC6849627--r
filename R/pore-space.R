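#' Air-filled pore space above the water table
#'
#' The fraction of peat pore volume that is air-filled at a given distance
#' above the water table.  Saturated peat at the water table retains most of
#' its water by capillarity, so only 20% of pore space is available there;
#' availability rises exponentially with distance and is capped at 1 about a
#' metre above the water table:
#' \deqn{\phi(d) = \min\{1,\; 0.2\, e^{1.6 d^2}\}}
#' with \eqn{d} the distance above the water table in metres.  The exponent
#' only spans the (0.2, 1) range for distances measured in metres; any other
#' unit makes the curve degenerate within centimetres, so metres are used
#' throughout.
#'
#' @param distance_m distance above the water table, metres (>= 0).
#' @param pore_a,pore_b constants of the exponential law (defaults 0.2, 1.6).
#' @return available (air-fillable) pore-space fraction in (0, 1].
#' @examples
#' available_pore_space(0)    # 0.2 at the water table
#' available_pore_space(1)    # ~0.99 one metre up
#' @export
available_pore_space <- function(distance_m, pore_a = 0.2, pore_b = 1.6) {
  if (any(!is.finite(distance_m)) || any(distance_m < 0)) {
    abort("`distance_m` must be finite and >= 0 (distance above the water table).")
  }
  pmin(1, pore_a * exp(pore_b * distance_m^2))
}

# Depth (cm) at which the pore-space law reaches its cap of 1.
pore_cap_depth_cm <- function(pore_a = 0.2, pore_b = 1.6) {
  100 * sqrt(log(1 / pore_a) / pore_b)
}

#' Water-storage deficit implied by a water-table depth
#'
#' Integrates the air-filled pore-space fraction from the surface down to the
#' water table, giving the depth of water (cm) needed to raise the water
#' table to the surface.  The closed form uses the imaginary error function;
#' above the surface (negative depths, standing water) storage is one-to-one.
#'
#' @param wtd_cm water-table depth, cm (positive down; negative = standing
#'   water above the surface).
#' @param pore_a,pore_b pore-space constants.
#' @return water deficit, cm of water (negative for standing water).
#' @seealso [wtd_from_deficit()] for the inverse.
#' @export
water_deficit <- function(wtd_cm, pore_a = 0.2, pore_b = 1.6) {
  stopifnot(is.numeric(wtd_cm), all(is.finite(wtd_cm)))
  b_cm <- pore_b / 100^2           # exponent constant per cm^2
  cap <- pore_cap_depth_cm(pore_a, pore_b)
  # antiderivative of pore_a * exp(b_cm h^2) is pore_a * sqrt(pi)/(2 sqrt(b)) erfi(sqrt(b) h)
  erfi_int <- function(h) pore_a * sqrt(pi) / (2 * sqrt(b_cm)) * pracma::erfi(sqrt(b_cm) * h)
  deficit_at_cap <- erfi_int(cap)
  out <- numeric(length(wtd_cm))
  below <- wtd_cm > cap
  mid <- wtd_cm >= 0 & !below
  out[mid] <- erfi_int(wtd_cm[mid])
  out[below] <- deficit_at_cap + (wtd_cm[below] - cap)  # fully air-filled beyond cap
  out[wtd_cm < 0] <- wtd_cm[wtd_cm < 0]                 # standing water: 1 cm water per cm
  out
}

#' Water-table depth implied by a storage deficit
#'
#' Inverse of [water_deficit()]: given a deficit (cm of water missing
#' relative to a water table at the surface), returns the water-table depth.
#' Strictly increasing, so inversion is by bracketed root finding on the
#' positive branch and exact on the standing-water branch.
#'
#' @param deficit_cm water deficit, cm of water.
#' @inheritParams water_deficit
#' @return water-table depth, cm.
#' @export
wtd_from_deficit <- function(deficit_cm, pore_a = 0.2, pore_b = 1.6) {
  stopifnot(is.numeric(deficit_cm), all(is.finite(deficit_cm)))
  cap <- pore_cap_depth_cm(pore_a, pore_b)
  d_cap <- water_deficit(cap, pore_a, pore_b)
  vapply(deficit_cm, function(d) {
    if (d <= 0) return(d)
    if (d >= d_cap) return(cap + (d - d_cap))
    uniroot(function(w) water_deficit(w, pore_a, pore_b) - d,
            lower = 0, upper = cap, tol = 1e-10)$root
  }, numeric(1))
}

# Cached fast inverse of the storage function for the simulation loop:
# a dense monotone interpolation table, keyed by the pore constants.
.deficit_cache <- new.env(parent = emptyenv())

deficit_maps <- function(pore_a, pore_b) {
  key <- paste(pore_a, pore_b)
  hit <- .deficit_cache[[key]]
  if (!is.null(hit)) return(hit)
  cap <- pore_cap_depth_cm(pore_a, pore_b)
  w <- seq(0, cap, length.out = 16384)
  d <- water_deficit(w, pore_a, pore_b)
  d_cap <- d[length(d)]
  maps <- list(
    fwd = function(wtd) {
      if (wtd <= 0) return(wtd)
      if (wtd >= cap) return(d_cap + (wtd - cap))
      approx(w, d, xout = wtd)$y
    },
    inv = function(deficit) {
      if (deficit <= 0) return(deficit)
      if (deficit >= d_cap) return(cap + (deficit - d_cap))
      approx(d, w, xout = deficit)$y
    }
  )
  .deficit_cache[[key]] <- maps
  maps
}
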