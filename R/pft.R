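pft_names <- c("shrub", "sedge", "rush", "grass", "herb", "sphagnum", "moss")

# Community composition at fixed water-table knots (fractions sum to 1 per
# row).  Shrub share rises and Sphagnum+sedge share falls monotonically as
# the 5-year mean water table deepens; linear interpolation between knots
# preserves both the unit sum and the monotonicity.
pft_lookup_table <- function() {
  tab <- rbind(
    # wtd   shrub sedge rush grass herb sphag moss
    c(-10,  0.00, 0.23, 0.25, 0.00, 0.04, 0.45, 0.03),
    c(  0,  0.05, 0.25, 0.12, 0.03, 0.04, 0.40, 0.11),
    c(  5,  0.15, 0.22, 0.08, 0.07, 0.06, 0.28, 0.14),
    c( 10,  0.28, 0.18, 0.05, 0.10, 0.07, 0.20, 0.12),
    c( 20,  0.45, 0.12, 0.02, 0.12, 0.07, 0.10, 0.12),
    c( 40,  0.58, 0.05, 0.01, 0.15, 0.09, 0.02, 0.10)
  )
  colnames(tab) <- c("wtd", pft_names)
  tab
}

#' Plant-functional-type composition from recent water tables
#'
#' Vegetation responds to the moving average of the last five annual mean
#' water-table depths (padded by repetition when fewer are available), so a
#' single anomalous wet or dry year does not flip the community: vegetation
#' is more stable and resilient than the year-to-year water table.  The
#' composition is a piecewise-linear interpolation of a fixed lookup table
#' over seven functional types (shrub, sedge, rush, grass, herb, Sphagnum,
#' other moss); wetter 5-year means give larger Sphagnum+sedge shares and
#' smaller shrub shares.
#'
#' @param wtd_history numeric vector of annual mean water-table depths (cm),
#'   most recent last; at least one value.  Only the last five are used.
#' @return named numeric vector of 7 fractions summing to 1.
#' @export
pft_composition <- function(wtd_history) {
  if (length(wtd_history) < 1 || any(!is.finite(wtd_history))) {
    abort("`wtd_history` needs at least one finite water-table depth.")
  }
  h <- tail(wtd_history, 5)
  h <- c(rep(h[1], 5 - length(h)), h)   # pad by repetition at the start
  w <- mean(h)
  tab <- pft_lookup_table()
  w <- min(max(w, tab[1, "wtd"]), tab[nrow(tab), "wtd"])
  out <- vapply(pft_names, function(p) {
    approx(tab[, "wtd"], tab[, p], xout = w)$y
  }, numeric(1))
  out / sum(out)
}

# Litter-quality allocation (fast, mid, slow, humic) by functional type;
# Sphagnum litter is the most recalcitrant, herbs the most labile.
litter_allocation <- function() {
  alloc <- rbind(
    shrub    = c(0.25, 0.30, 0.30, 0.15),
    sedge    = c(0.40, 0.35, 0.20, 0.05),
    rush     = c(0.40, 0.35, 0.20, 0.05),
    grass    = c(0.50, 0.30, 0.15, 0.05),
    herb     = c(0.55, 0.30, 0.10, 0.05),
    sphagnum = c(0.15, 0.25, 0.40, 0.20),
    moss     = c(0.20, 0.30, 0.35, 0.15)
  )
  colnames(alloc) <- c("fast", "mid", "slow", "humic")
  alloc
}
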