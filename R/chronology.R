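#' Detect the three SCP stratigraphic markers
#'
#' Spheroidal carbonaceous particles give three age-equivalent features in
#' recent peat: the start of the record (~1850, onset of high-temperature
#' combustion), the rapid increase (~1950, post-war power generation) and
#' the concentration peak (~1978, before clean-fuel technologies).  The
#' start is the deepest depth above which concentration first exceeds the
#' detection threshold, the increase is where the rapid rise begins — the
#' deeper endpoint of the segment with the largest upward (toward the
#' surface) first difference between the peak and the start — and the peak
#' is the depth of maximum concentration (ties resolved to the shallowest
#' depth).
#'
#' @param profile data frame with `depth_cm` (strictly increasing downward)
#'   and `conc_per_g`.
#' @param threshold detection noise floor, particles/g (default 0: any
#'   nonzero concentration counts as presence).
#' @return named numeric vector `c(start, increase, peak)`, cm.
#' @export
detect_scp_markers <- function(profile, threshold = 0) {
  d <- profile$depth_cm; conc <- profile$conc_per_g
  if (is.null(d) || is.null(conc)) abort("profile needs depth_cm and conc_per_g.")
  if (length(d) < 5) abort("need at least 5 points spanning the zero-to-peak structure.")
  if (any(diff(d) <= 0)) abort("depths must be strictly increasing.")
  if (any(conc < 0)) abort("concentrations must be >= 0.")
  above <- conc > threshold
  if (!any(above)) abort("no concentrations above the detection threshold.")
  if (above[length(above)]) {
    abort("no zero tail: the record must start (concentration at threshold) within the profile.")
  }
  # the boundary: the deepest depth above which concentrations exceed the
  # threshold (concentration at the start depth itself is at the threshold)
  start <- d[max(which(above)) + 1]
  peak_i <- which.max(conc)          # which.max takes the first (shallowest) tie
  if (peak_i == 1 || peak_i == length(conc)) {
    if (peak_i == length(conc)) abort("no interior peak in the profile.")
  }
  peak <- d[peak_i]
  # steepest upward rise: for segment j between depths d[j] (shallow) and
  # d[j+1] (deep), the upward gain is conc[j] - conc[j+1]; the marker is the
  # deeper endpoint of the steepest such segment between peak and start
  gain <- (head(conc, -1) - tail(conc, -1)) / diff(d)
  cand <- which(head(d, -1) >= peak & tail(d, -1) <= start)
  if (!length(cand) || max(gain[cand]) <= 0) {
    abort("profile has no rise between peak and start.")
  }
  increase <- d[cand[which.max(gain[cand])] + 1]
  if (!(peak < increase && increase < start)) {
    abort("marker ordering peak < increase < start could not be established.")
  }
  c(start = start, increase = increase, peak = peak)
}

#' Build an SCP age-depth model
#'
#' Piecewise-linear age-depth model anchored at the core top (sampling
#' year) and the three SCP markers (peak, rapid increase, start of
#' record); depths below the start of the record are extrapolated at the
#' deepest segment's accumulation rate.
#'
#' @param markers named vector from [detect_scp_markers()], or any numeric
#'   vector `c(start, increase, peak)` in cm.
#' @param top_year calendar year of core sampling (default 2011).
#' @param marker_years calendar years of the three markers (default
#'   1850, 1950, 1978).
#' @return object of class `age_depth_model` with an `anchors` tibble
#'   (`depth_cm`, `year`), years strictly decreasing with depth.
#' @export
build_age_model <- function(markers, top_year = 2011,
                            marker_years = c(start = 1850, increase = 1950, peak = 1978)) {
  m <- as.numeric(markers[c("start", "increase", "peak")])
  if (any(is.na(m))) m <- as.numeric(markers)[1:3]
  anchors <- tibble::tibble(
    depth_cm = c(0, m[3], m[2], m[1]),
    year = c(top_year, marker_years[["peak"]], marker_years[["increase"]],
             marker_years[["start"]])
  )
  if (any(diff(anchors$depth_cm) <= 0)) abort("anchor depths must increase: need peak < increase < start.")
  if (any(diff(anchors$year) >= 0)) abort("anchor years must strictly decrease with depth.")
  structure(list(anchors = anchors), class = "age_depth_model")
}

#' Age at depth (and inverse)
#'
#' Linear interpolation between the anchors; below the deepest anchor,
#' linear extrapolation at the deepest segment's accumulation rate.
#' Fractional years are returned; round when pairing with annual model
#' output.
#'
#' @param model an [build_age_model()] result.
#' @param depth_cm depth(s), cm (>= 0).
#' @return calendar year(s), monotone nonincreasing in depth.
#' @export
age_at_depth <- function(model, depth_cm) {
  if (any(depth_cm < 0)) abort("`depth_cm` must be >= 0.")
  a <- model$anchors
  n <- nrow(a)
  slope_deep <- (a$year[n] - a$year[n - 1]) / (a$depth_cm[n] - a$depth_cm[n - 1])
  out <- approx(a$depth_cm, a$year, xout = depth_cm, rule = 1)$y
  deep <- depth_cm > a$depth_cm[n]
  out[deep] <- a$year[n] + slope_deep * (depth_cm[deep] - a$depth_cm[n])
  out
}

#' @rdname age_at_depth
#' @param year calendar year(s) no later than the core-top year.
#' @export
depth_at_age <- function(model, year) {
  a <- model$anchors
  n <- nrow(a)
  if (any(year > a$year[1])) abort("year is after core sampling.")
  slope_deep <- (a$year[n] - a$year[n - 1]) / (a$depth_cm[n] - a$depth_cm[n - 1])
  out <- approx(a$year, a$depth_cm, xout = year, rule = 1)$y
  old <- year < a$year[n]
  out[old] <- a$depth_cm[n] + (year[old] - a$year[n]) / slope_deep
  out
}

#' @export
print.age_depth_model <- function(x, ...) {
  cat("<age_depth_model> anchors:\n")
  print(as.data.frame(x$anchors), row.names = FALSE)
  invisible(x)
}

#' Export or import an age-depth model as anchor pairs
#'
#' @param model an [build_age_model()] result.
#' @param path CSV path (`depth_cm,year`).
#' @return the model (invisibly for the writer).
#' @export
write_age_model <- function(model, path) {
  readr::write_csv(model$anchors, path)
  invisible(model)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  anchors <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("depth_cm", "year") %in% names(anchors))) {
    abort("age model file needs columns depth_cm, year.")
  }
  structure(list(anchors = tibble::as_tibble(anchors)), class = "age_depth_model")
}
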