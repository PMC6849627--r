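#' Default synthetic testate-amoeba taxon set
#'
#' Eight synthetic taxa with Gaussian (unimodal) responses along the
#' water-table gradient, spanning optima from standing water (-2 cm) to dry
#' hummock conditions (35 cm) with tolerances of 4-10 cm, bracketing the
#' wet and dry indicator taxa of north-European bogs.
#'
#' @return tibble with columns `taxon`, `optimum` (cm WTD), `tolerance`
#'   (cm, > 0) and `max_abundance` (peak relative abundance, 0-1).
#' @export
default_taxa <- function() {
  tibble::tribble(
    ~taxon,        ~optimum, ~tolerance, ~max_abundance,
    "Aquatica_a",      -2,        4,          0.9,
    "Pools_b",          2,        6,          1.0,
    "Lawn_c",           6,        5,          1.0,
    "Lawn_d",          10,        7,          0.9,
    "Hummock_e",       15,        6,          1.0,
    "Hummock_f",       20,        8,          0.8,
    "Dry_g",           27,        9,          0.9,
    "Xeric_h",         35,       10,          0.8
  )
}

check_taxa <- function(taxa) {
  need <- c("taxon", "optimum", "tolerance", "max_abundance")
  if (!all(need %in% names(taxa))) {
    abort("taxa must have columns taxon, optimum, tolerance, max_abundance.")
  }
  if (any(taxa$tolerance <= 0)) abort("taxon tolerances must be > 0.")
  if (any(taxa$max_abundance <= 0 | taxa$max_abundance > 1)) {
    abort("max_abundance must lie in (0, 1].")
  }
  invisible(taxa)
}

# expected (unnormalized) abundance of each taxon at water-table depth x
response_at <- function(taxa, wtd) {
  vapply(seq_len(nrow(taxa)), function(k) {
    taxa$max_abundance[k] *
      exp(-(wtd - taxa$optimum[k])^2 / (2 * taxa$tolerance[k]^2))
  }, numeric(1))
}

#' Generate a synthetic transfer-function training set
#'
#' Samples water-table depths across a gradient and draws taxon counts
#' multinomially from Gaussian response curves evaluated at each sample's
#' WTD — the data-generating process assumed by weighted-averaging
#' calibration.
#'
#' @param taxa taxon response table, see [default_taxa()].
#' @param n_samples number of training samples (>= 3).
#' @param wtd_range numeric length-2 interval (cm) over which sample WTDs
#'   are spread (evenly, with small jitter).
#' @param count_total tests counted per sample (default 150, a typical
#'   testate-amoeba count).
#' @param seed integer seed.
#' @return tibble with `sample_id`, `wtd_obs` and one count column per taxon.
#' @export
gen_training_set <- function(taxa = default_taxa(), n_samples = 40,
                             wtd_range = c(-5, 40), count_total = 150,
                             seed = NULL) {
  check_taxa(taxa)
  if (nrow(taxa) < 1) abort("need at least 1 taxon.")
  if (n_samples < 3) abort("need at least 3 training samples.")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  wtd <- seq(wtd_range[1], wtd_range[2], length.out = n_samples)
  if (n_samples > 3) wtd <- wtd + rnorm(n_samples, 0, diff(wtd_range) / (8 * n_samples))
  counts <- draw_assemblages(taxa, wtd, count_total)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n_samples)), wtd_obs = wtd),
    counts
  )
}

draw_assemblages <- function(taxa, wtd, count_total) {
  mat <- vapply(wtd, function(x) {
    p <- response_at(taxa, x)
    if (sum(p) <= 0) {
      abort("a sample falls outside every taxon's response; widen tolerances or narrow wtd_range.")
    }
    as.numeric(rmultinom(1, count_total, p))
  }, numeric(nrow(taxa)))
  mat <- matrix(mat, nrow = nrow(taxa), dimnames = list(taxa$taxon, NULL))
  tibble::as_tibble(t(mat))
}

#' Generate a synthetic fossil core with known water-table history
#'
#' Draws an assemblage for each depth from the taxon responses evaluated at
#' the prescribed true WTD, retaining the truth for parameter-recovery
#' checks.
#'
#' @param true_wtd_by_depth tibble/data frame with columns `depth_cm`
#'   (strictly increasing) and `wtd_true` (cm).
#' @inheritParams gen_training_set
#' @return tibble with `depth_cm`, `wtd_true` and one count column per taxon.
#' @export
gen_fossil_core <- function(true_wtd_by_depth, taxa = default_taxa(),
                            count_total = 150, seed = NULL) {
  check_taxa(taxa)
  if (nrow(true_wtd_by_depth) == 0) abort("empty depth list.")
  d <- true_wtd_by_depth$depth_cm
  if (is.null(d) || is.null(true_wtd_by_depth$wtd_true)) {
    abort("true_wtd_by_depth needs columns depth_cm and wtd_true.")
  }
  if (any(diff(d) <= 0)) abort("depths must be strictly increasing.")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  counts <- draw_assemblages(taxa, true_wtd_by_depth$wtd_true, count_total)
  dplyr::bind_cols(
    tibble::tibble(depth_cm = d, wtd_true = true_wtd_by_depth$wtd_true),
    counts
  )
}

#' Generate a synthetic spheroidal-carbonaceous-particle profile
#'
#' Builds a concentration-by-depth curve with the three stratigraphic
#' features used as age markers in recent peat: a start of record (deepest
#' nonzero concentrations), a rapid increase, and a concentration peak,
#' declining again toward the surface.  Optional additive noise is truncated
#' so concentrations stay nonnegative.
#'
#' @param depths depth grid, cm, strictly increasing downward.
#' @param start_depth,increase_depth,peak_depth feature depths (cm) with
#'   `peak_depth < increase_depth < start_depth`.
#' @param peak_conc concentration at the peak (particles per g dry peat).
#' @param surface_conc concentration at 0 cm (decline above the peak).
#' @param noise_sd additive noise sd (particles/g).
#' @param seed integer seed.
#' @return tibble with `depth_cm`, `conc_per_g`.
#' @export
gen_scp_profile <- function(depths = seq(0, 20, by = 0.5),
                            start_depth = 14, increase_depth = 9,
                            peak_depth = 4.5, peak_conc = 10000,
                            surface_conc = 2000, noise_sd = 0, seed = NULL) {
  if (!(peak_depth < increase_depth && increase_depth < start_depth)) {
    abort("need peak_depth < increase_depth < start_depth (depth increases downward).")
  }
  if (any(diff(depths) <= 0)) abort("depths must be strictly increasing.")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  base_conc <- 0.04 * peak_conc   # slow pre-1950 ramp between start and increase
  conc <- vapply(depths, function(d) {
    if (d >= start_depth) 0
    else if (d > increase_depth) {
      base_conc * (start_depth - d) / (start_depth - increase_depth)
    } else if (d > peak_depth) {
      # rapid rise from the increase point, steepest at its onset and
      # decelerating toward the peak
      f <- (increase_depth - d) / (increase_depth - peak_depth)
      base_conc + (peak_conc - base_conc) * sqrt(f)
    } else {
      peak_conc - (peak_conc - surface_conc) * (peak_depth - d) / peak_depth
    }
  }, numeric(1))
  if (noise_sd > 0) conc <- pmax(0, conc + rnorm(length(conc), 0, noise_sd))
  tibble::tibble(depth_cm = depths, conc_per_g = conc)
}

#' Read or write assemblage count tables and SCP profiles as CSV
#'
#' @param x tibble to write.
#' @param path file path.
#' @return the tibble (invisibly for writers).
#' @export
read_counts <- function(path) tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))

#' @rdname read_counts
#' @export
write_counts <- function(x, path) { readr::write_csv(x, path); invisible(x) }

#' @rdname read_counts
#' @export
read_scp <- function(path) {
  out <- tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))
  if (!all(c("depth_cm", "conc_per_g") %in% names(out))) {
    abort("SCP file needs columns depth_cm, conc_per_g.")
  }
  out
}

#' @rdname read_counts
#' @export
write_scp <- function(x, path) { readr::write_csv(x, path); invisible(x) }
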