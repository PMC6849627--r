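#' Fit a weighted-averaging tolerance-downweighted transfer function
#'
#' Weighted averaging (WA) with tolerance downweighting and inverse
#' deshrinking, the standard calibration for reconstructing water-table
#' depth from testate-amoeba assemblages.  Abundances are converted to
#' within-sample proportions first (so counts and percentages fit
#' identically).  Taxon optima are abundance-weighted means of the observed
#' WTD, tolerances are abundance-weighted standard deviations (floored at
#' 1% of the training WTD range, so taxa seen in a single sample do not
#' collapse the weights), initial estimates are tolerance-downweighted
#' weighted averages, and inverse deshrinking regresses the observed values
#' on those initial estimates.
#'
#' @param counts data frame of taxon counts or percentages, one row per
#'   sample, one column per taxon (non-taxon id columns such as
#'   `sample_id`/`wtd_obs`/`depth_cm` are dropped automatically if present).
#' @param wtd_obs observed water-table depth per sample, cm.  If `counts`
#'   has a `wtd_obs` column it is used when this argument is missing.
#' @return object of class `wa_tol`: taxon table (`optimum`, `tolerance`),
#'   deshrinking coefficients `b0`, `b1`, apparent `rmse`, and the training
#'   data.
#' @examples
#' tr <- gen_training_set(seed = 1)
#' tf <- fit_wa_tol(tr)
#' glance(tf)
#' @export
fit_wa_tol <- function(counts, wtd_obs = NULL) {
  if (is.null(wtd_obs)) {
    if (!"wtd_obs" %in% names(counts)) abort("supply `wtd_obs` or include a wtd_obs column.")
    wtd_obs <- counts$wtd_obs
  }
  y <- taxon_matrix(counts)
  if (nrow(y) < 3) abort("need at least 3 training samples.")
  if (length(wtd_obs) != nrow(y)) abort("`wtd_obs` length must match rows of `counts`.")
  present <- colSums(y) > 0
  if (!all(present)) {
    warn(paste0("dropping taxa absent from all samples: ",
                paste(colnames(y)[!present], collapse = ", ")))
    y <- y[, present, drop = FALSE]
  }
  if (ncol(y) < 1) abort("no taxa with positive abundance.")
  p <- y / rowSums(y)

  colsum <- colSums(p)
  u <- colSums(p * wtd_obs) / colsum
  t2 <- colSums(p * outer(wtd_obs, u, "-")^2) / colsum
  tol <- sqrt(t2)
  floor_tol <- 0.01 * diff(range(wtd_obs))
  low <- tol < floor_tol
  if (any(low)) {
    warn(paste0("tolerance floored at ", signif(floor_tol, 3), " cm for: ",
                paste(colnames(y)[low], collapse = ", ")))
    tol[low] <- floor_tol
  }

  init <- wa_tol_estimate(p, u, tol)
  if (var(init) == 0) {
    # constant initial estimates (e.g. a single taxon everywhere): the
    # deshrinking degenerates to recentring on the observed mean
    b1 <- 1
    b0 <- mean(wtd_obs) - init[1]
  } else {
    ds <- lm(wtd_obs ~ init)        # inverse deshrinking
    b0 <- unname(coef(ds)[1]); b1 <- unname(coef(ds)[2])
  }
  if (!is.finite(b1) || b1 == 0) abort("degenerate deshrinking regression.")
  pred <- b0 + b1 * init
  structure(list(
    taxa = tibble::tibble(taxon = colnames(y), optimum = unname(u),
                          tolerance = unname(tol), n_occ = unname(colSums(y > 0))),
    b0 = b0, b1 = b1,
    rmse = sqrt(mean((pred - wtd_obs)^2)),
    training = list(counts = y, wtd_obs = wtd_obs)
  ), class = "wa_tol")
}

# tolerance-downweighted weighted average, before deshrinking
wa_tol_estimate <- function(p, u, tol) {
  w <- 1 / tol^2
  num <- p %*% (u * w)
  den <- p %*% w
  as.numeric(num / den)
}

taxon_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (any(counts < 0)) abort("abundances must be >= 0.")
    return(counts)
  }
  id_cols <- intersect(names(counts),
                       c("sample_id", "depth_cm", "wtd_obs", "wtd_true", "age_yr"))
  m <- as.matrix(counts[setdiff(names(counts), id_cols)])
  if (!is.numeric(m)) abort("taxon columns must be numeric.")
  if (any(m < 0)) abort("abundances must be >= 0.")
  m
}

#' Predict water-table depth from assemblages
#'
#' Applies a fitted WA-Tol transfer function to new (typically fossil)
#' assemblages.  Predictions are invariant to rescaling counts to
#' percentages.  Samples sharing no taxon with the training set (or with
#' zero total count) are an error, so silent nonsense is impossible.
#'
#' @param object a [fit_wa_tol()] model.
#' @param newdata data frame of counts/percentages (id columns ignored).
#' @param ... unused.
#' @return numeric vector of deshrunk WTD predictions, cm.
#' @export
predict.wa_tol <- function(object, newdata, ...) {
  y <- taxon_matrix(newdata)
  if (all(rowSums(y) == 0)) abort("all samples have zero total count.")
  shared <- intersect(colnames(y), object$taxa$taxon)
  if (length(shared) == 0) abort("no taxa shared with the training set.")
  ys <- y[, shared, drop = FALSE]
  tot <- rowSums(ys)
  if (any(tot == 0)) {
    zero_all <- rowSums(y) == 0
    msg <- if (any(zero_all & tot == 0)) "some samples have zero total count."
           else "some samples contain no taxon shared with the training set."
    abort(msg)
  }
  p <- ys / tot
  i <- match(shared, object$taxa$taxon)
  init <- wa_tol_estimate(p, object$taxa$optimum[i], object$taxa$tolerance[i])
  object$b0 + object$b1 * init
}

#' @export
print.wa_tol <- function(x, ...) {
  cat("<wa_tol> ", nrow(x$taxa), " taxa, ", length(x$training$wtd_obs),
      " training samples\n", sep = "")
  cat(sprintf("  deshrinking: x = %.3f + %.3f * WA; apparent RMSE %.2f cm\n",
              x$b0, x$b1, x$rmse))
  invisible(x)
}

#' Reconstruct a fossil core with bootstrap errors
#'
#' Predicts WTD for each fossil sample and attaches sample-specific
#' standard errors from bootstrap resampling of the training set: the
#' training samples are resampled with replacement `n_boot` times, the
#' transfer function is refitted each cycle, and the per-sample SE combines
#' the spread of the fossil predictions across cycles with the mean squared
#' out-of-bag prediction error of the training data,
#' \eqn{SE_i = \sqrt{v_{boot,i} + s_1^2}}.
#'
#' @param tf a [fit_wa_tol()] model.
#' @param fossil data frame of fossil assemblages (a `depth_cm` column, if
#'   present, is carried through).
#' @param n_boot bootstrap cycles (default 1000).
#' @param seed integer seed; fixed seed gives identical SEs across runs.
#' @return tibble of class `wtd_reconstruction`: `depth_cm` (if supplied),
#'   `wtd_pred`, `se_boot`, plus `z` once [standardize_recon()] is applied.
#' @export
reconstruct_wtd <- function(tf, fossil, n_boot = 1000, seed = NULL) {
  if (n_boot < 2) abort("`n_boot` must be >= 2.")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  pred <- predict(tf, fossil)
  y <- tf$training$counts
  x <- tf$training$wtd_obs
  n <- nrow(y)
  boot_pred <- matrix(NA_real_, n_boot, length(pred))
  oob_err <- matrix(NA_real_, n_boot, n)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tf_b <- try(fit_wa_tol_quiet(y[idx, , drop = FALSE], x[idx]), silent = TRUE)
    if (inherits(tf_b, "try-error")) next
    boot_pred[b, ] <- try_predict(tf_b, y, seq_along(pred), fossil)
    oob <- setdiff(seq_len(n), idx)
    if (length(oob)) {
      p_oob <- try(predict(tf_b, as.data.frame(y[oob, , drop = FALSE])), silent = TRUE)
      if (!inherits(p_oob, "try-error")) oob_err[b, oob] <- p_oob - x[oob]
    }
  }
  v_boot <- apply(boot_pred, 2, var, na.rm = TRUE)
  s1_sq <- mean(oob_err^2, na.rm = TRUE)
  out <- tibble::tibble(wtd_pred = pred, se_boot = sqrt(v_boot + s1_sq))
  if ("depth_cm" %in% names(fossil)) {
    out <- dplyr::bind_cols(tibble::tibble(depth_cm = fossil$depth_cm), out)
  }
  structure(out, class = c("wtd_reconstruction", class(out)),
            s1 = sqrt(s1_sq), n_boot = n_boot)
}

fit_wa_tol_quiet <- function(counts, wtd_obs) {
  suppressWarnings(fit_wa_tol(as.data.frame(counts), wtd_obs))
}

try_predict <- function(tf_b, y, idx, fossil) {
  p <- try(predict(tf_b, fossil), silent = TRUE)
  if (inherits(p, "try-error")) rep(NA_real_, length(idx)) else p
}

#' Standardize a reconstruction to z-scores
#'
#' Centers and scales the predicted WTD series so reconstructions from
#' different transfer functions (whose absolute optima differ) can be
#' compared on a common scale: \eqn{z_i = (x_i - \bar x)/s}.
#'
#' @param recon a [reconstruct_wtd()] result, or any data frame with a
#'   `wtd_pred` column and at least two rows.
#' @return the input with a `z` column; its mean is 0 and sd 1.
#' @export
standardize_recon <- function(recon) {
  x <- recon$wtd_pred
  if (length(x) < 2) abort("need at least 2 samples to standardize.")
  s <- sd(x)
  if (s == 0) abort("zero variance: cannot standardize a constant series.")
  recon$z <- (x - mean(x)) / s
  recon
}

#' Compare two transfer functions on one fossil core
#'
#' Predicts the core with both models and regresses the first model's
#' predictions on the second's (ordinary least squares), the standard way
#' of quantifying systematic offsets between regional calibrations.
#'
#' @param tf_a,tf_b fitted [fit_wa_tol()] models.
#' @param fossil fossil assemblage data frame (>= 3 samples).
#' @return list with `predictions` (tibble `pred_a`, `pred_b` and
#'   `depth_cm` if present), `slope`, `intercept`, `r2`, `n`.
#' @export
compare_transfer_functions <- function(tf_a, tf_b, fossil) {
  pa <- predict(tf_a, fossil)
  pb <- predict(tf_b, fossil)
  if (length(pa) < 3) abort("need at least 3 common samples.")
  fit <- lm(pa ~ pb)
  preds <- tibble::tibble(pred_a = pa, pred_b = pb)
  if ("depth_cm" %in% names(fossil)) preds$depth_cm <- fossil$depth_cm
  list(predictions = preds,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = cor(pa, pb)^2, n = length(pa))
}
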