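#' Heart-to-mediastinum ratio over a time window
#'
#' Duration-weighted mean of the heart curve over the window divided by the
#' same for the mediastinal curve. The conventional windows are 10-15 min
#' (early HMR) and 190-195 min (delayed HMR).
#'
#' @param htac,mtac heart and mediastinal [tac()]s on a common schedule
#' @param window_min `c(t1, t2)` window in minutes (frames selected by
#'   midpoint)
#' @return unitless ratio
#' @examples
#' sched <- standard_schedule("scan1")
#' h <- tac(sched, rep(2, nrow(sched)), "heart")
#' m <- tac(sched, rep(1, nrow(sched)), "mediastinum")
#' hmr(h, m, c(10, 15))  # 2
#' @export
hmr <- function(htac, mtac, window_min = c(10, 15)) {
  stopifnot(inherits(htac, "tac"), inherits(mtac, "tac"))
  hv <- window_mean(htac, window_min)
  mv <- window_mean(mtac, window_min)
  if (mv <= 0) stop("mediastinal window mean must be positive")
  hv / mv
}

window_mean <- function(x, window_min) {
  tm <- frame_mid_min(x$schedule)
  sel <- tm >= window_min[1] & tm <= window_min[2]
  if (!any(sel)) {
    stop("no frames with midpoints inside [", window_min[1], ", ",
         window_min[2], "] min")
  }
  w <- x$schedule$duration_s[sel]
  sum(x$values[sel] * w) / sum(w)
}

#' Myocardial washout rate
#'
#' `WR = ((He - Me) - (Hd - Md)) / (He - Me)` where `He, Me` are the
#' duration-weighted heart and mediastinal window means in the early window
#' and `Hd, Md` in the delayed window, all decay-corrected to a common
#' reference time. Curves decay-corrected to injection already share a
#' reference (any common re-reference multiplies numerator terms and the
#' denominator by the same factor, leaving WR unchanged); curves still
#' carrying physical decay are corrected internally. WR is 1 for complete
#' washout, 0 for pure retention, and may be negative when uptake continues;
#' it is flagged undefined (NA) when the early tissue signal `He - Me` is
#' not positive.
#'
#' @param htac,mtac heart and mediastinal [tac()]s spanning both windows
#' @param early_min,delayed_min the two windows in minutes
#' @param half_life_min half-life used if decay correction is still needed
#' @return unitless washout fraction, or `NA` when undefined
#' @export
washout_rate <- function(htac, mtac, early_min = c(10, 15),
                         delayed_min = c(190, 195),
                         half_life_min = I123_HALF_LIFE_MIN) {
  stopifnot(inherits(htac, "tac"), inherits(mtac, "tac"))
  if (!htac$decay_corrected) htac <- decay_correct(htac, half_life_min)
  if (!mtac$decay_corrected) mtac <- decay_correct(mtac, half_life_min)
  He <- window_mean(htac, early_min); Me <- window_mean(mtac, early_min)
  Hd <- window_mean(htac, delayed_min); Md <- window_mean(mtac, delayed_min)
  if ((He - Me) <= 0) return(NA_real_)
  ((He - Me) - (Hd - Md)) / (He - Me)
}

#' Regressions linking kinetic and conventional indices
#'
#' `fit_linear()` is ordinary least squares `y = intercept + slope * x`
#' (used for predicting early/delayed HMR from iUp/iLoss, and WR from
#' 0.693/iLoss). `fit_monomolecular()` fits the saturating one-phase
#' association `y = Y0 + (plateau - Y0) * (1 - exp(-rate * x))` (used for WR
#' against iLoss).
#'
#' @param x,y numeric vectors of equal length
#' @return an object of class `regression_model` with `kind`, `coef`
#'   (named), `r_squared`, `predict(newx)`, `converged`
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x must not be constant")
  m <- stats::lm(y ~ x)
  cf <- stats::coef(m)
  structure(list(kind = "linear",
                 coef = c(intercept = unname(cf[1]), slope = unname(cf[2])),
                 r_squared = suppressWarnings(summary(m)$r.squared),
                 predict = function(newx) unname(cf[1] + cf[2] * newx),
                 converged = TRUE),
            class = "regression_model")
}

#' @rdname fit_linear
#' @export
fit_monomolecular <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 points")
  xr <- diff(range(x))
  if (xr <= 0) stop("x must not be constant")
  # rewrite y = plateau + (Y0 - plateau) exp(-rate x): linear in
  # (plateau, Y0 - plateau) at fixed rate, so profile the rate on a
  # log-spaced grid and refine by Brent. Robust on noise-free data, where
  # generic NLS stalls at zero residual.
  rss_at <- function(r) {
    B <- cbind(1, exp(-r * x))
    f <- stats::lm.fit(B, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients)
  }
  grid <- exp(seq(log(0.01 / xr), log(500 / xr), length.out = 80))
  rss <- vapply(grid, function(r) rss_at(r)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(r) rss_at(r)$rss, c(lo, hi), tol = 1e-12)
  rate <- if (opt$objective <= rss[i]) opt$minimum else grid[i]
  sol <- rss_at(rate)
  plateau <- unname(sol$coef[1])
  Y0 <- unname(sol$coef[1] + sol$coef[2])
  ss_tot <- sum((y - mean(y))^2)
  converged <- all(is.finite(c(plateau, Y0, rate)))
  structure(list(kind = "monomolecular",
                 coef = c(Y0 = Y0, plateau = plateau, rate = rate),
                 r_squared = if (ss_tot > 0) 1 - sol$rss / ss_tot else NA_real_,
                 predict = function(newx) {
                   plateau + (Y0 - plateau) * exp(-rate * newx)
                 },
                 converged = converged),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model:%s> %s  R^2=%.4g%s\n", x$kind,
              paste(names(x$coef), signif(x$coef, 4), sep = "=", collapse = " "),
              x$r_squared, if (x$converged) "" else " [not converged]"))
  invisible(x)
}
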