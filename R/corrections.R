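#' Population-based blood-to-plasma and metabolite correction curves
#'
#' The plasma input function is derived from the fitted mediastinal curve by
#' multiplying with `pbmc(t)/bpr(t)`:
#' * `bpr(t)` — blood-to-plasma activity ratio. Held at a floor of 0.6
#'   (haematocrit 40%) for the first 45 s, then rises smoothly and
#'   monotonically towards `bpr_plateau`:
#'   `bpr(t) = bpr_floor + (bpr_plateau - bpr_floor) * (1 - exp(-bpr_rate * (t - t_floor)))`.
#' * `pbmc(t)` — parent (unmetabolised) fraction in plasma. Starts at 1 at
#'   injection and declines monotonically to an asymptote of `pbmc_plateau`
#'   (default 0.30): `pbmc(t) = plateau + (1 - plateau) * exp(-pbmc_rate * t)`.
#'
#' The functional forms and time constants are parametric stand-ins for
#' published population curves whose shapes are not reproduced here; every
#' parameter is configurable and the defaults are documented as assumptions,
#' not measurements.
#'
#' @param bpr_floor floor value of the blood-to-plasma ratio (default 0.6)
#' @param bpr_floor_end_s end of the floor period in seconds (default 45)
#' @param bpr_plateau late asymptote of the blood-to-plasma ratio (default 1)
#' @param bpr_rate rise rate constant, 1/min (default 0.05)
#' @param pbmc_plateau late parent fraction, in (0, 1) (default 0.30)
#' @param pbmc_rate decline rate constant, 1/min (default 0.03)
#' @return an object of class `correction_curves` with callable elements
#'   `bpr(t_min)` and `pbmc(t_min)`
#' @examples
#' corr <- correction_curves()
#' corr$bpr(0.5)   # 0.6 (inside the floor)
#' corr$pbmc(0)    # 1
#' @export
correction_curves <- function(bpr_floor = 0.6, bpr_floor_end_s = 45,
                              bpr_plateau = 1.0, bpr_rate = 0.05,
                              pbmc_plateau = 0.30, pbmc_rate = 0.03) {
  if (pbmc_plateau <= 0 || pbmc_plateau >= 1) {
    stop("pbmc_plateau must lie strictly inside (0, 1)")
  }
  if (bpr_floor <= 0 || bpr_plateau < bpr_floor) {
    stop("require 0 < bpr_floor <= bpr_plateau")
  }
  if (bpr_rate < 0 || pbmc_rate < 0 || bpr_floor_end_s < 0) {
    stop("rates and floor end must be non-negative")
  }
  t_floor <- bpr_floor_end_s / 60
  bpr <- function(t_min) {
    ifelse(t_min <= t_floor, bpr_floor,
           bpr_floor + (bpr_plateau - bpr_floor) *
             (1 - exp(-bpr_rate * (t_min - t_floor))))
  }
  pbmc <- function(t_min) {
    pbmc_plateau + (1 - pbmc_plateau) * exp(-pbmc_rate * pmax(t_min, 0))
  }
  structure(list(bpr = bpr, pbmc = pbmc,
                 params = list(bpr_floor = bpr_floor,
                               bpr_floor_end_s = bpr_floor_end_s,
                               bpr_plateau = bpr_plateau, bpr_rate = bpr_rate,
                               pbmc_plateau = pbmc_plateau,
                               pbmc_rate = pbmc_rate)),
            class = "correction_curves")
}

#' @export
print.correction_curves <- function(x, ...) {
  p <- x$params
  cat(sprintf("<correction_curves> BPR: floor %.3g to %g s, plateau %.3g (rate %.3g/min); PBMC: 1 -> %.3g (rate %.3g/min)\n",
              p$bpr_floor, p$bpr_floor_end_s, p$bpr_plateau, p$bpr_rate,
              p$pbmc_plateau, p$pbmc_rate))
  invisible(x)
}
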