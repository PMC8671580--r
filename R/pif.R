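#' Plasma input function and tissue TAC construction
#'
#' `build_pif()` converts a fitted mediastinal curve into a plasma input
#' function by applying the metabolite and blood-to-plasma corrections:
#' `PIF(t) = m(t) * pbmc(t) / bpr(t)`, evaluated at frame midpoints on the
#' requested schedule. `pif_fun()` returns the same quantity as a function of
#' time in minutes, which the kinetic fit uses on its fine convolution grid.
#' `build_ttac()` subtracts the fitted mediastinal model (frame-averaged)
#' from the measured heart TAC to give the tissue output curve; tissue values
#' may be negative.
#'
#' @param mfit a [tri_exp_fit()] of the mediastinal TAC
#' @param corr a [correction_curves()] object
#' @param schedule a [frame_schedule()]
#' @param pre_peak pre-peak evaluation mode passed to [tri_exp_value()]
#' @return `build_pif`/`build_ttac`: a [tac()]; `pif_fun`: `function(t_min)`
#' @export
build_pif <- function(mfit, corr, schedule, pre_peak = "ramp") {
  stopifnot(inherits(mfit, "tri_exp_fit"), inherits(corr, "correction_curves"))
  tmid <- frame_mid_min(schedule)
  b <- corr$bpr(tmid)
  if (any(b <= 0)) stop("blood-to-plasma ratio must be positive everywhere")
  vals <- tri_exp_value(mfit, tmid, pre_peak = pre_peak) * corr$pbmc(tmid) / b
  tac(schedule, vals, roi_role = "plasma_input", decay_corrected = TRUE)
}

#' @rdname build_pif
#' @export
pif_fun <- function(mfit, corr, pre_peak = "ramp") {
  stopifnot(inherits(mfit, "tri_exp_fit"), inherits(corr, "correction_curves"))
  force(pre_peak)
  function(t_min) {
    b <- corr$bpr(t_min)
    if (any(b <= 0)) stop("blood-to-plasma ratio must be positive everywhere")
    tri_exp_value(mfit, t_min, pre_peak = pre_peak) * corr$pbmc(t_min) / b
  }
}

#' @param htac a heart [tac()]
#' @rdname build_pif
#' @export
build_ttac <- function(htac, mfit) {
  stopifnot(inherits(htac, "tac"), inherits(mfit, "tri_exp_fit"))
  if (htac$roi_role != "heart") stop("build_ttac expects a heart TAC")
  vals <- htac$values - tri_exp_frame_avg(mfit, htac$schedule, pre_peak = "ramp")
  tac(htac$schedule, vals, roi_role = "tissue",
      decay_corrected = htac$decay_corrected)
}
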