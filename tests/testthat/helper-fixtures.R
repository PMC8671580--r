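# Shared fixtures. The default synthetic cohort and its 30-min fit are
# expensive, so they are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Template mediastinal curve and corrections used by small fixtures.
template_mtac <- function() {
  tri_exp_fit(A = c(40, 8, 2), lambda = c(2.0, 0.15, 0.01), C = 0.8, t0 = 0.5)
}

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- generate_cohort(cohort_config(), seed = 101)
  }
  .fixture_cache$cohort
}

default_cohort_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    ch <- default_cohort()
    scans <- lapply(ch$scans, function(s) list(htac = s$htac, mtac = s$mtac))
    .fixture_cache$fit <- dps_fit_cohort(scans, ch$config$corrections,
                                         end_times_min = 30, models = "1T3P")
  }
  .fixture_cache$fit
}

# Independent segment-wise analytic solution of the compartment convolution
# for a piecewise-constant input: on each segment with constant input c,
# y(t) = y(t_i) exp(-L (t - t_i)) + U c (1 - exp(-L (t - t_i))) / L.
analytic_pc_conv <- function(breaks_min, values, U, L, t_eval) {
  y_at <- function(t) {
    y <- 0; t_prev <- 0
    for (i in seq_along(values)) {
      seg_end <- min(breaks_min[i + 1], t)
      if (seg_end <= t_prev) break
      dt <- seg_end - t_prev
      E <- exp(-L * dt)
      y <- y * E + U * values[i] * (1 - E) / L
      t_prev <- seg_end
      if (t_prev >= t) break
    }
    y
  }
  vapply(t_eval, y_at, numeric(1))
}

# Brute-force all-pairs AUC with half credit for ties (independent of the
# rank-based implementation).
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Noise-free simulated patient on a given schedule.
noiseless_scan <- function(iUp, iLoss, iNs, schedule = standard_schedule("scan1"),
                           corr = correction_curves()) {
  tpl <- template_mtac()
  m <- tri_exp_frame_avg(tpl, schedule, pre_peak = "ramp")
  pif <- pif_fun(tpl, corr, pre_peak = "ramp")
  tissue <- forward_model(pif, iUp, iLoss, iNs, schedule)
  list(htac = tac(schedule, tissue$values + m, "heart"),
       mtac = tac(schedule, m, "mediastinum"),
       pif = pif, tissue = tissue, mfit = tpl)
}
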