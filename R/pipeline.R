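#' Fit every patient of a cohort
#'
#' End-to-end kinetic analysis: per patient the mediastinal curve is fitted
#' (through 30 min for fit windows ending at or before 30 min, otherwise
#' through the window end), the plasma input function and tissue curve are
#' built, and both compartment models are fitted at every requested end
#' time. Conventional static indices (early/delayed HMR and WR) are computed
#' from the measured curves whenever the schedule spans their windows.
#' Per-patient failures are caught and reported, not fatal.
#'
#' @param scans named list (by patient id) of `list(htac = , mtac = )`
#' @param corr a [correction_curves()] object
#' @param end_times_min kinetic fit end times (minutes)
#' @param models `"1T3P"`, `"1T2P"` or both
#' @param t_start_min start of the kinetic fit window
#' @param ... passed to [fit_kinetics()]
#' @return list of class `cohort_fit`: `kinetic` (one row per patient x
#'   model x end time), `static` (one row per patient), `truncation`
#'   (summary of class `truncation_result`), `failed` (character)
#' @export
dps_fit_cohort <- function(scans, corr = correction_curves(),
                           end_times_min = c(5, 10, 15, 20, 25, 30, 105, 195),
                           models = c("1T3P", "1T2P"), t_start_min = 1, ...) {
  kin_rows <- list(); stat_rows <- list(); failed <- character()
  for (pid in names(scans)) {
    res <- tryCatch(
      analyze_patient(scans[[pid]]$htac, scans[[pid]]$mtac, corr,
                      end_times_min, models, t_start_min, ...),
      error = function(e) {
        warning("patient ", pid, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) { failed <- c(failed, pid); next }
    res$kinetic$patient_id <- pid
    kin_rows[[pid]] <- res$kinetic
    if (!is.null(res$static)) {
      res$static$patient_id <- pid
      stat_rows[[pid]] <- res$static
    }
  }
  kinetic <- do.call(rbind, c(kin_rows, list(make.row.names = FALSE)))
  static <- if (length(stat_rows)) {
    do.call(rbind, c(stat_rows, list(make.row.names = FALSE)))
  } else NULL
  structure(list(kinetic = kinetic, static = static,
                 truncation = truncation_summary(kinetic), failed = failed),
            class = "cohort_fit")
}

#' Analyse one patient
#'
#' @param htac,mtac measured heart and mediastinal [tac()]s
#' @inheritParams dps_fit_cohort
#' @return list with `kinetic` (data.frame) and `static` (one-row
#'   data.frame or `NULL` when the delayed window is not covered)
#' @export
analyze_patient <- function(htac, mtac, corr = correction_curves(),
                            end_times_min = 30, models = c("1T3P", "1T2P"),
                            t_start_min = 1, ...) {
  windows <- sort(unique(pmax(30, end_times_min)))
  rows <- list()
  for (wnd in windows) {
    mfit <- fit_mtac(mtac, t_end_min = wnd)
    pif <- pif_fun(mfit, corr)
    ttac <- build_ttac(htac, mfit)
    for (model in models) {
      for (te in end_times_min[pmax(30, end_times_min) == wnd]) {
        fit <- fit_kinetics(ttac, pif, model = model,
                            t_start_min = t_start_min, t_end_min = te, ...)
        idx <- derive_indices(fit)
        rows[[length(rows) + 1]] <- data.frame(
          model = model, t_end_min = te,
          iUp = fit$iUp, iLoss = fit$iLoss, iNs = fit$iNs,
          ratio = idx$ratio, half_life_min = idx$half_life_min,
          wssr = fit$wssr, n_frames = fit$n_frames,
          aic = fit$aic, sic = fit$sic,
          converged = fit$converged, identifiable = fit$identifiable)
      }
    }
  }
  t_last <- max(htac$schedule$start_s + htac$schedule$duration_s) / 60
  static <- NULL
  if (t_last >= 195) {
    static <- data.frame(
      eHMR = hmr(htac, mtac, c(10, 15)),
      dHMR = hmr(htac, mtac, c(190, 195)),
      WR = washout_rate(htac, mtac))
  } else if (t_last >= 15) {
    static <- data.frame(eHMR = hmr(htac, mtac, c(10, 15)),
                         dHMR = NA_real_, WR = NA_real_)
  }
  list(kinetic = do.call(rbind, rows), static = static)
}

# Aggregate per-patient kinetic rows into the truncation-study summary.
truncation_summary <- function(kin) {
  rows <- list()
  for (model in unique(kin$model)) {
    for (te in sort(unique(kin$t_end_min))) {
      d <- kin[kin$model == model & kin$t_end_min == te, ]
      if (!nrow(d)) next
      hl <- ifelse(d$iLoss > 0, 0.693 / d$iLoss, NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        model = model, t_end_min = te, n = nrow(d),
        iUp_mean = mean(d$iUp), iUp_sd = stats::sd(d$iUp),
        iLoss_mean = mean(d$iLoss), iLoss_sd = stats::sd(d$iLoss),
        iNs_mean = mean(d$iNs), iNs_sd = stats::sd(d$iNs),
        ratio_mean = mean(d$ratio, na.rm = TRUE),
        ratio_sd = stats::sd(d$ratio, na.rm = TRUE),
        half_life_mean = mean(hl, na.rm = TRUE),
        half_life_sd = stats::sd(hl, na.rm = TRUE),
        aic_mean = mean(d$aic), sic_mean = mean(d$sic),
        negcnt_iUp = sum(d$iUp < 0), negcnt_iLoss = sum(d$iLoss < 0),
        negcnt_iNs = if (model == "1T3P") sum(d$iNs < 0) else NA_integer_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("truncation_result", "data.frame")
  out
}

#' Diagnostic evaluation of a fitted cohort
#'
#' Builds the full diagnostic-performance report for the 30-min kinetic
#' indices and the conventional static indices: per-index ROC analysis with
#' Youden cut-offs (orientations: iLoss and WR rise with disease, iUp/iLoss
#' and the HMRs fall), paired bootstrap AUC comparisons of every index
#' against early HMR, SMOTE balancing of (iLoss, iUp/iLoss) followed by
#' linear- and RBF-kernel SVM evaluation over repeated stratified splits,
#' the mean diagnostic odds ratio of the fixed two-cut-off rule (positive
#' unless iLoss below its cut-off AND iUp/iLoss above its cut-off) over the
#' same splits, and Dunnett subgroup comparisons of iLoss and iUp/iLoss
#' against pRBD-negative PD. Patients with non-positive iLoss are excluded
#' from ratio-based analyses and counted.
#'
#' @param fit a [dps_fit_cohort()] result
#' @param labels data.frame with `patient_id`, `class_label`
#'   (`"LBD"`/`"non-LBD"`) and optionally `subgroup`
#' @param model,t_end_min which kinetic fit feeds the indices
#' @param n_runs,n_boot,seed evaluation settings
#' @return list of class `dps_report`
#' @export
dps_evaluate <- function(fit, labels, model = "1T3P", t_end_min = 30,
                         n_runs = 200, n_boot = 2000, seed = 1) {
  kin <- fit$kinetic[fit$kinetic$model == model &
                       fit$kinetic$t_end_min == t_end_min, ]
  d <- merge(kin, labels, by = "patient_id")
  if (!is.null(fit$static)) d <- merge(d, fit$static, by = "patient_id")
  d$is_lbd <- d$class_label == "LBD"
  if (!any(d$is_lbd) || all(d$is_lbd)) stop("need both classes in labels")

  orientations <- c(iLoss = "higher", ratio = "lower", eHMR = "lower",
                    dHMR = "lower", WR = "higher")
  avail <- intersect(names(orientations), names(d))
  n_excluded <- sum(!is.finite(d$ratio))

  roc_rows <- list(); rocs <- list()
  for (ix in avail) {
    ok <- is.finite(d[[ix]])
    if (sum(ok) < 4 || length(unique(d$is_lbd[ok])) < 2) next
    rr <- roc_auc(d[[ix]][ok], d$is_lbd[ok], orientation = orientations[[ix]],
                  n_boot = n_boot, seed = seed)
    rocs[[ix]] <- list(scores = d[[ix]][ok], labels = d$is_lbd[ok],
                       oriented = if (orientations[[ix]] == "higher")
                         d[[ix]][ok] else -d[[ix]][ok])
    roc_rows[[ix]] <- data.frame(
      index = ix, auc = rr$auc, auc_lo = rr$ci95[1], auc_hi = rr$ci95[2],
      cutoff = rr$cutoff, direction = rr$direction,
      sensitivity = rr$sensitivity, sens_lo = rr$sens_ci[1],
      sens_hi = rr$sens_ci[2],
      specificity = rr$specificity, spec_lo = rr$spec_ci[1],
      spec_hi = rr$spec_ci[2])
  }
  roc_table <- do.call(rbind, c(roc_rows, list(make.row.names = FALSE)))

  # bootstrap AUC comparisons vs early HMR on the common complete cases
  auc_tests <- NULL
  if ("eHMR" %in% names(rocs)) {
    tests <- list()
    for (ix in setdiff(names(rocs), "eHMR")) {
      ok <- is.finite(d[[ix]]) & is.finite(d$eHMR)
      if (sum(ok) < 4) next
      sa <- if (orientations[[ix]] == "higher") d[[ix]][ok] else -d[[ix]][ok]
      sb <- -d$eHMR[ok]
      bt <- bootstrap_auc_test(sa, sb, d$is_lbd[ok], n_boot = n_boot,
                               seed = seed)
      tests[[ix]] <- data.frame(index = ix, reference = "eHMR",
                                auc = bt$auc_a, auc_ref = bt$auc_b,
                                delta = bt$delta, p_value = bt$p_value)
    }
    auc_tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))
  }

  # SMOTE + SVMs in (iLoss, iUp/iLoss) space
  ok <- is.finite(d$iLoss) & is.finite(d$ratio)
  feats <- as.matrix(d[ok, c("iLoss", "ratio")])
  labs <- factor(d$class_label[ok], levels = c("LBD", "non-LBD"))
  bal <- smote(feats, as.character(labs), k = 5, seed = seed)
  bal_labels <- factor(bal$labels, levels = c("LBD", "non-LBD"))
  svm_linear <- repeated_svm_evaluation(bal$x, bal_labels, "linear",
                                        n_runs = n_runs, seed = seed,
                                        positive = "LBD")
  svm_rbf <- repeated_svm_evaluation(bal$x, bal_labels, "radial",
                                     n_runs = n_runs, seed = seed,
                                     positive = "LBD")
  cut_rule <- fixed_cutoff_dor(bal$x, bal_labels,
                               cut_iloss = roc_rows$iLoss$cutoff,
                               cut_ratio = roc_rows$ratio$cutoff,
                               n_runs = n_runs, seed = seed)

  # Dunnett subgroup comparison vs pRBD-negative PD
  dunnett <- NULL
  if ("subgroup" %in% names(d) && "PD_pRBDneg" %in% d$subgroup) {
    sub <- d[d$is_lbd & d$subgroup != "none", ]
    mk_groups <- function(v) split(v, sub$subgroup)
    if (length(unique(sub$subgroup)) >= 2 &&
        all(table(sub$subgroup) >= 2)) {
      dunnett <- list(
        ratio = dunnett_comparison(mk_groups(sub$ratio)[
          !vapply(mk_groups(sub$ratio), anyNA, logical(1))],
          reference_index = "PD_pRBDneg", seed = seed),
        iLoss = dunnett_comparison(mk_groups(sub$iLoss),
                                   reference_index = "PD_pRBDneg",
                                   seed = seed))
    }
  }

  structure(list(roc_table = roc_table, auc_tests = auc_tests,
                 svm = list(linear = svm_linear, rbf = svm_rbf),
                 fixed_cutoff = cut_rule, dunnett = dunnett,
                 n_patients = nrow(d), n_excluded_ratio = n_excluded,
                 model = model, t_end_min = t_end_min, seed = seed),
            class = "dps_report")
}

# Mean DOR of the fixed two-cut-off rule over repeated stratified test
# splits (same split scheme and seeds as the SVM evaluation).
fixed_cutoff_dor <- function(x, labels, cut_iloss, cut_ratio,
                             n_runs = 200, train_frac = 0.7, seed = 1) {
  if (is.null(cut_iloss) || is.null(cut_ratio)) return(NULL)
  labels <- factor(labels)
  dors <- vapply(seq_len(n_runs), function(r) {
    with_seed(seed + r, {
      tr <- stratified_train_idx(labels, train_frac)
      xte <- x[-tr, , drop = FALSE]; yte <- labels[-tr]
      pred_lbd <- !(xte[, "iLoss"] < cut_iloss & xte[, "ratio"] > cut_ratio)
      tp <- sum(pred_lbd & yte == "LBD"); fp <- sum(pred_lbd & yte != "LBD")
      fn <- sum(!pred_lbd & yte == "LBD"); tn <- sum(!pred_lbd & yte != "LBD")
      diagnostic_odds_ratio(tp, fp, fn, tn)
    })
  }, numeric(1))
  list(cut_iloss = cut_iloss, cut_ratio = cut_ratio, mean_dor = mean(dors),
       n_runs = n_runs)
}

#' Write an evaluation report to JSON
#'
#' Serialises a [dps_evaluate()] report (ROC table, AUC tests, classifier
#' summaries, Dunnett results) together with a provenance block (package
#' version, seed, model, fit window) to a JSON file. Identical inputs and
#' seed give a byte-identical file.
#'
#' @param report a `dps_report`
#' @param path output file
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "dps_report"))
  out <- list(
    provenance = list(
      package = "dpskin",
      version = as.character(utils::packageVersion("dpskin")),
      seed = report$seed, model = report$model,
      t_end_min = report$t_end_min),
    n_patients = report$n_patients,
    n_excluded_ratio = report$n_excluded_ratio,
    roc = report$roc_table,
    auc_tests = report$auc_tests,
    svm = list(
      linear = list(mean_auc = report$svm$linear$mean_auc,
                    mean_dor = report$svm$linear$mean_dor,
                    n_runs = report$svm$linear$n_runs),
      rbf = list(mean_auc = report$svm$rbf$mean_auc,
                 mean_dor = report$svm$rbf$mean_dor,
                 n_runs = report$svm$rbf$n_runs)),
    fixed_cutoff = report$fixed_cutoff,
    dunnett = report$dunnett)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @export
print.dps_report <- function(x, ...) {
  cat(sprintf("<dps_report> %d patients, %s at %g min\n", x$n_patients,
              x$model, x$t_end_min))
  if (!is.null(x$roc_table)) {
    cat("ROC:\n")
    print(x$roc_table[, c("index", "auc", "cutoff", "sensitivity",
                          "specificity")], digits = 3)
  }
  cat(sprintf("SVM mean AUC: linear %.3f, RBF %.3f; mean DOR: linear %.1f, RBF %.1f\n",
              x$svm$linear$mean_auc, x$svm$rbf$mean_auc,
              x$svm$linear$mean_dor, x$svm$rbf$mean_dor))
  invisible(x)
}
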