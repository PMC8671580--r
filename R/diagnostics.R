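#' ROC analysis with Youden cut-off
#'
#' The AUC is the Mann-Whitney concordance probability (ties receive half
#' credit), computed exactly from ranks. The 95% confidence interval comes
#' from a seeded stratified bootstrap (cases and controls resampled
#' separately). The reported cut-off maximises Youden's index
#' (sensitivity + specificity - 1) over the observed score values, with ties
#' broken towards the least extreme threshold (nearest the score median).
#' Sensitivity/specificity intervals are Wilson score intervals.
#'
#' `orientation` declares the polarity of the score: `"higher"` means high
#' values indicate the positive class (e.g. iLoss for Lewy body disease),
#' `"lower"` the reverse (e.g. iUp/iLoss and the HMRs, which fall with
#' disease).
#'
#' @param scores numeric score per subject
#' @param labels logical, `TRUE` for the positive (disease) class
#' @param orientation `"higher"` or `"lower"`
#' @param n_boot bootstrap replicates for the AUC CI (default 2000)
#' @param seed integer seed for the bootstrap
#' @param conf confidence level
#' @return object of class `roc_result`: `auc`, `ci95`, `cutoff`,
#'   `direction` (`">="` or `"<="`), `sensitivity`, `specificity`,
#'   `sens_ci`, `spec_ci`, `n_pos`, `n_neg`
#' @export
roc_auc <- function(scores, labels, orientation = c("higher", "lower"),
                    n_boot = 2000, seed = 1, conf = 0.95) {
  orientation <- match.arg(orientation)
  check_roc_input(scores, labels)
  s <- if (orientation == "higher") scores else -scores
  auc <- mw_auc(s, labels)
  ip <- which(labels); ineg <- which(!labels)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bp <- sample(ip, length(ip), replace = TRUE)
      bn <- sample(ineg, length(ineg), replace = TRUE)
      idx <- c(bp, bn)
      mw_auc(s[idx], c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
    }, numeric(1))
  })
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  yc <- youden_cutoff(scores, labels, orientation)
  np <- sum(labels); nn <- sum(!labels)
  structure(list(auc = auc, ci95 = ci,
                 cutoff = yc$cutoff, direction = yc$direction,
                 sensitivity = yc$sensitivity, specificity = yc$specificity,
                 sens_ci = wilson_ci(round(yc$sensitivity * np), np, conf),
                 spec_ci = wilson_ci(round(yc$specificity * nn), nn, conf),
                 n_pos = np, n_neg = nn, orientation = orientation),
            class = "roc_result")
}

check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!is.logical(labels)) stop("labels must be logical (TRUE = positive class)")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!any(labels) || all(labels)) stop("both classes must be present")
}

# Mann-Whitney AUC with half credit for ties; labels logical.
mw_auc <- function(s, labels) {
  r <- rank(s)
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname roc_auc
#' @export
youden_cutoff <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  check_roc_input(scores, labels)
  s <- if (orientation == "higher") scores else -scores
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!labels] < t), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  if (length(best) > 1) {                    # ties: least extreme threshold
    med <- stats::median(s)
    best <- best[order(abs(thr[best] - med), thr[best])][1]
  }
  cutoff <- if (orientation == "higher") thr[best] else -thr[best]
  list(cutoff = unname(cutoff),
       direction = if (orientation == "higher") ">=" else "<=",
       sensitivity = unname(sens[best]), specificity = unname(spec[best]),
       youden = unname(J[best]))
}

#' Paired bootstrap comparison of two AUCs
#'
#' Two-sided test of `AUC_A = AUC_B` for two scores measured on the same
#' subjects. Subjects are resampled with stratification (cases and controls
#' separately, the same resample applied to both scores); the p-value is
#' normal-based on the bootstrap standard error of the AUC difference.
#'
#' @param scores_a,scores_b paired score vectors (already oriented so that
#'   higher values indicate the positive class)
#' @param labels logical, `TRUE` = positive class
#' @param n_boot bootstrap replicates (default 2000)
#' @param seed integer seed
#' @return list with `p_value`, `auc_a`, `auc_b`, `delta`, `z`
#' @export
bootstrap_auc_test <- function(scores_a, scores_b, labels, n_boot = 2000,
                               seed = 1) {
  if (length(scores_a) != length(scores_b)) stop("paired scores differ in length")
  check_roc_input(scores_a, labels)
  check_roc_input(scores_b, labels)
  auc_a <- mw_auc(scores_a, labels)
  auc_b <- mw_auc(scores_b, labels)
  delta <- auc_a - auc_b
  ip <- which(labels); ineg <- which(!labels)
  dd <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      lab <- c(rep(TRUE, length(ip)), rep(FALSE, length(ineg)))
      mw_auc(scores_a[idx], lab) - mw_auc(scores_b[idx], lab)
    }, numeric(1))
  })
  se <- stats::sd(dd)
  if (se < 1e-12) {
    p <- if (abs(delta) < 1e-12) 1 else 2 * .Machine$double.eps
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p_value = p, auc_a = auc_a, auc_b = auc_b, delta = delta, z = z)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class dataset by synthesising minority-class points:
#' each synthetic sample lies on the segment between a minority point and
#' one of its `k` nearest minority neighbours (Euclidean distance), at a
#' uniform random fraction. The majority class is untouched; output class
#' counts are exactly equal. Already balanced input is returned unchanged.
#'
#' @param x numeric feature matrix (rows = samples)
#' @param labels class label per row (two classes)
#' @param k number of nearest neighbours (default 5; reduced with a warning
#'   when the minority class is too small)
#' @param seed integer seed
#' @return list with `x`, `labels`, `synthetic` (logical row flags)
#' @export
smote <- function(x, labels, k = 5, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stop("x rows and labels differ in length")
  tab <- table(labels)
  if (length(tab) != 2) stop("smote expects exactly two classes")
  if (tab[1] == tab[2]) {
    return(list(x = x, labels = labels, synthetic = rep(FALSE, nrow(x))))
  }
  min_lab <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_new <- max(tab) - n_min
  if (n_min < 2) stop("minority class needs at least 2 members")
  if (k >= n_min) {
    warning("k reduced to ", n_min - 1, " (minority class size ", n_min, ")")
    k <- n_min - 1
  }
  xm <- x[labels == min_lab, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  syn <- with_seed(seed, {
    parents <- sample(n_min, n_new, replace = n_new > n_min)
    t(vapply(parents, function(p) {
      q <- nn[p, sample.int(k, 1)]
      gap <- stats::runif(1)
      xm[p, ] + gap * (xm[q, ] - xm[p, ])
    }, numeric(ncol(x))))
  })
  out_x <- rbind(x, syn)
  rownames(out_x) <- NULL
  list(x = out_x,
       labels = c(labels, rep(min_lab, n_new)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)))
}

#' Repeated split-sample SVM evaluation
#'
#' Evaluates a support vector machine classifier over `n_runs` seeded
#' stratified train/test splits (default 70/30). Per run: features are
#' standardised with training-set statistics only, the SVM (cost `cost`;
#' for the RBF kernel, bandwidth `gamma = 1/d` on standardised features) is
#' fitted on the training part, the test AUC is computed from decision
#' values, and the confusion matrix at the default decision boundary yields
#' the diagnostic odds ratio `DOR = (TP*TN)/(FP*FN)`, with 0.5 added to every
#' cell whenever any cell is zero. Aggregates are arithmetic means over runs.
#'
#' @param x feature matrix (typically post-SMOTE, balanced)
#' @param labels factor (two levels) per row
#' @param kernel `"linear"` or `"radial"`
#' @param n_runs number of random splits (default 200)
#' @param train_frac training fraction (default 0.7)
#' @param cost SVM regularisation constant (default 1)
#' @param seed master seed; run r uses `seed + r`
#' @param positive label of the positive (disease) class (default first level)
#' @return object of class `classifier_evaluation`: `kernel`, `n_runs`,
#'   `mean_auc`, `mean_dor`, `runs` (per-run data.frame)
#' @export
repeated_svm_evaluation <- function(x, labels, kernel = c("linear", "radial"),
                                    n_runs = 200, train_frac = 0.7, cost = 1,
                                    seed = 1, positive = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  positive <- positive %||% levels(labels)[1]
  if (!positive %in% levels(labels)) stop("positive label not found")
  if (n_runs < 1) stop("n_runs must be at least 1")

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- with_seed(seed + r, {
      tr <- stratified_train_idx(labels, train_frac)
      xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(labels[tr])
      xte <- x[-tr, , drop = FALSE]; yte <- labels[-tr]
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd); sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      m <- e1071::svm(xtr, ytr, kernel = kernel, cost = cost,
                      gamma = 1 / ncol(x), scale = FALSE)
      pred <- stats::predict(m, xte, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      first_of_pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      score <- if (first_of_pair == positive) dv[, 1] else -dv[, 1]
      auc <- mw_auc(score, yte == positive)
      tp <- sum(pred == positive & yte == positive)
      fp <- sum(pred == positive & yte != positive)
      fn <- sum(pred != positive & yte == positive)
      tn <- sum(pred != positive & yte != positive)
      data.frame(seed = seed + r, auc = auc,
                 dor = diagnostic_odds_ratio(tp, fp, fn, tn),
                 tp = tp, fp = fp, fn = fn, tn = tn)
    })
  }
  runs <- do.call(rbind, runs)
  structure(list(kernel = kernel, n_runs = n_runs,
                 mean_auc = mean(runs$auc), mean_dor = mean(runs$dor),
                 runs = runs, positive = positive),
            class = "classifier_evaluation")
}

# Stratified training indices: floor per class, remainders assigned by
# largest fractional part (ties in class order) so that the overall training
# count equals round(train_frac * n).
stratified_train_idx <- function(labels, train_frac) {
  n_target <- round(train_frac * length(labels))
  lev <- levels(labels)
  n_c <- table(labels)[lev]
  base <- floor(train_frac * n_c)
  rem <- n_target - sum(base)
  if (rem > 0) {
    frac <- train_frac * n_c - base
    base[order(-frac)[seq_len(rem)]] <- base[order(-frac)[seq_len(rem)]] + 1
  }
  unlist(lapply(seq_along(lev), function(i) {
    idx <- which(labels == lev[i])
    sample(idx, base[i])
  }), use.names = FALSE)
}

#' Diagnostic odds ratio with zero-cell correction
#'
#' `(TP*TN)/(FP*FN)`; if any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe correction).
#' @param tp,fp,fn,tn confusion-matrix counts
#' @export
diagnostic_odds_ratio <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) == 0)) {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  (tp * tn) / (fp * fn)
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> %s kernel, %d runs: mean AUC %.3f, mean DOR %.1f\n",
              x$kernel, x$n_runs, x$mean_auc, x$mean_dor))
  invisible(x)
}

#' Dunnett many-to-one comparison
#'
#' Compares each group mean with the reference group using the many-to-one
#' multivariate-t adjustment (single-step Dunnett) on a pooled-variance
#' one-way model. The multivariate-t probabilities are evaluated by seeded
#' quasi-Monte-Carlo, so results are reproducible for a given seed.
#'
#' @param groups named list of numeric vectors, one per group (each n >= 2)
#' @param reference_index index (or name) of the reference group
#' @param seed integer seed for the multivariate-t evaluation
#' @return data.frame with one row per non-reference group: `group`,
#'   `estimate` (mean difference vs reference), `t_value`, `p_adjusted`
#' @export
dunnett_comparison <- function(groups, reference_index = 1, seed = 1) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  nm[nm == ""] <- paste0("group", which(nm == ""))
  if (is.character(reference_index)) reference_index <- match(reference_index, nm)
  ref <- nm[reference_index]
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, vapply(groups, length, integer(1))),
              levels = c(ref, setdiff(nm, ref)))
  pooled_var <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (length(y) - length(groups))
  if (pooled_var <= 0) stop("zero pooled variance")
  fit <- stats::aov(y ~ g)
  summ <- with_seed(seed, {
    summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  })
  data.frame(group = setdiff(levels(g), ref),
             estimate = as.vector(summ$test$coefficients),
             t_value = as.vector(summ$test$tstat),
             p_adjusted = as.vector(summ$test$pvalues))
}
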