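test_that("AUC equals brute-force pair concordance, including ties", {
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                       n_boot = 50)$auc, 0.75)   # 3 of 4 concordant pairs
  # perfectly separated and all-tied corner cases
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                       n_boot = 50)$auc, 1.0)
  expect_equal(roc_auc(rep(3, 6), rep(c(TRUE, FALSE), 3), n_boot = 50)$auc, 0.5)

  # random inputs with heavy ties, up to 200 subjects, exact agreement
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_identical(roc_auc(scores, labels, n_boot = 2)$auc,
                     brute_force_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4), n_boot = 2), "both classes")
})

test_that("AUC cross-checks against pROC and respects monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c(TRUE, FALSE), c(40, 60))
  ours <- roc_auc(scores, labels, n_boot = 10)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  # monotone transform leaves AUC and the Youden operating point unchanged
  tr <- roc_auc(exp(scores), labels, n_boot = 10)
  expect_equal(tr$auc, ours, tolerance = 1e-12)
  yo <- youden_cutoff(scores, labels)
  yt <- youden_cutoff(exp(scores), labels)
  expect_equal(yt$sensitivity, yo$sensitivity)
  expect_equal(yt$specificity, yo$specificity)
  expect_equal(yt$cutoff, exp(yo$cutoff), tolerance = 1e-12)
})

test_that("Youden cut-off scan handles separation and orientation", {
  # single positive above all negatives
  y <- youden_cutoff(c(9, 1, 2, 3), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  expect_equal(y$youden, 1)
  # orientation flip preserves J and mirrors the threshold side
  s <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2)
  l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  hi <- youden_cutoff(s, l, "higher")
  lo <- youden_cutoff(-s, l, "lower")
  expect_equal(lo$youden, hi$youden)
  expect_identical(lo$direction, "<=")
})

test_that("bootstrap AUC comparison behaves at its fixed points", {
  set.seed(41)
  labels <- rep(c(TRUE, FALSE), each = 100)
  perfect <- ifelse(labels, 1, 0) + rnorm(200, sd = 0.01)
  random <- rnorm(200)
  # identical scores: no difference
  expect_equal(bootstrap_auc_test(random, random, labels, n_boot = 200,
                                  seed = 5)$p_value, 1)
  # perfect vs random scorer: decisive
  bt <- bootstrap_auc_test(perfect, random, labels, n_boot = 500, seed = 5)
  expect_lt(bt$p_value, 0.01)
  expect_gt(bt$delta, 0.3)
  # two-sided symmetry under swapping A and B
  ba <- bootstrap_auc_test(random, perfect, labels, n_boot = 500, seed = 5)
  expect_equal(ba$p_value, bt$p_value, tolerance = 0.02)
  expect_error(bootstrap_auc_test(1:3, 1:4, c(TRUE, FALSE, TRUE)), "length")
})

test_that("SMOTE balances classes by minority interpolation", {
  set.seed(51)
  x <- rbind(matrix(rnorm(105 * 2, 0), ncol = 2),
             matrix(rnorm(61 * 2, 4), ncol = 2))
  labels <- rep(c("LBD", "non-LBD"), c(105, 61))
  bal <- smote(x, labels, k = 5, seed = 9)
  expect_equal(nrow(bal$x), 210)
  expect_equal(as.vector(table(bal$labels)), c(105L, 105L))
  expect_equal(sum(bal$synthetic), 44)
  # reproducibility is bit-for-bit under a fixed seed
  expect_identical(bal, smote(x, labels, k = 5, seed = 9))
  # every synthetic point lies on a segment between two minority points
  xm <- x[labels == "non-LBD", ]
  syn <- bal$x[bal$synthetic, , drop = FALSE]
  on_segment <- function(pt) {
    for (i in seq_len(nrow(xm))) for (j in seq_len(nrow(xm))) {
      if (i == j) next
      d <- xm[j, ] - xm[i, ]
      g <- sum((pt - xm[i, ]) * d) / sum(d * d)
      if (g >= -1e-9 && g <= 1 + 1e-9 &&
          sqrt(sum((xm[i, ] + g * d - pt)^2)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))
  # balanced input returned unchanged
  even <- smote(x[1:122, ], rep(c("a", "b"), each = 61), seed = 1)
  expect_identical(even$x, x[1:122, ])
})

test_that("repeated SVM evaluation: splits, separability and DOR arithmetic", {
  expect_equal(diagnostic_odds_ratio(9, 1, 1, 9), 81)
  expect_equal(diagnostic_odds_ratio(10, 0, 2, 8),
               (10.5 * 8.5) / (0.5 * 2.5))    # 35.7 after zero-cell correction

  # 210 balanced samples at 30% test share: 63 test samples per run
  set.seed(61)
  x <- rbind(matrix(rnorm(210, 0, 0.3), ncol = 2),
             matrix(rnorm(210, 3, 0.3), ncol = 2))
  labels <- factor(rep(c("LBD", "non-LBD"), each = 105))
  ev <- repeated_svm_evaluation(x, labels, "linear", n_runs = 8, seed = 3,
                                positive = "LBD")
  expect_true(all(ev$runs$tp + ev$runs$fp + ev$runs$fn + ev$runs$tn == 63))
  # perfectly separable clusters: AUC 1 and flawless confusion each run
  expect_equal(ev$mean_auc, 1.0)
  expect_true(all(ev$runs$fp == 0 & ev$runs$fn == 0))
  ev_rbf <- repeated_svm_evaluation(x, labels, "radial", n_runs = 4, seed = 3,
                                    positive = "LBD")
  expect_equal(ev_rbf$mean_auc, 1.0)
  # aggregate means equal means of per-run records
  expect_equal(ev$mean_dor, mean(ev$runs$dor))
})

test_that("random classifier DOR centres near 1 on balanced data", {
  set.seed(71)
  x <- matrix(rnorm(200 * 2), ncol = 2)          # features carry no signal
  labels <- factor(rep(c("a", "b"), each = 100))
  ev <- repeated_svm_evaluation(x, labels, "linear", n_runs = 60, seed = 11,
                                positive = "a")
  expect_lt(abs(mean(log(ev$runs$dor))), 0.35)
  expect_gt(mean(ev$runs$auc), 0.35)
  expect_lt(mean(ev$runs$auc), 0.65)
})

test_that("Dunnett comparison reduces to the pooled t-test for two groups", {
  set.seed(81)
  g1 <- rnorm(20, 0); g2 <- rnorm(15, 0.8)
  d <- dunnett_comparison(list(ref = g1, other = g2), reference_index = "ref",
                          seed = 4)
  expect_equal(nrow(d), 1)                      # reference never compared to itself
  tt <- t.test(g2, g1, var.equal = TRUE)
  expect_equal(d$p_adjusted, tt$p.value, tolerance = 1e-4)
  expect_equal(d$estimate, mean(g2) - mean(g1), tolerance = 1e-9)

  # three groups from one distribution: family-wise error near alpha
  set.seed(82)
  rej <- replicate(200, {
    g <- lapply(1:3, function(i) rnorm(12))
    any(dunnett_comparison(g, 1, seed = 1)$p_adjusted < 0.05)
  })
  expect_lt(mean(rej), 0.12)
  expect_error(dunnett_comparison(list(rep(1, 5), rep(1, 5))), "variance")
})
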