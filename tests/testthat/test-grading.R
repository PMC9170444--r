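test_that("compare_groups gates on normality and returns sound p-values", {
  # identical (skewed, hence rank-sum) groups: p = 1
  res <- compare_groups(c(1, 1, 1, 1, 5), c(1, 1, 1, 1, 5))
  expect_identical(res$method, "wilcoxon")
  expect_equal(res$p_value, 1)

  # small identical normal-looking groups pass the gate into the t branch
  expect_identical(compare_groups(c(1, 2, 3), c(1, 2, 3))$method, "t")

  # clearly separated groups: significant under either branch
  res2 <- compare_groups(1:4, 101:104)
  expect_lt(res2$p_value, 0.05)

  # normal samples take the t branch and match the textbook formula
  set.seed(31)
  x <- rnorm(30, 0, 1)
  y <- rnorm(30, 0.5, 1)
  res3 <- compare_groups(x, y)
  expect_identical(res3$method, "t")
  se <- sqrt(var(x) / 30 + var(y) / 30)
  tstat <- (mean(x) - mean(y)) / se
  expect_equal(res3$statistic, tstat, tolerance = 1e-10)
  df <- se^4 / ((var(x) / 30)^2 / 29 + (var(y) / 30)^2 / 29)
  expect_equal(res3$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-10)

  # constant groups cannot pass the normality gate
  res4 <- compare_groups(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_identical(res4$method, "wilcoxon")

  expect_error(compare_groups(1, c(1, 2)), class = "ikfcm_data_error")
})

test_that("roc_curve reproduces known AUCs and the Mann-Whitney identity", {
  # perfect separation
  expect_equal(roc_curve(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)

  # all scores tied: chance AUC by the tie convention
  expect_equal(roc_curve(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  # pair counting: positives {2,4}, negatives {1,3} -> 3/4 concordant
  expect_equal(roc_curve(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.75)

  # AUC from the trapezoid equals U/(n1 n2) with ties, on random data
  set.seed(17)
  for (rep in 1:10) {
    scores <- sample(1:8, 40, replace = TRUE) # heavy ties
    labels <- sample(c(TRUE, FALSE), 40, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (!any(labels) || all(labels)) next
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }

  expect_error(roc_curve(1:4, rep(TRUE, 4)), class = "ikfcm_data_error")
})

test_that("roc_curve agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- c(rnorm(40, 1), rnorm(40, 0))
  labels <- rep(c(TRUE, FALSE), each = 40)
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("optimal_cutoff maximizes Youden's J deterministically", {
  # brute-force scan on random score sets
  set.seed(23)
  for (rep in 1:10) {
    scores <- round(runif(20, 0, 10), 1)
    labels <- runif(20) < plogis(scores - 5)
    if (!any(labels) || all(labels)) next
    roc <- roc_curve(scores, labels)
    oc <- optimal_cutoff(roc)
    expect_equal(oc$youden, oracle_youden(scores, labels), tolerance = 1e-12)
    expect_equal(oc$youden, oc$sensitivity + oc$specificity - 1,
                 tolerance = 1e-12)
  }

  # perfectly separated groups reach J = 1
  roc <- roc_curve(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  oc <- optimal_cutoff(roc)
  expect_equal(oc$youden, 1)
  expect_true(oc$cutoff > 2 && oc$cutoff <= 8)

  # monotone transforms keep sensitivity/specificity at the mapped cutoff
  scores <- c(3, 1, 4, 1, 5, 9, 2, 6)
  labels <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  oc1 <- optimal_cutoff(roc_curve(scores, labels))
  oc2 <- optimal_cutoff(roc_curve(exp(scores), labels))
  expect_equal(oc2$sensitivity, oc1$sensitivity)
  expect_equal(oc2$specificity, oc1$specificity)
  expect_equal(oc2$cutoff, exp(oc1$cutoff))
})

test_that("simulate_grading_cohort is deterministic and well-formed", {
  tab <- simulate_grading_cohort(n_per_group = 10, seed = 5)
  tab2 <- simulate_grading_cohort(n_per_group = 10, seed = 5)
  expect_identical(tab, tab2)
  expect_setequal(unique(tab$group), c("high", "low"))
  expect_identical(nrow(tab), 10L * 2L * 5L)
  expect_false(anyDuplicated(tab[, c("subject", "parameter")]) > 0)

  # huge separation drives the AUC to 1
  par5 <- data.frame(parameter = "P", mean_high = 5, mean_low = 0, sd = 1)
  big <- simulate_grading_cohort(100, par5, seed = 7)
  expect_gte(roc_curve(big$value, big$group == "high")$auc, 0.99)
})

test_that("grading_report mirrors the per-parameter ROC table", {
  tab <- simulate_grading_cohort(n_per_group = 25, seed = 11)
  rep <- grading_report(tab)
  expect_identical(nrow(rep), 5L)
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_true(all(rep$sensitivity >= 0 & rep$sensitivity <= 1))
  expect_true(all(rep$specificity >= 0 & rep$specificity <= 1))
  # the synthetic defaults separate every parameter
  expect_true(all(rep$p_value < 0.05))
  # report rows equal direct per-parameter computation
  mk <- tab[tab$parameter == "MK", ]
  roc <- roc_curve(mk$value, mk$group == "high")
  expect_equal(rep$auc[rep$parameter == "MK"], roc$auc)
  expect_equal(rep$critical_value[rep$parameter == "MK"],
               optimal_cutoff(roc)$cutoff)

  expect_error(grading_report(tab[, -4]), class = "ikfcm_data_error")
})
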