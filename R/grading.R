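#' Two-group comparison with a normality gate
#'
#' Compares one parameter between two groups of subjects.  Each group is
#' checked for normality (Shapiro-Wilk at alpha = 0.05); if both pass, a
#' Welch two-sample t-test is used, otherwise the Wilcoxon rank-sum test.
#' Groups too small or degenerate (constant) for the normality test fall
#' back to the rank-sum branch.
#'
#' @param x,y Numeric vectors of per-subject values, one per group
#'   (length `>= 2` each).
#' @return A list: `method` (`"t"` or `"wilcoxon"`), `statistic`,
#'   `p_value` (two-sided), and the per-group normality verdicts.
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    ik_stop("need at least 2 subjects per group", "data")
  }
  is_normal <- function(v) {
    if (length(v) < 3 || length(unique(v)) < 2) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }
  nx <- is_normal(x)
  ny <- is_normal(y)
  if (nx && ny) {
    ht <- stats::t.test(x, y)
    list(method = "t", statistic = unname(ht$statistic),
         p_value = ht$p.value, normal_x = nx, normal_y = ny)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    list(method = "wilcoxon", statistic = unname(ht$statistic),
         p_value = ht$p.value, normal_x = nx, normal_y = ny)
  }
}

#' Empirical ROC curve and AUC
#'
#' Receiver operating characteristic over all observed score thresholds
#' (predict positive when `score >= threshold`), with the area under the
#' curve by trapezoidal integration.  Ties are handled by the diagonal
#' segments of the trapezoid rule, so the AUC equals the Mann-Whitney
#' statistic `U/(n1*n2)` with ties counted one half.
#'
#' @param scores Numeric vector of per-subject scores (higher = more
#'   likely positive).
#' @param labels Logical vector (or coercible), `TRUE` for the positive
#'   class; both classes must be present.
#' @return A `roc_curve` object: `points` (data frame with `threshold`,
#'   `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    ik_stop("scores and labels must be complete and the same length", "data")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    ik_stop("both classes must be present", "data")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t0) sum(scores >= t0 & labels) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t0) sum(scores >= t0 & !labels) / n_neg,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                    fpr = c(0, fpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Youden-optimal cutoff of an ROC curve
#'
#' The threshold maximizing Youden's `J = sensitivity + specificity - 1`.
#' Ties are broken toward higher specificity, then toward the higher
#' threshold, making the choice deterministic.
#'
#' @param roc A [roc_curve()] object.
#' @return A list: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(roc) {
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  ord <- order(-j, pts$fpr, -pts$threshold)
  best <- pts[ord[1], ]
  list(cutoff = best$threshold,
       sensitivity = best$tpr,
       specificity = 1 - best$fpr,
       youden = best$tpr - best$fpr)
}

#' Simulate a two-group grading cohort
#'
#' Seeded Gaussian draws of per-subject parameter values for a high-grade
#' and a low-grade group — a synthetic stand-in for a patient cohort's
#' diffusion-kurtosis metrics (MK/AK/RK) and metabolite ratios (Cho/Cr,
#' Cho/NAA), whose real per-subject values are never published.
#'
#' @param n_per_group Subjects per group.
#' @param parameters Data frame with columns `parameter`, `mean_high`,
#'   `mean_low`, `sd` (common within-group standard deviation, `> 0`).
#' @param seed Integer seed.
#' @return A `ParameterTable`-style data frame: `subject`, `group`
#'   (`"high"`/`"low"`), `parameter`, `value`.
#' @export
simulate_grading_cohort <- function(n_per_group = 20,
                                    parameters = default_grading_parameters(),
                                    seed = 1) {
  req <- c("parameter", "mean_high", "mean_low", "sd")
  if (!all(req %in% names(parameters))) {
    ik_stop("parameters needs columns parameter, mean_high, mean_low, sd",
            "data")
  }
  if (any(parameters$sd <= 0)) ik_stop("sds must be positive", "data")
  subj <- sprintf("S%03d", seq_len(2 * n_per_group))
  grp <- rep(c("high", "low"), each = n_per_group)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(parameters)), function(i) {
      p <- parameters[i, ]
      vals <- c(stats::rnorm(n_per_group, p$mean_high, p$sd),
                stats::rnorm(n_per_group, p$mean_low, p$sd))
      data.frame(subject = subj, group = grp,
                 parameter = p$parameter, value = vals)
    })
    do.call(rbind, out)
  })
}

#' Synthetic default grading parameters
#'
#' Literature-plausible group means and spreads for the five grading
#' parameters; purely synthetic defaults for [simulate_grading_cohort()].
#'
#' @return Data frame usable as the `parameters` argument of
#'   [simulate_grading_cohort()].
#' @export
default_grading_parameters <- function() {
  data.frame(
    parameter = c("MK", "AK", "RK", "Cho/Cr", "Cho/NAA"),
    mean_high = c(0.92, 0.81, 0.76, 3.2, 2.9),
    mean_low  = c(0.61, 0.66, 0.60, 2.1, 1.7),
    sd        = c(0.12, 0.14, 0.13, 0.85, 0.80)
  )
}

#' Per-parameter grading report
#'
#' For every parameter in a cohort table: the two-group comparison
#' ([compare_groups()]), the ROC of high-vs-low grading
#' ([roc_curve()]) and the Youden-optimal critical value
#' ([optimal_cutoff()]), collected in one table (AUC, critical value,
#' sensitivity and specificity at the cutoff, p-value, test used).
#'
#' @param table Data frame with columns `subject`, `group`
#'   (`"high"`/`"low"`), `parameter`, `value`.
#' @return Data frame, one row per parameter.
#' @export
grading_report <- function(table) {
  req <- c("subject", "group", "parameter", "value")
  if (!all(req %in% names(table))) {
    ik_stop("cohort table needs columns subject, group, parameter, value",
            "data")
  }
  if (!all(table$group %in% c("high", "low"))) {
    ik_stop("group must be 'high' or 'low'", "data")
  }
  if (anyDuplicated(table[, c("subject", "parameter")])) {
    ik_stop("duplicated (subject, parameter) pair", "data")
  }
  params <- unique(table$parameter)
  rows <- lapply(params, function(pn) {
    sub <- table[table$parameter == pn, ]
    hi <- sub$value[sub$group == "high"]
    lo <- sub$value[sub$group == "low"]
    if (length(hi) < 2 || length(lo) < 2) {
      ik_stop(paste0("parameter '", pn, "' needs >= 2 subjects per group"),
              "data")
    }
    cg <- compare_groups(hi, lo)
    roc <- roc_curve(sub$value, sub$group == "high")
    oc <- optimal_cutoff(roc)
    data.frame(parameter = pn, auc = roc$auc,
               critical_value = oc$cutoff,
               sensitivity = oc$sensitivity,
               specificity = oc$specificity,
               p_value = cg$p_value, method = cg$method)
  })
  do.call(rbind, rows)
}
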