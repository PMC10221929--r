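# Biomarker-evaluation statistics for the clinical cohort: group
# comparison, ROC/AUC, Youden cutoff, confusion matrix, correlation.

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  u <- sort(unique(as.character(labels)))
  if (is.null(positive)) {
    if (all(u %in% c("0", "1"))) {
      positive <- "1"
    } else if (length(u) == 2) {
      positive <- u[2]
    } else {
      stop("labels must be binary; got levels: ", paste(u, collapse = ", "))
    }
  }
  as.character(labels) == as.character(positive)
}

#' Empirical ROC curve and AUC
#'
#' Classification rule: predict positive (case) when `score > threshold`,
#' evaluated at every observed threshold. The AUC is computed as the
#' trapezoidal integral of the curve, which equals the all-pairs rank
#' statistic `(#\{case > control\} + 0.5 #ties) / (n1 n0)` exactly.
#'
#' @param scores Numeric biomarker values.
#' @param labels Binary labels (logical, 0/1, or two-level with `positive`).
#' @param positive Label value treated as the positive (case) class.
#' @return List of class `roc_curve`: `points` (tibble `threshold`,
#'   `sensitivity`, `specificity`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("undefined AUC: both classes must be present")
  }
  cuts <- c(-Inf, sort(unique(scores)))
  sens <- vapply(cuts, function(t) sum(scores[y] > t) / n1, numeric(1))
  spec <- vapply(cuts, function(t) sum(scores[!y] <= t) / n0, numeric(1))
  pts <- tibble::tibble(threshold = cuts, sensitivity = sens,
                        specificity = spec)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + sens[ord][-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Optimal classification cutoff by the Youden index
#'
#' Maximizes `J = sensitivity + specificity - 1` over the curve's
#' thresholds. Ties break toward the lower threshold; the returned cutoff is
#' the midpoint between the chosen threshold score and the next distinct
#' score above it (the decision boundary lies anywhere in that gap). When
#' the curve is flat (max J = 0) the lowest threshold is returned with a
#' `degenerate` attribute.
#'
#' @param curve A [roc_curve()].
#' @return Numeric cutoff; attributes `youden` (the maximal J) and
#'   `degenerate` (flag).
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  j <- pts$sensitivity + pts$specificity - 1
  jmax <- max(j)
  best <- which(j == jmax)[1]  # thresholds ascend, so [1] is the lowest
  thr <- pts$threshold[best]
  finite_thr <- pts$threshold[is.finite(pts$threshold)]
  if (!is.finite(thr)) thr <- min(finite_thr)
  above <- finite_thr[finite_thr > thr]
  cutoff <- if (length(above) > 0) (thr + min(above)) / 2 else thr
  structure(cutoff, youden = jmax, degenerate = jmax <= 0)
}

#' Confusion matrix at a cutoff
#'
#' Predicts positive when `score > cutoff` (strict) and tabulates counts and
#' the derived metrics.
#'
#' @param scores,labels,positive As in [roc_curve()].
#' @param cutoff Finite classification threshold.
#' @return List of class `confusion_summary`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_at <- function(scores, labels, cutoff, positive = NULL) {
  stopifnot(is.finite(cutoff))
  y <- as_binary_labels(labels, positive)
  pred <- scores > cutoff
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(y)
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d tn=%d fn=%d | sens=%.3f spec=%.3f acc=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
              x$accuracy))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; the two-sided p-value uses the t transform
#' `t = r sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return List with `r`, `pvalue`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_r requires n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(x))
}

#' Group comparison with a documented normality/homogeneity screen
#'
#' For numeric data: with `family = "auto"` a Shapiro-Wilk test per group
#' (each at 0.05) plus a Bartlett homogeneity test decide between the
#' parametric family (two-sample t test, or one-way ANOVA for k > 2 groups)
#' and the nonparametric family (Wilcoxon rank-sum, or Kruskal-Wallis).
#' Categorical data are compared with a chi-square test on the contingency
#' table. The screen's p-values and the test actually run are reported.
#'
#' @param values Numeric measurements, or a factor/character vector for a
#'   count comparison.
#' @param groups Group labels (2 or more groups).
#' @param family `"auto"` (default), `"parametric"` or `"nonparametric"`.
#' @return List with `test` (name), `statistic`, `pvalue`, `degenerate`
#'   flag, and `screen` (Shapiro and homogeneity p-values, when run).
#' @export
group_compare <- function(values, groups,
                          family = c("auto", "parametric",
                                     "nonparametric")) {
  family <- match.arg(family)
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")

  if (is.factor(values) || is.character(values)) {
    tab <- table(values, groups)
    ct <- suppressWarnings(chisq.test(tab))
    return(list(test = "chi-square", statistic = unname(ct$statistic),
                pvalue = ct$p.value, degenerate = is.na(ct$p.value),
                screen = NULL))
  }

  screen <- NULL
  if (family == "auto") {
    sh <- vapply(split(values, groups), function(v) {
      if (length(v) >= 3 && sd(v) > 0) shapiro.test(v)$p.value else 0
    }, numeric(1))
    bt <- tryCatch(bartlett.test(values, groups)$p.value,
                   error = function(e) 0)
    screen <- list(shapiro_p = sh, homogeneity_p = bt)
    family <- if (all(sh > 0.05) && !is.na(bt) && bt > 0.05) {
      "parametric"
    } else {
      "nonparametric"
    }
  }

  degenerate <- sd(values) == 0
  if (degenerate) {
    return(list(test = paste0(family, " (degenerate: constant data)"),
                statistic = 0, pvalue = 1, degenerate = TRUE,
                screen = screen))
  }
  if (family == "parametric") {
    if (any(tapply(values, groups, length) < 2)) {
      stop("parametric comparison needs >= 2 observations per group")
    }
    if (k == 2) {
      sp <- split(values, groups)
      if (sd(sp[[1]]) == 0 && sd(sp[[2]]) == 0) {
        return(list(test = "t-test (degenerate)", statistic = 0,
                    pvalue = 1, degenerate = TRUE, screen = screen))
      }
      tt <- t.test(sp[[1]], sp[[2]])
      list(test = "two-sample t-test", statistic = unname(tt$statistic),
           pvalue = tt$p.value, degenerate = FALSE, screen = screen)
    } else {
      fit <- summary(aov(values ~ groups))[[1]]
      list(test = "one-way ANOVA", statistic = fit[["F value"]][1],
           pvalue = fit[["Pr(>F)"]][1], degenerate = FALSE,
           screen = screen)
    }
  } else {
    if (k == 2) {
      sp <- split(values, groups)
      wt <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]]))
      list(test = "Wilcoxon rank-sum", statistic = unname(wt$statistic),
           pvalue = wt$p.value, degenerate = FALSE, screen = screen)
    } else {
      kt <- kruskal.test(values, groups)
      list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
           pvalue = kt$p.value,
           degenerate = is.nan(kt$statistic) || is.na(kt$p.value),
           screen = screen)
    }
  }
}

#' Bootstrap confidence interval for an AUC
#'
#' Percentile bootstrap over subjects, stratified by class.
#'
#' @param scores,labels,positive As in [roc_curve()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
auc_ci <- function(scores, labels, positive = NULL, n_boot = 2000,
                   seed = 1L, conf = 0.95) {
  y <- as_binary_labels(labels, positive)
  i1 <- which(y); i0 <- which(!y)
  withr::with_seed(seed, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      roc_curve(scores[idx], y[idx])$auc
    }, numeric(1))
    unname(stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  })
}

#' Clinical biomarker validation report
#'
#' Runs the full validation battery on a cohort table for one comparison:
#' group test on abundance, ROC/AUC with bootstrap CI, Youden cutoff,
#' confusion matrix at the cutoff, and Pearson correlations of abundance
#' with albuminuria and eGFR within the case group.
#'
#' @param cohort Tibble as produced by [simulate_clinical_cohort()]
#'   (columns `group`, `abundance`, `albuminuria_g_24h`, `egfr`).
#' @param case,control Group labels to compare (defaults `"IgAN"` vs
#'   `"HC"`).
#' @param n_boot,seed Bootstrap settings for the AUC CI.
#' @return List with `group_test`, `roc` ([roc_curve()]), `auc`, `auc_ci`,
#'   `cutoff`, `confusion`, `cor_albuminuria`, `cor_egfr`.
#' @export
validate_biomarker <- function(cohort, case = "IgAN", control = "HC",
                               n_boot = 2000, seed = 1L) {
  sub <- cohort[cohort$group %in% c(case, control), ]
  y <- sub$group == case
  gt <- group_compare(sub$abundance, sub$group)
  roc <- roc_curve(sub$abundance, y)
  ci <- auc_ci(sub$abundance, y, n_boot = n_boot, seed = seed)
  cut <- youden_cutoff(roc)
  conf <- confusion_at(sub$abundance, y, as.numeric(cut))
  cases <- cohort[cohort$group == case, ]
  cor_alb <- tryCatch(pearson_r(cases$abundance, cases$albuminuria_g_24h),
                      error = function(e) NULL)
  cor_egfr <- tryCatch(pearson_r(cases$abundance, cases$egfr),
                       error = function(e) NULL)
  list(group_test = gt, roc = roc, auc = roc$auc, auc_ci = ci,
       cutoff = as.numeric(cut), youden = attr(cut, "youden"),
       confusion = conf, cor_albuminuria = cor_alb, cor_egfr = cor_egfr)
}
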