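# Causal-effect estimators over harmonized instruments. Each estimator
# returns a one-row tibble (an MR estimate) with the effect on the log-odds
# scale, its standard error, odds ratio with 95% CI, and a p-value.
#
# Conventions: per-instrument weights are inverse-variance weights on the
# Wald-ratio scale, w_j = 1 / ratio_se_j^2 = beta_exp_j^2 / se_out_j^2.

check_hs <- function(hs, min_n, what) {
  stopifnot(is.data.frame(hs))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out", "ratio", "ratio_se")
  if (!all(need %in% names(hs))) {
    stop("harmonized instruments must carry columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(hs) < min_n) {
    stop(sprintf("%s requires at least %d instruments (got %d)",
                 what, min_n, nrow(hs)))
  }
  invisible(hs)
}

mr_estimate_row <- function(method, beta, se, n_snps, pvalue = NULL,
                            df = NULL, ...) {
  if (is.null(pvalue)) {
    z <- if (se > 0) beta / se else 0
    pvalue <- if (!is.null(df)) {
      2 * pt(abs(z), df = df, lower.tail = FALSE)
    } else {
      2 * pnorm(abs(z), lower.tail = FALSE)
    }
  }
  tibble::tibble(
    method = method,
    beta = beta,
    se = se,
    or_ = exp(beta),
    ci_low = exp(beta - qnorm(0.975) * se),
    ci_high = exp(beta + qnorm(0.975) * se),
    pvalue = pvalue,
    n_snps = as.integer(n_snps),
    ...
  )
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, with first-order standard error `se_out / |beta_exp|`.
#'
#' @param h One harmonized instrument (1-row tibble from [harmonize()]).
#' @return One-row tibble with `method = "wald"`, `beta`, `se`, `or_`,
#'   `ci_low`, `ci_high`, `pvalue`, `n_snps`.
#' @export
wald_ratio <- function(h) {
  check_hs(h, 1, "wald_ratio")
  h <- h[1, ]
  if (h$beta_exp == 0) stop("degenerate instrument: beta_exp = 0")
  mr_estimate_row("wald", h$ratio, h$ratio_se, 1L)
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Combines Wald ratios with inverse-variance weights,
#' `beta = sum(w_j ratio_j) / sum(w_j)` with `w_j = 1/ratio_se_j^2` —
#' algebraically the origin-constrained weighted regression of outcome on
#' exposure effects. The fixed-effect standard error is
#' `(sum w_j)^(-1/2)`; under multiplicative random effects (the default) it
#' is inflated by `max(1, sqrt(Q/(J−1)))`, a scale-up-only correction for
#' between-instrument heterogeneity.
#'
#' @param hs Harmonized instruments ([harmonize()] output), at least 2 rows.
#' @param re_mode `"multiplicative"` (default) or `"fixed"`.
#' @return One-row tibble with `method = "ivw"`.
#' @export
ivw <- function(hs, re_mode = c("multiplicative", "fixed")) {
  re_mode <- match.arg(re_mode)
  if (nrow(hs) == 1) {
    stop("ivw requires >= 2 instruments; use wald_ratio() for a single one")
  }
  check_hs(hs, 2, "ivw")
  w <- 1 / hs$ratio_se^2
  beta <- sum(w * hs$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (re_mode == "multiplicative") {
    q <- sum(w * (hs$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (nrow(hs) - 1)))
  }
  mr_estimate_row("ivw", beta, se, nrow(hs))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`). Instruments are first oriented so every
#' exposure effect is positive. Under the InSIDE assumption (pleiotropic
#' effects independent of instrument strength) the slope estimates the causal
#' effect and the intercept the average directional pleiotropy; an intercept
#' distinguishable from zero signals horizontal pleiotropy. Inference uses
#' the t distribution with J−2 degrees of freedom.
#'
#' @param hs Harmonized instruments, at least 3 rows.
#' @return One-row tibble with `method = "egger"` plus `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
egger <- function(hs) {
  check_hs(hs, 3, "egger")
  flip <- sign(hs$beta_exp)
  flip[flip == 0] <- 1
  x <- hs$beta_exp * flip
  y <- hs$beta_out * flip
  w <- 1 / hs$se_out^2
  # closed-form weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  denom <- sw * swxx - swx^2
  if (denom <= 0) stop("degenerate design: no variation in exposure effects")
  slope <- (sw * swxy - swx * swy) / denom
  inter <- (swxx * swy - swx * swxy) / denom
  j <- nrow(hs)
  resid <- y - inter - slope * x
  # multiplicative overdispersion (scale-up only), as for IVW
  sigma2 <- max(1, sum(w * resid^2) / (j - 2))
  slope_se <- sqrt(sigma2 * sw / denom)
  inter_se <- sqrt(sigma2 * swxx / denom)
  slope_p <- 2 * pt(abs(slope / slope_se), df = j - 2, lower.tail = FALSE)
  inter_p <- 2 * pt(abs(inter / inter_se), df = j - 2, lower.tail = FALSE)
  mr_estimate_row("egger", slope, slope_se, j, pvalue = slope_p,
                  intercept = inter, intercept_se = inter_se,
                  intercept_p = inter_p)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(ratio[1])
  if (s[length(s)] <= 0.5) return(ratio[length(s)])
  below <- max(which(s < 0.5))
  ratio[below] + (ratio[below + 1] - ratio[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

boot_se <- function(hs, point_fun, n_boot, seed) {
  withr::with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(hs), hs$beta_exp, hs$se_exp)
      by <- rnorm(nrow(hs), hs$beta_out, hs$se_out)
      ratio <- by / bx
      w <- bx^2 / hs$se_out^2
      point_fun(ratio, w)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' The median of the Wald ratios under inverse-variance weights: consistent
#' when instruments carrying at least half the total weight are valid, hence
#' more robust to invalid instruments than IVW. Ratios are ordered and the
#' estimate interpolates them at standardized cumulative weight 1/2; the
#' standard error comes from a parametric bootstrap resampling exposure and
#' outcome effects from their normal sampling distributions.
#'
#' @param hs Harmonized instruments, at least 3 rows.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @return One-row tibble with `method = "weighted_median"`.
#' @export
weighted_median <- function(hs, n_boot = 1000, seed = 1L) {
  check_hs(hs, 3, "weighted_median")
  w <- 1 / hs$ratio_se^2
  beta <- weighted_median_point(hs$ratio, w)
  se <- boot_se(hs, weighted_median_point, n_boot, seed)
  mr_estimate_row("weighted_median", beta, se, nrow(hs))
}

# Modified Silverman bandwidth over the ratio estimates.
mode_bandwidth <- function(ratio, bandwidth_factor) {
  spread <- min(sd(ratio), mad(ratio))
  if (!is.finite(spread) || spread <= 0) spread <- sd(ratio)
  if (!is.finite(spread) || spread <= 0) spread <- 1e-8
  h <- bandwidth_factor * 0.9 * spread * length(ratio)^(-1 / 5)
  if (h <= 0) stop("zero bandwidth: check bandwidth_factor and ratios")
  h
}

weighted_mode_point <- function(ratio, w, bandwidth_factor = 1) {
  if (diff(range(ratio)) == 0) return(ratio[1])
  h <- mode_bandwidth(ratio, bandwidth_factor)
  w <- w / sum(w)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * dnorm((xi - ratio) / h)), numeric(1))
  }
  lo <- min(ratio) - 3 * h
  hi <- max(ratio) + 3 * h
  grid <- seq(lo, hi, length.out = 512)
  fx <- dens(grid)
  i <- which.max(fx)
  span <- grid[c(max(1, i - 1), min(length(grid), i + 1))]
  optimize(dens, interval = span, maximum = TRUE, tol = 1e-9)$maximum
}

#' Weighted-mode causal estimate
#'
#' The mode of the weighted Gaussian-kernel density over the Wald ratios:
#' consistent when the largest group of instruments sharing the same causal
#' estimate is valid, even if most instruments individually are not.
#' Bandwidth follows a modified Silverman rule on the ratio estimates,
#' scaled by `bandwidth_factor`. Bootstrap SE as in [weighted_median()].
#'
#' @param hs Harmonized instruments, at least 3 rows.
#' @param bandwidth_factor Positive multiplier on the default bandwidth
#'   (default 1).
#' @param n_boot,seed Bootstrap settings as in [weighted_median()].
#' @return One-row tibble with `method = "weighted_mode"`.
#' @export
weighted_mode <- function(hs, bandwidth_factor = 1, n_boot = 1000,
                          seed = 1L) {
  check_hs(hs, 3, "weighted_mode")
  if (bandwidth_factor <= 0) stop("bandwidth_factor must be positive")
  w <- 1 / hs$ratio_se^2
  beta <- weighted_mode_point(hs$ratio, w, bandwidth_factor)
  se <- boot_se(hs, function(r, wt) weighted_mode_point(r, wt,
                                                        bandwidth_factor),
                n_boot, seed)
  mr_estimate_row("weighted_mode", beta, se, nrow(hs))
}

#' Run all four MR estimators on one instrument set
#'
#' @param hs Harmonized instruments.
#' @param n_boot,seed Bootstrap settings for median/mode standard errors.
#' @param re_mode IVW variance mode (see [ivw()]).
#' @return Tibble with one row per method (IVW first, flagged as primary in
#'   the `primary` column); with exactly one instrument, a single Wald-ratio
#'   row.
#' @export
mr_all_methods <- function(hs, n_boot = 1000, seed = 1L,
                           re_mode = "multiplicative") {
  if (nrow(hs) == 1) {
    out <- wald_ratio(hs)
    out$primary <- TRUE
    return(out)
  }
  rows <- list(ivw(hs, re_mode = re_mode))
  if (nrow(hs) >= 3) {
    rows <- c(rows, list(
      egger(hs),
      weighted_median(hs, n_boot = n_boot, seed = seed),
      weighted_mode(hs, n_boot = n_boot, seed = seed + 1L)
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$primary <- out$method == "ivw"
  out
}
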