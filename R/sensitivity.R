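# Heterogeneity, pleiotropy, outlier and influence diagnostics for one
# exposure-outcome instrument set.

ivw_point <- function(ratio, w) sum(w * ratio) / sum(w)

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j − theta)^2` with inverse-variance weights
#' `w_j = 1/ratio_se_j^2`, compared to the chi-square distribution with J−1
#' degrees of freedom. Large Q indicates the per-variant causal estimates
#' disagree beyond sampling error (heterogeneity, possibly pleiotropy).
#'
#' @param hs Harmonized instruments, at least 2 rows.
#' @param theta Causal effect the instruments are compared against; defaults
#'   to the fixed-effect IVW estimate.
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(hs, theta = NULL) {
  check_hs(hs, 2, "cochran_q")
  w <- 1 / hs$ratio_se^2
  if (is.null(theta)) theta <- ivw_point(hs$ratio, w)
  q <- sum(w * (hs$ratio - theta)^2)
  df <- nrow(hs) - 1L
  list(q_stat = q, q_df = df,
       q_pvalue = pchisq(q, df = df, lower.tail = FALSE))
}

# Observed and simulated leave-one-out weighted residual sums for PRESSO.
# Residual for instrument j uses the IVW slope fitted without j, so an
# outlier cannot mask itself. Weights are outcome-variance weights.
presso_rss <- function(bx, by, se_out) {
  w_ivw <- bx^2 / se_out^2
  ratio <- by / bx
  sw <- sum(w_ivw)
  swr <- sum(w_ivw * ratio)
  theta_loo <- (swr - w_ivw * ratio) / (sw - w_ivw)
  res2 <- (by - theta_loo * bx)^2 / se_out^2
  list(rss = sum(res2), res2 = res2, theta_loo = theta_loo)
}

presso_simulate <- function(hs, n_sim, seed) {
  obs <- presso_rss(hs$beta_exp, hs$beta_out, hs$se_out)
  j <- nrow(hs)
  withr::with_seed(seed, {
    sim_rss <- numeric(n_sim)
    sim_res2 <- matrix(0, n_sim, j)
    for (s in seq_len(n_sim)) {
      bx <- rnorm(j, hs$beta_exp, hs$se_exp)
      by <- rnorm(j, obs$theta_loo * hs$beta_exp, hs$se_out)
      sm <- presso_rss(bx, by, hs$se_out)
      sim_rss[s] <- sm$rss
      sim_res2[s, ] <- sm$res2
    }
    list(obs = obs, sim_rss = sim_rss, sim_res2 = sim_res2)
  })
}

#' MR-PRESSO global pleiotropy test
#'
#' The observed residual sum of squares (each instrument's weighted squared
#' residual about the IVW fit excluding that instrument) is compared to its
#' parametric-simulation null distribution: exposure and outcome effects are
#' redrawn from their normal sampling distributions around the fitted values,
#' `n_sim` times. The p-value uses the add-one rule
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`, so it is never below
#' `1/(n_sim+1)`.
#'
#' @param hs Harmonized instruments, at least 4 rows.
#' @param n_sim Simulation count (default 1000); below 100 a warning is
#'   issued (the p-value is unstable).
#' @param seed Integer seed.
#' @return List with `rss_obs` and `global_p`.
#' @export
presso_global <- function(hs, n_sim = 1000, seed = 1L) {
  check_hs(hs, 4, "presso_global")
  if (n_sim < 100) warning("n_sim < 100: global p-value will be unstable")
  sims <- presso_simulate(hs, n_sim, seed)
  list(rss_obs = sims$obs$rss,
       global_p = (1 + sum(sims$sim_rss >= sims$obs$rss)) / (n_sim + 1))
}

#' MR-PRESSO outlier and distortion tests with outlier-corrected estimate
#'
#' Per-instrument observed weighted squared residuals are compared to their
#' simulated null distributions; the resulting p-values are Bonferroni
#' adjusted by the number of instruments, and instruments with adjusted
#' p <= `alpha` are flagged as outliers (the boundary is inclusive so that
#' `alpha = 1` flags everything). The distortion test compares the IVW
#' estimate shift after removing the flagged outliers to shifts obtained by
#' removing random same-size instrument subsets. The IVW re-estimate on the
#' retained instruments is returned.
#'
#' @param hs Harmonized instruments, at least 4 rows.
#' @param n_sim,seed Simulation settings (shared with the global test).
#' @param alpha Significance level for the adjusted outlier p-values
#'   (default 0.05).
#' @return List with `global_p`, `rss_obs`, `outliers` (tibble `variant_id`,
#'   `outlier_p` of flagged instruments), `outlier_p_all` (every instrument's
#'   adjusted p), `distortion_p` (`NA` when no outlier is found), and
#'   `corrected` (IVW estimate on the retained set).
#' @export
presso <- function(hs, n_sim = 1000, seed = 1L, alpha = 0.05) {
  check_hs(hs, 4, "presso")
  sims <- presso_simulate(hs, n_sim, seed)
  j <- nrow(hs)
  global_p <- (1 + sum(sims$sim_rss >= sims$obs$rss)) / (n_sim + 1)
  raw_p <- vapply(seq_len(j), function(i) {
    (1 + sum(sims$sim_res2[, i] >= sims$obs$res2[i])) / (n_sim + 1)
  }, numeric(1))
  adj_p <- pmin(1, raw_p * j)
  is_out <- adj_p <= alpha
  if (all(is_out)) stop("all instruments flagged as outliers; no estimate possible")
  outliers <- tibble::tibble(variant_id = hs$variant_id[is_out],
                             outlier_p = adj_p[is_out])
  corrected <- ivw(hs[!is_out, , drop = FALSE])
  distortion_p <- NA_real_
  if (any(is_out)) {
    full <- ivw_point(hs$ratio, 1 / hs$ratio_se^2)
    kept <- hs[!is_out, , drop = FALSE]
    d_obs <- ivw_point(kept$ratio, 1 / kept$ratio_se^2) - full
    n_out <- sum(is_out)
    d_null <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        rm_idx <- sample.int(j, n_out)
        sub <- hs[-rm_idx, , drop = FALSE]
        ivw_point(sub$ratio, 1 / sub$ratio_se^2) - full
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }
  list(global_p = global_p, rss_obs = sims$obs$rss, outliers = outliers,
       outlier_p_all = tibble::tibble(variant_id = hs$variant_id,
                                      outlier_p = adj_p),
       distortion_p = distortion_p, corrected = corrected)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate excluding each instrument in turn. A row is
#' flagged when dropping that instrument flips the sign of the estimate or
#' removes nominal significance (full-set p < 0.05 but leave-one-out
#' p >= 0.05) — i.e. the finding leans on that single variant.
#'
#' @param hs Harmonized instruments, at least 3 rows.
#' @param re_mode IVW variance mode (see [ivw()]).
#' @return Tibble with one row per left-out variant: `variant_id`, `beta`,
#'   `se`, `pvalue`, `flag`.
#' @export
leave_one_out <- function(hs, re_mode = "multiplicative") {
  check_hs(hs, 3, "leave_one_out")
  full <- ivw(hs, re_mode = re_mode)
  rows <- lapply(seq_len(nrow(hs)), function(j) {
    est <- ivw(hs[-j, , drop = FALSE], re_mode = re_mode)
    tibble::tibble(variant_id = hs$variant_id[j], beta = est$beta,
                   se = est$se, pvalue = est$pvalue)
  })
  out <- dplyr::bind_rows(rows)
  out$flag <- (sign(out$beta) != sign(full$beta) & full$beta != 0) |
    (full$pvalue < 0.05 & out$pvalue >= 0.05)
  out
}

#' Funnel-plot table
#'
#' Per-instrument Wald ratio against its precision (1/ratio_se), plus the
#' method estimates as vertical reference lines — asymmetry about the
#' reference suggests directional pleiotropy.
#'
#' @param hs Harmonized instruments.
#' @param estimates Optional tibble of method estimates (e.g. from
#'   [mr_all_methods()]) used as reference lines.
#' @return Tibble (`variant_id`, `ratio`, `precision`); attribute
#'   `reference` holds `method`/`beta` reference lines.
#' @export
funnel_table <- function(hs, estimates = NULL) {
  pts <- tibble::tibble(
    variant_id = if (nrow(hs)) hs$variant_id else character(),
    ratio = if (nrow(hs)) hs$ratio else double(),
    precision = if (nrow(hs)) 1 / hs$ratio_se else double()
  )
  ref <- if (!is.null(estimates)) {
    tibble::tibble(method = estimates$method, beta = estimates$beta)
  } else {
    tibble::tibble(method = character(), beta = double())
  }
  attr(pts, "reference") <- ref
  pts
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Cochran's Q, the MR-Egger intercept test, MR-PRESSO global/outlier/
#' distortion tests, and leave-one-out influence — the diagnostics that must
#' all be quiet (p > 0.05, no outliers, no influential single variant) for
#' an MR finding to be trusted.
#'
#' @param hs Harmonized instruments.
#' @param n_sim,seed PRESSO simulation settings.
#' @param alpha Outlier significance level.
#' @return List of class `sensitivity_report` with fields `q_stat`, `q_df`,
#'   `q_pvalue`, `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `presso_global_p`, `presso_outliers`, `presso_distortion_p`, `loo`.
#'   Components whose minimum instrument count is not met are `NA`/`NULL`.
#' @export
sensitivity_report <- function(hs, n_sim = 1000, seed = 1L, alpha = 0.05) {
  rep <- list(q_stat = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
              egger_intercept = NA_real_, egger_intercept_se = NA_real_,
              egger_intercept_p = NA_real_, presso_global_p = NA_real_,
              presso_outliers = tibble::tibble(variant_id = character(),
                                               outlier_p = double()),
              presso_distortion_p = NA_real_, loo = NULL)
  if (nrow(hs) >= 2) {
    q <- cochran_q(hs)
    rep[c("q_stat", "q_df", "q_pvalue")] <- q
  }
  if (nrow(hs) >= 3) {
    eg <- egger(hs)
    rep$egger_intercept <- eg$intercept
    rep$egger_intercept_se <- eg$intercept_se
    rep$egger_intercept_p <- eg$intercept_p
    rep$loo <- leave_one_out(hs)
  }
  if (nrow(hs) >= 4) {
    pr <- tryCatch(presso(hs, n_sim = n_sim, seed = seed, alpha = alpha),
                   error = function(e) NULL)
    if (!is.null(pr)) {
      rep$presso_global_p <- pr$global_p
      rep$presso_outliers <- pr$outliers
      rep$presso_distortion_p <- pr$distortion_p
    }
  }
  structure(rep, class = "sensitivity_report")
}
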