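# Shared fixture builders. All randomness is seeded by the caller.

# Harmonized-instrument tibble straight from exposure/outcome effects.
make_hs <- function(beta_exp, beta_out, se_out, se_exp = NULL,
                    variant_id = NULL) {
  n <- length(beta_exp)
  if (is.null(se_exp)) se_exp <- rep(0.01, n)
  if (is.null(variant_id)) variant_id <- sprintf("rs%03d", seq_len(n))
  tibble::tibble(
    variant_id = variant_id,
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf_exp = rep(0.3, n),
    ratio = beta_out / beta_exp,
    ratio_se = se_out / abs(beta_exp)
  )
}

# A small valid summary-statistics table.
make_records <- function(n = 5, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      variant_id = sprintf("rs%05d", sample.int(99999, n)),
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e8, n),
      effect_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      other_allele = NA_character_,
      eaf = runif(n, 0.05, 0.95),
      beta = rnorm(n, 0, 0.1),
      se = runif(n, 0.005, 0.05),
      pvalue = runif(n, 1e-12, 0.99),
      n = 18340
    ) -> rec
    # pick a different other allele per row
    rec$other_allele <- vapply(rec$effect_allele, function(a) {
      sample(setdiff(c("A", "C", "G", "T"), a), 1)
    }, character(1))
    rec
  })
}

# Weighted least squares (with intercept) via lm(): the independent oracle
# for IVW (origin-constrained) and Egger fits.
lm_ivw_oracle <- function(hs) {
  fit <- stats::lm(beta_out ~ beta_exp - 1, data = hs,
                   weights = 1 / hs$se_out^2)
  unname(stats::coef(fit)[1])
}

lm_egger_oracle <- function(hs) {
  flip <- ifelse(hs$beta_exp < 0, -1, 1)
  d <- data.frame(x = hs$beta_exp * flip, y = hs$beta_out * flip)
  fit <- stats::lm(y ~ x, data = d, weights = 1 / hs$se_out^2)
  unname(stats::coef(fit))  # (intercept, slope)
}

# All-pairs rank form of the AUC: the independent oracle for the ROC curve.
allpairs_auc <- function(scores, labels) {
  s1 <- scores[as.logical(labels)]
  s0 <- scores[!as.logical(labels)]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Combined multi-exposure study: one causal class-level exposure among
# nulls, sharing a single stacked outcome dataset.
make_study <- function(theta_true = log(1.2), j = 50, seed = 1) {
  kinds <- c("class", "genus", "family", "order", "phylum")
  exps <- list()
  outs <- list()
  for (i in seq_along(kinds)) {
    sim <- simulate_summary_pair(
      theta = if (i == 1) theta_true else 0, j = j,
      trait_id = paste0(kinds[i], ".taxonA"), trait_kind = kinds[i],
      seed = 1000 * seed + i)
    exps[[i]] <- sim$exposure
    outs[[i]] <- sim$outcome$records
  }
  outrec <- do.call(rbind, outs)
  outrec <- outrec[!duplicated(outrec$variant_id), ]
  list(exposures = exps,
       outcome = summary_dataset(outrec, trait_id = "IgAN",
                                 trait_kind = "disease"))
}
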