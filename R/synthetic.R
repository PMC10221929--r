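# Synthetic-data generators emulating the study's inputs: two-sample GWAS
# summary statistics under a known causal model, the taxa manifest, and a
# small clinical cohort. Every generator is a pure function of its
# parameters and seed.

# Non-palindromic allele pairs so harmonization keeps every variant.
NONPALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T")
)

#' Simulate an exposure/outcome summary-statistics pair under a known model
#'
#' Generates two-sample MR input data with known truth. Per instrument `j`:
#' a true instrument effect `gamma_j ~ N(gamma_mean, gamma_sd^2)`; the
#' observed exposure effect adds normal sampling noise with a standard error
#' derived from `n_exp` on the standardized-trait scale,
#' `se = 1/sqrt(2 eaf (1-eaf) n_exp)`. The outcome (disease) effect is
#' `theta * gamma_j + alpha_j` plus sampling noise with the binary-trait
#' large-sample standard error
#' `se = 1/sqrt(2 eaf (1-eaf) n_out cf (1-cf))` where `cf` is the case
#' fraction. Pleiotropy `alpha_j` depends on `pleiotropy_mode`:
#' `"none"` (0), `"balanced"` (`N(0, alpha_sd^2)`), `"directional"`
#' (`N(alpha_mean, alpha_sd^2)`), or `"inside_violating"` (correlated with
#' `gamma_j` at `inside_cor`, violating the InSIDE assumption). EAFs are
#' uniform on (0.05, 0.95); instruments are independent (identity LD table).
#'
#' @param theta True causal effect (log-odds per exposure SD).
#' @param j Number of instruments.
#' @param gamma_mean,gamma_sd Instrument-effect distribution (defaults 0.15,
#'   0.08: strong instruments, single-SNP F mostly in the tens to hundreds
#'   at the default sample size).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param alpha_mean,alpha_sd Pleiotropy distribution (defaults 0.02, 0.01).
#' @param inside_cor Correlation between pleiotropy and instrument strength
#'   under `"inside_violating"` (default 0.6).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes (defaults
#'   18340 and 628000, the scale of the microbiota and IgAN meta-analyses).
#' @param case_fraction Outcome case fraction (default 0.01; IgAN is rare).
#' @param trait_id,trait_kind Exposure labelling.
#' @param seed Integer seed.
#' @return List with `exposure` and `outcome` ([summary_dataset()]s), `ld`
#'   (identity [ld_table()]), and `truth` (the generating parameters plus
#'   the drawn `gamma` and `alpha` vectors).
#' @export
simulate_summary_pair <- function(theta, j, gamma_mean = 0.15,
                                  gamma_sd = 0.08,
                                  pleiotropy_mode = c("none", "balanced",
                                                      "directional",
                                                      "inside_violating"),
                                  alpha_mean = 0.02, alpha_sd = 0.01,
                                  inside_cor = 0.6,
                                  n_exp = 18340, n_out = 628000,
                                  case_fraction = 0.01,
                                  trait_id = "sim_exposure",
                                  trait_kind = "class", seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(j >= 1, gamma_sd >= 0, alpha_sd >= 0,
            case_fraction > 0, case_fraction < 1)
  withr::with_seed(seed, {
    ids <- sprintf("rs%06d", sample.int(999999, j))
    # spread instruments across chromosomes, > 10 Mb apart, so that
    # physical-window clumping treats them as independent (as they are)
    chrom <- as.character(1 + (seq_len(j) - 1) %% 22)
    pos <- 20000001L * (1L + (seq_len(j) - 1L) %/% 22L)
    eaf <- runif(j, 0.05, 0.95)
    pair_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), j, replace = TRUE)
    ea <- NONPALINDROMIC_PAIRS[pair_idx, 1]
    oa <- NONPALINDROMIC_PAIRS[pair_idx, 2]
    gamma <- rnorm(j, gamma_mean, gamma_sd)
    alpha <- switch(pleiotropy_mode,
      none = rep(0, j),
      balanced = rnorm(j, 0, alpha_sd),
      directional = rnorm(j, alpha_mean, alpha_sd),
      inside_violating = {
        z <- rnorm(j)
        g_std <- if (gamma_sd > 0) (gamma - gamma_mean) / gamma_sd else
          rep(0, j)
        alpha_mean + alpha_sd * (inside_cor * g_std +
                                   sqrt(1 - inside_cor^2) * z)
      })
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out *
                         case_fraction * (1 - case_fraction))
    beta_exp <- gamma + rnorm(j, 0, se_exp)
    beta_out <- theta * gamma + alpha + rnorm(j, 0, se_out)
    p_exp <- 2 * pnorm(abs(beta_exp) / se_exp, lower.tail = FALSE)
    p_out <- 2 * pnorm(abs(beta_out) / se_out, lower.tail = FALSE)
    p_exp <- pmax(p_exp, .Machine$double.xmin)
    p_out <- pmax(p_out, .Machine$double.xmin)

    exposure <- summary_dataset(
      tibble::tibble(variant_id = ids, chrom = chrom, pos = pos,
                     effect_allele = ea, other_allele = oa, eaf = eaf,
                     beta = beta_exp, se = se_exp, pvalue = p_exp,
                     n = n_exp),
      trait_id = trait_id, trait_kind = trait_kind)
    outcome <- summary_dataset(
      tibble::tibble(variant_id = ids, chrom = chrom, pos = pos,
                     effect_allele = ea, other_allele = oa, eaf = eaf,
                     beta = beta_out, se = se_out, pvalue = p_out,
                     n = n_out),
      trait_id = "sim_disease", trait_kind = "disease")
    truth <- list(theta = theta, j = j, gamma_mean = gamma_mean,
                  gamma_sd = gamma_sd, pleiotropy_mode = pleiotropy_mode,
                  alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                  inside_cor = inside_cor, n_exp = n_exp, n_out = n_out,
                  case_fraction = case_fraction, seed = seed,
                  gamma = gamma, alpha = alpha)
    list(exposure = exposure, outcome = outcome, ld = ld_table(),
         truth = truth)
  })
}

#' Synthetic taxa manifest across taxonomic levels
#'
#' Trait identifiers labelled by taxonomic level, with counts per level.
#' The defaults reproduce the 211-taxon structure of the microbiota GWAS:
#' 131 genera, 35 families, 20 orders, 16 classes, 9 phyla.
#'
#' @param counts Named integer vector: level -> number of traits.
#' @param seed Integer seed (reserved; generation is deterministic).
#' @return Tibble (`trait_id`, `level`) with `sum(counts)` rows.
#' @export
simulate_taxa_manifest <- function(counts = c(genus = 131, family = 35,
                                              order = 20, class = 16,
                                              phylum = 9),
                                   seed = 1L) {
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  rows <- lapply(names(counts), function(lv) {
    k <- counts[[lv]]
    if (k == 0) return(NULL)
    tibble::tibble(trait_id = sprintf("%s.taxon_%03d", lv, seq_len(k)),
                   level = lv)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(trait_id = character(), level = character())
  }
  out
}

#' Simulate a small clinical cohort with a taxon biomarker
#'
#' Per-group relative abundances are drawn from logit-normal distributions
#' (group means on the logit scale); 24-hour albuminuria is a linear
#' function of logit abundance plus normal noise whose variance is
#' calibrated, against the realized spread of the linear predictor, so the
#' correlation between logit abundance and albuminuria equals `target_r`;
#' negative draws are truncated at zero. eGFR is generated around
#' group-specific means with a configurable (possibly zero) dependence on
#' centred logit abundance.
#'
#' @param n_igan,n_hc,n_other Group sizes (defaults 10, 10, 5).
#' @param mu_logit Named numeric: group means of logit abundance (defaults
#'   give typical abundances ~0.22 IgAN, ~0.08 healthy, ~0.11 other GN).
#' @param sd_logit Common logit-scale SD of abundance (default 0.5).
#' @param target_r Target correlation between logit abundance and
#'   albuminuria, in (-1, 1) (default 0.85).
#' @param albuminuria_mean Mean 24-h albuminuria (g/24 h) in the IgAN group
#'   (default 1.3).
#' @param albuminuria_slope Slope of albuminuria on logit abundance
#'   (default 1 g/24 h per logit unit); must be nonzero when
#'   `target_r != 0`.
#' @param egfr_means Named numeric: group eGFR means (mL/min/1.73 m^2).
#' @param egfr_sd Residual eGFR SD (default 10).
#' @param egfr_slope eGFR change per centred logit-abundance unit
#'   (default -14; set 0 for no dependence).
#' @param seed Integer seed.
#' @return Tibble (`subject_id`, `group`, `abundance`, `albuminuria_g_24h`,
#'   `egfr`); attribute `truth` echoes the generating parameters.
#' @export
simulate_clinical_cohort <- function(n_igan = 10, n_hc = 10, n_other = 5,
                                     mu_logit = c(IgAN = -1.27, HC = -2.44,
                                                  OtherGN = -2.09),
                                     sd_logit = 0.5, target_r = 0.85,
                                     albuminuria_mean = 1.3,
                                     albuminuria_slope = 1,
                                     egfr_means = c(IgAN = 55.5, HC = 93.5,
                                                    OtherGN = 17.9),
                                     egfr_sd = 10, egfr_slope = -14,
                                     seed = 1L) {
  if (abs(target_r) >= 1) stop("target_r must lie in (-1, 1)")
  if (target_r != 0 && albuminuria_slope == 0) {
    stop("infeasible: nonzero target_r requires a nonzero albuminuria slope")
  }
  groups <- rep(c("IgAN", "HC", "OtherGN"), times = c(n_igan, n_hc, n_other))
  n <- length(groups)
  withr::with_seed(seed, {
    logit_ab <- rnorm(n, mu_logit[groups], sd_logit)
    abundance <- stats::plogis(logit_ab)
    lin <- albuminuria_slope * logit_ab
    if (target_r == 0) {
      noise_sd <- 0.6
      lin <- lin * 0
    } else {
      spread <- sd(lin)
      if (!is.finite(spread) || spread == 0) {
        stop("infeasible correlation: linear predictor has zero spread")
      }
      noise_sd <- spread * sqrt(1 / target_r^2 - 1)
    }
    alb <- albuminuria_mean +
      (lin - if (target_r == 0) 0 else
        albuminuria_slope * mu_logit[["IgAN"]]) +
      rnorm(n, 0, noise_sd)
    alb <- pmax(alb, 0)
    egfr <- egfr_means[groups] +
      egfr_slope * (logit_ab - mu_logit[groups]) + rnorm(n, 0, egfr_sd)
    egfr <- pmax(egfr, 5)
    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = groups,
      abundance = abundance,
      albuminuria_g_24h = alb,
      egfr = egfr
    )
    attr(out, "truth") <- list(n_igan = n_igan, n_hc = n_hc,
                               n_other = n_other, mu_logit = mu_logit,
                               sd_logit = sd_logit, target_r = target_r,
                               albuminuria_slope = albuminuria_slope,
                               seed = seed)
    out
  })
}
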