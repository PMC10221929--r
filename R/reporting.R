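# Multiple-testing scheme, significance classification, and the forward /
# reverse pipeline orchestration.

#' Per-level Bonferroni correction scheme
#'
#' The correction divisor is the number of traits tested at each taxonomic
#' level (defaults: 131 genera, 35 families, 20 orders, 16 classes, 9 phyla)
#' plus the metabolite panel (15), each dividing the family-wise level
#' `alpha`.
#'
#' @param m Named integer vector: trait kind -> number of tests.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `bonferroni_scheme`.
#' @export
bonferroni_scheme <- function(m = c(genus = 131, family = 35, order = 20,
                                    class = 16, phylum = 9,
                                    metabolite = 15),
                              alpha = 0.05) {
  stopifnot(all(m >= 1), alpha > 0, alpha < 1)
  structure(list(m = m, alpha = alpha), class = "bonferroni_scheme")
}

#' Bonferroni-corrected threshold for a trait kind
#' @param scheme A [bonferroni_scheme()].
#' @param kind Trait kind, e.g. `"class"`.
#' @return `alpha / m[kind]`.
#' @export
bonferroni_threshold <- function(scheme, kind) {
  stopifnot(inherits(scheme, "bonferroni_scheme"))
  if (!kind %in% names(scheme$m)) {
    stop("no Bonferroni divisor configured for trait kind '", kind, "'")
  }
  scheme$alpha / scheme$m[[kind]]
}

#' Classify an MR p-value against the per-level scheme
#'
#' `significant` when `p < threshold` (the Bonferroni-corrected level),
#' `nominal` when `threshold <= p < alpha`, else `null`. Comparisons are
#' strict at both boundaries (closed-open nominal band).
#'
#' @param pvalue MR p-value (vectorized).
#' @param threshold Corrected threshold (`alpha/m`).
#' @param alpha Family-wise level (default 0.05).
#' @return Character vector: `"significant"`, `"nominal"` or `"null"`.
#' @export
classify_estimate <- function(pvalue, threshold, alpha = 0.05) {
  stopifnot(threshold <= alpha)
  ifelse(pvalue < threshold, "significant",
         ifelse(pvalue < alpha, "nominal", "null"))
}

default_pipeline_params <- function() {
  list(p_threshold = 1e-5, p_threshold_metabolite = 5e-5,
       r2_max = 0.001, window_kb = 10000, eaf_min = 0.01, f_min = 10,
       outcome_p_cut = 0.05, palindrome_eaf_window = 0.08,
       blacklist = character(), alpha = 0.05, n_boot = 1000, n_sim = 1000,
       sensitivity = TRUE,
       re_mode = "multiplicative", seed = 1L)
}

resolve_dataset <- function(x, trait_id = NULL, trait_kind = "genus") {
  if (inherits(x, "summary_dataset")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_summary_table(x, trait_id = trait_id %||% basename(x),
                              trait_kind = trait_kind))
  }
  stop("expected a summary_dataset or a file path")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyze_one_exposure <- function(exposure, outcome, ld, params, scheme,
                                 seed) {
  p_thr <- if (exposure$trait_kind == "metabolite") {
    params$p_threshold_metabolite
  } else {
    params$p_threshold
  }
  instr <- select_instruments(
    exposure, outcome, ld = ld, p_threshold = p_thr,
    r2_max = params$r2_max, window_kb = params$window_kb,
    eaf_min = params$eaf_min, f_min = params$f_min,
    outcome_p_cut = params$outcome_p_cut, blacklist = params$blacklist)
  hs <- harmonize(instr$dataset, outcome,
                  palindrome_eaf_window = params$palindrome_eaf_window)
  if (nrow(hs) == 0) {
    return(list(trait_id = exposure$trait_id,
                trait_kind = exposure$trait_kind, status = "no instruments",
                n_snps = 0L, estimates = NULL, sensitivity = NULL,
                verdict = NA_character_, audit = instr$audit))
  }
  estimates <- mr_all_methods(hs, n_boot = params$n_boot, seed = seed,
                              re_mode = params$re_mode)
  sens <- if (isTRUE(params$sensitivity) && nrow(hs) >= 2) {
    sensitivity_report(hs, n_sim = params$n_sim, seed = seed + 1L,
                       alpha = params$alpha)
  } else {
    NULL
  }
  primary <- estimates[estimates$primary, ][1, ]
  thr <- bonferroni_threshold(scheme, exposure$trait_kind)
  verdict <- classify_estimate(primary$pvalue, thr, scheme$alpha)
  list(trait_id = exposure$trait_id, trait_kind = exposure$trait_kind,
       status = "ok", n_snps = nrow(hs), estimates = estimates,
       sensitivity = sens, verdict = verdict, audit = instr$audit,
       instruments = hs)
}

#' Run the forward MR pipeline over a set of exposures
#'
#' Per exposure: instrument screening, harmonization against the outcome,
#' the four estimators (IVW flagged as primary), the sensitivity battery,
#' and Bonferroni classification at the exposure's taxonomic level.
#' Deterministic under a fixed config seed (per-exposure seeds are derived
#' from it).
#'
#' @param config List with elements:
#'   * `exposures`: named list of [summary_dataset()]s (or file paths);
#'   * `outcome`: outcome [summary_dataset()] (or path);
#'   * `ld`: optional [ld_table()] (or TSV path);
#'   * `scheme`: optional [bonferroni_scheme()];
#'   * `params`: optional overrides of the screening/estimation defaults
#'     (`p_threshold` 1e-5, `p_threshold_metabolite` 5e-5, `r2_max` 0.001,
#'     `window_kb` 10000, `eaf_min` 0.01, `f_min` 10, `outcome_p_cut` 0.05,
#'     `palindrome_eaf_window` 0.08, `alpha` 0.05, `n_boot`/`n_sim` 1000,
#'     `seed` 1).
#' @return List of class `mr_pipeline_result`: `results` (tibble, one row
#'   per exposure x method with OR, CI, p), `classified` (one row per
#'   exposure: `trait_id`, `trait_kind`, `status`, `n_snps`, IVW estimate,
#'   `verdict`), `sensitivity` (named list of [sensitivity_report()]s),
#'   `audit` (named list of exclusion tibbles).
#' @export
run_pipeline <- function(config) {
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  scheme <- config$scheme %||% bonferroni_scheme(alpha = params$alpha)
  outcome <- resolve_dataset(config$outcome, trait_kind = "disease")
  ld <- config$ld %||% ld_table()
  if (is.character(ld)) ld <- read_ld_table(ld)
  exposures <- config$exposures
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1)

  results <- list()
  classified <- list()
  sens_list <- list()
  audit_list <- list()
  for (i in seq_along(exposures)) {
    exp_ds <- resolve_dataset(exposures[[i]])
    res <- analyze_one_exposure(exp_ds, outcome, ld, params, scheme,
                                seed = params$seed + 1000L * i)
    audit_list[[res$trait_id]] <- res$audit
    if (res$status == "ok") {
      est <- res$estimates
      est$trait_id <- res$trait_id
      est$trait_kind <- res$trait_kind
      results[[res$trait_id]] <- est
      sens_list[[res$trait_id]] <- res$sensitivity
      primary <- est[est$primary, ][1, ]
      classified[[res$trait_id]] <- tibble::tibble(
        trait_id = res$trait_id, trait_kind = res$trait_kind,
        status = res$status, n_snps = res$n_snps, beta = primary$beta,
        se = primary$se, or_ = primary$or_, ci_low = primary$ci_low,
        ci_high = primary$ci_high, pvalue = primary$pvalue,
        verdict = res$verdict)
    } else {
      classified[[res$trait_id]] <- tibble::tibble(
        trait_id = res$trait_id, trait_kind = res$trait_kind,
        status = res$status, n_snps = 0L, beta = NA_real_, se = NA_real_,
        or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        pvalue = NA_real_, verdict = NA_character_)
    }
  }
  structure(list(
    results = if (length(results)) dplyr::bind_rows(results) else
      tibble::tibble(),
    classified = dplyr::bind_rows(classified),
    sensitivity = sens_list,
    audit = audit_list,
    scheme = scheme,
    params = params
  ), class = "mr_pipeline_result")
}

#' Run the reverse-direction MR analysis
#'
#' Swaps the causal roles: the disease is the exposure (instruments are
#' selected from the disease GWAS at `p_threshold`) and each original
#' exposure trait is analysed as an outcome, probing reverse causation.
#'
#' @param config As in [run_pipeline()]; `config$outcome` is the disease
#'   dataset used as the exposure, `config$exposures` are analysed as
#'   outcomes.
#' @return An `mr_pipeline_result` over the reversed pairs.
#' @export
run_reverse <- function(config) {
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  scheme <- config$scheme %||% bonferroni_scheme(alpha = params$alpha)
  disease <- resolve_dataset(config$outcome, trait_kind = "disease")
  ld <- config$ld %||% ld_table()
  if (is.character(ld)) ld <- read_ld_table(ld)
  exposures <- config$exposures
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)

  results <- list(); classified <- list(); sens_list <- list()
  audit_list <- list()
  for (i in seq_along(exposures)) {
    target <- resolve_dataset(exposures[[i]])
    res <- analyze_one_exposure(disease, target, ld, params, scheme,
                                seed = params$seed + 1000L * i)
    label <- paste0("IgAN->", target$trait_id)
    audit_list[[label]] <- res$audit
    thr <- bonferroni_threshold(scheme, target$trait_kind)
    if (res$status == "ok") {
      est <- res$estimates
      est$trait_id <- label
      est$trait_kind <- target$trait_kind
      results[[label]] <- est
      sens_list[[label]] <- res$sensitivity
      primary <- est[est$primary, ][1, ]
      classified[[label]] <- tibble::tibble(
        trait_id = label, trait_kind = target$trait_kind,
        status = res$status, n_snps = res$n_snps, beta = primary$beta,
        se = primary$se, or_ = primary$or_, ci_low = primary$ci_low,
        ci_high = primary$ci_high, pvalue = primary$pvalue,
        verdict = classify_estimate(primary$pvalue, thr, scheme$alpha))
    } else {
      classified[[label]] <- tibble::tibble(
        trait_id = label, trait_kind = target$trait_kind,
        status = res$status, n_snps = 0L, beta = NA_real_, se = NA_real_,
        or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        pvalue = NA_real_, verdict = NA_character_)
    }
  }
  structure(list(
    results = if (length(results)) dplyr::bind_rows(results) else
      tibble::tibble(),
    classified = dplyr::bind_rows(classified),
    sensitivity = sens_list,
    audit = audit_list,
    scheme = scheme,
    params = params
  ), class = "mr_pipeline_result")
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  cat(sprintf("<mr_pipeline_result> %d exposures (%d with instruments)\n",
              nrow(x$classified), sum(x$classified$status == "ok")))
  if (nrow(x$classified)) {
    tab <- table(x$classified$verdict, useNA = "ifany")
    cat("  verdicts:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write the per-method results table to TSV
#'
#' Columns mirror the standard MR results layout: exposure, method, odds
#' ratio, 95% CI bounds, p-value, instrument count.
#'
#' @param result An `mr_pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path) {
  stopifnot(inherits(result, "mr_pipeline_result"))
  res <- result$results
  cols <- c("trait_id", "method", "or_", "ci_low", "ci_high", "pvalue",
            "n_snps")
  out <- if (nrow(res)) res[, cols] else
    setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize the sensitivity reports to JSON
#'
#' @param result An `mr_pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_json <- function(result, path) {
  stopifnot(inherits(result, "mr_pipeline_result"))
  payload <- lapply(result$sensitivity, function(s) {
    if (is.null(s)) return(NULL)
    unclass(s)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
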