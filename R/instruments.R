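# Instrument screening: significance, LD independence, strength, frequency,
# and outcome/confounder exclusions. Each filter is a pure predicate over the
# dataset; exclusions are recorded on an "excluded" attribute so the pipeline
# can assemble a complete audit trail (retained + excluded = candidates).

excluded_tbl <- function(variant_id = character(), reason = character()) {
  tibble::tibble(variant_id = variant_id, reason = reason)
}

subset_with_audit <- function(ds, keep, reason) {
  rec <- ds$records
  out <- ds
  out$records <- rec[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded_tbl(rec$variant_id[!keep],
                                        rep(reason, sum(!keep)))
  attr(out, "rejections") <- attr(ds, "rejections")
  out
}

#' Build a pairwise LD lookup table
#'
#' Stores r-squared for unordered variant pairs. Pairs absent from the table
#' are treated as r² = 0 (independent); a variant with itself has r² = 1.
#'
#' @param pairs Data frame with columns `variant_a`, `variant_b`, `r2`
#'   (fractions in \[0, 1\]), or `NULL` for an empty (identity) table.
#' @return An `ld_table` object.
#' @export
ld_table <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- tibble::tibble(variant_a = character(), variant_b = character(),
                            r2 = double())
  }
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) stop("r2 must lie in [0,1]")
  key <- ifelse(pairs$variant_a < pairs$variant_b,
                paste(pairs$variant_a, pairs$variant_b, sep = "\r"),
                paste(pairs$variant_b, pairs$variant_a, sep = "\r"))
  env <- new.env(parent = emptyenv(), size = max(64L, nrow(pairs)))
  for (i in seq_len(nrow(pairs))) assign(key[i], pairs$r2[i], envir = env)
  structure(list(env = env, n_pairs = nrow(pairs)), class = "ld_table")
}

#' Read an LD table from a TSV file (`variant_a`, `variant_b`, `r2`)
#' @param path Path to a tab-separated file with header.
#' @return An [ld_table()].
#' @export
read_ld_table <- function(path) {
  ld_table(read.delim(path, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "numeric")))
}

#' Look up pairwise r-squared
#' @param ld An [ld_table()].
#' @param a,b Variant identifiers (vectorized).
#' @return Numeric vector of r² values; missing pairs give 0, `a == b` gives 1.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- numeric(length(key))
  for (i in seq_along(key)) {
    if (a[i] == b[i]) {
      out[i] <- 1
    } else {
      out[i] <- mget(key[i], envir = ld$env,
                     ifnotfound = list(0))[[1]]
    }
  }
  out
}

#' Retain variants below a significance threshold
#'
#' The locus-wide instrument screen: keeps rows with `pvalue < threshold`.
#' Microbiota exposures conventionally use 1e-5; metabolites, for which too
#' few variants reach that level, use a relaxed 5e-5.
#'
#' @param ds A [summary_dataset()].
#' @param threshold Significance level in (0, 1\].
#' @return Filtered `summary_dataset` with an `excluded` audit attribute.
#' @export
select_by_pvalue <- function(ds, threshold = 1e-5) {
  stopifnot(inherits(ds, "summary_dataset"), threshold > 0, threshold <= 1)
  subset_with_audit(ds, ds$records$pvalue < threshold,
                    sprintf("pvalue >= %g", threshold))
}

#' Greedy LD clumping
#'
#' Iteratively keeps the most significant remaining variant and discards all
#' others with r² above `r2_max` against it, or (when the LD pair is absent
#' from the table) lying within `window_kb` of it on the same chromosome.
#' Ties in p-value break lexicographically on `variant_id`, so the result is
#' deterministic.
#'
#' @param ds A [summary_dataset()] of candidate instruments.
#' @param ld An [ld_table()].
#' @param r2_max Maximum allowed pairwise r² (default 0.001).
#' @param window_kb Physical pruning window in kilobases (default 10000);
#'   applied only when positions are available and the LD pair is missing.
#' @return Filtered `summary_dataset`; retained variants are pairwise
#'   independent at `r2_max`.
#' @export
greedy_ld_clump <- function(ds, ld = ld_table(), r2_max = 0.001,
                            window_kb = 10000) {
  stopifnot(inherits(ds, "summary_dataset"))
  rec <- ds$records
  if (nrow(rec) <= 1) return(subset_with_audit(ds, rep(TRUE, nrow(rec)),
                                               "ld"))
  ord <- order(rec$pvalue, rec$variant_id)
  keep_ids <- character(0)
  drop_ids <- character(0)
  drop_reason <- character(0)
  remaining <- ord
  while (length(remaining) > 0) {
    idx <- remaining[1]
    keep_ids <- c(keep_ids, rec$variant_id[idx])
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    r2 <- ld_r2(ld, rep(rec$variant_id[idx], length(remaining)),
                rec$variant_id[remaining])
    in_ld <- r2 > r2_max
    # physical window applies only where no LD estimate exists
    near <- rep(FALSE, length(remaining))
    if (!all(is.na(rec$pos))) {
      same_chr <- !is.na(rec$chrom[remaining]) & !is.na(rec$chrom[idx]) &
        rec$chrom[remaining] == rec$chrom[idx]
      has_pos <- !is.na(rec$pos[remaining]) & !is.na(rec$pos[idx])
      no_ld_entry <- r2 == 0
      near <- same_chr & has_pos & no_ld_entry &
        abs(rec$pos[remaining] - rec$pos[idx]) <= window_kb * 1000
    }
    prune <- in_ld | near
    if (any(prune)) {
      drop_ids <- c(drop_ids, rec$variant_id[remaining[prune]])
      drop_reason <- c(drop_reason,
                       ifelse(in_ld[prune],
                              sprintf("r2 > %g with %s", r2_max,
                                      rec$variant_id[idx]),
                              sprintf("within %d kb of %s", window_kb,
                                      rec$variant_id[idx])))
      remaining <- remaining[!prune]
    }
  }
  keep <- rec$variant_id %in% keep_ids
  out <- subset_with_audit(ds, keep, "ld")
  attr(out, "excluded") <- excluded_tbl(drop_ids, drop_reason)
  out
}

#' Per-variant instrument strength
#'
#' Variance explained by a single variant on the standardized trait scale,
#' `R² = 2·EAF·(1−EAF)·β²`, and the instrument F-statistic
#' `F = (R²/(1−R²)) · ((N−K−1)/K)` with `K` the number of instruments the
#' strength is judged against (default 1: single-SNP screening).
#'
#' @param eaf,beta,n Effect-allele frequency, effect size and sample size
#'   (vectorized).
#' @param k Instrument count in the F formula (default 1).
#' @return Tibble with columns `r2_explained` and `F`.
#' @export
instrument_strength <- function(eaf, beta, n, k = 1) {
  stopifnot(k >= 1)
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1, na.rm = TRUE)) {
    stop("degenerate input: per-variant R^2 >= 1")
  }
  f <- (r2 / (1 - r2)) * ((n - k - 1) / k)
  tibble::tibble(r2_explained = r2, F = f)
}

#' Drop weak instruments (F below a threshold)
#' @param ds A [summary_dataset()].
#' @param f_min Minimum F-statistic retained (default 10).
#' @param k Instrument count used in the F formula (default 1).
#' @return Filtered `summary_dataset`; audit in `excluded` attribute.
#' @export
filter_weak <- function(ds, f_min = 10, k = 1) {
  stopifnot(inherits(ds, "summary_dataset"))
  st <- instrument_strength(ds$records$eaf, ds$records$beta, ds$records$n, k)
  out <- subset_with_audit(ds, st$F >= f_min, sprintf("F < %g", f_min))
  attr(out, "strength") <- st[st$F >= f_min, , drop = FALSE]
  out
}

#' Drop rare variants by allele frequency
#'
#' By default the filter is minor-allele symmetric: a variant is kept only
#' when both `eaf` and `1 − eaf` are at least `eaf_min`. Set
#' `symmetric = FALSE` for the literal effect-allele reading (`eaf >= eaf_min`
#' only).
#'
#' @param ds A [summary_dataset()].
#' @param eaf_min Minimum allele frequency (default 0.01).
#' @param symmetric Apply the bound to both alleles (default `TRUE`).
#' @return Filtered `summary_dataset`.
#' @export
filter_eaf <- function(ds, eaf_min = 0.01, symmetric = TRUE) {
  stopifnot(inherits(ds, "summary_dataset"))
  keep <- ds$records$eaf >= eaf_min
  if (symmetric) keep <- keep & (1 - ds$records$eaf) >= eaf_min
  subset_with_audit(ds, keep, sprintf("EAF < %g", eaf_min))
}

#' Drop instruments associated with the outcome
#'
#' Removes instruments whose outcome p-value falls below `p_cut` (they may act
#' directly on the outcome, violating the exclusion restriction). Variants
#' absent from the outcome dataset are kept but flagged in the audit.
#'
#' @param ds Exposure instruments ([summary_dataset()]).
#' @param outcome Outcome [summary_dataset()].
#' @param p_cut Outcome-association threshold (default 0.05).
#' @return Filtered `summary_dataset`; the `flagged` attribute lists variants
#'   missing from the outcome.
#' @export
exclude_outcome_associated <- function(ds, outcome, p_cut = 0.05) {
  stopifnot(inherits(ds, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  idx <- match(ds$records$variant_id, outcome$records$variant_id)
  p_out <- outcome$records$pvalue[idx]
  drop <- !is.na(p_out) & p_out < p_cut
  out <- subset_with_audit(ds, !drop,
                           sprintf("outcome-associated (p < %g)", p_cut))
  missing_ids <- ds$records$variant_id[is.na(p_out)]
  attr(out, "flagged") <- excluded_tbl(missing_ids,
                                       rep("absent from outcome dataset",
                                           length(missing_ids)))
  out
}

#' Remove blacklisted (confounder-associated) variants
#'
#' Static replacement for interactive confounder lookups: variants known to
#' associate with confounders of the exposure-outcome relation (e.g.
#' hypertension, autoimmune disease) are excluded by identifier.
#'
#' @param ds A [summary_dataset()].
#' @param blacklist Character vector of variant identifiers.
#' @return Filtered `summary_dataset`.
#' @export
apply_blacklist <- function(ds, blacklist = character()) {
  stopifnot(inherits(ds, "summary_dataset"))
  subset_with_audit(ds, !ds$records$variant_id %in% blacklist,
                    "blacklisted (confounder-associated)")
}

#' Full instrument-selection screen for one exposure
#'
#' Applies, in order: significance threshold, LD clumping, allele-frequency
#' filter, weak-instrument (F) filter, outcome-association exclusion and the
#' confounder blacklist, accumulating a complete audit trail.
#'
#' @param exposure Exposure [summary_dataset()].
#' @param outcome Outcome [summary_dataset()].
#' @param ld An [ld_table()] (default: empty, all variants independent).
#' @param p_threshold Instrument significance threshold (default 1e-5;
#'   metabolites conventionally 5e-5).
#' @param r2_max,window_kb LD-clumping parameters (defaults 0.001, 10000).
#' @param eaf_min Allele-frequency floor (default 0.01).
#' @param f_min Minimum instrument F (default 10).
#' @param outcome_p_cut Outcome-association exclusion threshold (default 0.05).
#' @param blacklist Confounder-associated variant identifiers.
#' @return List of class `instrument_set`: `trait_id`, `variants` (tibble with
#'   per-variant statistics, `r2_explained`, `F`), and `audit` (tibble
#'   `variant_id`, `reason`, `stage` covering every excluded candidate).
#' @export
select_instruments <- function(exposure, outcome, ld = ld_table(),
                               p_threshold = 1e-5, r2_max = 0.001,
                               window_kb = 10000, eaf_min = 0.01,
                               f_min = 10, outcome_p_cut = 0.05,
                               blacklist = character()) {
  audit <- tibble::tibble(variant_id = character(), reason = character(),
                          stage = character())
  grab <- function(ds, stage) {
    ex <- attr(ds, "excluded")
    if (!is.null(ex) && nrow(ex) > 0) {
      ex$stage <- stage
      audit <<- dplyr::bind_rows(audit, ex)
    }
    ds
  }
  ds <- grab(select_by_pvalue(exposure, p_threshold), "pvalue")
  ds <- grab(greedy_ld_clump(ds, ld, r2_max, window_kb), "ld_clump")
  ds <- grab(filter_eaf(ds, eaf_min), "eaf")
  ds <- grab(filter_weak(ds, f_min), "weak_f")
  ds <- grab(exclude_outcome_associated(ds, outcome, outcome_p_cut),
             "outcome_assoc")
  ds <- grab(apply_blacklist(ds, blacklist), "blacklist")
  st <- instrument_strength(ds$records$eaf, ds$records$beta, ds$records$n)
  variants <- dplyr::bind_cols(ds$records, st)
  structure(list(trait_id = exposure$trait_id, variants = variants,
                 audit = audit, dataset = ds),
            class = "instrument_set")
}
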