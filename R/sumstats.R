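#' @importFrom stats pnorm pchisq pt qnorm rnorm runif sd mad median
#'   shapiro.test bartlett.test t.test wilcox.test aov kruskal.test
#'   chisq.test cor cor.test dnorm optimize setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

# Canonical column order for summary-statistic tables.
SUMSTATS_COLUMNS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics dataset
#'
#' A `summary_dataset` holds per-variant association statistics for one trait:
#' one row per variant with effect/other allele, effect-allele frequency (EAF),
#' effect size (log-odds for binary traits), standard error, p-value and sample
#' size. Rows violating the type invariants (`se > 0`, `0 < eaf < 1`, alleles
#' in A/C/G/T and distinct, `pvalue` in (0, 1], `n > 0`) are rejected and
#' reported in the `rejections` attribute.
#'
#' @param records Data frame with (at least) columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`;
#'   optional `chrom` and `pos`.
#' @param trait_id Trait identifier, e.g. `"class.Actinobacteria"`.
#' @param trait_kind One of `"genus"`, `"family"`, `"order"`, `"class"`,
#'   `"phylum"`, `"metabolite"`, `"disease"`.
#' @param validate If `TRUE` (default), drop and report invalid rows.
#' @return A `summary_dataset`: list with `trait_id`, `trait_kind` and a
#'   tibble `records`; attribute `rejections` is a tibble
#'   (`row`, `variant_id`, `reason`) describing dropped rows.
#' @export
summary_dataset <- function(records, trait_id, trait_kind = "genus",
                            validate = TRUE) {
  kinds <- c("genus", "family", "order", "class", "phylum", "metabolite",
             "disease")
  if (!trait_kind %in% kinds) {
    stop("trait_kind must be one of: ", paste(kinds, collapse = ", "))
  }
  records <- tibble::as_tibble(records)
  required <- setdiff(SUMSTATS_COLUMNS, c("chrom", "pos"))
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("records lacks required columns: ", paste(missing, collapse = ", "))
  }
  if (!"chrom" %in% names(records)) records$chrom <- NA_character_
  if (!"pos" %in% names(records)) records$pos <- NA_integer_
  records <- records[, SUMSTATS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$n <- as.numeric(records$n)

  rejections <- tibble::tibble(row = integer(), variant_id = character(),
                               reason = character())
  if (validate && nrow(records) > 0) {
    reason <- rep(NA_character_, nrow(records))
    bad <- function(cond, why) {
      cond[is.na(cond)] <- TRUE
      ifelse(is.na(reason) & cond, why, reason)
    }
    reason <- bad(!records$effect_allele %in% VALID_ALLELES |
                    !records$other_allele %in% VALID_ALLELES,
                  "allele not in A/C/G/T")
    reason <- bad(records$effect_allele == records$other_allele,
                  "effect and other allele identical")
    reason <- bad(!(records$eaf > 0 & records$eaf < 1), "eaf outside (0,1)")
    reason <- bad(!(records$se > 0), "se not positive")
    reason <- bad(!(records$pvalue > 0 & records$pvalue <= 1),
                  "pvalue outside (0,1]")
    reason <- bad(!(records$n > 0), "n not positive")
    reason <- bad(is.na(records$beta), "beta missing")
    drop <- !is.na(reason)
    if (any(drop)) {
      rejections <- tibble::tibble(
        row = which(drop),
        variant_id = records$variant_id[drop],
        reason = reason[drop]
      )
      records <- records[!drop, , drop = FALSE]
    }
  }
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id within dataset: ",
         records$variant_id[duplicated(records$variant_id)][1])
  }
  structure(
    list(trait_id = trait_id, trait_kind = trait_kind, records = records),
    rejections = rejections,
    class = "summary_dataset"
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s [%s], %d variants\n",
              x$trait_id, x$trait_kind, nrow(x$records)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat(sprintf("  %d rows rejected on read (see attr 'rejections')\n",
                nrow(rej)))
  }
  print(head(x$records, 5), ...)
  invisible(x)
}

#' Read a tab-separated GWAS summary-statistics table
#'
#' Expects a header line; non-canonical column names are translated through
#' `column_map`. Rows that fail validation are dropped and listed (with line
#' numbers) in the `rejections` attribute of the result.
#'
#' @param path Path to a TSV file.
#' @param trait_id,trait_kind Trait metadata (see [summary_dataset()]).
#' @param column_map Named character vector mapping canonical names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, optionally `chrom`, `pos`) to the file's column names.
#'   Defaults to the identity mapping on the canonical header.
#' @return A [summary_dataset()].
#' @export
read_summary_table <- function(path, trait_id = basename(path),
                               trait_kind = "genus",
                               column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  if (is.null(column_map)) {
    column_map <- setNames(SUMSTATS_COLUMNS, SUMSTATS_COLUMNS)
  }
  required <- setdiff(SUMSTATS_COLUMNS, c("chrom", "pos"))
  for (canon in required) {
    src <- if (canon %in% names(column_map)) column_map[[canon]] else canon
    if (!src %in% names(raw)) {
      stop(sprintf("mapped column '%s' (for '%s') not found in %s",
                   src, canon, path))
    }
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in SUMSTATS_COLUMNS) {
    src <- if (canon %in% names(column_map)) column_map[[canon]] else canon
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  # flag unparseable numerics with their file line (header = line 1)
  for (col in c("eaf", "beta", "se", "pvalue", "n", "pos")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- !is.na(out[[col]]) & nzchar(out[[col]]) & is.na(vals)
    if (any(bad) && col != "pos") {
      warning(sprintf("%s: unparseable %s at file line(s) %s", path, col,
                      paste(which(bad) + 1L, collapse = ", ")))
    }
    out[[col]] <- vals
  }
  ds <- summary_dataset(out, trait_id = trait_id, trait_kind = trait_kind)
  rej <- attr(ds, "rejections")
  if (nrow(rej) > 0) {
    rej$line <- rej$row + 1L
    attr(ds, "rejections") <- rej
  }
  ds
}

#' Write a summary-statistics dataset to TSV
#'
#' Values are printed at full double precision so that
#' [read_summary_table()] inverts the file exactly.
#'
#' @param ds A [summary_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  rec <- ds$records
  fmt <- rec
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    fmt[[col]] <- sprintf("%.17g", rec[[col]])
  }
  fmt$pos <- ifelse(is.na(rec$pos), "NA", as.character(rec$pos))
  fmt$chrom <- ifelse(is.na(rec$chrom), "NA", rec$chrom)
  ok <- tryCatch({
    write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' For every variant present in both datasets the outcome effect is aligned to
#' the exposure's effect allele: matching alleles are kept as-is; swapped
#' effect/other alleles flip the sign of the outcome beta (and reflect its
#' EAF); inconsistent allele pairs are dropped. Palindromic variants (A/T or
#' C/G) whose exposure EAF lies within `palindrome_eaf_window` of 0.5 are
#' dropped because their strand cannot be resolved from frequency. The Wald
#' ratio `beta_out / beta_exp` and its first-order delta-method standard error
#' `se_out / |beta_exp|` are computed on the aligned scale.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param palindrome_eaf_window Half-width of the EAF window around 0.5 inside
#'   which palindromic variants are dropped (default 0.08).
#' @return A tibble of harmonized instruments with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `ratio`,
#'   `ratio_se`; attribute `dropped` records discarded variants and reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$variant_id, ou$variant_id)
  dropped <- tibble::tibble(variant_id = character(), reason = character())
  if (length(shared) == 0) {
    warning("no shared variants between exposure and outcome datasets")
    out <- tibble::tibble(
      variant_id = character(), beta_exp = double(), se_exp = double(),
      beta_out = double(), se_out = double(), eaf_exp = double(),
      ratio = double(), ratio_se = double()
    )
    attr(out, "dropped") <- dropped
    return(out)
  }
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)
  ambiguous <- palin &
    abs(ex$eaf - 0.5) <= palindrome_eaf_window
  zero_exp <- ex$beta == 0

  keep <- (same | swapped) & !ambiguous & !zero_exp
  if (any(!keep)) {
    why <- ifelse(!(same | swapped), "allele mismatch",
                  ifelse(ambiguous, "palindromic with EAF near 0.5",
                         "zero exposure effect"))
    dropped <- tibble::tibble(variant_id = shared[!keep],
                              reason = why[!keep])
  }
  ex <- ex[keep, ]
  ou <- ou[keep, ]
  flip <- swapped[keep]
  beta_out <- ifelse(flip, -ou$beta, ou$beta)

  out <- tibble::tibble(
    variant_id = ex$variant_id,
    beta_exp = ex$beta,
    se_exp = ex$se,
    beta_out = beta_out,
    se_out = ou$se,
    eaf_exp = ex$eaf,
    ratio = beta_out / ex$beta,
    ratio_se = ou$se / abs(ex$beta)
  )
  attr(out, "dropped") <- dropped
  out
}
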