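test_that("per-level Bonferroni thresholds match the published scheme", {
  sch <- bonferroni_scheme()
  expect_equal(bonferroni_threshold(sch, "order"), 0.0025)
  expect_equal(bonferroni_threshold(sch, "class"), 0.05 / 16)
  expect_equal(signif(bonferroni_threshold(sch, "class"), 2), 3.1e-3)
  expect_equal(signif(bonferroni_threshold(sch, "family"), 2), 1.4e-3)
  expect_equal(signif(bonferroni_threshold(sch, "metabolite"), 2), 3.3e-3)
  expect_equal(bonferroni_threshold(bonferroni_scheme(m = c(x = 1)), "x"),
               0.05)
  expect_error(bonferroni_threshold(sch, "species"), "divisor")
  # strictly decreasing in m
  ms <- c(1, 9, 16, 20, 35, 131)
  thr <- 0.05 / ms
  expect_true(all(diff(thr) < 0))
})

test_that("classification respects the closed-open nominal band", {
  expect_identical(classify_estimate(0.0029, 0.05 / 16), "significant")
  expect_identical(classify_estimate(0.044, 0.05 / 35), "nominal")
  expect_identical(classify_estimate(0.5, 0.05 / 35), "null")
  # boundary behaviour: strict at both ends
  expect_identical(classify_estimate(0.05 / 16, 0.05 / 16), "nominal")
  expect_identical(classify_estimate(0.05, 0.05 / 16), "null")
  # monotone in p
  ps <- sort(runif(50))
  v <- classify_estimate(ps, 0.003)
  expect_true(all(diff(match(v, c("significant", "nominal", "null"))) >= 0))
})

test_that("the published per-level IVW p-values classify as 1 significant + 8 nominal", {
  tab <- tibble::tibble(
    trait_id = c("class.Actinobacteria", "family.Erysipelotrichaceae",
                 "order.Erysipelotrichales", "genus.Lachnospira",
                 "genus.Parabacteroides", "genus.Butyrivibrio",
                 "genus.Phascolarctobacterium", "genus.Ruminococcus",
                 "metabolite.beta_hydroxybutyrate"),
    kind = c("class", "family", "order", "genus", "genus", "genus",
             "genus", "genus", "metabolite"),
    pvalue = c(0.0029, 0.044, 0.018, 0.012, 0.0078, 0.048, 0.024, 0.02,
               0.037))
  sch <- bonferroni_scheme()
  verdicts <- mapply(function(p, k) {
    classify_estimate(p, bonferroni_threshold(sch, k))
  }, tab$pvalue, tab$kind)
  expect_identical(sum(verdicts == "significant"), 1L)
  expect_identical(tab$trait_id[verdicts == "significant"],
                   "class.Actinobacteria")
  expect_identical(sum(verdicts == "nominal"), 8L)
})

test_that("the forward pipeline isolates the one causal exposure", {
  study <- make_study(theta_true = log(1.2), j = 50, seed = 1)
  cfg <- list(exposures = study$exposures, outcome = study$outcome,
              params = list(seed = 7, n_boot = 100, n_sim = 300))
  res <- run_pipeline(cfg)
  cl <- res$classified
  expect_identical(nrow(cl), 5L)
  expect_identical(cl$verdict[cl$trait_id == "class.taxonA"], "significant")
  expect_false(any(cl$verdict[cl$trait_id != "class.taxonA"] ==
                     "significant"))
  # conservation: every exposure is classified or recorded as failed
  expect_true(all(cl$status %in% c("ok", "no instruments")))
  expect_identical(sum(!is.na(cl$verdict)) + sum(cl$status != "ok"), 5L)
  # IVW is the primary method
  expect_true(all(res$results$method[res$results$primary] == "ivw"))
})

test_that("pipeline runs are deterministic and survive empty overlap", {
  study <- make_study(j = 20, seed = 3)
  cfg <- list(exposures = study$exposures[1:2], outcome = study$outcome,
              params = list(seed = 5, n_boot = 50, n_sim = 200))
  a <- run_pipeline(cfg)
  b <- run_pipeline(cfg)
  expect_identical(a$classified, b$classified)
  expect_identical(a$results, b$results)

  # no shared variants -> recorded, not fatal
  other <- study$outcome
  other$records$variant_id <- paste0("zz", other$records$variant_id)
  cfg2 <- list(exposures = study$exposures[1], outcome = other,
               params = list(seed = 5))
  res2 <- suppressWarnings(run_pipeline(cfg2))
  expect_identical(res2$classified$status, "no instruments")
})

test_that("results tables round-trip to TSV with the standard layout", {
  study <- make_study(j = 15, seed = 9)
  res <- run_pipeline(list(exposures = study$exposures[1:2],
                           outcome = study$outcome,
                           params = list(seed = 2, n_boot = 20,
                                         n_sim = 150)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(res, path)
  back <- read.delim(path)
  expect_identical(names(back), c("trait_id", "method", "or_", "ci_low",
                                  "ci_high", "pvalue", "n_snps"))
  expect_identical(nrow(back), nrow(res$results))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_sensitivity_json(res, jpath)
  expect_true(jsonlite::validate(paste(readLines(jpath), collapse = "")))
})

test_that("reverse analysis applies the same machinery with roles swapped", {
  sim <- simulate_summary_pair(theta = 0, j = 25, seed = 41,
                               trait_id = "genus.diseaseproxy",
                               trait_kind = "genus")
  # relabel so both directions use taxon-level classification
  disease <- sim$exposure           # has genome-wide instruments
  target <- sim$outcome
  target$trait_kind <- "genus"
  target$trait_id <- "genus.target"
  pars <- list(seed = 3, n_boot = 30, n_sim = 150, sensitivity = FALSE)

  rev <- run_reverse(list(exposures = list(target), outcome = disease,
                          params = pars))
  fwd <- run_pipeline(list(exposures = list(disease), outcome = target,
                           params = pars))
  # identical estimates; only the trait labelling differs
  expect_equal(rev$classified$beta, fwd$classified$beta)
  expect_equal(rev$classified$pvalue, fwd$classified$pvalue)
  expect_match(rev$classified$trait_id, "^IgAN->")

  # disease with no sub-threshold variants -> "no instruments"
  weak <- disease
  weak$records$pvalue <- pmax(weak$records$pvalue, 0.5)
  res <- suppressWarnings(run_reverse(list(exposures = list(target),
                                           outcome = weak,
                                           params = pars)))
  expect_identical(res$classified$status, "no instruments")
})

test_that("reverse-direction false-positive rate is at the nominal level", {
  hits <- logical(120)
  for (r in seq_len(120)) {
    # a disease GWAS with genome-wide instruments and zero causal effect
    # on the taxon
    sim <- simulate_summary_pair(theta = 0, j = 30, seed = 3000 + r)
    disease <- sim$exposure
    target <- sim$outcome
    target$trait_kind <- "genus"
    res <- run_reverse(list(
      exposures = list(target), outcome = disease,
      params = list(seed = r, sensitivity = FALSE, n_boot = 10)))
    hits[r] <- !is.na(res$classified$pvalue) && res$classified$pvalue < 0.05
  }
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.11)
})
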