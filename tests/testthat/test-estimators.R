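test_that("Wald ratio divides outcome by exposure effect with delta SE", {
  h <- make_hs(0.1, 0.02, 0.01)
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$or_, exp(0.2))

  expect_equal(wald_ratio(make_hs(-0.1, 0.02, 0.01))$beta, -0.2)
  zero <- wald_ratio(make_hs(0.1, 0, 0.01))
  expect_equal(zero$beta, 0)
  expect_equal(zero$pvalue, 1)
  bad <- make_hs(0.1, 0.02, 0.01)
  bad$beta_exp <- 0
  expect_error(wald_ratio(bad), "beta_exp")
})

test_that("IVW equals the inverse-variance weighted mean of ratios", {
  hs <- make_hs(c(0.10, 0.20, 0.15), c(0.020, 0.044, 0.033),
                rep(0.010, 3))
  # brute-force weighted mean with w = beta_exp^2 / se_out^2
  w <- hs$beta_exp^2 / hs$se_out^2
  expect_equal(sum(w * hs$ratio) / sum(w), 157.5 / 725)
  expect_equal(ivw(hs)$beta, 157.5 / 725, tolerance = 1e-12)
  expect_equal(ivw(hs)$beta, 0.21724, tolerance = 1e-4)

  # equal weights -> arithmetic mean of ratios
  eq <- make_hs(rep(0.1, 3), c(0.01, 0.02, 0.03), rep(0.01, 3))
  expect_equal(ivw(eq)$beta, mean(eq$ratio))

  # two identical instruments -> their common ratio
  two <- make_hs(c(0.1, 0.1), c(0.02, 0.02), c(0.01, 0.01))
  expect_equal(ivw(two)$beta, 0.2)

  expect_error(ivw(make_hs(0.1, 0.02, 0.01)), "wald_ratio")
})

test_that("fixed and multiplicative IVW differ only in SE scale-up", {
  hs <- make_hs(c(0.1, 0.12, 0.2, 0.3), c(0.02, 0.05, 0.01, 0.09),
                rep(0.01, 4))
  f <- ivw(hs, re_mode = "fixed")
  m <- ivw(hs, re_mode = "multiplicative")
  expect_equal(f$beta, m$beta)
  q <- cochran_q(hs)$q_stat
  expect_equal(m$se, f$se * max(1, sqrt(q / 3)))
  expect_gte(m$se, f$se)
})

test_that("IVW and Egger match weighted least-squares oracles to 1e-10", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      j <- sample(5:25, 1)
      hs <- make_hs(beta_exp = runif(j, 0.05, 0.4) * sample(c(-1, 1), j, TRUE),
                    beta_out = rnorm(j, 0.02, 0.05),
                    se_out = runif(j, 0.005, 0.05))
      expect_equal(ivw(hs)$beta, lm_ivw_oracle(hs), tolerance = 1e-10)
      eg <- egger(hs)
      oracle <- lm_egger_oracle(hs)
      expect_equal(eg$intercept, oracle[1], tolerance = 1e-10)
      expect_equal(eg$beta, oracle[2], tolerance = 1e-10)
    }
  })
})

test_that("Egger recovers an exact line and handles degenerate outcomes", {
  hs <- make_hs(c(0.1, 0.2, 0.3), 0.05 + 0.2 * c(0.1, 0.2, 0.3),
                rep(0.01, 3))
  eg <- egger(hs)
  expect_equal(eg$beta, 0.2, tolerance = 1e-12)
  expect_equal(eg$intercept, 0.05, tolerance = 1e-12)

  null <- make_hs(c(0.1, 0.2, 0.3), rep(0, 3), rep(0.01, 3))
  eg0 <- egger(null)
  expect_equal(eg0$beta, 0, tolerance = 1e-12)
  expect_equal(eg0$intercept, 0, tolerance = 1e-12)

  expect_error(egger(make_hs(c(0.1, 0.2), c(0.01, 0.02), c(0.01, 0.01))),
               "at least 3")
})

test_that("weighted median interpolates the 50% weight point", {
  eq <- make_hs(rep(0.1, 3), 0.1 * c(0.1, 0.2, 0.3), rep(0.01, 3))
  expect_equal(weighted_median(eq, n_boot = 50, seed = 1)$beta, 0.2)

  # two equally weighted ratios -> midpoint (interpolation formula)
  expect_equal(mrgut:::weighted_median_point(c(0.1, 0.2), c(1, 1)), 0.15)

  # an instrument holding > 50% of the weight dictates the estimate
  dom <- make_hs(c(1, 0.1, 0.1), c(0.5, 0.02, 0.03),
                 c(0.01, 0.01, 0.01))
  w <- 1 / dom$ratio_se^2
  expect_gt(max(w) / sum(w), 0.5)
  # interpolation leaves a small offset proportional to the minority weight
  expect_equal(weighted_median(dom, n_boot = 50, seed = 1)$beta,
               dom$ratio[which.max(w)], tolerance = 0.02)
})

test_that("weighted mode finds the majority cluster and matches a grid oracle", {
  hs <- make_hs(rep(0.1, 4), 0.1 * c(0.2, 0.2, 0.2, 0.9), rep(0.01, 4))
  expect_equal(weighted_mode(hs, n_boot = 50, seed = 1)$beta, 0.2,
               tolerance = 0.02)

  const <- make_hs(rep(0.1, 3), rep(0.05, 3), rep(0.01, 3))
  expect_equal(weighted_mode(const, n_boot = 50, seed = 1)$beta, 0.5)

  withr::with_seed(7, {
    hs7 <- make_hs(runif(7, 0.1, 0.3), rnorm(7, 0.03, 0.02),
                   runif(7, 0.005, 0.02))
    w <- 1 / hs7$ratio_se^2
    h <- mrgut:::mode_bandwidth(hs7$ratio, 1)
    grid <- seq(min(hs7$ratio) - 3 * h, max(hs7$ratio) + 3 * h,
                length.out = 1e5)
    dens <- vapply(grid, function(x) {
      sum(w / sum(w) * dnorm((x - hs7$ratio) / h))
    }, numeric(1))
    oracle <- grid[which.max(dens)]
    est <- weighted_mode(hs7, n_boot = 50, seed = 2)$beta
    expect_equal(est, oracle, tolerance = 1e-3)
  })

  expect_error(weighted_mode(hs, bandwidth_factor = 0), "bandwidth")
})

test_that("estimators are sign- and scale-equivariant", {
  withr::with_seed(13, {
    hs <- make_hs(runif(10, 0.05, 0.4), rnorm(10, 0.03, 0.03),
                  runif(10, 0.005, 0.03))
    neg <- hs
    neg$beta_out <- -neg$beta_out
    neg$ratio <- -neg$ratio
    scaled <- hs
    scaled$beta_exp <- 3 * scaled$beta_exp
    scaled$ratio <- scaled$beta_out / scaled$beta_exp
    scaled$ratio_se <- scaled$se_out / abs(scaled$beta_exp)
    for (f in list(function(h) ivw(h)$beta,
                   function(h) egger(h)$beta,
                   function(h) weighted_median(h, n_boot = 10,
                                               seed = 3)$beta,
                   function(h) weighted_mode(h, n_boot = 10, seed = 3)$beta)) {
      expect_equal(f(neg), -f(hs), tolerance = 1e-6)
      expect_equal(f(scaled), f(hs) / 3, tolerance = 1e-6)
    }
  })
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  withr::with_seed(3, {
    hs <- make_hs(runif(8, 0.1, 0.3), rnorm(8, 0.02, 0.02),
                  runif(8, 0.005, 0.02))
  })
  a <- weighted_median(hs, n_boot = 200, seed = 5)
  b <- weighted_median(hs, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  c <- weighted_median(hs, n_boot = 200, seed = 6)
  expect_false(identical(a$se, c$se))
})

test_that("mr_all_methods returns the battery with IVW primary", {
  sim <- simulate_summary_pair(theta = 0.1, j = 12, seed = 8)
  hs <- harmonize(sim$exposure, sim$outcome)
  out <- mr_all_methods(hs, n_boot = 50, seed = 1)
  expect_setequal(out$method, c("ivw", "egger", "weighted_median",
                                "weighted_mode"))
  expect_identical(out$method[out$primary], "ivw")
  expect_true(all(out$ci_low < out$or_ & out$or_ < out$ci_high))
  expect_true(all(out$pvalue > 0 & out$pvalue <= 1))
  # single instrument falls back to the Wald ratio
  single <- mr_all_methods(hs[1, ], n_boot = 10, seed = 1)
  expect_identical(single$method, "wald")
})
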