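test_that("dose equations give the hand-computed values and published
           percentile end-points", {
  p <- exposure_params()
  expect_equal(compute_add(0, p), 0)
  expect_equal(compute_add(0.430, p), 0.430 * 37 * 1e-3 / 63,
               tolerance = 1e-12)
  expect_equal(compute_add(0.430, p), 2.525e-4, tolerance = 1e-3)
  # published HQ end-points (area maxima)
  expect_equal(round(compute_hq(0.242, p), 2), 0.14)
  expect_equal(round(compute_hq(0.839, p), 2), 0.49)
  expect_equal(compute_hq(0, p), 0)
  # published CR end-points (area minima/maxima)
  expect_equal(signif(compute_cr(0.036, p), 2), 1.3e-4)
  expect_equal(signif(compute_cr(0.839, p), 2), 3.0e-3)
  expect_error(compute_add(-0.1, p), ">= 0")
})

test_that("dose metrics are linear in concentration and intake and
           inverse in body weight; CR = HQ * RfD * SF to 1e-12", {
  p <- exposure_params()
  cs <- c(0.01, 0.1, 0.43, 0.839, 2)
  expect_equal(compute_add(2 * cs, p), 2 * compute_add(cs, p))
  p2 <- exposure_params(IR = 74)
  expect_equal(compute_add(cs, p2), 2 * compute_add(cs, p))
  p3 <- exposure_params(BW = 126)
  expect_equal(compute_add(cs, p3), compute_add(cs, p) / 2)
  expect_equal(compute_cr(cs, p), compute_hq(cs, p) * p$RfD * p$SF,
               tolerance = 1e-12)
  # the ratio is a constant of the parameter set
  expect_equal(compute_cr(cs, p) / compute_hq(cs, p),
               rep(6.1e-3, length(cs)), tolerance = 1e-12)
})

test_that("risk classification follows the regulatory bands with the
           stated boundary conventions", {
  expect_equal(classify_cr(c(1e-7, 5e-5, 1e-4, 1.01e-4, 5e-3)),
               c("negligible", "acceptable", "acceptable", "significant",
                 "significant"))
  expect_equal(classify_cr(1e-6), "acceptable")
  expect_equal(classify_hq(c(0.99, 1, 2)),
               c("acceptable", "concern", "concern"))
  recs <- risk_records(make_samples(c(1, 1), c(6, 6), c(0.242, 0.839)))
  expect_equal(recs$cr_class, c("significant", "significant"))
  expect_equal(recs$hq_class, c("acceptable", "acceptable"))
})

test_that("per-sample percentiles use the nearest-rank convention: P1/P99
           hit min/max at n = 18", {
  vals <- seq(0.05, 0.90, length.out = 18)
  s <- make_samples(rep(1, 18), rep(6, 18), vals)
  rs <- per_sample_summary(s, area = "low")
  expect_equal(rs$cr[["P99"]], compute_cr(max(vals)))
  expect_equal(rs$cr[["P1"]], compute_cr(min(vals)))
  expect_equal(rs$hq[["P25"]], compute_hq(sort(vals)[ceiling(0.25 * 18)]))
  expect_true(all(diff(rs$cr) >= 0))

  # all-equal values collapse every percentile
  eq <- make_samples(rep(1, 5), rep(6, 5), rep(0.2, 5))
  rse <- per_sample_summary(eq, area = "low")
  expect_true(all(rse$hq == rse$hq[[1]]))

  # a cohort whose maximum grain Cd is the published low-area maximum
  # reproduces the published P99 HQ
  low_like <- make_samples(rep(0.5, 18), rep(5.4, 18),
                           seq(0.036, 0.242, length.out = 18))
  expect_equal(round(per_sample_summary(low_like)$hq[["P99"]], 2), 0.14)
})

test_that("distribution fitting: lognormal MLE recovers parameters, the
           fit equals the closed-form log-moment solution, and the
           empirical family resamples observed values", {
  set.seed(44)
  x <- exp(rnorm(10000, 0, 1))
  d <- fit_concentration_distribution(x, "lognormal")
  expect_lt(abs(d$params$meanlog - 0), 0.05)
  # closed-form MLE oracle
  expect_equal(d$params$meanlog, mean(log(x)), tolerance = 1e-4)
  expect_equal(d$params$sdlog, sqrt(mean((log(x) - mean(log(x)))^2)),
               tolerance = 1e-3)
  expect_error(fit_concentration_distribution(c(0, 1, 2, 3, 4),
                                              "lognormal"), "positive")
  expect_error(fit_concentration_distribution(c(1, 2, 3), "lognormal"),
               ">= 5")

  obs <- c(0.1, 0.2, 0.4)
  emp <- fit_concentration_distribution(obs, "empirical")
  set.seed(1)
  expect_true(all(emp$r(500) %in% obs))

  set.seed(5)
  sym <- rnorm(5000, 10, 2)
  dn <- fit_concentration_distribution(sym, "normal")
  set.seed(2)
  draws <- dn$r(20000)
  expect_lt(abs(mean(draws) - stats::median(draws)), 0.1)
})

test_that("Monte-Carlo risk: degenerate distribution, determinism,
           truncation at zero, convergence, and agreement with the
           analytic exceedance threshold", {
  p <- exposure_params()
  deg <- fit_concentration_distribution(0.430, "empirical")
  rs <- monte_carlo_risk(deg, p, mc_config(seed = 1))
  expect_equal(unname(rs$cr), rep(compute_cr(0.430), 6), tolerance = 1e-12)
  expect_equal(signif(rs$cr[["P50"]], 3), 1.54e-3)
  expect_equal(rs$exceedance, 1.0)

  coh <- generate_cohort(default_cohort_spec(seed = 2))
  d <- fit_concentration_distribution(coh$soybean_cd, "lognormal")
  a <- monte_carlo_risk(d, p, mc_config(seed = 9))
  b <- monte_carlo_risk(d, p, mc_config(seed = 9))
  expect_identical(a$cr, b$cr)

  # exceedance matches the analytic tail beyond c* = 1e-4*BW/(IR*1e-3*SF)
  cstar <- cr_threshold_conc(p)
  expect_equal(cstar, 0.0279, tolerance = 1e-3)
  analytic <- 1 - stats::plnorm(cstar, d$params$meanlog, d$params$sdlog)
  expect_lt(abs(a$exceedance - analytic), 0.01)

  # doubling the iterations moves the median by < 2%
  big <- monte_carlo_risk(d, p, mc_config(seed = 9, n_iterations = 20000))
  expect_lt(abs(big$cr[["P50"]] / a$cr[["P50"]] - 1), 0.02)

  # normal family: truncation leaves no negative concentration draws
  wide <- fit_concentration_distribution(c(0.01, 0.02, 0.05, 0.3, 0.9),
                                         "normal")
  rn <- monte_carlo_risk(wide, p, mc_config(seed = 3, family = "normal"))
  expect_true(all(rn$concentration_draws >= 0))
})

test_that("bootstrap percentile bands are degenerate for constant draws,
           reproducible, and shrink with larger resamples", {
  cfg <- mc_config(seed = 5)
  const <- rep(2e-4, 1000)
  bc <- bootstrap_percentiles(const, cfg)
  expect_true(all(bc$lower == 2e-4 & bc$upper == 2e-4))

  set.seed(77)
  draws <- rlnorm(10000, -7.5, 0.7)
  set.seed(1); b1 <- bootstrap_percentiles(draws, cfg)
  set.seed(1); b2 <- bootstrap_percentiles(draws, cfg)
  expect_identical(b1, b2)

  set.seed(2)
  wide <- bootstrap_percentiles(draws, mc_config(bootstrap_size = 200))
  set.seed(2)
  tight <- bootstrap_percentiles(draws, mc_config(bootstrap_size = 2000))
  expect_lt(mean(tight$upper - tight$lower),
            mean(wide$upper - wide$lower))
})
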