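test_that("the Wald ratio and its first-order SE follow the definition", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$ratio_se, 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$ratio, 0)
  neg <- wald_ratio(-0.1, 0.01, 0.05, 0.01)
  expect_equal(neg$ratio, -0.5)
  expect_equal(neg$ratio_se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "domain error")
})

test_that("IVW reduces to the Wald ratio for one variant and pools exactly for known cases", {
  h1 <- make_h(0.1, 0.01, 0.05, 0.01)
  est <- mr_ivw(h1)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$lci, 0.5 - 1.96 * 0.1)

  # two identical ratios: no heterogeneity, se shrinks by sqrt(2)
  h2 <- make_h(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05), c(0.001, 0.001))
  e2 <- mr_ivw(h2)
  expect_equal(e2$beta, 0.5)
  expect_equal(e2$q_stat, 0)
  expect_equal(e2$se, 0.01 / sqrt(2))
  expect_equal(mr_ivw(h2, "fixed")$se, e2$se)  # floor at 1 binds when Q = 0

  # ratios 0.5 and 1.0 with ratio SE 0.1 each: w = 100, beta = 0.75,
  # Q = 100*(0.25^2)*2 = 12.5, random se = fixed se * sqrt(12.5)
  h3 <- make_h(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.10), c(0.01, 0.01))
  e3 <- mr_ivw(h3)
  expect_equal(e3$beta, 0.75)
  expect_equal(e3$q_stat, 12.5)
  expect_equal(e3$q_df, 1)
  fixed_se <- 1 / sqrt(200)
  expect_equal(mr_ivw(h3, "fixed")$se, fixed_se)
  expect_equal(e3$se, fixed_se * sqrt(12.5))
})

test_that("fixed-effect IVW agrees with metafor on random inputs and random se >= fixed se", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      J <- sample(3:30, 1)
      h <- make_h(runif(J, 0.05, 0.2), runif(J, 0.005, 0.02),
                  rnorm(J, 0.05, 0.03), runif(J, 0.005, 0.02))
    })
    wr <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
    rma <- suppressWarnings(metafor::rma(yi = wr$ratio, sei = wr$ratio_se,
                                         method = "FE"))
    fixed <- mr_ivw(h, "fixed")
    expect_equal(fixed$beta, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(fixed$se, rma$se, tolerance = 1e-10)
    expect_equal(fixed$q_stat, rma$QE, tolerance = 1e-10)
    expect_gte(mr_ivw(h, "random")$se, fixed$se)
  }
})

test_that("MR-Egger recovers exact linear data and matches weighted lm", {
  # exact construction: beta_out = 0.02 + 0.4 * beta_exp, equal weights
  bx <- c(0.05, 0.1, 0.15, 0.2)
  h <- make_h(bx, rep(0.01, 4), 0.02 + 0.4 * bx, rep(0.01, 4))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.4)
  expect_equal(e$egger_intercept, 0.02)
  expect_equal(e$q_stat, 0, tolerance = 1e-20)

  # with zero intercept and equal outcome SEs the slope equals fixed IVW
  h0 <- make_h(bx, rep(0.01, 4), 0.4 * bx, rep(0.01, 4))
  expect_equal(mr_egger(h0)$beta, mr_ivw(h0, "fixed")$beta, tolerance = 1e-10)

  # WLS oracle: coefficients and (unscaled-vs-inflated) SEs from stats::lm
  for (seed in 1:8) {
    withr::with_seed(seed, {
      J <- sample(4:40, 1)
      h <- make_h(runif(J, 0.02, 0.2), runif(J, 0.005, 0.02),
                  rnorm(J, 0.04, 0.05), runif(J, 0.005, 0.02))
    })
    s <- sign(h$beta_exp)
    fit <- lm(I(h$beta_out * s) ~ I(h$beta_exp * s),
              weights = 1 / h$se_out^2)
    e <- mr_egger(h)
    expect_equal(e$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    sig <- summary(fit)$sigma
    expect_equal(e$se, unname(coef(summary(fit))[2, 2]) / min(1, sig),
                 tolerance = 1e-8)
  }
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.01, 0.01), c(0.1, 0.1),
                               c(0.01, 0.01))), "at least 3")
  expect_error(mr_egger(make_h(rep(0.1, 4), rep(0.01, 4), rnorm(4),
                               rep(0.01, 4))), "degenerate")
})

test_that("IVW and the Egger slope are invariant to joint sign flips", {
  withr::with_seed(42, {
    J <- 20
    h <- make_h(runif(J, 0.05, 0.2), runif(J, 0.005, 0.02),
                rnorm(J, 0.05, 0.02), runif(J, 0.005, 0.02))
    flip <- sample(c(-1, 1), J, replace = TRUE)
  })
  hf <- make_h(h$beta_exp * flip, h$se_exp, h$beta_out * flip, h$se_out)
  expect_equal(mr_ivw(hf)$beta, mr_ivw(h)$beta)
  expect_equal(mr_egger(hf)$beta, mr_egger(h)$beta)
  expect_equal(mr_egger(hf)$egger_intercept, mr_egger(h)$egger_intercept)
})

test_that("the weighted median matches its oracle and has a reproducible bootstrap SE", {
  # equal weights, ratios {1,2,3} -> 2
  h <- make_h(rep(1, 3), rep(0.1, 3), c(1, 2, 3), rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 2)
  # constant ratios -> that constant
  hc <- make_h(c(0.1, 0.2, 0.4), rep(0.01, 3), c(0.05, 0.10, 0.20),
               c(0.01, 0.02, 0.04))
  expect_equal(mr_weighted_median(hc, n_boot = 50)$beta, 0.5)
  # oracle on random small instances
  for (seed in 1:40) {
    withr::with_seed(seed, {
      J <- sample(3:7, 1)
      b <- rnorm(J)
      se <- runif(J, 0.1, 2)
    })
    expect_equal(mrmediate:::weighted_median_point(b, se),
                 oracle_weighted_median(b, se), tolerance = 1e-12)
  }
  # seeded determinism of the bootstrap SE
  withr::with_seed(7, hr <- make_h(runif(8, 0.05, 0.2), runif(8, 0.005, 0.02),
                                   rnorm(8, 0.05, 0.03),
                                   runif(8, 0.005, 0.02)))
  e1 <- mr_weighted_median(hr, n_boot = 200, seed = 99)
  e2 <- mr_weighted_median(hr, n_boot = 200, seed = 99)
  expect_identical(e1$se, e2$se)
  expect_error(mr_weighted_median(make_h(1, 0.1, 1, 0.1)), "at least 3")
})

test_that("Cochran's Q flags heterogeneity and is null-calibrated", {
  h <- make_h(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05), c(0.001, 0.001))
  q <- cochran_q(h)
  expect_equal(q$q, 0)
  expect_equal(q$pval, 1)
  h3 <- make_h(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.10), c(0.01, 0.01))
  q3 <- cochran_q(h3)
  expect_equal(q3$q, 12.5)
  expect_equal(q3$df, 1)
  expect_equal(q3$pval, pchisq(12.5, 1, lower.tail = FALSE))
  expect_error(cochran_q(make_h(0.1, 0.01, 0.05, 0.01)), "at least 2")

  # under the generative null (no pleiotropy) Q/df hovers around one, the
  # ratio-SE approximation adding only mild extra dispersion
  qdf <- vapply(1:15, function(seed) {
    r <- pipeline_step1(sim_config(n_snps = 60, seed = seed))
    r$ivw$q_stat / r$ivw$q_df
  }, numeric(1))
  expect_gt(mean(qdf), 0.85)
  expect_lt(mean(qdf), 1.35)
})

test_that("leave-one-out reproduces IVW on each reduced set and flags nothing for homogeneous data", {
  withr::with_seed(11, {
    J <- 8
    h <- make_h(runif(J, 0.05, 0.2), runif(J, 0.005, 0.02),
                rnorm(J, 0.05, 0.02), runif(J, 0.005, 0.02))
  })
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), J)
  expect_equal(loo$omitted_snp_id, sort(h$snp_ids))
  for (k in seq_len(J)) {
    omit <- match(loo$omitted_snp_id[k], h$snp_ids)
    direct <- mr_ivw(mrmediate:::subset_harmonized(h, -omit), "random")
    expect_equal(loo$beta[k], direct$beta)
    expect_equal(loo$se[k], direct$se)
  }
  # identical variants: every reduced estimate equals the full one
  hid <- make_h(rep(0.1, 4), rep(0.01, 4), rep(0.05, 4), rep(0.01, 4))
  lid <- leave_one_out(hid)
  full <- mr_ivw(hid)
  expect_equal(lid$beta, rep(full$beta, 4))
  expect_false(any(lid$influential))
  expect_error(leave_one_out(make_h(c(1, 1), c(0.1, 0.1), c(1, 1),
                                    c(0.1, 0.1))), "at least 3")
})
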