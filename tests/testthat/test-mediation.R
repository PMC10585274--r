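test_that("the product-of-coefficients matches the published worked example", {
  # step one: PM2.5 -> BMI (beta 0.082, CI 0.024-0.14); step two:
  # BMI -> susceptibility (beta 0.16, CI 0.13-0.19); SEs = CI width / 3.92
  ind <- indirect_effect(0.082, (0.14 - 0.024) / 3.92,
                         0.16, (0.19 - 0.13) / 3.92)
  expect_equal(ind$indirect_beta, 0.082 * 0.16)
  expect_equal(round(ind$or_point, 2), 1.01)
  expect_equal(round(ind$or_lci, 2), 1.00)
  expect_equal(round(ind$or_uci, 2), 1.02)
  expect_gt(ind$pval, 0.0070)
  expect_lt(ind$pval, 0.0078)  # published 7.41e-3
})

test_that("indirect-effect edge cases and symmetry hold", {
  z <- indirect_effect(0, 0.01, 0.5, 0.02)
  expect_equal(z$indirect_beta, 0)
  expect_equal(z$or_point, 1)
  expect_equal(z$pval, 1)
  a <- indirect_effect(0.3, 0.05, -0.2, 0.03)
  b <- indirect_effect(-0.2, 0.03, 0.3, 0.05)
  expect_equal(a, b)
  expect_equal(a$indirect_se, sqrt(0.3^2 * 0.03^2 + 0.2^2 * 0.05^2))
  expect_lte(a$or_lci, a$or_point)
  expect_lte(a$or_point, a$or_uci)
  expect_error(indirect_effect(0.1, 0, 0.2, 0.01), "domain error")
  expect_error(indirect_effect(0.1, 0.01, 0.2, -1), "domain error")
})

test_that("the three-case classification follows the stated rules", {
  # published PM2.5 -> BMI -> susceptibility p-values: total 2.06e-1,
  # step one 5.73e-3, step two 1.74e-27, indirect 7.41e-3
  expect_equal(classify_mediation(0.206, 5.73e-3, 1.74e-27, 7.41e-3),
               "indirect_only")
  expect_equal(classify_mediation(0.01, 0.5, 0.01, 0.001), "no_mediation")
  expect_equal(classify_mediation(0.01, 0.01, 0.01, 0.5), "partial_mediation")
  expect_equal(classify_mediation(0.5, 0.01, 0.01, 0.5), "no_mediation")
  expect_equal(classify_mediation(0.5, 0.01, 0.01, NA), "no_mediation")
  # alpha is configurable
  expect_equal(classify_mediation(0.09, 0.09, 0.09, 0.5, alpha = 0.1),
               "partial_mediation")
  # underflowed p = 0 counts as extreme significance; negatives are invalid
  expect_equal(classify_mediation(0, 0, 0, 0.5), "partial_mediation")
  expect_error(classify_mediation(-0.1, 0.5, 0.5, 0.5))
})

test_that("run_two_step recovers the simulated indirect effect with a coherent audit trail", {
  st <- simulate_study(sim_config(n_snps = 150, n_exposure = 100000,
                                  n_mediator = 100000, n_outcome = 100000,
                                  seed = 31))
  res <- suppressMessages(run_two_step(st$exposure_stats, st$mediator_stats,
                                       st$outcome_stats, "X", "M", "Y"))
  # truth: indirect = 0.3 * 0.2 = 0.06; recovery within 3 delta-method SDs
  expect_lt(abs(res$indirect_beta - 0.06), 3 * res$indirect_se)
  expect_identical(res$indirect_beta, res$beta1 * res$beta2)
  expect_identical(res$beta1, res$audit$step1$beta)
  expect_identical(res$beta2, res$audit$step2$beta)
  expect_identical(res$beta0, res$audit$total$beta)
  expect_equal(res$or_point, exp(res$indirect_beta))
  # with no direct effect the total effect IS the indirect one (0.06), which
  # at these sample sizes is detected, so all three paths are significant
  expect_lt(res$p0, 0.05)
  expect_equal(res$case, "partial_mediation")
  expect_lt(res$p1, 1e-10)  # extreme step-one significance at N = 100,000
  # determinism end to end
  res2 <- suppressMessages(run_two_step(st$exposure_stats, st$mediator_stats,
                                        st$outcome_stats, "X", "M", "Y"))
  expect_identical(res[setdiff(names(res), "audit")],
                   res2[setdiff(names(res2), "audit")])
})

test_that("a null exposure->mediator path is classified as no mediation", {
  # the mediator keeps its own genetic basis through balanced SNP-specific
  # effects, but the exposure no longer influences it
  st <- simulate_study(sim_config(n_snps = 120, beta_xm = 0,
                                  prop_invalid = 0.5, pleiotropy_mean = 0,
                                  pleiotropy_sd = 0.08, seed = 17))
  res <- suppressMessages(run_two_step(st$exposure_stats, st$mediator_stats,
                                       st$outcome_stats))
  expect_equal(res$case, "no_mediation")
  expect_gt(res$p1, 0.05)
})

test_that("exposure instruments associated with the mediator are excluded from the total-effect arm", {
  st <- simulate_study(sim_config(n_snps = 150, n_exposure = 100000,
                                  n_mediator = 100000, n_outcome = 100000,
                                  seed = 31))
  res <- suppressMessages(run_two_step(st$exposure_stats, st$mediator_stats,
                                       st$outcome_stats))
  n_iv <- nrow(res$audit$exposure_instruments$records)
  n_excl <- res$audit$n_excluded_mediator_associated
  expect_gt(n_excl, 0)  # beta_xm = 0.3 makes strong SNPs mediator-associated
  expect_lte(res$audit$total$n_snp, n_iv - n_excl)
  expect_gte(res$audit$step1$n_snp, res$audit$total$n_snp)
})

test_that("delta-method CI for the indirect effect attains nominal coverage", {
  hits <- vapply(1:300, function(seed) {
    st <- simulate_study(sim_config(n_snps = 80, seed = 4000 + seed))
    r1 <- pipeline_step1(sim_config(n_snps = 80, seed = 4000 + seed))$ivw
    iv_m <- suppressMessages(select_instruments(st$mediator_stats, "M"))
    r2 <- mr_ivw(harmonize(iv_m$records, st$outcome_stats))
    ind <- indirect_effect(r1$beta, r1$se, r2$beta, r2$se)
    abs(ind$indirect_beta - 0.06) <= 1.96 * ind$indirect_se
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})
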