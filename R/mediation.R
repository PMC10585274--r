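#' Indirect effect by the product of coefficients
#'
#' Combines the step-one (exposure -> mediator) and step-two (mediator ->
#' outcome) causal estimates into the mediated effect
#' `indirect = beta1 * beta2`, with first-order delta-method standard error
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (the two estimates come from
#' non-overlapping samples, so their covariance is taken as zero).  The effect
#' and its 95% CI are also reported on the odds-ratio scale,
#' `exp(indirect +/- 1.96 se)`; the p-value is a two-sided normal test of
#' `indirect / se`.
#'
#' @param beta1,se1 Exposure -> mediator estimate and SE.
#' @param beta2,se2 Mediator -> outcome estimate and SE.
#' @param alpha Significance level recorded alongside (CIs are 95%).
#' @return List: `indirect_beta`, `indirect_se`, `or_point`, `or_lci`,
#'   `or_uci`, `pval`.
#' @export
indirect_effect <- function(beta1, se1, beta2, se2, alpha = 0.05) {
  if (!is.finite(se1) || se1 <= 0 || !is.finite(se2) || se2 <= 0)
    stop("domain error: standard errors must be positive")
  b <- beta1 * beta2
  se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  z <- if (se > 0) b / se else 0
  list(indirect_beta = b, indirect_se = se,
       or_point = exp(b), or_lci = exp(b - Z95 * se),
       or_uci = exp(b + Z95 * se),
       pval = 2 * pnorm(-abs(z)))
}

#' Classify the mediation pattern
#'
#' Applies the three-case rule on the significance of the total effect (p0,
#' exposure -> outcome), the two mediation steps (p1: exposure -> mediator;
#' p2: mediator -> outcome), and the quantified indirect effect:
#'
#' * `partial_mediation`: p0, p1 and p2 all significant — a causal
#'   exposure -> outcome association partially carried by the mediator;
#' * `indirect_only`: p0 not significant but p1, p2 and the indirect effect
#'   all significant — the association is indirect, through the mediator;
#' * `no_mediation`: otherwise (in particular whenever either step is
#'   non-significant).
#'
#' @param p0,p1,p2 P-values of the total effect and the two steps.  An exact
#'   zero (double underflow of an extreme test statistic) is accepted and
#'   treated as significant.
#' @param p_indirect P-value of the product-of-coefficients indirect effect;
#'   `NA` is treated as non-significant.
#' @param alpha Significance level.
#' @return One of `"partial_mediation"`, `"indirect_only"`, `"no_mediation"`.
#' @export
classify_mediation <- function(p0, p1, p2, p_indirect = NA, alpha = 0.05) {
  stopifnot(p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  sig <- function(p) !is.na(p) & p < alpha
  if (sig(p0) && sig(p1) && sig(p2)) return("partial_mediation")
  if (!sig(p0) && sig(p1) && sig(p2) && sig(p_indirect))
    return("indirect_only")
  "no_mediation"
}

#' Two-step MR mediation analysis
#'
#' Runs the full chain on three summary-statistics tables: instruments are
#' selected for the exposure and used against the mediator (step one, beta1)
#' and against the outcome (the total effect, beta0); instruments selected
#' for the mediator are used against the outcome (step two, beta2).  For the
#' exposure -> outcome arm, exposure instruments that are themselves
#' associated with the mediator at the instrument threshold are excluded, so
#' the total-effect instruments are independent of the mediator.  The
#' indirect effect is then `beta1 * beta2` with delta-method uncertainty, and
#' the pattern is classified with [classify_mediation()].
#'
#' @param exposure_stats,mediator_stats,outcome_stats Summary-statistics
#'   data.frames in the [gwas_columns] dialect.
#' @param exposure_name,mediator_name,outcome_name Trait labels.
#' @param settings Named list overriding any of: `p_threshold` (5e-5),
#'   `clump_r2` (0.001), `clump_window_bp` (1e7), `f_min` (10), `ld_matrix`
#'   (NULL), `palindromic_eaf_window` (0.08), `effects_model` ("random"),
#'   `alpha` (0.05), `r2_mode` ("normalized").
#' @return Object of class `mediation_result`: the three arm estimates
#'   (`beta0/p0`, `beta1/se1/p1`, `beta2/se2/p2`), the indirect effect with
#'   OR-scale CI and p, the `case` classification, and an `audit` list with
#'   the full `mr_estimate` objects and instrument sets of every arm.
#' @export
run_two_step <- function(exposure_stats, mediator_stats, outcome_stats,
                         exposure_name = "exposure",
                         mediator_name = "mediator",
                         outcome_name = "outcome",
                         settings = list()) {
  s <- utils::modifyList(list(p_threshold = 5e-5, clump_r2 = 0.001,
                              clump_window_bp = 1e7, f_min = 10,
                              ld_matrix = NULL,
                              palindromic_eaf_window = 0.08,
                              effects_model = "random", alpha = 0.05,
                              r2_mode = "normalized"),
                         settings)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  iv_exp <- stage("exposure instruments",
                  select_instruments(exposure_stats, exposure_name,
                                     s$p_threshold, s$ld_matrix, s$clump_r2,
                                     s$clump_window_bp, s$f_min, s$r2_mode))
  # step one: exposure -> mediator
  h1 <- stage("harmonize exposure-mediator",
              harmonize(iv_exp$records, mediator_stats,
                        s$palindromic_eaf_window, exposure_name,
                        mediator_name))
  est1 <- stage("IVW exposure-mediator", mr_ivw(h1, s$effects_model))

  # total effect: exposure -> outcome, excluding instruments associated with
  # the mediator at the instrument threshold
  med_p <- mediator_stats$pval[match(iv_exp$records$snp_id,
                                     mediator_stats$snp_id)]
  med_assoc <- !is.na(med_p) & med_p < s$p_threshold
  rec0 <- iv_exp$records[!med_assoc, , drop = FALSE]
  if (nrow(rec0) == 0)
    stop("stage 'total-effect instruments': every exposure instrument is ",
         "associated with the mediator at p < ", format(s$p_threshold))
  h0 <- stage("harmonize exposure-outcome",
              harmonize(rec0, outcome_stats, s$palindromic_eaf_window,
                        exposure_name, outcome_name))
  est0 <- stage("IVW exposure-outcome", mr_ivw(h0, s$effects_model))

  # step two: mediator -> outcome
  iv_med <- stage("mediator instruments",
                  select_instruments(mediator_stats, mediator_name,
                                     s$p_threshold, s$ld_matrix, s$clump_r2,
                                     s$clump_window_bp, s$f_min, s$r2_mode))
  h2 <- stage("harmonize mediator-outcome",
              harmonize(iv_med$records, outcome_stats,
                        s$palindromic_eaf_window, mediator_name,
                        outcome_name))
  est2 <- stage("IVW mediator-outcome", mr_ivw(h2, s$effects_model))

  ind <- indirect_effect(est1$beta, est1$se, est2$beta, est2$se, s$alpha)
  case <- classify_mediation(est0$pval, est1$pval, est2$pval, ind$pval,
                             s$alpha)
  structure(c(list(exposure = exposure_name, mediator = mediator_name,
                   outcome = outcome_name,
                   beta0 = est0$beta, p0 = est0$pval,
                   beta1 = est1$beta, se1 = est1$se, p1 = est1$pval,
                   beta2 = est2$beta, se2 = est2$se, p2 = est2$pval),
              ind[c("indirect_beta", "indirect_se", "or_point", "or_lci",
                    "or_uci")],
              list(indirect_pval = ind$pval, case = case,
                   n_snp = est1$n_snp,
                   audit = list(total = est0, step1 = est1, step2 = est2,
                                exposure_instruments = iv_exp,
                                mediator_instruments = iv_med,
                                n_excluded_mediator_associated =
                                  sum(med_assoc)))),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Two-step MR mediation: %s -> %s -> %s\n", x$exposure,
              x$mediator, x$outcome))
  cat(sprintf("  beta0 (total)    = %.4g (p = %.3g)\n", x$beta0, x$p0))
  cat(sprintf("  beta1 (step one) = %.4g (p = %.3g)\n", x$beta1, x$p1))
  cat(sprintf("  beta2 (step two) = %.4g (p = %.3g)\n", x$beta2, x$p2))
  cat(sprintf("  indirect = %.4g, OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$indirect_beta, x$or_point, x$or_lci, x$or_uci,
              x$indirect_pval))
  cat("  classification:", x$case, "\n")
  invisible(x)
}
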