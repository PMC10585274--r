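# Constructor for a single causal estimate with its diagnostics.
new_mr_estimate <- function(method, beta, se, n_snp,
                            q_stat = NA_real_, q_df = NA_real_,
                            q_pval = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_pval = NA_real_,
                            exposure = "exposure", outcome = "outcome") {
  stopifnot(is.finite(beta), is.finite(se), se > 0, n_snp >= 1)
  structure(list(method = method, beta = beta, se = se,
                 lci = beta - Z95 * se, uci = beta + Z95 * se,
                 pval = 2 * pnorm(-abs(beta / se)), n_snp = as.integer(n_snp),
                 q_stat = q_stat, q_df = q_df, q_pval = q_pval,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_pval = egger_intercept_pval,
                 exposure = exposure, outcome = outcome),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: %s -> %s  beta = %.4g (95%% CI %.4g to %.4g), p = %.3g, nSNP = %d\n",
              x$method, x$exposure, x$outcome, x$beta, x$lci, x$uci, x$pval,
              x$n_snp))
  if (is.finite(x$q_stat))
    cat(sprintf("  Cochran Q = %.4g on %d df, p = %.3g\n", x$q_stat,
                as.integer(x$q_df), x$q_pval))
  if (is.finite(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  invisible(x)
}

#' Per-variant Wald ratio
#'
#' The single-SNP causal estimate: outcome effect divided by exposure effect,
#' with the first-order standard error `se_out / |beta_exp|` (exposure-side
#' uncertainty neglected, the convention for strong instruments).
#'
#' @param beta_exp,se_exp Exposure effect and SE (vectorized).
#' @param beta_out,se_out Outcome effect and SE.
#' @return List with numeric vectors `ratio` and `ratio_se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0))
    stop("domain error: Wald ratio undefined for beta_exp = 0")
  list(ratio = beta_out / beta_exp, ratio_se = se_out / abs(beta_exp))
}

#' Inverse-variance weighted causal estimate
#'
#' Meta-analytic combination of the per-variant Wald ratios with weights
#' `1/se_j^2`.  Under the multiplicative random-effects model (the default)
#' the fixed-effect standard error is inflated by `sqrt(Q / (J - 1))`, floored
#' at 1, so heterogeneity widens but never narrows the interval.  P-values are
#' two-sided normal; the CI is `beta +/- 1.96 se`.
#'
#' @param h A `harmonized_set` (see [harmonize()]).
#' @param effects_model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` carrying Cochran's Q when J >= 2.
#' @export
mr_ivw <- function(h, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$beta_exp)
  if (J < 1) stop("data error: empty harmonized set")
  wr <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  w <- 1 / wr$ratio_se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  if (J >= 2) {
    df <- J - 1
    q_pval <- pchisq(q, df, lower.tail = FALSE)
    se <- if (effects_model == "random")
      se_fixed * max(1, sqrt(q / df)) else se_fixed
  } else {
    df <- NA_real_; q <- NA_real_; q_pval <- NA_real_
    se <- se_fixed
  }
  new_mr_estimate(paste0("ivw_", effects_model), beta, se, J,
                  q_stat = q, q_df = df, q_pval = q_pval,
                  exposure = h$exposure_name, outcome = h$outcome_name)
}

# Weighted least squares of y on x with weights w; returns coefficients,
# unscaled (model-based) SEs, and the weighted residual sum of squares.
wls_fit <- function(x, y, w) {
  X <- cbind(intercept = 1, slope = x)
  XtWX <- crossprod(X * sqrt(w))
  V <- solve(XtWX)
  coefs <- drop(V %*% crossprod(X, w * y))
  resid <- y - drop(X %*% coefs)
  list(coef = coefs, se_unscaled = sqrt(diag(V)),
       rss_w = sum(w * resid^2))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' a free intercept, weights `1/se_out^2`, after orienting every variant so
#' its exposure effect is nonnegative (flipping the paired outcome effect).
#' The slope is the causal estimate; a nonzero intercept estimates the average
#' directional pleiotropy of the instruments.  Standard errors are the WLS
#' model-based SEs inflated by `max(1, sqrt(Q_residual / (J - 2)))`
#' (multiplicative overdispersion, floored at 1); p-values two-sided normal.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @return An `mr_estimate` with `egger_intercept` diagnostics and the
#'   residual heterogeneity in `q_stat` (J - 2 df).
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$beta_exp)
  if (J < 3) stop("data error: MR-Egger requires at least 3 variants")
  s <- sign(h$beta_exp); s[s == 0] <- 1
  bx <- h$beta_exp * s
  by <- h$beta_out * s
  if (sd(bx) == 0)
    stop("degenerate-design error: no variance in exposure effects")
  w <- 1 / h$se_out^2
  fit <- wls_fit(bx, by, w)
  infl <- max(1, sqrt(fit$rss_w / (J - 2)))
  se <- fit$se_unscaled * infl
  est <- new_mr_estimate("egger", fit$coef[["slope"]], se[["slope"]], J,
                         q_stat = fit$rss_w, q_df = J - 2,
                         q_pval = pchisq(fit$rss_w, J - 2, lower.tail = FALSE),
                         egger_intercept = fit$coef[["intercept"]],
                         egger_intercept_se = se[["intercept"]],
                         exposure = h$exposure_name, outcome = h$outcome_name)
  est$egger_intercept_pval <-
    2 * pnorm(-abs(est$egger_intercept / est$egger_intercept_se))
  est
}

# Inverse-variance weighted median of ratio estimates b with SEs se:
# order the ratios, accumulate normalized weights, and interpolate linearly
# to the ratio at cumulative weight 1/2.
weighted_median_point <- function(b, se) {
  w <- 1 / se^2
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  below <- which(cw < 0.5)
  if (length(below) == 0) return(b[1])
  i <- max(below)
  if (i == length(b)) return(b[length(b)])
  b[i] + (b[i + 1] - b[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
}

#' Weighted median causal estimate
#'
#' The inverse-variance weighted median of the per-variant Wald ratios:
#' consistent when variants contributing at least half the weight are valid
#' instruments, hence robust to up to 50% invalid weight.  The standard error
#' comes from a seeded parametric bootstrap: each ratio is resampled from
#' `N(ratio_j, se_j^2)` (weights held fixed), the weighted median recomputed,
#' and the SD over replicates taken.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed making the SE reproducible.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$beta_exp)
  if (J < 3) stop("data error: weighted median requires at least 3 variants")
  wr <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  beta <- weighted_median_point(wr$ratio, wr$ratio_se)
  boots <- withr::with_seed(seed, {
    draws <- matrix(rnorm(J * n_boot, mean = wr$ratio, sd = wr$ratio_se),
                    nrow = J)
    apply(draws, 2, weighted_median_point, se = wr$ratio_se)
  })
  new_mr_estimate("weighted_median", beta, sd(boots), J,
                  exposure = h$exposure_name, outcome = h$outcome_name)
}

#' Cochran's Q heterogeneity test
#'
#' Heterogeneity of the per-variant Wald ratios about the IVW estimate:
#' `Q = sum w_j (ratio_j - beta_ivw)^2`, referred to chi-square on J - 1
#' degrees of freedom.  Excess Q signals pleiotropy or model misfit.
#'
#' @param h A `harmonized_set` with at least 2 variants.
#' @return List with `q`, `df`, and `pval`.
#' @export
cochran_q <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (length(h$beta_exp) < 2)
    stop("data error: Cochran's Q requires at least 2 variants")
  est <- mr_ivw(h, "fixed")
  list(q = est$q_stat, df = est$q_df, pval = est$q_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the random-effects IVW estimate J times, omitting one variant
#' each, in variant-id order.  An omission is flagged influential when it
#' flips the sign of the estimate or moves its p-value across 0.05 relative
#' to the full-set estimate.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @param alpha Significance level used for the influence flag.
#' @return data.frame with one row per omitted variant: `omitted_snp_id`,
#'   `beta`, `se`, `lci`, `uci`, `pval`, `influential`.
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$beta_exp)
  if (J < 3) stop("data error: leave-one-out requires at least 3 variants")
  full <- mr_ivw(h, "random")
  ord <- order(h$snp_ids)
  rows <- lapply(ord, function(k) {
    est <- mr_ivw(subset_harmonized(h, -k), "random")
    data.frame(omitted_snp_id = h$snp_ids[k], beta = est$beta, se = est$se,
               lci = est$lci, uci = est$uci, pval = est$pval,
               influential = sign(est$beta) != sign(full$beta) ||
                 (est$pval < alpha) != (full$pval < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
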