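# Independent oracles and fixture builders used across the suite.

# Build a harmonized set directly from aligned effect vectors.
make_h <- function(beta_exp, se_exp, beta_out, se_out, ids = NULL) {
  mrmediate:::harmonized_set(beta_exp, se_exp, beta_out, se_out, ids)
}

# Conflict indicator for clumping: same chromosome, strictly within the
# window, and r^2 at or above the threshold.
clump_conflicts <- function(records, ld, r2_threshold, window_bp) {
  n <- nrow(records)
  conf <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    conf[i, j] <- records$chrom[i] == records$chrom[j] &&
      abs(records$pos[i] - records$pos[j]) < window_bp &&
      ld[records$snp_id[i], records$snp_id[j]] >= r2_threshold
  }
  conf
}

# Brute-force clumping oracle: enumerate all subsets and return the unique
# one that is (a) conflict-free and (b) greedy-dominant -- every excluded
# record conflicts with a kept record of strictly smaller priority, where
# priority is ascending (pval, chrom, pos, snp_id).  That characterization
# has exactly one solution: the greedy index-variant selection.
oracle_clump_bruteforce <- function(records, ld, r2_threshold = 0.001,
                                    window_bp = 1e7) {
  ord <- order(records$pval, records$chrom, records$pos, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  conf <- clump_conflicts(rec, ld, r2_threshold, window_bp)
  solutions <- list()
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) == 0) next
    if (any(conf[S, S])) next
    excluded <- setdiff(seq_len(n), S)
    dominated <- vapply(excluded, function(e)
      any(conf[e, S[S < e]]), logical(1))
    if (all(dominated)) solutions[[length(solutions) + 1]] <- S
  }
  stopifnot(length(solutions) == 1)
  rec[solutions[[1]], , drop = FALSE]
}

# Weighted-median oracle: invert the piecewise-linear cumulative weight
# function with stats::approx rather than an explicit bracketing search.
oracle_weighted_median <- function(b, se) {
  w <- 1 / se^2
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(b[1])
  if (0.5 >= cw[length(cw)]) return(b[length(b)])
  stats::approx(cw, b, xout = 0.5, ties = "ordered")$y
}

# Random summary-statistics table for instrument tests: a handful of
# chromosomes, positions inside/outside typical windows, valid invariants.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(snp_id = sprintf("rs%04d", sample.int(9999, n)),
               chrom = as.character(sample.int(3, n, replace = TRUE)),
               pos = sample.int(3e7, n),
               effect_allele = sample(c("A", "C"), n, replace = TRUE),
               other_allele = "G",
               eaf = runif(n, 0.05, 0.95),
               beta = rnorm(n, 0, 0.05),
               se = runif(n, 0.005, 0.02),
               pval = runif(n)^3,
               n = 50000,
               stringsAsFactors = FALSE)
  })
}

# Random symmetric r^2 matrix over the records' ids, with a point mass at 0
# so sub-threshold and absent pairs both occur.
random_ld <- function(records, seed) {
  withr::with_seed(seed, {
    n <- nrow(records)
    m <- matrix(0, n, n, dimnames = list(records$snp_id, records$snp_id))
    vals <- runif(n * (n - 1) / 2)
    vals[runif(length(vals)) < 0.4] <- 0
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    diag(m) <- 1
    m
  })
}

# Full exposure -> mediator pipeline on one simulated study; returns the IVW
# estimate (and optionally the other estimators) for recovery experiments.
pipeline_step1 <- function(config, estimators = "ivw") {
  st <- simulate_study(config)
  iv <- suppressMessages(select_instruments(st$exposure_stats, "exposure"))
  h <- harmonize(iv$records, st$mediator_stats)
  out <- list(ivw = mr_ivw(h, "random"))
  if ("egger" %in% estimators) out$egger <- mr_egger(h)
  if ("wm" %in% estimators)
    out$wm_point <- {
      wr <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
      mrmediate:::weighted_median_point(wr$ratio, wr$ratio_se)
    }
  out
}
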