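#' Configuration for the summary-statistics simulator
#'
#' Builds and validates the parameter set for [simulate_study()].  The
#' generator emulates a two-sample MR design with a causal chain
#' exposure -> mediator -> outcome: per-SNP effects on the exposure are drawn
#' from N(0, sigma_gamma^2), propagate to the mediator and outcome through the
#' chain coefficients, and are observed with allele-frequency-dependent
#' sampling noise, se = 1 / sqrt(2 EAF (1 - EAF) N).
#'
#' Horizontal pleiotropy is injected on a `prop_invalid` fraction of SNPs as
#' direct SNP -> mediator and SNP -> outcome effects drawn from
#' N(pleiotropy_mean, pleiotropy_sd^2) and applied in the orientation of the
#' exposure-increasing allele (directional pleiotropy is only well defined
#' relative to that orientation; allele coding itself is arbitrary).
#'
#' @param n_snps Number of variants J (>= 2).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes per trait (>= 3).
#' @param sigma_gamma SD of true per-SNP exposure effects.  The default 0.08
#'   makes the selected instrument panel strong (F well above 10) so that
#'   two-sample regression-dilution bias is negligible relative to sampling
#'   error.
#' @param beta_xm Causal effect of exposure on mediator.
#' @param beta_my Causal effect of mediator on outcome.
#' @param beta_xy_direct Direct exposure -> outcome effect (not through the
#'   mediator).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the horizontal
#'   pleiotropy effects on invalid SNPs (mean 0 gives balanced, nonzero mean
#'   directional pleiotropy).
#' @param prop_invalid Fraction of SNPs carrying pleiotropy, in \[0, 1\].
#' @param eaf_range Interval inside (0, 1) from which effect-allele
#'   frequencies are drawn uniformly.
#' @param ld_block_size,ld_rho LD structure: variants are grouped into blocks
#'   of `ld_block_size` with within-block r^2 = `ld_rho`^|i-k| and zero r^2
#'   across blocks.  Defaults give mutually independent variants, emulating
#'   post-clumping data.
#' @param prop_palindromic Fraction of variants forced to ambiguous A/T or G/C
#'   allele pairs.
#' @param seed Integer RNG seed; the simulation is a pure function of the
#'   configuration.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_snps = 100L,
                       n_exposure = 50000L, n_mediator = 50000L,
                       n_outcome = 50000L,
                       sigma_gamma = 0.08,
                       beta_xm = 0.3, beta_my = 0.2, beta_xy_direct = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       prop_invalid = 0,
                       eaf_range = c(0.05, 0.95),
                       ld_block_size = 1L, ld_rho = 0,
                       prop_palindromic = 0.2,
                       seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), n_exposure = as.integer(n_exposure),
              n_mediator = as.integer(n_mediator),
              n_outcome = as.integer(n_outcome),
              sigma_gamma = sigma_gamma, beta_xm = beta_xm, beta_my = beta_my,
              beta_xy_direct = beta_xy_direct,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              prop_invalid = prop_invalid, eaf_range = as.numeric(eaf_range),
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              prop_palindromic = prop_palindromic, seed = as.integer(seed))
  fail <- function(field, why) stop("configuration error: field '", field,
                                    "' ", why, call. = FALSE)
  if (is.na(cfg$n_snps) || cfg$n_snps < 2) fail("n_snps", "must be >= 2")
  for (f in c("n_exposure", "n_mediator", "n_outcome"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 3) fail(f, "must be >= 3")
  if (!is.finite(cfg$sigma_gamma) || cfg$sigma_gamma < 0)
    fail("sigma_gamma", "must be a nonnegative number")
  if (!is.finite(cfg$pleiotropy_sd) || cfg$pleiotropy_sd < 0)
    fail("pleiotropy_sd", "must be a nonnegative number")
  if (!is.finite(cfg$prop_invalid) || cfg$prop_invalid < 0 ||
      cfg$prop_invalid > 1) fail("prop_invalid", "must lie in [0, 1]")
  if (length(cfg$eaf_range) != 2 || any(!is.finite(cfg$eaf_range)) ||
      cfg$eaf_range[1] <= 0 || cfg$eaf_range[2] >= 1 ||
      cfg$eaf_range[1] > cfg$eaf_range[2])
    fail("eaf_range", "must be an ordered interval within (0, 1)")
  if (is.na(cfg$ld_block_size) || cfg$ld_block_size < 1)
    fail("ld_block_size", "must be >= 1")
  if (!is.finite(cfg$ld_rho) || cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    fail("ld_rho", "must lie in [0, 1)")
  if (!is.finite(cfg$prop_palindromic) || cfg$prop_palindromic < 0 ||
      cfg$prop_palindromic > 1)
    fail("prop_palindromic", "must lie in [0, 1]")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Random allele flip of one trait table: swap allele labels, negate beta,
# complement EAF.  `flip` is a logical vector over rows.
flip_records <- function(df, flip) {
  ea <- df$effect_allele
  df$effect_allele[flip] <- df$other_allele[flip]
  df$other_allele[flip] <- ea[flip]
  df$beta[flip] <- -df$beta[flip]
  df$eaf[flip] <- 1 - df$eaf[flip]
  df
}

#' Simulate exposure, mediator, and outcome GWAS summary statistics
#'
#' Generates three coherent summary-statistics tables under the causal chain
#' described in [sim_config()], with known ground truth.  For SNP j with true
#' exposure effect `gamma_j ~ N(0, sigma_gamma^2)` and exposure-increasing
#' orientation `s_j = sign(gamma_j)`:
#'
#' * true mediator effect  = `beta_xm * gamma_j + s_j * alphaM_j`
#' * true outcome effect   = `(beta_xy_direct + beta_my * beta_xm) * gamma_j +
#'                            beta_my * s_j * alphaM_j + s_j * alphaY_j`
#'
#' where `alphaM_j`, `alphaY_j` are the pleiotropy draws (zero on valid SNPs).
#' Observed betas add N(0, se^2) noise with se = 1/sqrt(2 EAF (1-EAF) N); each
#' trait table then independently randomizes its allele coding (swapping
#' labels, negating beta, complementing EAF) so that downstream harmonization
#' is exercised.  P-values are two-sided normal on beta/se.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `simulated_study`: a list with elements
#'   `exposure_stats`, `mediator_stats`, `outcome_stats` (data.frames in the
#'   [gwas_columns] dialect, same variants in the same order), `ld_matrix`
#'   (J x J symmetric r^2 matrix with unit diagonal, dimnames = SNP ids),
#'   `truth` (realized per-SNP true effects, pleiotropy draws, invalid and
#'   palindromic indicators, per-table allele-flip indicators), and `config`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  J <- config$n_snps
  withr::with_seed(config$seed, {
    eaf <- runif(J, config$eaf_range[1], config$eaf_range[2])
    palindromic <- runif(J) < config$prop_palindromic
    ea <- character(J); oa <- character(J)
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    for (j in seq_len(J)) {
      if (palindromic[j]) {
        p <- pal_pairs[[sample.int(4L, 1L)]]
      } else {
        a1 <- sample(names(DNA_COMPLEMENT), 1L)
        a2 <- sample(setdiff(names(DNA_COMPLEMENT),
                             c(a1, DNA_COMPLEMENT[[a1]])), 1L)
        p <- c(a1, a2)
      }
      ea[j] <- p[1]; oa[j] <- p[2]
    }

    gamma <- rnorm(J, 0, config$sigma_gamma)
    invalid <- runif(J) < config$prop_invalid
    alpha_m <- ifelse(invalid,
                      rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd), 0)
    alpha_y <- ifelse(invalid,
                      rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd), 0)
    s <- sign(gamma); s[s == 0] <- 1

    true_exp <- gamma
    true_med <- config$beta_xm * gamma + s * alpha_m
    true_out <- (config$beta_xy_direct + config$beta_my * config$beta_xm) *
      gamma + config$beta_my * s * alpha_m + s * alpha_y

    # genomic placement: one LD block per stretch of ld_block_size variants,
    # blocks cycled over 22 chromosomes and spaced 20 Mb so inter-block pairs
    # are outside any clumping window
    block <- (seq_len(J) - 1L) %/% config$ld_block_size
    within <- (seq_len(J) - 1L) %% config$ld_block_size
    chrom <- as.character(block %% 22L + 1L)
    pos <- (block %/% 22L) * 2e7 + within * 1e5 + 1

    snp_id <- sprintf("rs%06d", seq_len(J))
    make_table <- function(true_effect, n) {
      se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
      beta <- true_effect + rnorm(J, 0, se)
      data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)),
                 n = n, stringsAsFactors = FALSE)
    }
    exposure <- make_table(true_exp, config$n_exposure)
    mediator <- make_table(true_med, config$n_mediator)
    outcome <- make_table(true_out, config$n_outcome)

    flip_e <- runif(J) < 0.5
    flip_m <- runif(J) < 0.5
    flip_o <- runif(J) < 0.5
    exposure <- flip_records(exposure, flip_e)
    mediator <- flip_records(mediator, flip_m)
    outcome <- flip_records(outcome, flip_o)

    ld <- matrix(0, J, J, dimnames = list(snp_id, snp_id))
    for (b in unique(block)) {
      idx <- which(block == b)
      ld[idx, idx] <- config$ld_rho ^ abs(outer(idx, idx, "-"))
    }
    diag(ld) <- 1

    structure(list(
      exposure_stats = exposure, mediator_stats = mediator,
      outcome_stats = outcome,
      ld_matrix = ld,
      truth = list(gamma = gamma, alpha_mediator = alpha_m,
                   alpha_outcome = alpha_y, invalid = invalid,
                   palindromic = palindromic, eaf = eaf,
                   true_exposure = true_exp, true_mediator = true_med,
                   true_outcome = true_out,
                   flip_exposure = flip_e, flip_mediator = flip_m,
                   flip_outcome = flip_o,
                   total_effect = config$beta_xy_direct +
                     config$beta_my * config$beta_xm,
                   indirect_effect = config$beta_xm * config$beta_my),
      config = config), class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated two-sample MR study:", x$config$n_snps, "SNPs;",
      "N =", x$config$n_exposure, "/", x$config$n_mediator, "/",
      x$config$n_outcome, "(exposure/mediator/outcome)\n")
  cat("  chain: beta_xm =", x$config$beta_xm, ", beta_my =", x$config$beta_my,
      ", direct =", x$config$beta_xy_direct,
      "; invalid fraction =", x$config$prop_invalid, "\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the three summary-statistics tables in the canonical TSV dialect,
#' the LD matrix as a `snp_a / snp_b / r2` pair list (upper triangle,
#' nonzero entries), and the configuration plus realized ground truth as YAML.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir, prefix = "sim") {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, paste0(prefix, "_exposure.tsv")),
             mediator = file.path(dir, paste0(prefix, "_mediator.tsv")),
             outcome = file.path(dir, paste0(prefix, "_outcome.tsv")),
             ld = file.path(dir, paste0(prefix, "_ld.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.yaml")))
  write_summary_stats(study$exposure_stats, paths[["exposure"]])
  write_summary_stats(study$mediator_stats, paths[["mediator"]])
  write_summary_stats(study$outcome_stats, paths[["outcome"]])
  ut <- upper.tri(study$ld_matrix)
  nz <- which(ut & study$ld_matrix > 0, arr.ind = TRUE)
  ld_pairs <- data.frame(snp_a = rownames(study$ld_matrix)[nz[, 1]],
                         snp_b = colnames(study$ld_matrix)[nz[, 2]],
                         r2 = study$ld_matrix[nz])
  utils::write.table(ld_pairs, paths[["ld"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(config = unclass(study$config),
                        truth = lapply(study$truth, unname)),
                   paths[["truth"]])
  invisible(paths)
}
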