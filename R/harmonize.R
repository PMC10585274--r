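is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Strand complement; applies to single ACGT bases only, so indels and
# multi-base alleles are compared literally.
complement_allele <- function(a) {
  ifelse(a %in% c("A", "C", "G", "T"), chartr("ACGT", "TGCA", a), a)
}

#' Harmonize exposure and outcome effects onto a common effect allele
#'
#' For each variant shared between the two tables the outcome record is
#' aligned to the exposure's effect allele: kept as-is when the alleles match
#' directly; beta negated and EAF complemented when they match with
#' effect/other swapped; strand-complemented first (A<->T, C<->G) when they
#' match only on the opposite strand.  Palindromic variants (A/T or G/C),
#' whose strand cannot be resolved from the alleles, are dropped when either
#' study's EAF lies within `palindromic_eaf_window` of 0.5 and otherwise
#' aligned by allele-frequency concordance.  Variants whose alleles cannot be
#' reconciled are dropped.  Output vectors are ordered by variant id.
#'
#' @param exposure_records,outcome_records Summary-statistics data.frames
#'   sharing at least one `snp_id`.
#' @param palindromic_eaf_window Half-width of the ambiguity zone around
#'   EAF = 0.5 within which palindromic variants are discarded.
#' @param exposure_name,outcome_name Trait labels carried into the result.
#' @return Object of class `harmonized_set`: aligned vectors `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out` over `snp_ids`, plus
#'   drop counters `n_dropped_palindromic` and `n_dropped_mismatch`.
#' @export
harmonize <- function(exposure_records, outcome_records,
                      palindromic_eaf_window = 0.08,
                      exposure_name = "exposure", outcome_name = "outcome") {
  shared <- intersect(exposure_records$snp_id, outcome_records$snp_id)
  if (length(shared) == 0)
    stop("data error: no shared variants between ", exposure_name, " and ",
         outcome_name)
  shared <- sort(shared)
  ex <- exposure_records[match(shared, exposure_records$snp_id), ,
                         drop = FALSE]
  ou <- outcome_records[match(shared, outcome_records$snp_id), , drop = FALSE]

  n <- length(shared)
  keep <- rep(TRUE, n)
  n_pal <- 0L; n_mis <- 0L
  bo <- ou$beta; fo <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    ea_e <- ex$effect_allele[i]; oa_e <- ex$other_allele[i]
    ea_o <- ou$effect_allele[i]; oa_o <- ou$other_allele[i]
    if (ea_o == ea_e && oa_o == oa_e) {
      # direct match
    } else if (ea_o == oa_e && oa_o == ea_e) {
      bo[i] <- -bo[i]; fo[i] <- 1 - fo[i]
    } else {
      ea_c <- complement_allele(ea_o); oa_c <- complement_allele(oa_o)
      if (ea_c == ea_e && oa_c == oa_e) {
        # same orientation on the opposite strand
      } else if (ea_c == oa_e && oa_c == ea_e) {
        bo[i] <- -bo[i]; fo[i] <- 1 - fo[i]
      } else {
        keep[i] <- FALSE; n_mis <- n_mis + 1L
        next
      }
    }
    if (pal[i]) {
      if (abs(ex$eaf[i] - 0.5) <= palindromic_eaf_window ||
          abs(fo[i] - 0.5) <= palindromic_eaf_window) {
        keep[i] <- FALSE; n_pal <- n_pal + 1L
      } else if ((ex$eaf[i] - 0.5) * (fo[i] - 0.5) < 0) {
        # frequencies disagree: the outcome study reports the complementary
        # strand's allele as its effect allele
        bo[i] <- -bo[i]; fo[i] <- 1 - fo[i]
      }
    }
  }
  if (!any(keep)) {
    stop("data error: no variants survive harmonization (",
         n_pal, " palindromic, ", n_mis, " irreconcilable)")
  }
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 snp_ids = shared[keep],
                 beta_exp = ex$beta[keep], se_exp = ex$se[keep],
                 beta_out = bo[keep], se_out = ou$se[keep],
                 eaf_exp = ex$eaf[keep], eaf_out = fo[keep],
                 n_dropped_palindromic = n_pal, n_dropped_mismatch = n_mis),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set ", x$exposure_name, " -> ", x$outcome_name, ": ",
      length(x$snp_ids), " variants (dropped ", x$n_dropped_palindromic,
      " palindromic, ", x$n_dropped_mismatch, " irreconcilable)\n", sep = "")
  invisible(x)
}

# Subset of a harmonized set by index, preserving the class and counters.
subset_harmonized <- function(h, idx) {
  h$snp_ids <- h$snp_ids[idx]
  h$beta_exp <- h$beta_exp[idx]; h$se_exp <- h$se_exp[idx]
  h$beta_out <- h$beta_out[idx]; h$se_out <- h$se_out[idx]
  h$eaf_exp <- h$eaf_exp[idx]; h$eaf_out <- h$eaf_out[idx]
  h
}

# Build a harmonized_set directly from aligned vectors (used by simulations
# and tests that start from already-oriented effects).
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_ids = NULL, exposure_name = "exposure",
                           outcome_name = "outcome") {
  stopifnot(length(beta_exp) == length(beta_out),
            length(se_exp) == length(beta_exp),
            length(se_out) == length(beta_exp),
            all(se_exp > 0), all(se_out > 0))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_along(beta_exp))
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 snp_ids = snp_ids, beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out,
                 eaf_exp = rep(NA_real_, length(beta_exp)),
                 eaf_out = rep(NA_real_, length(beta_exp)),
                 n_dropped_palindromic = 0L, n_dropped_mismatch = 0L),
            class = "harmonized_set")
}
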