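#' Select variants associated with the exposure
#'
#' Keeps the records whose p-value falls strictly below the instrument
#' threshold, preserving input order.  The default 5e-5 is the relaxed
#' genome-wide threshold commonly used when few variants reach 5e-8.
#'
#' @param records Summary-statistics data.frame ([gwas_columns]).
#' @param p_threshold Inclusion threshold; records with `pval < p_threshold`
#'   are retained.
#' @return Filtered data.frame (possibly zero rows, with a warning).
#' @export
select_by_pvalue <- function(records, p_threshold = 5e-5) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  out <- records[records$pval < p_threshold, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no variants pass p < ", format(p_threshold),
            "; instrument set is empty")
  rownames(out) <- NULL
  out
}

#' Build a symmetric r-squared matrix from a pair list
#'
#' Converts a long-format LD table (`snp_a`, `snp_b`, `r2`) into a square
#' symmetric matrix over `snp_ids`.  Pairs absent from the table default to
#' r^2 = 0; the diagonal is 1.
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @param snp_ids Character vector of variant ids covering the matrix.
#' @return Square numeric matrix with `snp_ids` dimnames.
#' @export
ld_matrix_from_pairs <- function(pairs, snp_ids) {
  m <- matrix(0, length(snp_ids), length(snp_ids),
              dimnames = list(snp_ids, snp_ids))
  diag(m) <- 1
  if (nrow(pairs) > 0) {
    keep <- pairs$snp_a %in% snp_ids & pairs$snp_b %in% snp_ids
    pairs <- pairs[keep, , drop = FALSE]
    m[cbind(pairs$snp_a, pairs$snp_b)] <- pairs$r2
    m[cbind(pairs$snp_b, pairs$snp_a)] <- pairs$r2
  }
  m
}

# Deterministic candidate ordering used by clumping: ascending p, ties broken
# by (chrom, pos, snp_id).
clump_order <- function(records) {
  order(records$pval, records$chrom, records$pos, records$snp_id)
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the not-yet-removed record with the smallest p-value as an
#' index variant and removes every remaining record on the same chromosome
#' strictly within `window_bp` of it whose r^2 with the index is at least
#' `r2_threshold`.  Defaults mirror the stringent r^2 < 0.001 / 10 Mb clumping
#' convention.  Ties on p are broken by (chrom, pos, snp_id) so the result is
#' invariant to input row order.
#'
#' @param records Candidate summary-statistics data.frame.
#' @param ld_matrix Symmetric r^2 matrix whose dimnames cover all records
#'   (see [ld_matrix_from_pairs()]), or `NULL` for mutually independent
#'   variants (all r^2 = 0).
#' @param r2_threshold Removal threshold on pairwise r^2.
#' @param window_bp Clumping window in base pairs around the index variant.
#' @return The index records, sorted by ascending p-value.
#' @export
clump <- function(records, ld_matrix = NULL, r2_threshold = 0.001,
                  window_bp = 1e7) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  if (!is.null(ld_matrix)) {
    miss <- setdiff(records$snp_id, rownames(ld_matrix))
    if (length(miss) > 0)
      stop("data error: variant(s) missing from LD matrix: ",
           paste(miss, collapse = ", "))
  }
  rec <- records[clump_order(records), , drop = FALSE]
  alive <- rep(TRUE, nrow(rec))
  kept <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) < window_bp)
    if (length(cand) > 0) {
      r2 <- if (is.null(ld_matrix)) rep(0, length(cand))
            else ld_matrix[rec$snp_id[i], rec$snp_id[cand]]
      alive[cand[r2 >= r2_threshold]] <- FALSE
    }
  }
  out <- rec[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-variant variance explained
#'
#' Two modes are provided.  `"printed"` is the textbook shorthand
#' `2 EAF (1 - EAF) (Beta/SE)^2`; because `Beta/SE` is the association z-score
#' this quantity approximates N times the variance explained and can exceed 1,
#' so it is retained for fidelity to published usage but not recommended for
#' F-statistics.  `"normalized"` is the properly scaled per-variant
#' `r^2 = z^2 / (n + z^2)`, the pipeline default.
#'
#' @param record One-or-more-row summary-statistics data.frame.
#' @param mode `"normalized"` (default) or `"printed"`.
#' @return Numeric vector of per-variant r^2 values.
#' @export
snp_r2 <- function(record, mode = c("normalized", "printed")) {
  mode <- match.arg(mode)
  z2 <- (record$beta / record$se)^2
  if (mode == "printed") 2 * record$eaf * (1 - record$eaf) * z2
  else z2 / (record$n + z2)
}

#' Instrument-strength F-statistic
#'
#' `F = (R^2 / K) / ((1 - R^2) / (N - K - 1))` for an instrument set of K
#' variants jointly explaining R^2 of the exposure in a sample of size N.
#' F below 10 conventionally flags weak instruments.
#'
#' @param r2_total Total variance explained, in \[0, 1).
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments.
#' @return The F-statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (!is.finite(r2_total) || r2_total < 0 || r2_total >= 1)
    stop("domain error: r2_total must lie in [0, 1)")
  if (k < 1 || n <= k + 1)
    stop("domain error: require n > k + 1 >= 2")
  (r2_total / k) / ((1 - r2_total) / (n - k - 1))
}

#' Assemble an instrument set with strength diagnostics
#'
#' Packages index records with per-variant and total variance explained and
#' the set-level F-statistic, sorted by ascending p-value.
#'
#' @param records Index-variant records (already thresholded/clumped).
#' @param exposure_name Label for the exposure trait.
#' @param p_threshold,clump_r2,clump_window_bp Selection settings recorded for
#'   provenance.
#' @param r2_mode Variance-explained mode passed to [snp_r2()].
#' @return Object of class `instrument_set`.
#' @export
instrument_set <- function(records, exposure_name = "exposure",
                           p_threshold = 5e-5, clump_r2 = 0.001,
                           clump_window_bp = 1e7,
                           r2_mode = c("normalized", "printed")) {
  r2_mode <- match.arg(r2_mode)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  records <- records[order(records$pval, records$chrom, records$pos,
                           records$snp_id), , drop = FALSE]
  rownames(records) <- NULL
  r2 <- snp_r2(records, mode = r2_mode)
  n <- stats::median(records$n)
  k <- nrow(records)
  r2_total <- sum(r2)
  f <- if (r2_total < 1 && n > k + 1) f_statistic(r2_total, n, k) else NA_real_
  structure(list(exposure_name = exposure_name, records = records,
                 p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_bp = clump_window_bp, r2_mode = r2_mode,
                 r2_per_snp = r2, r2_total = r2_total, n = n,
                 f_stat = f),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for", x$exposure_name, ":", nrow(x$records),
      "variants, R2 =", signif(x$r2_total, 4),
      ", F =", signif(x$f_stat, 5), "\n")
  invisible(x)
}

# Iterative weak-instrument pruning on a vector of per-variant r2
# contributions: drop the smallest contribution until the set-level F clears
# f_min or one variant remains.  Returns the indices kept.
prune_weak_r2 <- function(r2_per_snp, n, f_min) {
  keep <- seq_along(r2_per_snp)
  repeat {
    k <- length(keep)
    r2 <- sum(r2_per_snp[keep])
    f <- if (r2 < 1 && n > k + 1) f_statistic(r2, n, k) else NA_real_
    if (k <= 1 || (is.finite(f) && f >= f_min)) return(keep)
    keep <- keep[-which.min(r2_per_snp[keep])]
  }
}

#' Weak-instrument filtering
#'
#' If the set-level F-statistic falls below `f_min` (conventionally 10), drops
#' the variant contributing least variance explained and recomputes,
#' iterating until F clears the threshold or a single variant remains.  The
#' F-statistic is a property of the whole set, so exclusion of "weak IVs" is
#' operationalized as this iterative pruning.
#'
#' @param iset An [instrument_set()].
#' @param f_min Minimum acceptable F.
#' @return The (possibly pruned) `instrument_set`.
#' @export
filter_weak <- function(iset, f_min = 10) {
  stopifnot(inherits(iset, "instrument_set"))
  if (is.finite(iset$f_stat) && iset$f_stat >= f_min) {
    message("filter_weak: F = ", signif(iset$f_stat, 5), " >= ", f_min,
            "; set unchanged")
    return(iset)
  }
  keep <- prune_weak_r2(iset$r2_per_snp, iset$n, f_min)
  if (length(keep) < nrow(iset$records))
    message("filter_weak: dropped ", nrow(iset$records) - length(keep),
            " weakest variant(s) to reach F >= ", f_min)
  instrument_set(iset$records[keep, , drop = FALSE], iset$exposure_name,
                 iset$p_threshold, iset$clump_r2, iset$clump_window_bp,
                 iset$r2_mode)
}

#' Full instrument selection pipeline
#'
#' p-value thresholding, LD clumping, and weak-instrument filtering in one
#' call.
#'
#' @param records Exposure summary statistics.
#' @param exposure_name Trait label.
#' @param p_threshold Association threshold (variants with smaller p kept).
#' @param ld_matrix Optional r^2 matrix for clumping (`NULL` = independent).
#' @param clump_r2,clump_window_bp Clumping parameters.
#' @param f_min Minimum set-level F; `NA` disables the filter.
#' @param r2_mode Variance-explained mode.
#' @return An [instrument_set()].
#' @export
select_instruments <- function(records, exposure_name = "exposure",
                               p_threshold = 5e-5, ld_matrix = NULL,
                               clump_r2 = 0.001, clump_window_bp = 1e7,
                               f_min = 10,
                               r2_mode = c("normalized", "printed")) {
  r2_mode <- match.arg(r2_mode)
  sel <- select_by_pvalue(records, p_threshold)
  if (nrow(sel) == 0)
    stop("data error: no instruments for ", exposure_name,
         " at p < ", format(p_threshold))
  idx <- clump(sel, ld_matrix, clump_r2, clump_window_bp)
  iset <- instrument_set(idx, exposure_name, p_threshold, clump_r2,
                         clump_window_bp, r2_mode)
  if (is.finite(f_min)) iset <- filter_weak(iset, f_min)
  iset
}
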