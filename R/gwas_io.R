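#' Canonical summary-statistics columns
#'
#' Column order of the tab-separated GWAS summary-statistics dialect used
#' throughout the package: variant ID, chromosome, 1-based position, effect
#' allele, other allele, effect-allele frequency, per-allele effect (log odds
#' ratio for binary traits), standard error, p-value, sample size.
#'
#' @format Character vector of the ten canonical column names.
#' @export
gwas_columns <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

# Row-wise validity under the record invariants: positive SE, frequency
# strictly inside (0,1), p in (0,1], distinct alleles, position >= 1.
gwas_record_valid <- function(df) {
  ok <- is.finite(df$se) & df$se > 0 &
    is.finite(df$eaf) & df$eaf > 0 & df$eaf < 1 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    is.finite(df$beta) &
    is.finite(df$pos) & df$pos >= 1 &
    !is.na(df$effect_allele) & !is.na(df$other_allele) &
    df$effect_allele != df$other_allele
  ok & !is.na(ok)
}

#' Read GWAS summary statistics from a TSV file
#'
#' Reads a tab-separated summary-statistics table with a header row.  Rows
#' violating the record invariants (non-positive SE, frequency outside (0,1),
#' identical alleles, ...) are dropped with a message reporting the count.
#'
#' @param path Path to a tab-separated file with a header.
#' @param column_map Optional named character vector mapping canonical names to
#'   the file's headers, e.g. `c(snp_id = "SNP", pval = "P")`, for files using
#'   a nonstandard dialect.
#' @return A `data.frame` with the columns in [gwas_columns], one row per
#'   retained variant, input order preserved.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("format error: empty file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0 && ncol(df) <= 1) stop("format error: empty file: ", path)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), gwas_columns)
    if (length(bad) > 0)
      stop("column_map names must be canonical columns; unknown: ",
           paste(bad, collapse = ", "))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop("format error: mapped column '", src, "' not present in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(gwas_columns, names(df))
  if (length(missing) > 0)
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "),
         " (required: ", paste(gwas_columns, collapse = ", "), ")")
  df <- df[, gwas_columns, drop = FALSE]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    df[[col]] <- as.numeric(df[[col]])
  keep <- gwas_record_valid(df)
  if (any(!keep))
    message("read_summary_stats: dropped ", sum(!keep),
            " row(s) violating record invariants in ", basename(path))
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write GWAS summary statistics to a TSV file
#'
#' Writes records in the canonical column order, tab-separated, with numeric
#' columns at full double precision so that a write/read round trip is exact.
#'
#' @param records Nonempty `data.frame` of summary statistics.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a nonempty data.frame")
  missing <- setdiff(gwas_columns, names(records))
  if (length(missing) > 0)
    stop("records missing column(s): ", paste(missing, collapse = ", "))
  out <- records[, gwas_columns, drop = FALSE]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("I/O error writing ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Write an analysis report table
#'
#' Serializes a homogeneous collection of MR estimates or mediation results as
#' a TSV.  MR estimates produce the columns `Exposure, Outcome, nSNP, Beta,
#' LCI, UCI, p`; mediation results produce `Exposure, Mediate, Outcome, OR,
#' LCI, UCI, p` (the indirect effect on the odds-ratio scale).
#'
#' @param results List of `mr_estimate` or of `mediation_result` objects.  May
#'   be empty, in which case a header-only file of the type given by `type` is
#'   written.
#' @param path Output file path.
#' @param type Report layout used when `results` is empty.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, type = c("mr", "mediation")) {
  type <- match.arg(type)
  if (length(results) > 0) {
    is_mr <- vapply(results, inherits, logical(1), what = "mr_estimate")
    is_med <- vapply(results, inherits, logical(1), what = "mediation_result")
    if (all(is_mr)) type <- "mr"
    else if (all(is_med)) type <- "mediation"
    else stop("usage error: results must be all mr_estimate or all ",
              "mediation_result objects, not a mixture")
  }
  if (type == "mr") {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(Exposure = r$exposure, Outcome = r$outcome, nSNP = r$n_snp,
                 Beta = r$beta, LCI = r$lci, UCI = r$uci, p = r$pval,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df))
      df <- data.frame(Exposure = character(), Outcome = character(),
                       nSNP = integer(), Beta = numeric(), LCI = numeric(),
                       UCI = numeric(), p = numeric())
  } else {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(Exposure = r$exposure, Mediate = r$mediator,
                 Outcome = r$outcome, OR = r$or_point, LCI = r$or_lci,
                 UCI = r$or_uci, p = r$indirect_pval, stringsAsFactors = FALSE)
    }))
    if (is.null(df))
      df <- data.frame(Exposure = character(), Mediate = character(),
                       Outcome = character(), OR = numeric(), LCI = numeric(),
                       UCI = numeric(), p = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Published reference IVW and indirect-effect estimates
#'
#' Loads the reference estimates bundled with the package: inverse-variance
#' weighted causal estimates from a published two-sample MR study of three air
#' pollutants (PM2.5, NO2, NOx), nine obesity-related traits, and three
#' COVID-19 phenotypes, together with the study's reported significant
#' indirect (mediated) effects.  Betas are on the log odds-ratio scale for
#' binary outcomes; standard errors are recoverable from the 95% CI bounds as
#' `(UCI - LCI) / 3.92`.  Used to validate the package's product-of-coefficients
#' mediation arithmetic against independently computed results.
#'
#' @return Named list of four data.frames: `pollution_obesity`,
#'   `pollution_covid`, `obesity_covid` (columns `Exposure, Outcome, nSNP,
#'   Beta, LCI, UCI, p`) and `indirect_effects` (columns `Exposure, Mediate,
#'   Outcome, OR, LCI, UCI, p`).
#' @export
load_reference_estimates <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "mrmediate", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(pollution_obesity = rd("ivw_pollution_obesity.tsv"),
       pollution_covid = rd("ivw_pollution_covid.tsv"),
       obesity_covid = rd("ivw_obesity_covid.tsv"),
       indirect_effects = rd("indirect_effects.tsv"))
}
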