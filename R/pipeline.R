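#' Two-sample MR analysis of one exposure/outcome pair
#'
#' Instrument selection, harmonization, and the full estimator battery: IVW
#' (the primary estimate), MR-Egger and weighted median as supplements,
#' Cochran's Q, the Egger intercept, and leave-one-out.  Egger, the weighted
#' median and leave-one-out require at least 3 harmonized variants and are
#' returned as `NULL` below that.
#'
#' @param exposure_records,outcome_records Summary-statistics data.frames.
#' @param exposure_name,outcome_name Trait labels.
#' @param settings Named list as in [run_two_step()], plus `n_boot` (1000) and
#'   `seed` (1) for the weighted-median bootstrap.
#' @return List with `instruments` (the [instrument_set()]), `harmonized`,
#'   `ivw`, `egger`, `weighted_median`, `q`, and `loo`.
#' @export
run_mr <- function(exposure_records, outcome_records,
                   exposure_name = "exposure", outcome_name = "outcome",
                   settings = list()) {
  s <- utils::modifyList(list(p_threshold = 5e-5, clump_r2 = 0.001,
                              clump_window_bp = 1e7, f_min = 10,
                              ld_matrix = NULL,
                              palindromic_eaf_window = 0.08,
                              effects_model = "random", n_boot = 1000,
                              seed = 1L, alpha = 0.05,
                              r2_mode = "normalized"),
                         settings)
  iv <- select_instruments(exposure_records, exposure_name, s$p_threshold,
                           s$ld_matrix, s$clump_r2, s$clump_window_bp,
                           s$f_min, s$r2_mode)
  h <- harmonize(iv$records, outcome_records, s$palindromic_eaf_window,
                 exposure_name, outcome_name)
  J <- length(h$snp_ids)
  list(instruments = iv, harmonized = h,
       ivw = mr_ivw(h, s$effects_model),
       egger = if (J >= 3) mr_egger(h) else NULL,
       weighted_median = if (J >= 3)
         mr_weighted_median(h, s$n_boot, s$seed) else NULL,
       q = if (J >= 2) cochran_q(h) else NULL,
       loo = if (J >= 3) leave_one_out(h, s$alpha) else NULL)
}

#' Build or load a multi-trait analysis configuration
#'
#' A configuration names the summary-statistics files for each trait role and
#' the analysis settings.  It can be given directly as a list or read from a
#' YAML file with top-level keys `schema` (currently `"mrmediate/1"`),
#' `exposures`, `mediators`, `outcomes` (named maps trait -> file path), and
#' optional `settings` and `output_dir`.
#'
#' @param x A named list or a path to a YAML configuration file.
#' @return Validated object of class `analysis_config`.
#' @export
analysis_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("configuration error: file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  cfg <- list(schema = x$schema %||% "mrmediate/1",
              exposures = x$exposures, mediators = x$mediators,
              outcomes = x$outcomes,
              settings = x$settings %||% list(),
              output_dir = x$output_dir %||% ".")
  if (!identical(cfg$schema, "mrmediate/1"))
    stop("configuration error: unsupported schema '", cfg$schema, "'")
  for (role in c("exposures", "mediators", "outcomes")) {
    tr <- cfg[[role]]
    if (is.null(tr) || length(tr) == 0 || is.null(names(tr)) ||
        any(names(tr) == ""))
      stop("configuration error: '", role,
           "' must be a nonempty named map of trait -> file path")
    missing <- unlist(tr)[!file.exists(unlist(tr))]
    if (length(missing) > 0)
      stop("configuration error: missing file(s) for ", role, ": ",
           paste(missing, collapse = ", "))
  }
  structure(cfg, class = "analysis_config")
}

# One log line, appended to the run log and echoed as a message.
log_line <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

#' Run the full three-arm analysis over every trait combination
#'
#' For every (exposure, mediator), (exposure, outcome) and (mediator,
#' outcome) pair, runs [run_mr()]; for every (exposure, mediator, outcome)
#' triple, runs [run_two_step()].  Writes to the output directory:
#' `exposure_mediator.tsv`, `exposure_outcome.tsv`, `mediator_outcome.tsv`
#' (IVW rows in `Exposure / Outcome / nSNP / Beta / LCI / UCI / p` layout),
#' `mediation.tsv` (`Exposure / Mediate / Outcome / OR / LCI / UCI / p`),
#' `sensitivity.tsv` (Egger slope and intercept, weighted median, Cochran's
#' Q, influential leave-one-out count per pair), and `run.log` recording
#' settings, seeds, and the variant counts at each filtering stage.  A
#' failure in one pair or triple is logged and skipped rather than aborting
#' the run.
#'
#' @param config An [analysis_config()] (or list / YAML path coercible to
#'   one).
#' @return Invisibly, a list with the per-pair MR results (`mr`), the
#'   mediation results (`mediation`), and the written file paths (`files`).
#' @export
run_all <- function(config) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  cat("", file = log_path)
  s <- config$settings
  log_line(log_path, "settings: ",
           paste(names(s), vapply(s, function(v) paste(format(v),
                                                       collapse = ","),
                                  character(1)),
                 sep = "=", collapse = " "))

  tables <- list()
  for (role in c("exposures", "mediators", "outcomes"))
    for (trait in names(config[[role]])) {
      tables[[trait]] <- read_summary_stats(config[[role]][[trait]])
      log_line(log_path, "loaded ", trait, ": ", nrow(tables[[trait]]),
               " records")
    }

  arms <- list(
    exposure_mediator = expand.grid(a = names(config$exposures),
                                    b = names(config$mediators),
                                    stringsAsFactors = FALSE),
    exposure_outcome = expand.grid(a = names(config$exposures),
                                   b = names(config$outcomes),
                                   stringsAsFactors = FALSE),
    mediator_outcome = expand.grid(a = names(config$mediators),
                                   b = names(config$outcomes),
                                   stringsAsFactors = FALSE))
  mr_results <- list()
  sens_rows <- list()
  files <- c()
  for (arm in names(arms)) {
    ests <- list()
    for (i in seq_len(nrow(arms[[arm]]))) {
      a <- arms[[arm]]$a[i]; b <- arms[[arm]]$b[i]
      key <- paste(a, b, sep = "~")
      res <- tryCatch(run_mr(tables[[a]], tables[[b]], a, b, s),
                      error = function(e) {
                        log_line(log_path, "SKIP ", key, ": ",
                                 conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      mr_results[[key]] <- res
      ests[[key]] <- res$ivw
      log_line(log_path, arm, " ", key, ": ",
               nrow(res$instruments$records), " instruments (F=",
               signif(res$instruments$f_stat, 4), "), ",
               length(res$harmonized$snp_ids), " harmonized, IVW beta=",
               signif(res$ivw$beta, 4), " p=", signif(res$ivw$pval, 3))
      sens_rows[[key]] <- data.frame(
        Exposure = a, Outcome = b,
        Q = res$q$q %||% NA_real_, Q_df = res$q$df %||% NA_real_,
        Q_p = res$q$pval %||% NA_real_,
        Egger_beta = if (is.null(res$egger)) NA_real_ else res$egger$beta,
        Egger_p = if (is.null(res$egger)) NA_real_ else res$egger$pval,
        Egger_intercept = if (is.null(res$egger)) NA_real_
                          else res$egger$egger_intercept,
        Egger_intercept_p = if (is.null(res$egger)) NA_real_
                            else res$egger$egger_intercept_pval,
        WM_beta = if (is.null(res$weighted_median)) NA_real_
                  else res$weighted_median$beta,
        WM_p = if (is.null(res$weighted_median)) NA_real_
               else res$weighted_median$pval,
        n_influential_loo = if (is.null(res$loo)) NA_integer_
                            else sum(res$loo$influential),
        stringsAsFactors = FALSE)
    }
    path <- file.path(config$output_dir, paste0(arm, ".tsv"))
    write_report(unname(ests), path, type = "mr")
    files[arm] <- path
  }

  med_results <- list()
  for (e in names(config$exposures))
    for (m in names(config$mediators))
      for (o in names(config$outcomes)) {
        key <- paste(e, m, o, sep = "~")
        res <- tryCatch(
          run_two_step(tables[[e]], tables[[m]], tables[[o]], e, m, o, s),
          error = function(err) {
            log_line(log_path, "SKIP mediation ", key, ": ",
                     conditionMessage(err))
            NULL
          })
        if (is.null(res)) next
        med_results[[key]] <- res
        log_line(log_path, "mediation ", key, ": indirect=",
                 signif(res$indirect_beta, 4), " p=",
                 signif(res$indirect_pval, 3), " case=", res$case)
      }
  med_path <- file.path(config$output_dir, "mediation.tsv")
  write_report(unname(med_results), med_path, type = "mediation")
  files["mediation"] <- med_path

  sens_path <- file.path(config$output_dir, "sensitivity.tsv")
  sens <- do.call(rbind, sens_rows)
  if (is.null(sens))
    sens <- data.frame(Exposure = character(), Outcome = character())
  utils::write.table(sens, sens_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["sensitivity"] <- sens_path
  files["log"] <- log_path
  invisible(list(mr = mr_results, mediation = med_results, files = files))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a simulated study's tables),
#' `mr` (two-sample MR between two summary-statistics files),
#' `mediate` (two-step mediation over three files), and
#' `run` (full [run_all()] bundle from a YAML configuration).
#' Common flags `--seed`, `--alpha`, `--p-threshold`, `--clump-r2`,
#' `--clump-window`, `--f-min` and `--out` override configuration values.
#'
#' @param argv Character vector of arguments (defaults to the command line).
#' @return Integer exit code, 0 on success.
#' @export
mr_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mrmediate {simulate|mr|mediate|run} [files...] [options]"
  opts <- list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--p-threshold", type = "double", default = 5e-5,
                          dest = "p_threshold"),
    optparse::make_option("--clump-r2", type = "double", default = 0.001,
                          dest = "clump_r2"),
    optparse::make_option("--clump-window", type = "double", default = 1e7,
                          dest = "clump_window_bp"),
    optparse::make_option("--f-min", type = "double", default = 10,
                          dest = "f_min"),
    optparse::make_option("--n-snps", type = "integer", default = 100L,
                          dest = "n_snps"),
    optparse::make_option("--out", type = "character", default = "."))
  run <- function() {
    if (length(argv) == 0) stop(usage)
    cmd <- argv[1]
    parsed <- optparse::parse_args(
      optparse::OptionParser(option_list = opts, usage = usage),
      args = argv[-1], positional_arguments = TRUE)
    o <- parsed$options
    pos <- parsed$args
    settings <- list(p_threshold = o$p_threshold, clump_r2 = o$clump_r2,
                     clump_window_bp = o$clump_window_bp, f_min = o$f_min,
                     alpha = o$alpha, seed = o$seed)
    if (cmd == "simulate") {
      study <- simulate_study(sim_config(n_snps = o$n_snps, seed = o$seed))
      paths <- write_study(study, o$out)
      message("wrote ", paste(paths, collapse = ", "))
    } else if (cmd == "mr") {
      if (length(pos) != 2)
        stop("usage: mrmediate mr <exposure.tsv> <outcome.tsv> [options]")
      res <- run_mr(read_summary_stats(pos[1]), read_summary_stats(pos[2]),
                    basename(pos[1]), basename(pos[2]), settings)
      dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(o$out, "mr_report.tsv")
      ests <- Filter(Negate(is.null),
                     list(res$ivw, res$egger, res$weighted_median))
      write_report(ests, path, type = "mr")
      message("wrote ", path)
    } else if (cmd == "mediate") {
      if (length(pos) != 3)
        stop("usage: mrmediate mediate <exposure.tsv> <mediator.tsv> ",
             "<outcome.tsv> [options]")
      res <- run_two_step(read_summary_stats(pos[1]),
                          read_summary_stats(pos[2]),
                          read_summary_stats(pos[3]),
                          basename(pos[1]), basename(pos[2]),
                          basename(pos[3]), settings)
      dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(o$out, "mediation_report.tsv")
      write_report(list(res), path, type = "mediation")
      message("wrote ", path)
    } else if (cmd == "run") {
      if (length(pos) != 1) stop("usage: mrmediate run <config.yaml>")
      cfg <- analysis_config(pos[1])
      cfg$settings <- utils::modifyList(settings, cfg$settings)
      if (o$out != ".") cfg$output_dir <- o$out
      run_all(cfg)
      message("analysis bundle written to ", cfg$output_dir)
    } else {
      stop(usage)
    }
    0L
  }
  tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
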