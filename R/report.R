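# Deterministic, byte-stable report tables: fixed column order, fixed float
# format (%.6g), fixed row sort (exposure, outcome, method), no timestamps.

format_table <- function(df, num_cols) {
  out <- df
  for (col in num_cols) out[[col]] <- fmt_num(df[[col]])
  for (col in names(out)) out[[col]] <- as.character(out[[col]])
  c(paste(names(out), collapse = "\t"),
    if (nrow(out)) do.call(paste, c(unname(as.list(out)), sep = "\t")))
}

sensitivity_table <- function(sensitivity) {
  rows <- lapply(sensitivity, function(s) {
    pr <- s$presso
    data.frame(
      exposure = s$exposure_id, outcome = s$outcome_id, n_snp = s$n_snp,
      q = s$q$q, q_df = s$q$df, q_pval = s$q$pval,
      egger_intercept = s$egger_intercept$estimate,
      intercept_se = s$egger_intercept$se,
      intercept_pval = s$egger_intercept$pval,
      presso_global_rss = if (is.null(pr)) NA_real_ else pr$global_rss_obs,
      presso_global_pval = if (is.null(pr)) NA_real_ else pr$global_pval,
      presso_n_outliers = if (is.null(pr)) NA_integer_
                          else length(pr$outlier_rsids),
      presso_outliers = if (is.null(pr) || !length(pr$outlier_rsids)) ""
                        else paste(pr$outlier_rsids, collapse = ";"),
      presso_distortion_pval = if (is.null(pr)) NA_real_
                               else pr$distortion_pval,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame(
    exposure = character(), outcome = character(), n_snp = integer(),
    q = numeric(), q_df = integer(), q_pval = numeric(),
    egger_intercept = numeric(), intercept_se = numeric(),
    intercept_pval = numeric(), presso_global_rss = numeric(),
    presso_global_pval = numeric(), presso_n_outliers = integer(),
    presso_outliers = character(), presso_distortion_pval = numeric(),
    stringsAsFactors = FALSE)
  out[order(out$exposure, out$outcome), , drop = FALSE]
}

#' Write the study's report tables
#'
#' Emits tab-delimited result tables (`estimates.tsv`, `sensitivity.tsv`,
#' `replication.tsv`, `mediation.tsv`) and a JSON run-metadata file
#' recording thresholds, seeds and counts. Output is byte-stable: fixed
#' column order, numeric fields formatted `%.6g`, rows sorted by exposure
#' then outcome then method, no timestamps. Binary-outcome effects are
#' reported both as log-odds (`beta`) and as odds ratios with 95% CI.
#' Sections absent from `results` produce header-only files.
#'
#' @param results an `"mr_study"`, an `"mr_screen"`, or a list with any of
#'   `estimates` (data.frame), `sensitivity` (list of `"mr_sensitivity"`),
#'   `replication`, `mediation` (data.frames) and `metadata` (list).
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  if (inherits(results, "mr_study")) {
    results <- list(estimates = results$screen$table,
                    sensitivity = results$screen$sensitivity,
                    replication = results$replication,
                    mediation = results$mediation,
                    metadata = results$metadata)
  } else if (inherits(results, "mr_screen")) {
    results <- list(estimates = results$table,
                    sensitivity = results$sensitivity)
  }
  if (!length(results)) stop("`results` is empty", call. = FALSE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  paths <- character()

  est <- results$estimates %||% data.frame(
    exposure = character(), outcome = character(), method = character(),
    n_snp = integer(), beta = numeric(), se = numeric(), ci_low = numeric(),
    ci_high = numeric(), pval = numeric(), or = numeric(),
    or_lci95 = numeric(), or_uci95 = numeric(), stringsAsFactors = FALSE)
  est <- est[order(est$exposure, est$outcome, est$method), , drop = FALSE]
  cols <- c("exposure", "outcome", "method", "n_snp", "beta", "se", "or",
            "or_lci95", "or_uci95", "pval")
  p <- file.path(out_dir, "estimates.tsv")
  writeLines(format_table(est[, cols, drop = FALSE],
                          c("beta", "se", "or", "or_lci95", "or_uci95", "pval")),
             p)
  paths <- c(paths, p)

  sens <- sensitivity_table(results$sensitivity %||% list())
  p <- file.path(out_dir, "sensitivity.tsv")
  writeLines(format_table(sens, c("q", "q_pval", "egger_intercept",
                                  "intercept_se", "intercept_pval",
                                  "presso_global_rss", "presso_global_pval",
                                  "presso_distortion_pval")), p)
  paths <- c(paths, p)

  repl <- results$replication %||% data.frame(
    exposure = character(), outcome = character(), n_snp = integer(),
    beta = numeric(), se = numeric(), pval = numeric(),
    direction_consistent = logical(), replicated = logical(),
    status = character(), stringsAsFactors = FALSE)
  repl <- repl[order(repl$exposure, repl$outcome), , drop = FALSE]
  p <- file.path(out_dir, "replication.tsv")
  writeLines(format_table(repl, c("beta", "se", "pval")), p)
  paths <- c(paths, p)

  med <- results$mediation %||% data.frame(
    exposure = character(), mediator = character(), outcome = character(),
    beta1 = numeric(), se1 = numeric(), beta2 = numeric(), se2 = numeric(),
    beta3 = numeric(), se3 = numeric(), indirect = numeric(),
    proportion = numeric(), prop_ci_low = numeric(),
    prop_ci_high = numeric(), prop_pval = numeric(), consistent = logical(),
    stringsAsFactors = FALSE)
  med <- med[order(med$exposure, med$mediator), , drop = FALSE]
  p <- file.path(out_dir, "mediation.tsv")
  writeLines(format_table(med, c("beta1", "se1", "beta2", "se2", "beta3",
                                 "se3", "indirect", "proportion",
                                 "prop_ci_low", "prop_ci_high", "prop_pval")),
             p)
  paths <- c(paths, p)

  if (!is.null(results$metadata)) {
    p <- file.path(out_dir, "run_metadata.json")
    jsonlite::write_json(results$metadata, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
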