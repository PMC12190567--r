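# Study orchestration: screen many exposures against a primary outcome,
# replicate hits in independent outcomes, and quantify mediation through
# candidate mediators, with every threshold, skip and seed recorded.

#' Assemble a study configuration
#'
#' @param exposures named list; each element a `"sumstats"` object or a file
#'   path readable by [read_sumstats()].
#' @param outcome primary outcome: `"sumstats"` or file path (binary traits
#'   read from file need `outcome_type`/`n_cases`/`n_controls` supplied here).
#' @param replication_outcomes named list of additional outcomes (same forms).
#' @param mediators named list of mediator `"sumstats"`/paths.
#' @param ld optional `"ld_ref"` (clumping and proxy search are skipped
#'   without one; simulated instruments are unlinked by construction).
#' @param p_threshold,eaf_min instrument selection thresholds.
#' @param clump_r2,clump_kb LD clumping parameters.
#' @param proxy_r2 minimum proxy r².
#' @param min_instruments exposures with fewer harmonized instruments are
#'   excluded from estimation (default 3).
#' @param alpha two-sided screening level (default 0.05, nominal; adjusted
#'   p-values are reported alongside, not used for gating).
#' @param ivw_model `"random"` or `"fixed"`.
#' @param n_boot weighted-median / mediation bootstrap draws.
#' @param n_sim MR-PRESSO simulations.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory for [write_report_tables()].
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(exposures, outcome, replication_outcomes = list(),
                       mediators = list(), ld = NULL, p_threshold = 1e-5,
                       eaf_min = 0.01, clump_r2 = 0.1, clump_kb = 1000,
                       proxy_r2 = 0.8, min_instruments = 3, alpha = 0.05,
                       ivw_model = c("random", "fixed"), n_boot = 1000,
                       n_sim = 1000, seed = 1, out_dir = NULL) {
  ivw_model <- match.arg(ivw_model)
  if (!length(exposures)) stop("`exposures` must be non-empty", call. = FALSE)
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    stop("`exposures` must be a named list", call. = FALSE)
  }
  for (v in c("p_threshold", "eaf_min", "clump_r2", "proxy_r2", "alpha")) {
    val <- get(v)
    if (!is.numeric(val) || val <= 0 || val > 1) {
      stop("`", v, "` must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(exposures = exposures, outcome = outcome,
                 replication_outcomes = replication_outcomes,
                 mediators = mediators, ld = ld, p_threshold = p_threshold,
                 eaf_min = eaf_min, clump_r2 = clump_r2, clump_kb = clump_kb,
                 proxy_r2 = proxy_r2, min_instruments = min_instruments,
                 alpha = alpha, ivw_model = ivw_model, n_boot = n_boot,
                 n_sim = n_sim, seed = seed, out_dir = out_dir),
            class = "run_config")
}

resolve_sumstats <- function(x, id, trait_type = "quantitative",
                             n_cases = NA_integer_, n_controls = NA_integer_) {
  if (inherits(x, "sumstats")) return(x)
  if (inherits(x, "mr_simulation")) return(x$exposure)
  if (is.character(x) && length(x) == 1L) {
    return(read_sumstats(x, trait_id = id, trait_type = trait_type,
                         n_cases = n_cases, n_controls = n_controls))
  }
  stop("cannot interpret input '", id,
       "': expected a sumstats object or file path", call. = FALSE)
}

# Fail-fast validation pass before any computation starts.
validate_inputs <- function(config) {
  paths <- c(Filter(is.character, config$exposures),
             if (is.character(config$outcome)) config$outcome,
             Filter(is.character, config$replication_outcomes),
             Filter(is.character, config$mediators))
  missing <- unlist(paths)[!file.exists(unlist(paths) %||% character())]
  if (length(missing)) {
    stop("unreadable input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Shared per-exposure instrument workflow: select, clump, harmonize.
build_instruments <- function(exposure, outcome, config, exposure_id) {
  cand <- suppressWarnings(
    select_instruments(exposure, p_threshold = config$p_threshold,
                       eaf_min = config$eaf_min))
  if (nrow(cand) == 0L) {
    return(list(instruments = NULL, reason = "no instruments pass selection"))
  }
  if (!is.null(config$ld)) {
    cand <- ld_clump(cand, config$ld, r2_max = config$clump_r2,
                     window_kb = config$clump_kb)
  }
  inst <- harmonize(cand, outcome, ld = config$ld,
                    proxy_r2 = config$proxy_r2, exposure_id = exposure_id)
  if (nrow(inst$data) < config$min_instruments) {
    return(list(instruments = inst, reason = "insufficient instruments"))
  }
  list(instruments = inst, reason = NA_character_)
}

#' Screen every exposure against the primary outcome
#'
#' For each exposure: select instruments, clump, harmonize, skip (logged) if
#' fewer than `min_instruments` remain, fit IVW + MR-Egger + weighted median,
#' and run the full sensitivity battery for exposures whose IVW p-value is
#' below `alpha`. Deterministic given the configuration, including its seed.
#'
#' @param config a `"run_config"`.
#' @return An object of class `"mr_screen"`: list with `table` (all-method
#'   estimates), `ivw` (IVW rows plus Bonferroni/BH-adjusted p-values),
#'   `hits`, `sensitivity` (named list of `"mr_sensitivity"`), `skips`,
#'   `instruments` (named list), `exposures`/`outcome` (resolved tables) and
#'   `config`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_inputs(config)
  outcome <- resolve_sumstats(config$outcome, "outcome", trait_type = "binary",
                              n_cases = NA_integer_, n_controls = NA_integer_)
  exposures <- lapply(seq_along(config$exposures), function(i) {
    resolve_sumstats(config$exposures[[i]], names(config$exposures)[i])
  })
  names(exposures) <- names(config$exposures)

  rows <- list()
  skips <- list()
  instruments <- list()
  fits <- list()
  for (i in seq_along(exposures)) {
    id <- names(exposures)[i]
    built <- build_instruments(exposures[[i]], outcome, config, id)
    if (!is.na(built$reason)) {
      skips[[id]] <- built$reason
      next
    }
    inst <- built$instruments
    fit <- mr_fit(inst, ivw_model = config$ivw_model, n_boot = config$n_boot,
                  seed = derive_seed(config$seed, i), alpha = config$alpha)
    est <- fit$estimates
    est <- cbind(data.frame(exposure = id, outcome = outcome$trait_id,
                            stringsAsFactors = FALSE), est)
    rows[[id]] <- est
    instruments[[id]] <- inst
    fits[[id]] <- fit
  }

  table <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(table) <- NULL
  ivw <- table[table$method == "IVW", , drop = FALSE]
  if (nrow(ivw)) {
    ivw$pval_bonferroni <- stats::p.adjust(ivw$pval, "bonferroni")
    ivw$pval_bh <- stats::p.adjust(ivw$pval, "BH")
  }
  hits <- ivw$exposure[ivw$pval < config$alpha]

  sensitivity <- list()
  for (id in hits) {
    if (nrow(instruments[[id]]$data) >= 3L) {
      sensitivity[[id]] <- mr_sensitivity(
        instruments[[id]], n_sim = config$n_sim,
        seed = derive_seed(config$seed, 10000L + match(id, names(exposures))),
        ivw_model = config$ivw_model)
    }
  }

  structure(list(table = table, ivw = ivw, hits = hits,
                 sensitivity = sensitivity,
                 skips = data.frame(exposure = names(skips),
                                    reason = unlist(skips) %||% character(),
                                    stringsAsFactors = FALSE),
                 instruments = instruments, fits = fits,
                 exposures = exposures, outcome = outcome, config = config),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("MR screen: %d exposure(s) tested, %d skipped, %d hit(s) at alpha = %g\n",
              length(x$instruments), nrow(x$skips), length(x$hits),
              x$config$alpha))
  if (length(x$hits)) cat("  hits:", paste(x$hits, collapse = ", "), "\n")
  invisible(x)
}

#' Replicate screening hits in independent outcome datasets
#'
#' Re-selects and re-harmonizes each hit exposure against each replication
#' outcome and re-estimates IVW. A hit replicates in an outcome when the
#' effect direction matches the discovery estimate and p < alpha; exposures
#' with too few instruments in an outcome are emitted as `"not testable"`.
#' Per-exposure status aggregates to `"replicated"`, `"partially replicated"`
#' or `"not replicated"`.
#'
#' @param screen an `"mr_screen"`.
#' @param outcomes named list of replication outcomes (`"sumstats"`/paths);
#'   defaults to the configuration's `replication_outcomes`.
#' @return data.frame with per-(exposure, outcome) rows and an
#'   `"exposure_status"` attribute; empty when there are no hits.
#' @export
run_replication <- function(screen, outcomes = NULL) {
  stopifnot(inherits(screen, "mr_screen"))
  config <- screen$config
  outcomes <- outcomes %||% config$replication_outcomes
  empty <- data.frame(exposure = character(), outcome = character(),
                      n_snp = integer(), beta = numeric(), se = numeric(),
                      pval = numeric(), direction_consistent = logical(),
                      replicated = logical(), status = character(),
                      stringsAsFactors = FALSE)
  if (!length(screen$hits) || !length(outcomes)) {
    attr(empty, "exposure_status") <- stats::setNames(character(), character())
    return(empty)
  }
  outcomes <- lapply(seq_along(outcomes), function(i) {
    resolve_sumstats(outcomes[[i]], names(outcomes)[i], trait_type = "binary")
  })

  rows <- list()
  for (id in screen$hits) {
    disc_beta <- screen$ivw$beta[screen$ivw$exposure == id][1]
    for (k in seq_along(outcomes)) {
      oc <- outcomes[[k]]
      built <- build_instruments(screen$exposures[[id]], oc, config, id)
      if (!is.na(built$reason)) {
        rows[[length(rows) + 1L]] <- data.frame(
          exposure = id, outcome = oc$trait_id, n_snp = 0L, beta = NA_real_,
          se = NA_real_, pval = NA_real_, direction_consistent = NA,
          replicated = NA, status = "not testable", stringsAsFactors = FALSE)
        next
      }
      df <- built$instruments$data
      fit <- ivw_engine(df$beta_exp, df$beta_out, df$se_out,
                        model = config$ivw_model)
      consistent <- sign(fit$beta) == sign(disc_beta)
      replicated <- consistent && fit$pval < config$alpha
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = id, outcome = oc$trait_id, n_snp = fit$n_snp,
        beta = fit$beta, se = fit$se, pval = fit$pval,
        direction_consistent = consistent, replicated = replicated,
        status = if (replicated) "replicated" else "not replicated",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tested <- out[out$status != "not testable", , drop = FALSE]
  status <- vapply(unique(out$exposure), function(id) {
    rep_k <- tested$replicated[tested$exposure == id]
    if (!length(rep_k)) "not testable"
    else if (all(rep_k)) "replicated"
    else if (any(rep_k)) "partially replicated"
    else "not replicated"
  }, character(1))
  attr(out, "exposure_status") <- status
  out
}

#' Run the complete screening, replication and mediation study
#'
#' Phase 1 screens every exposure against the primary outcome; phase 2
#' re-estimates hits in each replication outcome; phase 3 runs two-step MR
#' mediation through each mediator for which a qualifying triplet of
#' estimates exists (exposure-to-outcome, exposure-to-mediator,
#' mediator-to-outcome, all passing `alpha`), with bootstrap CIs. Report
#' tables are written when the configuration names an output directory. The
#' bundle is a pure function of the inputs and configuration (seed included).
#'
#' @param config a `"run_config"`.
#' @return An object of class `"mr_study"`: list with `screen`,
#'   `replication`, `mediation` (`NULL` when no mediators are configured),
#'   `mediation_inputs`, and `metadata` (thresholds, seed, counts, skips).
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  screen <- run_screen(config)
  replication <- run_replication(screen)

  mediation <- NULL
  med_inputs <- NULL
  med_skips <- character()
  if (length(config$mediators)) {
    mediators <- lapply(seq_along(config$mediators), function(i) {
      resolve_sumstats(config$mediators[[i]], names(config$mediators)[i])
    })
    names(mediators) <- names(config$mediators)

    exp_out <- data.frame(exposure = screen$ivw$exposure,
                          beta = screen$ivw$beta, se = screen$ivw$se,
                          pval = screen$ivw$pval, stringsAsFactors = FALSE)
    # mediator -> outcome, each mediator instrumented from its own GWAS
    mo_rows <- list()
    for (m in names(mediators)) {
      built <- build_instruments(mediators[[m]], screen$outcome, config, m)
      if (!is.na(built$reason)) {
        med_skips[m] <- paste0("mediator-outcome: ", built$reason)
        next
      }
      df <- built$instruments$data
      fit <- ivw_engine(df$beta_exp, df$beta_out, df$se_out,
                        model = config$ivw_model)
      mo_rows[[m]] <- data.frame(mediator = m, beta = fit$beta, se = fit$se,
                                 pval = fit$pval, n_snp = fit$n_snp,
                                 stringsAsFactors = FALSE)
    }
    med_out <- do.call(rbind, mo_rows) %||%
      data.frame(mediator = character(), beta = numeric(), se = numeric(),
                 pval = numeric(), stringsAsFactors = FALSE)
    # exposure -> mediator, reusing the screening instruments
    em_rows <- list()
    for (id in screen$hits) {
      for (m in names(mediators)) {
        cand <- screen$instruments[[id]]
        exp_rows <- screen$exposures[[id]]$data
        exp_rows <- exp_rows[exp_rows$rsid %in% cand$data$rsid, , drop = FALSE]
        inst <- harmonize(exp_rows, mediators[[m]], ld = config$ld,
                          proxy_r2 = config$proxy_r2, exposure_id = id)
        if (nrow(inst$data) < config$min_instruments) {
          med_skips[paste(id, m, sep = "->")] <-
            "exposure-mediator: insufficient instruments"
          next
        }
        df <- inst$data
        fit <- ivw_engine(df$beta_exp, df$beta_out, df$se_out,
                          model = config$ivw_model)
        em_rows[[paste(id, m)]] <- data.frame(
          exposure = id, mediator = m, beta = fit$beta, se = fit$se,
          pval = fit$pval, n_snp = fit$n_snp, stringsAsFactors = FALSE)
      }
    }
    exp_med <- do.call(rbind, em_rows) %||%
      data.frame(exposure = character(), mediator = character(),
                 beta = numeric(), se = numeric(), pval = numeric(),
                 stringsAsFactors = FALSE)
    mediation <- mediation_screen(exp_out, exp_med, med_out,
                                  outcome_id = screen$outcome$trait_id,
                                  alpha = config$alpha,
                                  n_boot = max(config$n_boot, 1000),
                                  seed = derive_seed(config$seed, 77L))
    med_inputs <- list(exp_out = exp_out, exp_med = exp_med, med_out = med_out)
  }

  metadata <- list(
    thresholds = config[c("p_threshold", "eaf_min", "clump_r2", "clump_kb",
                          "proxy_r2", "min_instruments", "alpha")],
    ivw_model = config$ivw_model, seed = config$seed,
    n_boot = config$n_boot, n_sim = config$n_sim,
    n_exposures = length(config$exposures),
    n_tested = length(screen$instruments),
    n_hits = length(screen$hits),
    skips = screen$skips,
    mediation_skips = as.list(med_skips),
    mediation_run = length(config$mediators) > 0
  )
  study <- structure(list(screen = screen, replication = replication,
                          mediation = mediation,
                          mediation_inputs = med_inputs,
                          metadata = metadata),
                     class = "mr_study")
  if (!is.null(config$out_dir)) write_report_tables(study, config$out_dir)
  study
}

#' @export
print.mr_study <- function(x, ...) {
  print(x$screen)
  if (nrow(x$replication)) {
    st <- attr(x$replication, "exposure_status")
    cat("Replication:", paste(sprintf("%s=%s", names(st), st), collapse = ", "),
        "\n")
  }
  if (!is.null(x$mediation)) {
    cat(sprintf("Mediation: %d qualifying pathway(s)\n", nrow(x$mediation)))
  } else if (!x$metadata$mediation_run) {
    cat("Mediation phase skipped (no mediators configured)\n")
  }
  invisible(x)
}
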