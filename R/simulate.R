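# Seeded generator of GWAS summary statistics with known ground truth. It
# emulates the study design this package targets: a quantitative microbiome
# exposure GWAS (n = 1539) whose instruments reach p < 1e-5, a rare-outcome
# case-control GWAS on the log-odds scale (489 cases / 75,531 controls, SEs
# via the effective sample size 4/(1/cases + 1/controls)), an optional
# quantitative mediator (serum protein) chain, block-structured LD, and
# configurable horizontal pleiotropy.

NON_PALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Simulation configuration
#'
#' Defaults mirror the target study design: 20 instruments per exposure
#' (the observed range is 3-40), exposure GWAS n = 1539, outcome GWAS with
#' 489 cases and 75,531 controls, instrument selection at p < 1e-5, and
#' per-SNP effects drawn from Normal(0, gamma_sd^2) conditioned on reaching
#' the selection threshold (gamma_sd = 0.12 puts most selected F-statistics
#' in the 20-40 range, all above 10).
#'
#' @param n_snp instruments for the exposure.
#' @param n_exposure exposure GWAS sample size.
#' @param n_cases,n_controls outcome case/control counts.
#' @param theta true total causal effect (log-OR per SD of exposure).
#' @param gamma_sd scale of instrument effects before selection.
#' @param eaf_range range of the uniform effect-allele-frequency draw.
#' @param p_threshold selection threshold the instruments must reach.
#' @param pleiotropy list with `mode` (`"none"`, `"balanced"`,
#'   `"directional"`, `"inside-violating"`), `mean`, `sd`, and `frac` (the
#'   fraction of instruments carrying pleiotropy, default 1). Pleiotropic
#'   shifts (and contamination offsets) act relative to the
#'   exposure-increasing allele, so "directional" means the same outcome
#'   direction for every exposure-raising allele.
#' @param mediator `NULL`, or list with `beta1` (exposure-to-mediator),
#'   `beta2` (mediator-to-outcome), `n_snp` (mediator instruments, default
#'   15) and `n_gwas` (mediator GWAS size, default 2000).
#' @param contaminate `NULL`, or data.frame/list with `index` and `offset`
#'   (per-SNP outcome shift in units of the outcome SE).
#' @param ld_blocks `NULL`, or list with `size` (SNPs per block) and `r2`
#'   (exchangeable within-block r-squared).
#' @param noise_free logical; zero outcome noise (exact-recovery limit).
#' @param snp_offset integer added to the generated variant indices, so that
#'   studies drawn for different features occupy disjoint rsid ranges and
#'   their outcome rows can be merged into one table (see
#'   [panel_outcome()]).
#' @param seed mandatory seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_snp = 20, n_exposure = 1539, n_cases = 489,
                       n_controls = 75531, theta = 0, gamma_sd = 0.12,
                       eaf_range = c(0.05, 0.95), p_threshold = 1e-5,
                       pleiotropy = list(mode = "none", mean = 0, sd = 0,
                                         frac = 1),
                       mediator = NULL, contaminate = NULL, ld_blocks = NULL,
                       noise_free = FALSE, snp_offset = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot_scalar(n_snp, "n_snp", positive = TRUE)
  stopifnot_scalar(n_exposure, "n_exposure", positive = TRUE)
  stopifnot_scalar(n_cases, "n_cases", positive = TRUE)
  stopifnot_scalar(n_controls, "n_controls", positive = TRUE)
  stopifnot_scalar(gamma_sd, "gamma_sd", positive = TRUE)
  pleiotropy <- utils::modifyList(list(mode = "none", mean = 0, sd = 0,
                                       frac = 1), pleiotropy)
  if (!pleiotropy$mode %in% c("none", "balanced", "directional",
                              "inside-violating")) {
    stop("unknown pleiotropy mode: ", pleiotropy$mode, call. = FALSE)
  }
  if (pleiotropy$sd < 0) stop("pleiotropy sd must be >= 0", call. = FALSE)
  if (!is.null(mediator)) {
    mediator <- utils::modifyList(list(n_snp = 15, n_gwas = 2000), mediator)
    if (is.null(mediator$beta1) || is.null(mediator$beta2)) {
      stop("mediator requires `beta1` and `beta2`", call. = FALSE)
    }
  }
  structure(list(n_snp = as.integer(n_snp), n_exposure = n_exposure,
                 n_cases = n_cases, n_controls = n_controls, theta = theta,
                 gamma_sd = gamma_sd, eaf_range = eaf_range,
                 p_threshold = p_threshold, pleiotropy = pleiotropy,
                 mediator = mediator, contaminate = contaminate,
                 ld_blocks = ld_blocks, noise_free = noise_free,
                 snp_offset = as.integer(snp_offset), seed = seed),
            class = "sim_config")
}

# Selected instrument effects: Normal(0, sd^2) conditioned on |gamma| above
# the per-SNP selection threshold. Sampled exactly by inverse CDF on the
# truncated tail (the same distribution rejection sampling converges to).
draw_selected_effects <- function(n, sd, threshold) {
  lo <- stats::pnorm(threshold / sd)
  if (any(lo > 1 - 1e-12)) {
    stop("instrument p-value threshold unreachable: increase `gamma_sd` or ",
         "relax `p_threshold`", call. = FALSE)
  }
  mag <- sd * stats::qnorm(stats::runif(n, lo, 1))
  sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  mag * sign
}

sumstat_se <- function(n_eff, eaf) 1 / sqrt(2 * n_eff * eaf * (1 - eaf))

#' Simulate one exposure-outcome(-mediator) study
#'
#' Generates internally consistent summary-statistics tables plus the ground
#' truth that determines expected estimator behaviour. Exposure effects are
#' the true instrument effects (two-sample MR with a precisely estimated
#' exposure); outcome effects are `theta * gamma + alpha + eps` with `alpha`
#' the pleiotropy draw and `eps ~ Normal(0, se_out)`. With a mediator,
#' `theta` is the *total* effect, of which `beta1 * beta2` flows through the
#' mediator; the mediator table contains both the exposure instruments (as
#' outcome rows for the exposure-to-mediator MR) and the mediator's own
#' instruments.
#'
#' @param config a `"sim_config"` object.
#' @return An object of class `"mr_simulation"`: list with `exposure`,
#'   `outcome`, `mediator` (`"sumstats"` or `NULL`), `ld` (`"ld_ref"` or
#'   `NULL`) and `truth` (list incl. `theta`, `gamma`, `alpha`,
#'   `pleiotropy_idx`, `contaminated_idx`, `beta1`, `beta2`, `proportion`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  J <- config$n_snp
  z_sel <- stats::qnorm(config$p_threshold / 2, lower.tail = FALSE)

  eaf <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
  se_exp <- sumstat_se(config$n_exposure, eaf)

  block_id <- seq_len(J)
  ld <- NULL
  if (!is.null(config$ld_blocks)) {
    size <- config$ld_blocks$size
    block_id <- ceiling(seq_len(J) / size)
    # block mates share the leader's frequency (tight LD implies similar MAF)
    leader <- match(block_id, block_id)
    eaf <- eaf[leader]
    se_exp <- se_exp[leader]
  }

  gamma <- draw_selected_effects(J, config$gamma_sd, z_sel * se_exp)
  if (!is.null(config$ld_blocks)) {
    leader <- match(block_id, block_id)
    jitter <- 1 + stats::rnorm(J, 0, 0.02)
    jitter[leader == seq_len(J)] <- 1
    gamma <- gamma[leader] * jitter
  }

  # genomic layout: blocks adjacent (10 kb), distinct blocks > 1 Mb apart
  n_block <- max(block_id)
  chrom_b <- as.character(((seq_len(n_block) - 1) %% 22) + 1)
  pos_b <- 1e6 + 2e6 * ((seq_len(n_block) - 1) %/% 22)
  within <- stats::ave(seq_len(J), block_id, FUN = seq_along)
  chrom <- chrom_b[block_id]
  pos <- pos_b[block_id] + (within - 1) * 1e4

  rsid <- sprintf("rs%07d", config$snp_offset + seq_len(J))
  if (!is.null(config$ld_blocks)) {
    pairs <- do.call(rbind, lapply(unique(block_id), function(b) {
      idx <- which(block_id == b)
      if (length(idx) < 2) return(NULL)
      cmb <- utils::combn(idx, 2)
      data.frame(rsid_a = rsid[cmb[1, ]], rsid_b = rsid[cmb[2, ]],
                 r2 = config$ld_blocks$r2, stringsAsFactors = FALSE)
    }))
    ld <- ld_reference(pairs %||% NULL)
  }

  alleles <- NON_PALINDROMIC_PAIRS[sample(nrow(NON_PALINDROMIC_PAIRS), J,
                                          replace = TRUE), , drop = FALSE]

  n_eff <- 4 / (1 / config$n_cases + 1 / config$n_controls)
  se_out <- sumstat_se(n_eff, eaf)

  # Pleiotropy and contamination are planted relative to the
  # exposure-increasing allele (anchored to sign(gamma)): a "directional"
  # shift with respect to an arbitrary allele coding would cancel in ratio
  # space and bias nothing.
  pl <- config$pleiotropy
  alpha <- numeric(J)
  n_pl <- round(pl$frac * J)
  idx_pl <- if (n_pl >= J) seq_len(J) else sort(sample(J, n_pl))
  if (pl$mode != "none" && n_pl > 0) {
    base <- stats::rnorm(n_pl, 0, pl$sd)
    raw <- switch(pl$mode,
      balanced = base,
      directional = pl$mean + base,
      `inside-violating` = pl$mean * abs(gamma[idx_pl]) / config$gamma_sd + base)
    alpha[idx_pl] <- raw * sign(gamma[idx_pl])
  }

  eps <- if (config$noise_free) numeric(J) else stats::rnorm(J, 0, se_out)
  by <- config$theta * gamma + alpha + eps

  contaminated_idx <- integer()
  if (!is.null(config$contaminate)) {
    cont <- as.data.frame(config$contaminate)
    contaminated_idx <- as.integer(cont$index)
    by[contaminated_idx] <- by[contaminated_idx] +
      cont$offset * se_out[contaminated_idx] * sign(gamma[contaminated_idx])
  }

  base_df <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                        effect_allele = alleles[, 1], other_allele = alleles[, 2],
                        eaf = eaf, stringsAsFactors = FALSE)
  exposure <- sumstats(
    transform(base_df, beta = gamma, se = se_exp,
              pval = z_pvalue(gamma / se_exp), n = config$n_exposure),
    trait_id = "exposure", trait_type = "quantitative")
  outcome_df <- transform(base_df, beta = by, se = se_out,
                          pval = z_pvalue(by / se_out),
                          n = config$n_cases + config$n_controls)

  mediator <- NULL
  truth_med <- list(beta1 = NA_real_, beta2 = NA_real_,
                    proportion = NA_real_)
  if (!is.null(config$mediator)) {
    m <- config$mediator
    se_med_at_exp <- sumstat_se(m$n_gwas, eaf)
    bm <- m$beta1 * gamma + stats::rnorm(J, 0, se_med_at_exp)
    med_rows_exp <- transform(base_df, beta = bm, se = se_med_at_exp,
                              pval = z_pvalue(bm / se_med_at_exp), n = m$n_gwas)

    K <- m$n_snp
    eaf_m <- stats::runif(K, config$eaf_range[1], config$eaf_range[2])
    se_m <- sumstat_se(m$n_gwas, eaf_m)
    delta <- draw_selected_effects(K, config$gamma_sd, z_sel * se_m)
    rsid_m <- sprintf("rsM%07d", config$snp_offset + seq_len(K))
    all_m <- NON_PALINDROMIC_PAIRS[sample(nrow(NON_PALINDROMIC_PAIRS), K,
                                          replace = TRUE), , drop = FALSE]
    med_base <- data.frame(rsid = rsid_m,
                           chrom = as.character(((seq_len(K) - 1) %% 22) + 1),
                           pos = 5e7 + 2e6 * ((seq_len(K) - 1) %/% 22),
                           effect_allele = all_m[, 1], other_allele = all_m[, 2],
                           eaf = eaf_m, stringsAsFactors = FALSE)
    med_rows_own <- transform(med_base, beta = delta, se = se_m,
                              pval = z_pvalue(delta / se_m), n = m$n_gwas)
    mediator <- sumstats(rbind(med_rows_exp, med_rows_own),
                         trait_id = "mediator", trait_type = "quantitative")

    se_out_m <- sumstat_se(n_eff, eaf_m)
    by_m <- m$beta2 * delta + stats::rnorm(K, 0, se_out_m)
    outcome_df <- rbind(outcome_df,
                        transform(med_base, beta = by_m, se = se_out_m,
                                  pval = z_pvalue(by_m / se_out_m),
                                  n = config$n_cases + config$n_controls))
    truth_med <- list(beta1 = m$beta1, beta2 = m$beta2,
                      proportion = if (config$theta != 0)
                        m$beta1 * m$beta2 / config$theta else NA_real_)
  }

  outcome <- sumstats(outcome_df, trait_id = "outcome", trait_type = "binary",
                      n_cases = config$n_cases, n_controls = config$n_controls)

  structure(list(
    exposure = exposure, outcome = outcome, mediator = mediator, ld = ld,
    truth = c(list(theta = config$theta, gamma = gamma, alpha = alpha,
                   eaf = eaf, pleiotropy_idx = if (pl$mode == "none")
                     integer() else idx_pl,
                   contaminated_idx = contaminated_idx,
                   block_id = block_id, n_eff = n_eff), truth_med),
    config = config
  ), class = "mr_simulation")
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf("Simulated MR study (seed %s): theta = %g, %d instrument(s)\n",
              format(x$config$seed), x$truth$theta, x$config$n_snp))
  if (!is.null(x$mediator)) {
    cat(sprintf("  mediator chain: beta1 = %g, beta2 = %g, proportion = %g\n",
                x$truth$beta1, x$truth$beta2, x$truth$proportion))
  }
  invisible(x)
}

#' Fast instrument assembly for a simulated study
#'
#' Joins a simulated study's exposure instruments with their outcome records
#' (alleles are already aligned by construction), computing per-SNP strength.
#' The file-facing route through [select_instruments()], [ld_clump()] and
#' [harmonize()] produces the same set for LD-free studies; this shortcut is
#' what the calibration loops use.
#'
#' @param study an `"mr_simulation"` object.
#' @return An `"mr_instruments"` object.
#' @export
instruments_from_study <- function(study) {
  stopifnot(inherits(study, "mr_simulation"))
  e <- study$exposure$data
  o <- study$outcome$data[match(e$rsid, study$outcome$data$rsid), ]
  mr_instruments(rsid = e$rsid, beta_exp = e$beta, se_exp = e$se,
                 beta_out = o$beta, se_out = o$se, eaf_exp = e$eaf,
                 eaf_out = o$eaf, pval_exp = e$pval, n_exp = e$n,
                 exposure_id = study$exposure$trait_id,
                 outcome_id = study$outcome$trait_id)
}

#' The three IVW links of a simulated mediation chain
#'
#' Convenience wrapper for mediator-carrying studies: estimates
#' exposure-to-outcome (via the exposure instruments), exposure-to-mediator
#' (same instruments against the mediator table) and mediator-to-outcome
#' (via the mediator's own instruments), returning the `list(beta =, se =)`
#' triplet consumed by [two_step_mediation()] / [bootstrap_mediation()].
#'
#' @param study an `"mr_simulation"` with a mediator chain.
#' @param ivw_model IVW model for the three fits (default `"fixed"`, the
#'   exactly calibrated variant used in calibration studies).
#' @return list with elements `exp_med`, `med_out`, `exp_out`.
#' @export
mediation_fits <- function(study, ivw_model = c("fixed", "random")) {
  stopifnot(inherits(study, "mr_simulation"))
  if (is.null(study$mediator)) stop("study carries no mediator", call. = FALSE)
  ivw_model <- match.arg(ivw_model)
  d <- instruments_from_study(study)$data
  f3 <- ivw_engine(d$beta_exp, d$beta_out, d$se_out, model = ivw_model)
  m <- study$mediator$data[match(d$rsid, study$mediator$data$rsid), ]
  f1 <- ivw_engine(d$beta_exp, m$beta, m$se, model = ivw_model)
  md <- study$mediator$data[grepl("^rsM", study$mediator$data$rsid), ]
  o <- study$outcome$data[match(md$rsid, study$outcome$data$rsid), ]
  f2 <- ivw_engine(md$beta, o$beta, o$se, model = ivw_model)
  list(exp_med = list(beta = f1$beta, se = f1$se),
       med_out = list(beta = f2$beta, se = f2$se),
       exp_out = list(beta = f3$beta, se = f3$se))
}

#' Simulate a panel of microbial features
#'
#' Generates `n_features` independent studies sharing one configuration, the
#' first `n_causal` with `theta = theta_causal` and the rest null — the
#' testbed for the screening pipeline's false-positive behaviour.
#'
#' @param config a `"sim_config"`; its `seed` anchors per-feature sub-seeds.
#' @param n_features number of features (default 500).
#' @param n_causal how many features carry a true effect.
#' @param theta_causal the non-null effect size.
#' @return named list of `"mr_simulation"` objects; names are stable feature
#'   IDs (`feature_0001`, ...), causal features first.
#' @export
simulate_feature_panel <- function(config, n_features = 500, n_causal = 0,
                                   theta_causal = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  if (n_causal > n_features) stop("n_causal must not exceed n_features",
                                  call. = FALSE)
  out <- vector("list", n_features)
  ids <- sprintf("feature_%04d", seq_len(n_features))
  for (i in seq_len(n_features)) {
    cfg <- config
    cfg$theta <- if (i <= n_causal) theta_causal else 0
    cfg$seed <- derive_seed(config$seed, i)
    cfg$snp_offset <- config$snp_offset + (i - 1L) * config$n_snp
    study <- simulate_study(cfg)
    study$exposure$trait_id <- ids[i]
    out[[i]] <- study
  }
  stats::setNames(out, ids)
}

#' Merge the outcome tables of a study panel
#'
#' Features simulated with disjoint rsid ranges (as [simulate_feature_panel()]
#' arranges) conceptually share one outcome GWAS; this stitches their outcome
#' rows into a single table for use as the pipeline's outcome.
#'
#' @param studies list of `"mr_simulation"` objects with disjoint variant IDs.
#' @return A binary `"sumstats"` object covering every study's variants.
#' @export
panel_outcome <- function(studies) {
  stopifnot(length(studies) > 0)
  rows <- do.call(rbind, lapply(studies, function(s) s$outcome$data))
  if (anyDuplicated(rows$rsid)) {
    stop("studies share variant IDs; simulate them with disjoint `snp_offset`s",
         call. = FALSE)
  }
  first <- studies[[1]]$outcome
  sumstats(rows, trait_id = first$trait_id, trait_type = "binary",
           n_cases = first$n_cases, n_controls = first$n_controls)
}
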