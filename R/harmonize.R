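COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Harmonize exposure instruments against an outcome table
#'
#' Aligns each exposure variant's outcome association to the exposure's effect
#' allele. Matching allele pairs are kept as is; swapped pairs have the
#' outcome beta negated and EAF complemented; strand-complement pairs are
#' flipped to the exposure strand first. Palindromic variants (A/T or C/G)
#' cannot be strand-resolved from alleles alone: under the default
#' `"exclude-ambiguous"` mode they are dropped when the minor-allele frequency
#' is in `[0.42, 0.5]` in either dataset and otherwise oriented by
#' effect-allele-frequency agreement; `"strict"` drops all palindromes.
#' Variants whose allele sets remain irreconcilable are dropped, never
#' guessed.
#'
#' Variants absent from the outcome are replaced, when `ld` is supplied, by
#' the best available proxy with r² above `proxy_r2`. The LD reference stores
#' r² only, so a proxy's orientation is inferred from allele-frequency
#' similarity with the query; frequency-ambiguous proxies are dropped.
#'
#' Per-SNP instrument strength (variance explained and F-statistic) is
#' computed from the exposure record. The operation is idempotent:
#' re-harmonizing an already aligned set changes nothing.
#'
#' @param exposure_snps data.frame of exposure records (output of
#'   [select_instruments()] / [ld_clump()]).
#' @param outcome a `"sumstats"` object.
#' @param ld optional `"ld_ref"` for proxy search.
#' @param palindrome_mode `"exclude-ambiguous"` (default) or `"strict"`.
#' @param proxy_r2 minimum proxy r² (default 0.8).
#' @param ambiguous_eaf palindromes with minor-allele frequency at or above
#'   this value (default 0.42) in either dataset are ambiguous.
#' @param exposure_id label carried into the result.
#' @return An object of class `"mr_instruments"`: list with `exposure_id`,
#'   `outcome_id`, `data` (one row per harmonized instrument: `rsid`,
#'   `chrom`, `pos`, `beta_exp`, `se_exp`, `eaf_exp`, `pval_exp`, `beta_out`,
#'   `se_out`, `eaf_out`, `f_stat`, `r2_explained`, `flipped`, `proxy_of`)
#'   and `log` (per-SNP disposition).
#' @export
harmonize <- function(exposure_snps, outcome, ld = NULL,
                      palindrome_mode = c("exclude-ambiguous", "strict"),
                      proxy_r2 = 0.8, ambiguous_eaf = 0.42,
                      exposure_id = NULL) {
  palindrome_mode <- match.arg(palindrome_mode)
  stopifnot(inherits(outcome, "sumstats"))
  odf <- outcome$data
  out_idx <- stats::setNames(seq_len(nrow(odf)), odf$rsid)
  exposure_pval <- stats::setNames(exposure_snps$pval, exposure_snps$rsid)

  rows <- vector("list", nrow(exposure_snps))
  log_rsid <- character(nrow(exposure_snps))
  log_disp <- character(nrow(exposure_snps))

  for (i in seq_len(nrow(exposure_snps))) {
    e <- exposure_snps[i, ]
    log_rsid[i] <- e$rsid
    proxy_of <- NA_character_
    o_i <- out_idx[e$rsid]

    if (is.na(o_i) && !is.null(ld)) {
      proxy <- find_proxy(e$rsid, outcome, ld, r2_min = proxy_r2,
                          exposure_pval = exposure_pval)
      if (!is.null(proxy)) {
        o_i <- out_idx[proxy]
        proxy_of <- e$rsid
      }
    }
    if (is.na(o_i)) {
      log_disp[i] <- "absent-in-outcome"
      next
    }
    o <- odf[o_i, ]

    if (!is.na(proxy_of)) {
      # Orientation from EAF similarity only: r2 carries no allele phase.
      d_as_is <- abs(e$eaf - o$eaf)
      d_flip <- abs(e$eaf - (1 - o$eaf))
      if (abs(d_as_is - d_flip) < 0.05) {
        log_disp[i] <- "proxy-frequency-ambiguous"
        next
      }
      flip <- d_flip < d_as_is
      rows[[i]] <- harmonized_row(e, o, flip = flip, proxy_of = o$rsid)
      log_disp[i] <- "proxied"
      next
    }

    pal <- is_palindromic(e$effect_allele, e$other_allele)
    if (pal) {
      if (palindrome_mode == "strict") {
        log_disp[i] <- "palindromic-excluded"
        next
      }
      maf_e <- min(e$eaf, 1 - e$eaf)
      maf_o <- min(o$eaf, 1 - o$eaf)
      if (maf_e >= ambiguous_eaf || maf_o >= ambiguous_eaf) {
        log_disp[i] <- "palindromic-excluded"
        next
      }
      same_set <- sort(c(e$effect_allele, e$other_allele)) ==
        sort(c(o$effect_allele, o$other_allele))
      if (!all(same_set)) {
        log_disp[i] <- "incompatible-alleles"
        next
      }
      # Strand/order confounded for palindromes: orient purely by EAF.
      flip <- (e$eaf < 0.5) != (o$eaf < 0.5)
      rows[[i]] <- harmonized_row(e, o, flip = flip)
      log_disp[i] <- "kept"
      next
    }

    ea <- o$effect_allele
    oa <- o$other_allele
    if (ea == e$effect_allele && oa == e$other_allele) {
      rows[[i]] <- harmonized_row(e, o, flip = FALSE)
      log_disp[i] <- "kept"
    } else if (ea == e$other_allele && oa == e$effect_allele) {
      rows[[i]] <- harmonized_row(e, o, flip = TRUE)
      log_disp[i] <- "kept"
    } else {
      ea_c <- unname(COMPLEMENT[ea])
      oa_c <- unname(COMPLEMENT[oa])
      if (ea_c == e$effect_allele && oa_c == e$other_allele) {
        rows[[i]] <- harmonized_row(e, o, flip = FALSE)
        log_disp[i] <- "kept"
      } else if (ea_c == e$other_allele && oa_c == e$effect_allele) {
        rows[[i]] <- harmonized_row(e, o, flip = TRUE)
        log_disp[i] <- "kept"
      } else {
        log_disp[i] <- "incompatible-alleles"
      }
    }
  }

  data <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(data)) {
    data <- data.frame(rsid = character(), chrom = character(), pos = numeric(),
                       beta_exp = numeric(), se_exp = numeric(),
                       eaf_exp = numeric(), pval_exp = numeric(),
                       beta_out = numeric(), se_out = numeric(),
                       eaf_out = numeric(), f_stat = numeric(),
                       r2_explained = numeric(), flipped = logical(),
                       proxy_of = character(), stringsAsFactors = FALSE)
  }
  rownames(data) <- NULL
  structure(list(
    exposure_id = exposure_id %||% "exposure",
    outcome_id = outcome$trait_id,
    data = data,
    log = data.frame(rsid = log_rsid, disposition = log_disp,
                     stringsAsFactors = FALSE)
  ), class = "mr_instruments")
}

harmonized_row <- function(e, o, flip, proxy_of = NA_character_) {
  r2 <- variance_explained(e$beta, e$se, e$eaf, e$n)
  data.frame(
    rsid = e$rsid, chrom = e$chrom, pos = e$pos,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf, pval_exp = e$pval,
    beta_out = if (flip) -o$beta else o$beta,
    se_out = o$se,
    eaf_out = if (flip) 1 - o$eaf else o$eaf,
    f_stat = f_statistic(r2, e$n),
    r2_explained = r2,
    flipped = flip,
    proxy_of = proxy_of,
    stringsAsFactors = FALSE
  )
}

# Construct an "mr_instruments" object directly from aligned effect vectors.
# Used by the simulator-facing fast path and by tests; harmonize() is the
# file-facing route.

#' Assemble a harmonized instrument set from aligned vectors
#'
#' Convenience constructor for analyses where exposure and outcome effects
#' are already expressed on the same effect allele (e.g. simulated studies).
#'
#' @param rsid,beta_exp,se_exp,beta_out,se_out equal-length vectors.
#' @param eaf_exp,eaf_out,pval_exp,n_exp optional; EAF defaults to 0.5 and
#'   exposure p-values are recomputed from `beta_exp/se_exp` when omitted.
#' @param exposure_id,outcome_id labels.
#' @return An `"mr_instruments"` object.
#' @export
mr_instruments <- function(rsid, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NULL, eaf_out = NULL, pval_exp = NULL,
                           n_exp = NULL, exposure_id = "exposure",
                           outcome_id = "outcome") {
  J <- length(rsid)
  stopifnot(length(beta_exp) == J, length(beta_out) == J)
  se_exp <- rep_len(se_exp, J)
  se_out <- rep_len(se_out, J)
  eaf_exp <- rep_len(eaf_exp %||% 0.5, J)
  n_exp <- rep_len(n_exp %||% 1000, J)
  r2 <- variance_explained(beta_exp, se_exp, eaf_exp, n_exp)
  data <- data.frame(
    rsid = as.character(rsid), chrom = "1", pos = seq_len(J) * 2e6,
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf_exp,
    pval_exp = pval_exp %||% z_pvalue(beta_exp / se_exp),
    beta_out = beta_out, se_out = se_out,
    eaf_out = eaf_out %||% eaf_exp,
    f_stat = f_statistic(r2, n_exp), r2_explained = r2,
    flipped = FALSE, proxy_of = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 data = data,
                 log = data.frame(rsid = data$rsid, disposition = "kept",
                                  stringsAsFactors = FALSE)),
            class = "mr_instruments")
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %s -> %s\n", x$exposure_id, x$outcome_id))
  cat(sprintf("  %d instrument(s); dispositions: %s\n", nrow(x$data),
              paste(sprintf("%s=%d", names(table(x$log$disposition)),
                            as.integer(table(x$log$disposition))),
                    collapse = ", ")))
  invisible(x)
}

# Subset an instrument set by row index, preserving class and labels.
subset_instruments <- function(x, idx) {
  out <- x
  out$data <- x$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
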