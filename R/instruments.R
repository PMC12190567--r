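#' Select candidate instrumental variables for one exposure
#'
#' Retains variants reaching the locus-wide significance threshold used in
#' microbiome MR (`pval < p_threshold`, default 1e-5) whose minor-allele
#' frequency exceeds `eaf_min`. The frequency filter is applied in the
#' minor-allele sense, `min(eaf, 1 - eaf) > eaf_min`, so that a 0.995-frequency
#' effect allele (rare minor allele) is excluded as intended.
#'
#' @param exposure a `"sumstats"` object.
#' @param p_threshold significance threshold (default 1e-5).
#' @param eaf_min minimum minor-allele frequency (default 0.01).
#' @return data.frame of candidate rows, sorted by ascending p-value with rsid
#'   as tie-break. Zero candidates yield an empty data.frame with a warning.
#' @export
select_instruments <- function(exposure, p_threshold = 1e-5, eaf_min = 0.01) {
  stopifnot(inherits(exposure, "sumstats"))
  stopifnot_scalar(p_threshold, "p_threshold", positive = TRUE)
  df <- exposure$data
  keep <- df$pval < p_threshold & pmin(df$eaf, 1 - df$eaf) > eaf_min
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$pval, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning(sprintf("no instruments pass p < %g and MAF > %g for '%s'",
                    p_threshold, eaf_min, exposure$trait_id), call. = FALSE)
  }
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the remaining variant with the smallest p-value (rsid
#' tie-break) as an index SNP and removes every remaining variant on the same
#' chromosome within `window_kb` kilobases whose r² with the index is at least
#' `r2_max`. Cross-chromosome pairs and within-chromosome pairs beyond the
#' window are always treated as unlinked; pairs absent from the LD reference
#' are unlinked by convention. The result depends only on p-values, positions
#' and r² — not on input row order.
#'
#' @param candidates data.frame with at least `rsid`, `chrom`, `pos`, `pval`
#'   (as returned by [select_instruments()]).
#' @param ld an `"ld_ref"` object.
#' @param r2_max clumping threshold (pairs with r² >= r2_max are pruned;
#'   default 0.1, i.e. retained pairs satisfy r² < 0.1).
#' @param window_kb half-window in kb (default 1000).
#' @return data.frame of index SNPs (subset of `candidates`, ascending p),
#'   with an attribute `"removed"`: data.frame of pruned rsids and the index
#'   SNP that removed each.
#' @export
ld_clump <- function(candidates, ld, r2_max = 0.1, window_kb = 1000) {
  stopifnot(inherits(ld, "ld_ref"))
  if (nrow(candidates) == 0L) {
    out <- candidates
    attr(out, "removed") <- data.frame(rsid = character(),
                                       index_snp = character(),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  ord <- order(candidates$pval, candidates$rsid)
  df <- candidates[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  remaining <- seq_len(nrow(df))
  kept <- integer()
  removed_rsid <- character()
  removed_by <- character()
  while (length(remaining)) {
    i <- remaining[1L]
    kept <- c(kept, i)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    same <- df$chrom[remaining] == df$chrom[i] &
      abs(df$pos[remaining] - df$pos[i]) <= window_bp
    if (any(same)) {
      r2 <- ld_r2(ld, df$rsid[i], df$rsid[remaining[same]])
      prune <- remaining[same][r2 >= r2_max]
      if (length(prune)) {
        removed_rsid <- c(removed_rsid, df$rsid[prune])
        removed_by <- c(removed_by, rep(df$rsid[i], length(prune)))
        remaining <- setdiff(remaining, prune)
      }
    }
  }
  out <- df[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(rsid = removed_rsid,
                                     index_snp = removed_by,
                                     stringsAsFactors = FALSE)
  out
}

#' Find an LD proxy for a variant missing from the outcome table
#'
#' Returns the outcome-present variant with the highest r² above `r2_min`
#' (default 0.8) to the query, breaking ties by smaller exposure p-value then
#' rsid; `NULL` when no proxy qualifies.
#'
#' @param rsid query variant (absent from the outcome table).
#' @param outcome a `"sumstats"` object.
#' @param ld an `"ld_ref"` object.
#' @param r2_min minimum r² for a usable proxy (default 0.8, exclusive).
#' @param exposure_pval optional named numeric vector of exposure p-values
#'   used for tie-breaking.
#' @return the proxy rsid, or `NULL`.
#' @export
find_proxy <- function(rsid, outcome, ld, r2_min = 0.8, exposure_pval = NULL) {
  stopifnot(inherits(outcome, "sumstats"), inherits(ld, "ld_ref"))
  cand <- setdiff(outcome$data$rsid, rsid)
  if (!length(cand)) return(NULL)
  r2 <- ld_r2(ld, rsid, cand)
  ok <- r2 > r2_min
  if (!any(ok)) return(NULL)
  cand <- cand[ok]
  r2 <- r2[ok]
  p <- if (is.null(exposure_pval)) rep(1, length(cand)) else {
    pv <- exposure_pval[cand]
    pv[is.na(pv)] <- 1
    pv
  }
  cand[order(-r2, p, cand)][1L]
}

#' Variance in the exposure explained by one SNP
#'
#' R² = 2β²·EAF·(1−EAF) / (2β²·EAF·(1−EAF) + 2N·SE²·EAF·(1−EAF)).
#' Symmetric in EAF vs 1−EAF and zero for a null effect. Vectorized.
#'
#' @param beta,se per-allele effect and its standard error (`se > 0`).
#' @param eaf effect-allele frequency in (0, 1).
#' @param n exposure GWAS sample size.
#' @return R² values in \[0, 1).
#' @export
variance_explained <- function(beta, se, eaf, n) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be positive", call. = FALSE)
  }
  if (any(eaf <= 0 | eaf >= 1)) stop("`eaf` must be in (0, 1)", call. = FALSE)
  num <- 2 * beta^2 * eaf * (1 - eaf)
  num / (num + 2 * n * se^2 * eaf * (1 - eaf))
}

#' Instrument-strength F-statistic
#'
#' F = (N − 2)·R² / (1 − R²). Values above 10 conventionally indicate low
#' weak-instrument bias. Vectorized.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n exposure GWAS sample size (> 2).
#' @return F >= 0.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("`r2` must be in [0, 1)", call. = FALSE)
  if (any(n <= 2)) stop("`n` must exceed 2", call. = FALSE)
  (n - 2) * r2 / (1 - r2)
}

#' Summarize instrument strength for a harmonized set
#'
#' @param instruments an `"mr_instruments"` object (see [harmonize()]).
#' @return list with `n_snp`, `min_f`, `median_f`, `total_r2` and a logical
#'   `weak_flag` raised when the minimum F falls below 10.
#' @export
strength_summary <- function(instruments) {
  stopifnot(inherits(instruments, "mr_instruments"))
  df <- instruments$data
  if (nrow(df) == 0L) stop("instrument set is empty", call. = FALSE)
  list(n_snp = nrow(df),
       min_f = min(df$f_stat),
       median_f = stats::median(df$f_stat),
       total_r2 = sum(df$r2_explained),
       weak_flag = min(df$f_stat) < 10)
}
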