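# Fixtures built in code: small summary-statistics tables, instrument sets,
# and brute-force oracles the estimators are checked against.

variant_df <- function(rsid, beta, se, pval = NULL, eaf = 0.3, chrom = "1",
                       pos = NULL, ea = "A", oa = "G", n = 1539) {
  k <- length(rsid)
  data.frame(
    rsid = rsid, chrom = rep_len(chrom, k),
    pos = pos %||% (seq_len(k) * 5e6),
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = rep_len(beta, k), se = rep_len(se, k),
    pval = pval %||% pmax(2 * pnorm(-abs(rep_len(beta, k) / rep_len(se, k))),
                          1e-300),
    n = rep_len(n, k), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_sumstats <- function(..., trait_id = "trait",
                          trait_type = "quantitative", n_cases = NA,
                          n_controls = NA) {
  sumstats(variant_df(...), trait_id = trait_id, trait_type = trait_type,
           n_cases = n_cases, n_controls = n_controls)
}

# Brute-force weighted least squares via the normal equations; the
# independent oracle for IVW (no intercept) and MR-Egger (with intercept).
wls_oracle <- function(X, y, w) {
  W <- diag(w, nrow = length(w))
  xtwx <- t(X) %*% W %*% X
  coefs <- solve(xtwx, t(X) %*% W %*% y)
  resid <- y - X %*% coefs
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  list(coef = drop(coefs), vcov_fixed = solve(xtwx),
       vcov = sigma2 * solve(xtwx), sigma2 = sigma2, df = df)
}

# Brute-force clumping oracle: enumerate all subsets of candidates, keep
# those with no linked pair (r2 >= r2_max within the window), and return the
# maximal ones (no candidate can be added without violating).
clump_oracle <- function(candidates, ld, r2_max, window_kb) {
  n <- nrow(candidates)
  linked <- function(i, j) {
    candidates$chrom[i] == candidates$chrom[j] &&
      abs(candidates$pos[i] - candidates$pos[j]) <= window_kb * 1000 &&
      ld_r2(ld, candidates$rsid[i], candidates$rsid[j]) >= r2_max
  }
  valid <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      if (linked(idx[a], idx[b])) return(FALSE)
    }
    TRUE
  }
  subsets <- lapply(0:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  valid_sets <- Filter(valid, subsets)
  maximal <- Filter(function(idx) {
    extra <- setdiff(seq_len(n), idx)
    !any(vapply(extra, function(e) valid(c(idx, e)), logical(1)))
  }, valid_sets)
  lapply(maximal, function(idx) sort(candidates$rsid[idx]))
}

default_study <- function(seed, ...) {
  simulate_study(sim_config(seed = seed, ...))
}

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

subset_inst <- function(x, idx) gutmr:::subset_instruments(x, idx)

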