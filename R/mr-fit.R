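# Core two-sample MR estimators. All closed forms are authored here and
# cross-checked in the test suite against a brute-force weighted-least-squares
# oracle; nothing is delegated to an MR library.

#' Per-SNP Wald ratio estimate
#'
#' beta = beta_out / beta_exp with first-order (NOME) standard error
#' se_out / |beta_exp|; an optional second-order delta-method SE additionally
#' propagates the exposure uncertainty.
#'
#' @param beta_exp,beta_out SNP-exposure and SNP-outcome effects
#'   (`beta_exp != 0`).
#' @param se_out outcome standard error.
#' @param se_exp exposure standard error (needed for `second_order`).
#' @param second_order logical; use the second-order delta SE.
#' @return list with `beta` and `se`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out, se_exp = NULL,
                       second_order = FALSE) {
  if (any(beta_exp == 0)) stop("`beta_exp` must be non-zero", call. = FALSE)
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  if (second_order) {
    if (is.null(se_exp)) stop("`se_exp` required for second-order SE", call. = FALSE)
    se <- sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  list(beta = beta, se = se)
}

# ---- internal closed-form engines (vector interface) ----------------------

ivw_engine <- function(bx, by, sy, model = c("random", "fixed")) {
  model <- match.arg(model)
  J <- length(bx)
  if (J < 2L) stop("IVW requires at least 2 instruments", call. = FALSE)
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (by - beta * bx)^2)
  infl <- if (model == "random" && J > 2L) max(1, sqrt(q / (J - 1))) else 1
  se <- se_fixed * infl
  list(beta = beta, se = se, se_fixed = se_fixed, q = q, df = J - 1L,
       model = model, pval = z_pvalue(beta / se), n_snp = J)
}

egger_engine <- function(bx, by, sy) {
  J <- length(bx)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  s <- ifelse(bx < 0, -1, 1)          # orient so beta_exp > 0
  x <- bx * s
  y <- by * s
  if (stats::sd(x) == 0) {
    stop("degenerate design: all oriented exposure effects equal", call. = FALSE)
  }
  w <- 1 / sy^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (J - 2)
  se_slope <- sqrt(sigma2 * sw / det)
  se_intercept <- sqrt(sigma2 * swxx / det)
  df <- J - 2L
  list(slope = slope, se_slope = se_slope,
       pval_slope = 2 * stats::pt(-abs(slope / se_slope), df),
       intercept = intercept, se_intercept = se_intercept,
       pval_intercept = 2 * stats::pt(-abs(intercept / se_intercept), df),
       sigma = sqrt(sigma2), df = df, n_snp = J)
}

# Weighted median of ratios r with weights w: sort, form cumulative midpoints
# p_j = S_j - w_j/2 (S_j cumulative normalized weight), linearly interpolate
# r at p = 0.5.
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

weighted_median_engine <- function(bx, by, sx, sy, n_boot = 1000, seed = 1) {
  J <- length(bx)
  if (J < 3L) stop("weighted median requires at least 3 instruments", call. = FALSE)
  r <- by / bx
  w <- (bx / sy)^2
  beta <- weighted_median_point(r, w)
  boot <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(J * n_boot, bx, sx), nrow = J)
    bys <- matrix(stats::rnorm(J * n_boot, by, sy), nrow = J)
    rs <- bys / bxs
    ws <- (bxs / sy)^2
    vapply(seq_len(n_boot),
           function(b) weighted_median_point(rs[, b], ws[, b]), numeric(1))
  })
  se <- stats::sd(boot)
  list(beta = beta, se = se, pval = z_pvalue(beta / se), n_snp = J,
       n_boot = n_boot, seed = seed)
}

estimate_row <- function(method, beta, se, pval, ci_low, ci_high, n_snp) {
  data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high, pval = pval,
             or = exp(beta), or_lci95 = exp(ci_low), or_uci95 = exp(ci_high),
             stringsAsFactors = FALSE)
}

#' Fit two-sample Mendelian randomization estimators
#'
#' The package's central fitting function. Given a harmonized instrument set
#' it computes the inverse-variance-weighted (IVW) estimate, MR-Egger slope
#' and intercept, and the weighted median, returning a classed object with
#' `print`, `summary`, `coef`, `confint` and `plot` methods.
#'
#' IVW is the weighted regression of outcome effects on exposure effects
#' through the origin with weights 1/se_out²; the default
#' multiplicative-random-effects model inflates the fixed-effect SE by
#' `max(1, sqrt(Q/(J-1)))`, so it never reports less uncertainty than the
#' fixed-effect model (and is therefore conservative under homogeneity).
#' MR-Egger is weighted least squares with a free intercept on instruments
#' oriented to positive exposure effect; slope and intercept are tested
#' against a t distribution with J-2 df. The weighted median interpolates the
#' inverse-variance-weighted ordered Wald ratios at cumulative weight 0.5,
#' with a parametric-bootstrap SE.
#'
#' @param instruments an `"mr_instruments"` object.
#' @param methods subset of `c("ivw", "egger", "weighted_median")`.
#' @param ivw_model `"random"` (default) or `"fixed"`.
#' @param n_boot bootstrap replicates for the weighted-median SE.
#' @param seed seed for the bootstrap (explicit; no global RNG state used).
#' @param alpha two-sided level for confidence intervals (default 0.05).
#' @return An object of class `"mr_fit"` with elements `estimates` (one row
#'   per method including the Egger intercept, with beta/SE/CI/p and
#'   exponentiated odds-ratio transforms), `q` (Cochran's Q on the Wald
#'   ratios), `instruments`, `ivw_model` and `call`.
#' @examples
#' x <- mr_instruments(rsid = paste0("rs", 1:3),
#'                     beta_exp = c(0.1, 0.2, 0.15), se_exp = rep(0.03, 3),
#'                     beta_out = c(0.02, 0.05, 0.03),
#'                     se_out = c(0.01, 0.02, 0.015))
#' fit <- mr_fit(x, seed = 7)
#' coef(fit)
#' @export
mr_fit <- function(instruments, methods = c("ivw", "egger", "weighted_median"),
                   ivw_model = c("random", "fixed"), n_boot = 1000, seed = 1,
                   alpha = 0.05) {
  stopifnot(inherits(instruments, "mr_instruments"))
  ivw_model <- match.arg(ivw_model)
  methods <- match.arg(methods, several.ok = TRUE)
  df <- instruments$data
  bx <- df$beta_exp; by <- df$beta_out
  sx <- df$se_exp; sy <- df$se_out
  zq <- stats::qnorm(1 - alpha / 2)
  rows <- list()

  ivw <- ivw_engine(bx, by, sy, model = ivw_model)
  if ("ivw" %in% methods) {
    rows$ivw <- estimate_row("IVW", ivw$beta, ivw$se, ivw$pval,
                             ivw$beta - zq * ivw$se, ivw$beta + zq * ivw$se,
                             ivw$n_snp)
  }
  if ("egger" %in% methods) {
    eg <- egger_engine(bx, by, sy)
    tq <- stats::qt(1 - alpha / 2, eg$df)
    rows$egger <- estimate_row("MR-Egger", eg$slope, eg$se_slope, eg$pval_slope,
                               eg$slope - tq * eg$se_slope,
                               eg$slope + tq * eg$se_slope, eg$n_snp)
    rows$egger_int <- estimate_row("MR-Egger intercept", eg$intercept,
                                   eg$se_intercept, eg$pval_intercept,
                                   eg$intercept - tq * eg$se_intercept,
                                   eg$intercept + tq * eg$se_intercept,
                                   eg$n_snp)
  }
  if ("weighted_median" %in% methods) {
    wm <- weighted_median_engine(bx, by, sx, sy, n_boot = n_boot, seed = seed)
    rows$wm <- estimate_row("Weighted median", wm$beta, wm$se, wm$pval,
                            wm$beta - zq * wm$se, wm$beta + zq * wm$se,
                            wm$n_snp)
  }

  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  structure(list(
    estimates = estimates,
    q = list(q = ivw$q, df = ivw$df, pval = stats::pchisq(ivw$q, ivw$df,
                                                          lower.tail = FALSE)),
    instruments = instruments,
    ivw_model = ivw_model,
    alpha = alpha,
    call = match.call()
  ), class = "mr_fit")
}
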