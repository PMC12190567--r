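# Two-step MR mediation: the product-of-coefficients decomposition of an
# exposure's effect on the outcome through a mediator, with a parametric
# bootstrap over the three MR estimates (which come from non-overlapping
# cohorts and are treated as independent).

as_mr_estimate <- function(x, name) {
  if (inherits(x, "mr_fit")) {
    row <- x$estimates[x$estimates$method == "IVW", ]
    if (!nrow(row)) stop(name, ": mr_fit carries no IVW estimate", call. = FALSE)
    return(list(beta = row$beta[1], se = row$se[1]))
  }
  if (is.list(x) && all(c("beta", "se") %in% names(x))) {
    return(list(beta = as.numeric(x$beta), se = as.numeric(x$se)))
  }
  if (is.numeric(x) && length(x) == 2L) {
    return(list(beta = x[[1]], se = x[[2]]))
  }
  stop(name, " must be an mr_fit, a list(beta=, se=), or c(beta, se)",
       call. = FALSE)
}

#' Two-step MR mediation point estimates
#'
#' Given the exposure-to-mediator effect (beta1), the mediator-to-outcome
#' effect (beta2) and the exposure-to-outcome total effect (beta3), computes
#' the indirect effect beta1*beta2 and the proportion mediated
#' beta1*beta2/beta3. beta2 and beta3 must share the outcome scale (log-odds
#' for binary outcomes); the proportion is invariant to the mediator's units.
#' Proportions outside \[0, 1\] are reported as computed (inconsistent
#' mediation is informative) with a qualitative flag.
#'
#' @param exp_med,med_out,exp_out the three MR estimates, each an `"mr_fit"`,
#'   a `list(beta =, se =)`, or a length-2 numeric `c(beta, se)`.
#' @param beta3_tol |beta3| below this flags the proportion undefined.
#' @param exposure_id,mediator_id,outcome_id labels.
#' @return An object of class `"mediation_result"`: list with `beta1`,
#'   `beta2`, `beta3` (each with SE), `indirect`, `proportion`,
#'   `proportion_defined`, `consistent` (sign(beta1*beta2) == sign(beta3)).
#' @export
two_step_mediation <- function(exp_med, med_out, exp_out, beta3_tol = 1e-12,
                               exposure_id = "exposure",
                               mediator_id = "mediator",
                               outcome_id = "outcome") {
  e1 <- as_mr_estimate(exp_med, "exp_med")
  e2 <- as_mr_estimate(med_out, "med_out")
  e3 <- as_mr_estimate(exp_out, "exp_out")
  indirect <- e1$beta * e2$beta
  defined <- abs(e3$beta) >= beta3_tol
  proportion <- if (defined) indirect / e3$beta else NA_real_
  structure(list(
    exposure_id = exposure_id, mediator_id = mediator_id,
    outcome_id = outcome_id,
    beta1 = e1$beta, se1 = e1$se,
    beta2 = e2$beta, se2 = e2$se,
    beta3 = e3$beta, se3 = e3$se,
    indirect = indirect,
    proportion = proportion,
    proportion_defined = defined,
    consistent = defined && sign(indirect) == sign(e3$beta)
  ), class = "mediation_result")
}

#' Bootstrap confidence interval and p-value for the proportion mediated
#'
#' Parametric bootstrap over the estimate triplet: beta1*, beta2*, beta3* are
#' drawn independently from Normal(point, SE), the proportion is recomputed
#' per draw (draws with |beta3*| below `beta3_tol` are discarded and
#' counted), the CI is the 2.5/97.5 percentile interval, and the two-sided
#' p-value is the proportion-of-draws sign test against zero with an add-one
#' pseudo-count.
#'
#' @inheritParams two_step_mediation
#' @param n_boot bootstrap draws (default 10000).
#' @param seed explicit seed.
#' @return A `"mediation_result"` with additional elements `prop_ci_low`,
#'   `prop_ci_high`, `prop_pval`, `n_boot`, `n_discarded`, `seed`.
#' @export
bootstrap_mediation <- function(exp_med, med_out, exp_out, n_boot = 10000,
                                seed = 1, beta3_tol = 1e-12,
                                exposure_id = "exposure",
                                mediator_id = "mediator",
                                outcome_id = "outcome") {
  res <- two_step_mediation(exp_med, med_out, exp_out, beta3_tol = beta3_tol,
                            exposure_id = exposure_id,
                            mediator_id = mediator_id, outcome_id = outcome_id)
  if (!all(is.finite(c(res$se1, res$se2, res$se3)))) {
    stop("all three estimates must carry finite standard errors", call. = FALSE)
  }
  draws <- with_seed(seed, {
    b1 <- stats::rnorm(n_boot, res$beta1, res$se1)
    b2 <- stats::rnorm(n_boot, res$beta2, res$se2)
    b3 <- stats::rnorm(n_boot, res$beta3, res$se3)
    ok <- abs(b3) >= beta3_tol
    list(prop = (b1[ok] * b2[ok]) / b3[ok], n_discarded = sum(!ok))
  })
  if (draws$n_discarded > n_boot / 2) {
    stop("unstable denominator: more than half of the bootstrap draws have ",
         "|beta3*| below tolerance", call. = FALSE)
  }
  prop <- draws$prop
  nd <- length(prop)
  ci <- unname(stats::quantile(prop, c(0.025, 0.975)))
  pval <- min(1, 2 * min((1 + sum(prop <= 0)) / (nd + 1),
                         (1 + sum(prop >= 0)) / (nd + 1)))
  res$prop_ci_low <- ci[1]
  res$prop_ci_high <- ci[2]
  res$prop_pval <- pval
  res$n_boot <- n_boot
  res$n_discarded <- draws$n_discarded
  res$seed <- seed
  res
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure_id, x$mediator_id,
              x$outcome_id))
  cat(sprintf("  beta1 %.4g (se %.4g), beta2 %.4g (se %.4g), beta3 %.4g (se %.4g)\n",
              x$beta1, x$se1, x$beta2, x$se2, x$beta3, x$se3))
  if (x$proportion_defined) {
    cat(sprintf("  indirect %.4g; proportion mediated %.4g%s\n", x$indirect,
                x$proportion,
                if (!x$consistent) "  [inconsistent mediation]" else ""))
  } else {
    cat(sprintf("  indirect %.4g; proportion undefined (|beta3| below tolerance)\n",
                x$indirect))
  }
  if (!is.null(x$prop_ci_low)) {
    cat(sprintf("  95%% bootstrap CI [%.4g, %.4g], p = %.4g (%d draws, %d discarded)\n",
                x$prop_ci_low, x$prop_ci_high, x$prop_pval, x$n_boot,
                x$n_discarded))
  }
  invisible(x)
}

#' Screen exposure-mediator pairs and run mediation on qualifying triplets
#'
#' Mediation is computed only for pairs where all three links pass `alpha`
#' two-sided: exposure-to-outcome, exposure-to-mediator, and
#' mediator-to-outcome. Every skipped pair is logged with its reason.
#'
#' @param exp_out data.frame with columns `exposure`, `beta`, `se`, `pval`.
#' @param exp_med data.frame with columns `exposure`, `mediator`, `beta`,
#'   `se`, `pval`.
#' @param med_out data.frame with columns `mediator`, `beta`, `se`, `pval`.
#' @param outcome_id label for the outcome.
#' @param alpha screening level (default 0.05).
#' @param n_boot,seed passed to [bootstrap_mediation()]; each pair uses a
#'   deterministic sub-seed.
#' @return data.frame, one row per qualifying pair, with beta1/beta2/beta3
#'   (and SEs), indirect effect, proportion mediated, bootstrap CI and p.
#'   The attribute `"log"` lists skipped pairs and reasons.
#' @export
mediation_screen <- function(exp_out, exp_med, med_out, outcome_id = "outcome",
                             alpha = 0.05, n_boot = 10000, seed = 1) {
  needed <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(name, " is missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  needed(exp_out, c("exposure", "beta", "se", "pval"), "exp_out")
  needed(exp_med, c("exposure", "mediator", "beta", "se", "pval"), "exp_med")
  needed(med_out, c("mediator", "beta", "se", "pval"), "med_out")

  rows <- list()
  log <- list()
  k <- 0L
  for (i in seq_len(nrow(exp_med))) {
    pair <- exp_med[i, ]
    key <- sprintf("%s->%s", pair$exposure, pair$mediator)
    eo <- exp_out[exp_out$exposure == pair$exposure, ]
    mo <- med_out[med_out$mediator == pair$mediator, ]
    reason <- if (!nrow(eo)) "missing exposure-outcome estimate"
      else if (!nrow(mo)) "missing mediator-outcome estimate"
      else if (eo$pval[1] >= alpha) "exposure-outcome not significant"
      else if (mo$pval[1] >= alpha) "mediator-outcome not significant"
      else if (pair$pval >= alpha) "exposure-mediator not significant"
      else NA_character_
    if (!is.na(reason)) {
      log[[key]] <- reason
      next
    }
    k <- k + 1L
    med <- bootstrap_mediation(
      exp_med = list(beta = pair$beta, se = pair$se),
      med_out = list(beta = mo$beta[1], se = mo$se[1]),
      exp_out = list(beta = eo$beta[1], se = eo$se[1]),
      n_boot = n_boot, seed = derive_seed(seed, i),
      exposure_id = pair$exposure, mediator_id = pair$mediator,
      outcome_id = outcome_id)
    rows[[k]] <- data.frame(
      exposure = pair$exposure, mediator = pair$mediator,
      outcome = outcome_id,
      beta1 = med$beta1, se1 = med$se1, beta2 = med$beta2, se2 = med$se2,
      beta3 = med$beta3, se3 = med$se3, indirect = med$indirect,
      proportion = med$proportion, prop_ci_low = med$prop_ci_low,
      prop_ci_high = med$prop_ci_high, prop_pval = med$prop_pval,
      consistent = med$consistent, stringsAsFactors = FALSE)
  }
  out <- if (k) do.call(rbind, rows) else data.frame(
    exposure = character(), mediator = character(), outcome = character(),
    beta1 = numeric(), se1 = numeric(), beta2 = numeric(), se2 = numeric(),
    beta3 = numeric(), se3 = numeric(), indirect = numeric(),
    proportion = numeric(), prop_ci_low = numeric(), prop_ci_high = numeric(),
    prop_pval = numeric(), consistent = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log") <- unlist(log) %||% character()
  out
}
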