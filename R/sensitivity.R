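#' Sensitivity analyses
#'
#' Heterogeneity (Cochran's Q), directional pleiotropy (Egger
#' intercept), directionality (Steiger filtering), leave-one-out and
#' single-SNP analyses for a harmonized instrument set.
#'
#' @name sensitivity
NULL

#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (b_j - theta_FE)^2 over the per-SNP Wald ratios b_j,
#' with inverse-variance weights w_j = (se_out_j/|beta_exp_j|)^-2 and
#' theta_FE the fixed-effect IVW estimate. Under homogeneity Q is
#' chi-squared on J-1 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 2 retained pairs.
#' @return list `(q_stat, q_df, q_pval)`.
#' @export
cochran_q <- function(h) {
  r <- ratio_estimates(h)
  if (nrow(r) < 2) stop_instruments("cochran_q: needs >= 2 instruments")
  theta <- sum(r$w * r$b) / sum(r$w)
  q <- sum(r$w * (r$b - theta)^2)
  df <- nrow(r) - 1
  list(q_stat = q, q_df = df, q_pval = pchisq(q, df, lower.tail = FALSE))
}

#' Egger-intercept test for directional pleiotropy
#'
#' Reports the intercept of the MR-Egger regression with its SE and a
#' two-sided t test on J-2 degrees of freedom. A nonzero intercept
#' indicates that the average pleiotropic effect of the instruments is
#' directional.
#'
#' @param h a `harmonized_set` with at least 3 retained pairs.
#' @return list `(intercept, se, pval)`.
#' @export
egger_intercept_test <- function(h) {
  r <- mr_egger(h)
  list(intercept = r$extra$intercept, se = r$extra$intercept_se,
       pval = r$extra$intercept_pval)
}

steiger_r <- function(beta, se, n) {
  t <- beta / se
  sqrt(t^2 / (t^2 + n - 2))
}

#' Steiger directionality filtering
#'
#' For each SNP, compares the variance explained in the exposure versus
#' the outcome via the t-statistic route r = sqrt(t^2/(t^2 + n - 2)).
#' The causal direction exposure -> outcome is supported when
#' r2_exp > r2_out. The Steiger p-value is a two-sided z test on the
#' difference of Fisher-transformed |r| with variance
#' 1/(n_exp-3) + 1/(n_out-3). A SNP is removed only when the direction
#' is wrong AND p < alpha: direction alone is noisy for weak
#' instruments.
#'
#' @param h a `harmonized_set`.
#' @param n_exp,n_out fallback sample sizes used where the per-record
#'   `n` is missing; at least one route must resolve per side.
#' @param alpha removal threshold (default 0.05).
#' @return list with `harmonized` (filtered `harmonized_set`) and
#'   `report` (per-SNP data.frame: `snp_id`, `r2_exp`, `r2_out`,
#'   `direction_ok`, `steiger_pval`, `removed`).
#' @export
steiger_filter <- function(h, n_exp = NULL, n_out = NULL, alpha = 0.05) {
  p <- retained_pairs(h)
  ne <- ifelse(is.na(p$n_exp), n_exp %||% NA_real_, p$n_exp)
  no <- ifelse(is.na(p$n_out), n_out %||% NA_real_, p$n_out)
  if (any(is.na(ne)) || any(is.na(no))) {
    stop_config("steiger_filter: sample size unavailable for some SNPs ",
                "(supply n_exp/n_out)")
  }
  re <- steiger_r(p$beta_exp, p$se_exp, ne)
  ro <- steiger_r(p$beta_out, p$se_out, no)
  z <- (atanh(re) - atanh(ro)) / sqrt(1 / (ne - 3) + 1 / (no - 3))
  pv <- 2 * pnorm(-abs(z))
  direction_ok <- re^2 > ro^2
  removed <- !direction_ok & pv < alpha
  report <- data.frame(snp_id = p$snp_id, r2_exp = re^2, r2_out = ro^2,
                       direction_ok = direction_ok, steiger_pval = pv,
                       removed = removed, stringsAsFactors = FALSE)
  list(harmonized = subset_harmonized(h, p$snp_id[!removed]),
       report = report)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect (IVW by default) excluding each SNP in
#' turn, plus the all-SNP row. Large shifts flag influential
#' instruments.
#'
#' @param h a `harmonized_set` with at least 3 retained pairs.
#' @param mode IVW mode, `"random"` or `"fixed"`.
#' @return data.frame with `excluded` (`"none"` for the full set),
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pval`, `n_snp`.
#' @export
leave_one_out <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  p <- retained_pairs(h)
  if (nrow(p) < 3) stop_instruments("leave_one_out: needs >= 3 instruments")
  rows <- lapply(p$snp_id, function(id) {
    r <- mr_ivw(subset_harmonized(h, setdiff(p$snp_id, id)), mode)
    cbind(excluded = id, as.data.frame(r))
  })
  full <- cbind(excluded = "none", as.data.frame(mr_ivw(h, mode)))
  out <- rbind(do.call(rbind, rows), full)
  rownames(out) <- NULL
  out
}

#' Single-SNP analysis
#'
#' Wald ratio per SNP (forest-plot input) plus a summary row per
#' requested multi-SNP method.
#'
#' @param h a `harmonized_set` with at least 1 retained pair.
#' @param methods summary methods appended after the per-SNP rows
#'   (default IVW random effects).
#' @param n_boot,seed bootstrap controls for median/mode summaries.
#' @return data.frame with `snp_id` (method name for summary rows),
#'   `type` (`"snp"`/`"summary"`), `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pval`.
#' @export
single_snp <- function(h, methods = "ivw", n_boot = 1000, seed = 1L) {
  p <- retained_pairs(h)
  if (nrow(p) == 0) stop_instruments("single_snp: no retained instruments")
  rows <- lapply(seq_len(nrow(p)), function(i) {
    r <- mr_wald_ratio(p[i, ])
    data.frame(snp_id = p$snp_id[i], type = "snp", estimate = r$estimate,
               se = r$se, ci_low = r$ci_low, ci_high = r$ci_high,
               pval = r$pval, stringsAsFactors = FALSE)
  })
  summaries <- list()
  if (length(methods)) {
    res <- tryCatch(run_mr(h, methods, n_boot = n_boot, seed = seed),
                    mrtriad_insufficient_instruments = function(e) list())
    summaries <- lapply(res, function(r) {
      data.frame(snp_id = r$method, type = "summary", estimate = r$estimate,
                 se = r$se, ci_low = r$ci_low, ci_high = r$ci_high,
                 pval = r$pval, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, c(rows, unname(summaries)))
  rownames(out) <- NULL
  out
}

#' Full sensitivity report
#'
#' Bundles Cochran's Q, the Egger intercept test, the Steiger per-SNP
#' report, leave-one-out and single-SNP tables. Components whose
#' instrument minimum is unmet are `NULL` with a message.
#'
#' @param h a `harmonized_set`.
#' @param n_exp,n_out,alpha Steiger controls (see [steiger_filter()]);
#'   Steiger is skipped when sample sizes are unavailable.
#' @return object of class `sensitivity_report`: list with elements
#'   `q` (`q_stat`, `q_df`, `q_pval`), `egger_intercept`, `steiger`,
#'   `loo`, `single_snp`.
#' @export
sensitivity_report <- function(h, n_exp = NULL, n_out = NULL, alpha = 0.05) {
  try_part <- function(expr) tryCatch(expr, error = function(e) {
    message("sensitivity_report: ", conditionMessage(e)); NULL
  })
  rep <- list(
    q = try_part(cochran_q(h)),
    egger_intercept = try_part(egger_intercept_test(h)),
    steiger = try_part(steiger_filter(h, n_exp, n_out, alpha)$report),
    loo = try_part(leave_one_out(h)),
    single_snp = try_part(single_snp(h))
  )
  class(rep) <- "sensitivity_report"
  rep
}

#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(
    q_stat = x$q$q_stat %||% NA_real_,
    q_df = x$q$q_df %||% NA_integer_,
    q_pval = x$q$q_pval %||% NA_real_,
    egger_intercept = x$egger_intercept$intercept %||% NA_real_,
    egger_intercept_se = x$egger_intercept$se %||% NA_real_,
    egger_intercept_pval = x$egger_intercept$pval %||% NA_real_
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n",
                x$q$q_stat, x$q$q_df, x$q$q_pval))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4g (se %.3g), p = %.3g\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$pval))
  }
  if (!is.null(x$steiger)) {
    cat("  Steiger: ", sum(x$steiger$removed), " of ", nrow(x$steiger),
        " SNP(s) flagged and removed\n", sep = "")
  }
  invisible(x)
}
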