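#' MR estimators
#'
#' All estimators operate on the retained pairs of a `harmonized_set`.
#' Per-SNP Wald ratios b_j = beta_out_j / beta_exp_j with first-order
#' standard errors se_bj = se_out_j / |beta_exp_j| are the common
#' currency; inverse-variance weights w_j = 1 / se_bj^2 ignore the
#' exposure-side sampling error (the NOME approximation), matching the
#' weighting used by the IVW estimator.
#'
#' @name mr_estimators
NULL

MR_METHODS <- c("wald_ratio", "ivw_fe", "ivw_re", "egger", "weighted_median",
                "simple_median", "weighted_mode", "simple_mode")

new_mr_result <- function(method, estimate, se, pval, n_snp, extra = list()) {
  z <- qnorm(0.975)
  structure(
    list(method = method, estimate = estimate, se = se,
         ci_low = estimate - z * se, ci_high = estimate + z * se,
         pval = pval, n_snp = as.integer(n_snp), extra = extra),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: estimate %.4g (se %.3g), 95%% CI [%.4g, %.4g], p = %.3g, nSNP = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_snp = x$n_snp, stringsAsFactors = FALSE)
}

#' Combine mr_result objects into a table
#'
#' @param results list of `mr_result` objects.
#' @return data.frame, one row per result; Egger results contribute
#'   `egger_intercept*` columns.
#' @export
mr_results_table <- function(results) {
  if (inherits(results, "mr_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    df <- as.data.frame(r)
    df$egger_intercept <- r$extra$intercept %||% NA_real_
    df$egger_intercept_se <- r$extra$intercept_se %||% NA_real_
    df$egger_intercept_pval <- r$extra$intercept_pval %||% NA_real_
    df
  })
  do.call(rbind, rows)
}

#' Per-SNP ratio estimates
#'
#' @param h a `harmonized_set` (or its retained-pairs data.frame).
#' @return data.frame with `snp_id`, `b` (Wald ratio), `se_b`
#'   (first-order SE) and `w` (inverse-variance weight). Pairs with
#'   `beta_exp == 0` are excluded with a message: their ratio is
#'   undefined.
#' @export
ratio_estimates <- function(h) {
  p <- if (inherits(h, "harmonized_set")) retained_pairs(h) else h
  bad <- p$beta_exp == 0
  if (any(bad)) {
    message("ratio_estimates: dropping ", sum(bad),
            " pair(s) with zero exposure effect")
    p <- p[!bad, , drop = FALSE]
  }
  se_b <- p$se_out / abs(p$beta_exp)
  data.frame(snp_id = p$snp_id, b = p$beta_out / p$beta_exp,
             se_b = se_b, w = 1 / se_b^2, stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' estimate = beta_out / beta_exp with first-order (delta-method)
#' standard error se_out / |beta_exp|; two-sided normal p-value.
#'
#' @param pair one-row harmonized pair (data.frame or list with
#'   `beta_exp`, `beta_out`, `se_out`, optionally `snp_id`).
#' @return an `mr_result` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(pair) {
  pair <- as.list(pair)
  if (pair$beta_exp == 0) stop_param("wald ratio undefined: beta_exp = 0")
  est <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  new_mr_result("wald_ratio", est, se, 2 * pnorm(-abs(est / se)), 1,
                extra = list(snp_id = pair$snp_id %||% NA_character_))
}

ivw_core <- function(p) {
  # zero-intercept weighted regression of beta_out on beta_exp,
  # weights 1/se_out^2
  w <- 1 / p$se_out^2
  sxx <- sum(w * p$beta_exp^2)
  est <- sum(w * p$beta_exp * p$beta_out) / sxx
  list(estimate = est, se_fixed = 1 / sqrt(sxx))
}

#' Inverse-variance-weighted estimator
#'
#' The IVW estimate is the zero-intercept weighted regression of outcome
#' effects on exposure effects with weights 1/se_out^2 (equivalently the
#' inverse-variance-weighted mean of the Wald ratios). `mode = "fixed"`
#' uses the analytic SE; `mode = "random"` (default) inflates it
#' multiplicatively by `max(1, sqrt(Q/(J-1)))`, Cochran's Q being the
#' ratio-estimate heterogeneity statistic, so over-dispersion widens the
#' interval but under-dispersion never narrows it. A single retained
#' pair reduces to the Wald ratio.
#'
#' @param h a `harmonized_set`.
#' @param mode `"random"` or `"fixed"`.
#' @return an `mr_result` with method `"ivw_re"` or `"ivw_fe"`.
#' @export
mr_ivw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  p <- retained_pairs(h)
  if (nrow(p) == 0) stop_instruments("ivw: no retained instruments")
  if (nrow(p) == 1) {
    r <- mr_wald_ratio(p[1, ])
    r$method <- if (mode == "random") "ivw_re" else "ivw_fe"
    return(r)
  }
  core <- ivw_core(p)
  se <- core$se_fixed
  scale <- 1
  if (mode == "random") {
    q <- cochran_q(h)
    scale <- max(1, sqrt(q$q_stat / q$q_df))
    se <- se * scale
  }
  new_mr_result(if (mode == "random") "ivw_re" else "ivw_fe",
                core$estimate, se,
                2 * pnorm(-abs(core$estimate / se)), nrow(p),
                extra = list(re_scale = scale))
}

egger_core <- function(p) {
  # orient all exposure effects positive, then weighted LS with intercept
  sgn <- ifelse(p$beta_exp < 0, -1, 1)
  x <- p$beta_exp * sgn
  y <- p$beta_out * sgn
  w <- 1 / p$se_out^2
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  df <- length(x) - 2
  sigma2 <- if (df > 0) sum(w * resid^2) / df else 0
  scale <- max(1, sqrt(sigma2))
  se_slope <- sqrt(sw / det) * scale
  se_intercept <- sqrt(swxx / det) * scale
  list(slope = slope, intercept = intercept, se_slope = se_slope,
       se_intercept = se_intercept, df = df, sigma = sqrt(sigma2))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept, all pairs oriented so the exposure effect is positive.
#' The slope is the causal estimate; the intercept is the average
#' directional pleiotropic effect and feeds the pleiotropy test
#' ([egger_intercept_test()]). Standard errors carry a multiplicative
#' residual inflation `max(1, residual SE)`; p-values use a t
#' distribution on J-2 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 retained pairs.
#' @return an `mr_result` with method `"egger"`; `extra` holds
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h) {
  p <- retained_pairs(h)
  if (nrow(p) < 3) stop_instruments("egger: needs >= 3 instruments, have ",
                                    nrow(p))
  e <- egger_core(p)
  pval <- 2 * pt(-abs(e$slope / e$se_slope), df = e$df)
  ip <- 2 * pt(-abs(e$intercept / e$se_intercept), df = e$df)
  new_mr_result("egger", e$slope, e$se_slope, pval, nrow(p),
                extra = list(intercept = e$intercept,
                             intercept_se = e$se_intercept,
                             intercept_pval = ip))
}

weighted_median_core <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

median_boot_se <- function(p, weighted, n_boot, seed) {
  with_seed(seed, {
    J <- nrow(p)
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, p$beta_exp, p$se_exp)
      by <- stats::rnorm(J, p$beta_out, p$se_out)
      bad <- bx == 0
      bx <- bx[!bad]; by <- by[!bad]; seo <- p$se_out[!bad]
      b <- by / bx
      w <- if (weighted) (abs(bx) / seo)^2 else rep(1, length(b))
      weighted_median_core(b, w)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted (and simple) median estimator
#'
#' Orders the per-SNP Wald ratios and takes the weighted 50% quantile:
#' standardized cumulative weights p_j = (cumsum(w_j) - w_j/2) / sum(w_j)
#' are interpolated linearly at p = 0.5. Consistent when instruments
#' contributing at least half the weight are valid. The standard error
#' is a parametric bootstrap: exposure and outcome effects are resampled
#' from their reported normal sampling distributions and the estimator
#' is recomputed.
#'
#' @param h a `harmonized_set` with at least 3 retained pairs.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an `mr_result` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  p <- retained_pairs(h)
  if (nrow(p) < 3) stop_instruments("weighted_median: needs >= 3 instruments")
  r <- ratio_estimates(p)
  est <- weighted_median_core(r$b, r$w)
  se <- median_boot_se(p, weighted = TRUE, n_boot = n_boot, seed = seed)
  new_mr_result("weighted_median", est, se, 2 * pnorm(-abs(est / se)), nrow(p))
}

#' @rdname mr_weighted_median
#' @export
mr_simple_median <- function(h, n_boot = 1000, seed = 1L) {
  p <- retained_pairs(h)
  if (nrow(p) < 3) stop_instruments("simple_median: needs >= 3 instruments")
  r <- ratio_estimates(p)
  est <- weighted_median_core(r$b, rep(1, length(r$b)))
  se <- median_boot_se(p, weighted = FALSE, n_boot = n_boot, seed = seed)
  new_mr_result("simple_median", est, se, 2 * pnorm(-abs(est / se)), nrow(p))
}

silverman_bw <- function(b) {
  n <- length(b)
  s <- min(sd(b), stats::IQR(b) / 1.34)
  if (!is.finite(s) || s <= 0) s <- sd(b)
  if (!is.finite(s) || s <= 0) s <- abs(mean(b)) * 1e-3 + 1e-8
  0.9 * s * n^(-1 / 5)
}

mode_core <- function(b, w, bandwidth_factor) {
  if (length(unique(b)) == 1) return(b[1])
  h <- bandwidth_factor * silverman_bw(b)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  w <- w / sum(w)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, b, h)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimator
#'
#' Estimates the causal effect as the mode of the per-SNP Wald-ratio
#' distribution: a Gaussian kernel density (weights w_j when
#' `weighted = TRUE`) with bandwidth `bandwidth_factor` times the
#' Silverman rule-of-thumb, maximized on a 512-point grid spanning
#' `[min(b) - 3h, max(b) + 3h]`. Consistent when the largest group of
#' instruments sharing a ratio is valid (ZEMPA). Bootstrap SE as for the
#' median estimators.
#'
#' @param h a `harmonized_set` with at least 3 retained pairs.
#' @param weighted use inverse-variance weights in the density.
#' @param bandwidth_factor multiplier on the Silverman bandwidth
#'   (default 1).
#' @param n_boot,seed bootstrap controls.
#' @return an `mr_result` with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(h, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1L) {
  p <- retained_pairs(h)
  if (nrow(p) < 3) stop_instruments("mode estimator: needs >= 3 instruments")
  r <- ratio_estimates(p)
  w <- if (weighted) r$w else rep(1, nrow(r))
  est <- mode_core(r$b, w, bandwidth_factor)
  se <- with_seed(seed, {
    J <- nrow(p)
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, p$beta_exp, p$se_exp)
      by <- stats::rnorm(J, p$beta_out, p$se_out)
      bad <- bx == 0
      bx <- bx[!bad]; by <- by[!bad]; seo <- p$se_out[!bad]
      b <- by / bx
      wb <- if (weighted) (abs(bx) / seo)^2 else rep(1, length(b))
      mode_core(b, wb, bandwidth_factor)
    }, numeric(1))
    sd(ests)
  })
  new_mr_result(if (weighted) "weighted_mode" else "simple_mode",
                est, se, 2 * pnorm(-abs(est / se)), nrow(p))
}

#' @rdname mr_mode
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1L) {
  mr_mode(h, weighted = TRUE, bandwidth_factor = bandwidth_factor,
          n_boot = n_boot, seed = seed)
}

#' @rdname mr_mode
#' @export
mr_simple_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                           seed = 1L) {
  mr_mode(h, weighted = FALSE, bandwidth_factor = bandwidth_factor,
          n_boot = n_boot, seed = seed)
}

method_min_snps <- c(wald_ratio = 1, ivw_fe = 1, ivw_re = 1, egger = 3,
                     weighted_median = 3, simple_median = 3,
                     weighted_mode = 3, simple_mode = 3)

#' Run several MR methods on one harmonized set
#'
#' Dispatches each requested method; methods whose minimum instrument
#' count is unmet are skipped with a message (single-instrument sets
#' still yield IVW results via the Wald reduction). Method aliases:
#' `"ivw"` means the random-effects default.
#'
#' @param h a `harmonized_set`.
#' @param methods character vector from
#'   `c("wald_ratio","ivw","ivw_fe","ivw_re","egger","weighted_median",
#'   "simple_median","weighted_mode","simple_mode")`.
#' @param n_boot,seed bootstrap controls for median/mode methods.
#' @return list of `mr_result` (use [mr_results_table()] to tabulate).
#' @export
run_mr <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                   n_boot = 1000, seed = 1L) {
  if (length(methods) == 0) stop_param("run_mr: empty method list")
  methods[methods == "ivw"] <- "ivw_re"
  unknown <- setdiff(methods, MR_METHODS)
  if (length(unknown)) stop_param("unknown method(s): ",
                                  paste(unknown, collapse = ", "))
  J <- nrow(retained_pairs(h))
  out <- list()
  for (m in methods) {
    if (J < method_min_snps[[m]]) {
      message("run_mr: skipping ", m, " (needs >= ", method_min_snps[[m]],
              " instruments, have ", J, ")")
      next
    }
    out[[m]] <- switch(m,
      wald_ratio = mr_wald_ratio(retained_pairs(h)[1, ]),
      ivw_fe = mr_ivw(h, "fixed"),
      ivw_re = mr_ivw(h, "random"),
      egger = mr_egger(h),
      weighted_median = mr_weighted_median(h, n_boot, seed),
      simple_median = mr_simple_median(h, n_boot, seed),
      weighted_mode = mr_weighted_mode(h, n_boot = n_boot, seed = seed),
      simple_mode = mr_simple_mode(h, n_boot = n_boot, seed = seed)
    )
  }
  if (length(out) == 0) stop_instruments("run_mr: all methods skipped")
  out
}
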