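#' Phenome-wide MR scan
#'
#' Runs the full 2SMR pipeline over every exposure x outcome pair of a
#' grid, with family-wise Bonferroni control across the grid and a
#' Miami-plot data export (signed -log10 p per association, positive
#' effects up, negative effects down).
#'
#' @name phewas
NULL

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate in (0,1).
#' @param n_exposures,n_outcomes grid dimensions (>= 1).
#' @return `alpha / (n_exposures * n_outcomes)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_exposures, n_outcomes) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_param("alpha must lie in (0,1)")
  }
  if (n_exposures < 1 || n_outcomes < 1) {
    stop_param("grid dimensions must be >= 1")
  }
  alpha / (n_exposures * n_outcomes)
}

scan_pair <- function(exposure, outcome, ld, p_threshold, mhc_exclude,
                      r2_max, window_bp, proxy_r2_min, mode,
                      ambiguity_window, method, seed) {
  sel <- select_instruments(exposure, ld = ld, p_threshold = p_threshold,
                            mhc_exclude = mhc_exclude, r2_max = r2_max,
                            window_bp = window_bp, outcome = outcome,
                            proxy_r2_min = proxy_r2_min)
  if (length(sel$selection$kept) == 0) {
    return(list(skip = "no_instruments"))
  }
  out2 <- substitute_proxies(outcome, sel$exposure, sel$selection$proxies)
  h <- suppressWarnings(harmonize(sel$exposure, out2, mode = mode,
                                  ambiguity_window = ambiguity_window))
  if (nrow(retained_pairs(h)) == 0) {
    return(list(skip = "no_harmonized_pairs"))
  }
  res <- tryCatch(
    run_mr(h, method, seed = seed)[[1]],
    mrtriad_insufficient_instruments = function(e) NULL
  )
  if (is.null(res)) return(list(skip = "method_minimum_unmet"))
  list(result = res)
}

#' Phenome-wide scan over an exposure x outcome grid
#'
#' Per pair: instrument selection, proxy substitution, harmonization and
#' the headline MR method (IVW with multiplicative random effects by
#' default; a single instrument reduces to the Wald ratio). Pairs that
#' yield no usable instruments are recorded with a skip reason rather
#' than dropped, so result rows + skipped rows always equal the grid
#' size. Significance uses the strict Bonferroni cut
#' `pval < alpha / (n_exposures * n_outcomes)`.
#'
#' @param exposures,outcomes lists of [sumstats_set] objects.
#' @param ld optional `ld_provider` (clumping is skipped without one;
#'   simulated instruments are independent by construction).
#' @param alpha family-wise error rate (default 0.05).
#' @param method headline method (default `"ivw"`).
#' @param p_threshold,mhc_exclude,r2_max,window_bp,proxy_r2_min
#'   instrument-selection controls (see [select_instruments()]).
#' @param mode,ambiguity_window harmonization controls.
#' @param seed RNG seed for bootstrap-based methods.
#' @return object of class `scan_result`: list with `results`
#'   (data.frame: exposure_id, outcome_id, method, estimate, se, pval,
#'   n_snp, significant, skip_reason), `threshold`, `alpha_family`,
#'   `n_exposures`, `n_outcomes`.
#' @export
mr_scan <- function(exposures, outcomes, ld = NULL, alpha = 0.05,
                    method = "ivw", p_threshold = 5e-8, mhc_exclude = TRUE,
                    r2_max = 0.001, window_bp = 1e7, proxy_r2_min = 0.8,
                    mode = 2, ambiguity_window = 0.08, seed = 1L) {
  if (length(exposures) == 0 || length(outcomes) == 0) {
    stop_param("mr_scan: empty exposure or outcome grid")
  }
  threshold <- bonferroni_threshold(alpha, length(exposures), length(outcomes))
  rows <- list()
  k <- 0L
  for (ex in exposures) {
    for (ou in outcomes) {
      k <- k + 1L
      pr <- scan_pair(ex, ou, ld, p_threshold, mhc_exclude, r2_max,
                      window_bp, proxy_r2_min, mode, ambiguity_window,
                      method, seed)
      rows[[k]] <- if (is.null(pr$result)) {
        data.frame(exposure_id = ex$trait_id, outcome_id = ou$trait_id,
                   method = NA_character_, estimate = NA_real_,
                   se = NA_real_, pval = NA_real_, n_snp = NA_integer_,
                   significant = NA, skip_reason = pr$skip,
                   stringsAsFactors = FALSE)
      } else {
        r <- pr$result
        data.frame(exposure_id = ex$trait_id, outcome_id = ou$trait_id,
                   method = r$method, estimate = r$estimate, se = r$se,
                   pval = r$pval, n_snp = r$n_snp,
                   significant = r$pval < threshold,
                   skip_reason = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(results = do.call(rbind, rows), threshold = threshold,
         alpha_family = alpha, n_exposures = length(exposures),
         n_outcomes = length(outcomes)),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  r <- x$results
  cat("<scan_result> ", x$n_exposures, " x ", x$n_outcomes, " grid; ",
      sum(r$significant, na.rm = TRUE), " significant at p < ",
      signif(x$threshold, 3), "; ", sum(!is.na(r$skip_reason)),
      " pair(s) skipped\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.scan_result <- function(x, ...) x$results

#' Miami-plot data table
#'
#' One row per tested association: signed score
#' `sign(estimate) * (-log10 pval)` so positive effects plot upward and
#' negative effects downward, an outcome-category order index on the x
#' axis, and a super-pathway color key per exposure. Rows are sorted by
#' category, then outcome id, then exposure id; skipped pairs are
#' excluded.
#'
#' @param sr a `scan_result`.
#' @param outcome_categories named character vector mapping outcome_id
#'   to a biological-category label (free-form; unlabeled outcomes get
#'   `"unclassified"`).
#' @param exposure_pathways named character vector mapping exposure_id
#'   to a metabolite super-pathway label.
#' @return data.frame with `exposure_id`, `outcome_id`, `category`,
#'   `category_index`, `super_pathway`, `estimate`, `pval`,
#'   `signed_score`, `significant`.
#' @export
miami_table <- function(sr, outcome_categories = NULL,
                        exposure_pathways = NULL) {
  stopifnot(inherits(sr, "scan_result"))
  r <- sr$results[is.na(sr$results$skip_reason), , drop = FALSE]
  cat_of <- function(id) {
    v <- unname((outcome_categories %||% character())[id])
    ifelse(is.na(v) | !nzchar(v), "unclassified", v)
  }
  path_of <- function(id) {
    v <- unname((exposure_pathways %||% character())[id])
    ifelse(is.na(v) | !nzchar(v), "unclassified", v)
  }
  out <- data.frame(
    exposure_id = r$exposure_id, outcome_id = r$outcome_id,
    category = cat_of(r$outcome_id),
    super_pathway = path_of(r$exposure_id),
    estimate = r$estimate, pval = r$pval,
    signed_score = sign(r$estimate) * (-log10(r$pval)),
    significant = r$significant, stringsAsFactors = FALSE
  )
  out <- out[order(out$category, out$outcome_id, out$exposure_id), ,
             drop = FALSE]
  out$category_index <- match(out$category, unique(out$category))
  rownames(out) <- NULL
  out[, c("exposure_id", "outcome_id", "category", "category_index",
          "super_pathway", "estimate", "pval", "signed_score",
          "significant")]
}
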