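#' End-to-end 2SMR pipeline
#'
#' Orchestrates select -> harmonize -> estimate -> sensitivity from a
#' single declarative configuration, writing all tables, the four
#' diagnostic figures, the harmonization audit and the resolved
#' configuration to an output directory so a run can be reproduced
#' bit-identically from its own artifacts.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' Collects every pipeline parameter in one document. A seed is
#' mandatory: all stochastic steps (bootstrap SEs) derive from it.
#'
#' @param exposure,outcome file paths or [sumstats_set] objects.
#' @param ld optional LD reference: path to a pair table or an
#'   `ld_provider`.
#' @param methods MR methods for [run_mr()].
#' @param p_threshold,mhc_exclude,r2_max,window_bp,proxy_r2_min
#'   instrument selection (see [select_instruments()]).
#' @param harmonize_mode,ambiguity_window harmonization (see
#'   [harmonize()]).
#' @param steiger,steiger_alpha apply Steiger directionality filtering
#'   before estimation.
#' @param n_boot bootstrap resamples.
#' @param seed integer RNG seed (required).
#' @param fig_format,fig_dpi,fig_width,fig_height figure controls.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(exposure, outcome, ld = NULL,
                       methods = c("ivw", "egger", "weighted_median",
                                   "weighted_mode"),
                       p_threshold = 5e-8, mhc_exclude = TRUE,
                       r2_max = 0.001, window_bp = 1e7, proxy_r2_min = 0.8,
                       harmonize_mode = 2, ambiguity_window = 0.08,
                       steiger = FALSE, steiger_alpha = 0.05,
                       n_boot = 1000, seed = NULL,
                       fig_format = "png", fig_dpi = 300, fig_width = 7,
                       fig_height = 6, out_dir = tempfile("mr_run_")) {
  if (is.null(seed)) stop_config("run_config: a seed is required")
  structure(as.list(environment()), class = "run_config")
}

resolved_config <- function(cfg) {
  out <- cfg
  for (f in c("exposure", "outcome", "ld")) {
    if (!is.character(out[[f]]) && !is.null(out[[f]])) {
      out[[f]] <- paste0("<in-memory ", class(out[[f]])[1], ">")
    }
  }
  unclass(out)
}

load_side <- function(x, role) {
  if (inherits(x, "sumstats_set")) x else read_sumstats(x, role = role)
}

#' Run the full pipeline
#'
#' Stages: instrument selection (significance filter, optional MHC
#' exclusion, LD clumping, proxy substitution), harmonization, optional
#' Steiger filtering, MR estimation with all requested methods,
#' sensitivity analyses, figure rendering. Errors are re-signalled with
#' the failing stage prefixed.
#'
#' @param cfg a [run_config()].
#' @return object of class `mr_bundle`: list with `mr` (results table),
#'   `mr_objects`, `sensitivity`, `harmonized`, `selection`, `config`,
#'   `files` (paths of everything written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  exposure <- stage("load", load_side(cfg$exposure, "exposure"))
  outcome <- stage("load", load_side(cfg$outcome, "outcome"))
  ld <- stage("load", {
    if (is.character(cfg$ld)) ld_from_table(cfg$ld) else cfg$ld
  })

  sel <- stage("select", select_instruments(
    exposure, ld = ld, p_threshold = cfg$p_threshold,
    mhc_exclude = cfg$mhc_exclude, r2_max = cfg$r2_max,
    window_bp = cfg$window_bp, outcome = outcome,
    proxy_r2_min = cfg$proxy_r2_min))
  outcome2 <- stage("select",
    substitute_proxies(outcome, sel$exposure, sel$selection$proxies))
  h <- stage("harmonize", harmonize(sel$exposure, outcome2,
                                    mode = cfg$harmonize_mode,
                                    ambiguity_window = cfg$ambiguity_window))
  if (isTRUE(cfg$steiger)) {
    h <- stage("steiger", steiger_filter(h, alpha = cfg$steiger_alpha)$harmonized)
  }
  mr <- stage("estimate", run_mr(h, cfg$methods, n_boot = cfg$n_boot,
                                 seed = cfg$seed))
  sens <- stage("sensitivity", sensitivity_report(h))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    mr_results = file.path(cfg$out_dir, "mr_results.tsv"),
    sensitivity = file.path(cfg$out_dir, "sensitivity.tsv"),
    harmonization_audit = file.path(cfg$out_dir, "harmonization_audit.tsv"),
    selection = file.path(cfg$out_dir, "instrument_selection.tsv"),
    config = file.path(cfg$out_dir, "resolved_config.json")
  )
  mr_tab <- mr_results_table(mr)
  stage("report", {
    write_results(mr_tab, files["mr_results"])
    write_results(as.data.frame(sens), files["sensitivity"])
    write_results(harmonization_audit(h), files["harmonization_audit"])
    sel_tab <- rbind(
      data.frame(snp_id = sel$selection$kept, reason = "kept"),
      sel$selection$removed
    )
    write_results(sel_tab, files["selection"])
    jsonlite::write_json(resolved_config(cfg), files["config"],
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  })
  figs <- stage("figures", render_diagnostics(
    mr, sens, h, cfg$out_dir, format = cfg$fig_format, dpi = cfg$fig_dpi,
    width = cfg$fig_width, height = cfg$fig_height))

  structure(
    list(mr = mr_tab, mr_objects = mr, sensitivity = sens, harmonized = h,
         selection = sel$selection, config = cfg,
         files = c(files, figs)),
    class = "mr_bundle"
  )
}

#' @export
print.mr_bundle <- function(x, ...) {
  cat("<mr_bundle> ", x$harmonized$exposure_id, " -> ",
      x$harmonized$outcome_id, "\n", sep = "")
  print(x$mr[, c("method", "estimate", "se", "pval", "n_snp")])
  invisible(x)
}
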