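#' Diagnostic plots
#'
#' Four standard MR diagnostics: forest (per-SNP Wald ratios with CIs
#' plus method summaries), scatter (outcome vs exposure effects with one
#' fitted line per method; the Egger line keeps its intercept), funnel
#' (instrument precision 1/se_b against the ratio estimate, with method
#' verticals) and leave-one-out. Every figure's underlying numbers are
#' also written as a plot-data TSV: figures are views, tables are truth.
#'
#' @name diagnostics
NULL

open_device <- function(path, format, dpi, width, height) {
  switch(format,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = dpi),
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop_param("unsupported figure format: ", format)
  )
}

forest_data <- function(mr, sens) {
  ss <- sens$single_snp
  if (is.null(ss)) return(NULL)
  ss[ss$type == "snp", , drop = FALSE]
}

plot_forest <- function(mr, sens, path, format, dpi, width, height) {
  snp <- forest_data(mr, sens)
  meth <- mr_results_table(mr)
  dat <- rbind(
    data.frame(label = snp$snp_id, estimate = snp$estimate,
               ci_low = snp$ci_low, ci_high = snp$ci_high, kind = "snp"),
    data.frame(label = meth$method, estimate = meth$estimate,
               ci_low = meth$ci_low, ci_high = meth$ci_high, kind = "method")
  )
  open_device(path, format, dpi, width, height)
  on.exit(grDevices::dev.off())
  n <- nrow(dat)
  y <- rev(seq_len(n))
  graphics::par(mar = c(4, 10, 2, 1))
  graphics::plot(dat$estimate, y, xlim = range(c(dat$ci_low, dat$ci_high)),
                 pch = ifelse(dat$kind == "snp", 15, 18),
                 col = ifelse(dat$kind == "snp", "black", "red"),
                 yaxt = "n", ylab = "", xlab = "causal estimate (95% CI)",
                 main = "Forest plot")
  graphics::segments(dat$ci_low, y, dat$ci_high, y,
                     col = ifelse(dat$kind == "snp", "black", "red"))
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = y, labels = dat$label, las = 1, cex.axis = 0.7)
  dat
}

plot_scatter <- function(mr, h, path, format, dpi, width, height) {
  p <- retained_pairs(h)
  meth <- mr_results_table(mr)
  open_device(path, format, dpi, width, height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(p$beta_exp, p$beta_out, pch = 16,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", main = "Scatter plot")
  graphics::arrows(p$beta_exp, p$beta_out - 1.96 * p$se_out, p$beta_exp,
                   p$beta_out + 1.96 * p$se_out, angle = 90, code = 3,
                   length = 0.02, col = "grey60")
  cols <- grDevices::hcl.colors(max(nrow(meth), 2), "Dark 3")
  for (i in seq_len(nrow(meth))) {
    icpt <- if (!is.na(meth$egger_intercept[i])) meth$egger_intercept[i] else 0
    graphics::abline(a = icpt, b = meth$estimate[i], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = meth$method, col = cols[seq_len(nrow(meth))],
                   lwd = 2, cex = 0.7, bty = "n")
  cbind(p[, c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")],
        row.names = NULL)
}

plot_funnel <- function(mr, h, path, format, dpi, width, height) {
  r <- ratio_estimates(h)
  meth <- mr_results_table(mr)
  open_device(path, format, dpi, width, height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(r$b, 1 / r$se_b, pch = 16, xlab = "Wald ratio",
                 ylab = "precision (1/SE)", main = "Funnel plot")
  cols <- grDevices::hcl.colors(max(nrow(meth), 2), "Dark 3")
  graphics::abline(v = meth$estimate, col = cols[seq_len(nrow(meth))], lwd = 2)
  data.frame(snp_id = r$snp_id, b = r$b, precision = 1 / r$se_b)
}

plot_loo <- function(sens, path, format, dpi, width, height) {
  loo <- sens$loo
  if (is.null(loo)) return(NULL)
  open_device(path, format, dpi, width, height)
  on.exit(grDevices::dev.off())
  n <- nrow(loo)
  y <- rev(seq_len(n))
  graphics::par(mar = c(4, 10, 2, 1))
  graphics::plot(loo$estimate, y, xlim = range(c(loo$ci_low, loo$ci_high)),
                 pch = 15, yaxt = "n", ylab = "",
                 xlab = "IVW estimate excluding SNP (95% CI)",
                 main = "Leave-one-out")
  graphics::segments(loo$ci_low, y, loo$ci_high, y)
  graphics::abline(v = loo$estimate[loo$excluded == "none"], lty = 3,
                   col = "red")
  graphics::axis(2, at = y, labels = loo$excluded, las = 1, cex.axis = 0.7)
  loo
}

#' Render the four diagnostic figures
#'
#' Writes forest, scatter, funnel and leave-one-out figures plus a
#' `<name>_data.tsv` beside each. Empty inputs produce a warning and no
#' files.
#'
#' @param mr list of `mr_result` (from [run_mr()]).
#' @param sens a `sensitivity_report`.
#' @param h the `harmonized_set` the results came from.
#' @param out_dir output directory.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param dpi raster resolution (png only).
#' @param width,height figure size in inches.
#' @return invisible character vector of figure paths.
#' @export
render_diagnostics <- function(mr, sens, h, out_dir, format = "png",
                               dpi = 300, width = 7, height = 6) {
  if (length(mr) == 0 || nrow(retained_pairs(h)) == 0) {
    warning("render_diagnostics: empty inputs, nothing rendered")
    return(invisible(character()))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  figs <- c(forest = "forest", scatter = "scatter", funnel = "funnel",
            leave_one_out = "leave_one_out")
  paths <- file.path(out_dir, paste0(figs, ".", format))
  names(paths) <- names(figs)
  dat <- list(
    forest = plot_forest(mr, sens, paths["forest"], format, dpi, width, height),
    scatter = plot_scatter(mr, h, paths["scatter"], format, dpi, width, height),
    funnel = plot_funnel(mr, h, paths["funnel"], format, dpi, width, height),
    leave_one_out = plot_loo(sens, paths["leave_one_out"], format, dpi,
                             width, height)
  )
  for (nm in names(dat)) {
    if (!is.null(dat[[nm]])) {
      write_results(dat[[nm]], file.path(out_dir, paste0(figs[[nm]], "_data.tsv")))
    }
  }
  invisible(paths)
}
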