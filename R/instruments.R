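#' Instrument selection
#'
#' Instrumental variables for two-sample MR are chosen in three steps:
#' keep genome-wide-significant SNPs, drop the MHC region whose extended
#' LD defeats clumping, then greedily prune correlated SNPs so the kept
#' set is pairwise independent at the clumping r-squared threshold. SNPs
#' missing from the outcome GWAS may be replaced by an LD proxy.
#'
#' @name instruments
NULL

new_instrument_selection <- function(kept, removed, proxies = NULL) {
  removed <- removed %||% data.frame(snp_id = character(), reason = character())
  proxies <- proxies %||% data.frame(snp_id = character(),
                                     proxy_snp_id = character(),
                                     r2 = numeric())
  structure(list(kept = kept, removed = removed, proxies = proxies),
            class = "instrument_selection")
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat("<instrument_selection> kept ", length(x$kept), ", removed ",
      nrow(x$removed), ", proxies ", nrow(x$proxies), "\n", sep = "")
  invisible(x)
}

#' Keep SNPs below a p-value threshold
#'
#' @param s a [sumstats_set].
#' @param p_threshold significance threshold; SNPs with `pval < p_threshold`
#'   are kept (strict). Default 5e-8, the conventional genome-wide level.
#' @return filtered [sumstats_set], input order preserved.
#' @export
filter_significant <- function(s, p_threshold = 5e-8) {
  stopifnot(inherits(s, "sumstats_set"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop_param("p_threshold must lie in (0,1]")
  }
  replace_records(s, s$records[s$records$pval < p_threshold, , drop = FALSE])
}

#' Exclude a genomic interval (default: the MHC)
#'
#' Removes records whose position falls inside the closed interval
#' `[start_bp, end_bp]` on `chrom`. Coordinates are 1-based inclusive;
#' the default interval is the major histocompatibility complex,
#' chr6:26,000,000-34,000,000.
#'
#' @param s a [sumstats_set].
#' @param chrom chromosome label.
#' @param start_bp,end_bp interval bounds in base pairs, closed.
#' @return filtered [sumstats_set].
#' @export
exclude_mhc <- function(s, chrom = "6", start_bp = 26e6, end_bp = 34e6) {
  stopifnot(inherits(s, "sumstats_set"))
  if (start_bp >= end_bp) stop_param("start_bp must be < end_bp")
  r <- s$records
  inside <- r$chrom == as.character(chrom) & r$pos >= start_bp & r$pos <= end_bp
  replace_records(s, r[!inside, , drop = FALSE])
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending p-value (ties broken lexicographically by
#' snp_id), repeatedly keeps the top remaining SNP and removes all other
#' SNPs on the same chromosome within `window_bp` whose r-squared with it
#' is at or above `r2_max`. The kept set is pairwise independent:
#' all within-window pairs have r2 < `r2_max`. Pairs absent from the LD
#' reference count as r2 = 0.
#'
#' @param s a [sumstats_set].
#' @param ld an `ld_provider`.
#' @param r2_max clumping threshold in (0,1]; default 0.001.
#' @param window_bp clumping window in base pairs (default 10 Mb); SNPs
#'   farther apart are never clumped regardless of stored r2.
#' @return an `instrument_selection`; removed entries carry reason
#'   `"clumped_by:<snp_id>"`.
#' @export
clump <- function(s, ld, r2_max = 0.001, window_bp = 1e7) {
  stopifnot(inherits(s, "sumstats_set"), inherits(ld, "ld_provider"))
  if (!is.numeric(r2_max) || r2_max <= 0 || r2_max > 1) {
    stop_param("r2_max must lie in (0,1]")
  }
  r <- s$records
  unknown <- setdiff(r$snp_id, ld$ids)
  if (length(unknown)) {
    message("clump: ", length(unknown),
            " SNP(s) absent from LD reference treated as independent")
  }
  ord <- order(r$pval, r$snp_id)
  r <- r[ord, , drop = FALSE]
  kept <- character()
  removed_id <- character()
  removed_reason <- character()
  active <- rep(TRUE, nrow(r))
  for (i in seq_len(nrow(r))) {
    if (!active[i]) next
    top <- r$snp_id[i]
    kept <- c(kept, top)
    active[i] <- FALSE
    j <- which(active & r$chrom == r$chrom[i] &
                 abs(r$pos - r$pos[i]) <= window_bp)
    if (length(j)) {
      r2 <- ld_r2(ld, top, r$snp_id[j])
      hit <- j[r2 >= r2_max]
      if (length(hit)) {
        removed_id <- c(removed_id, r$snp_id[hit])
        removed_reason <- c(removed_reason, rep(paste0("clumped_by:", top),
                                                length(hit)))
        active[hit] <- FALSE
      }
    }
  }
  new_instrument_selection(
    kept = kept,
    removed = data.frame(snp_id = removed_id, reason = removed_reason)
  )
}

#' Find an LD proxy for a SNP missing from the outcome GWAS
#'
#' Among the SNP's LD neighbors at `r2 >= r2_min` that are present in
#' the outcome set, returns the highest-r2 candidate (ties broken by
#' lexicographic snp_id). Candidates whose allele orientation relative
#' to the query SNP is not resolved by the LD reference (`aligned` flag
#' missing or `FALSE`) are rejected: a proxy whose effect alleles cannot
#' be phased against the original would silently flip signs.
#'
#' @param snp query snp_id (absent from `outcome`).
#' @param outcome the outcome [sumstats_set].
#' @param ld an `ld_provider`.
#' @param r2_min minimum proxy r2 (default 0.8).
#' @return `list(snp_id=, r2=)` or `NULL` if no usable proxy exists.
#' @export
find_proxy <- function(snp, outcome, ld, r2_min = 0.8) {
  stopifnot(inherits(outcome, "sumstats_set"), inherits(ld, "ld_provider"))
  nb <- ld_neighbors(ld, snp, r2_min)
  nb <- nb[nb$snp_id %in% outcome$records$snp_id & !is.na(nb$aligned) &
             nb$aligned, , drop = FALSE]
  if (nrow(nb) == 0) return(NULL)
  nb <- nb[order(-nb$r2, nb$snp_id), , drop = FALSE]
  list(snp_id = nb$snp_id[1], r2 = nb$r2[1])
}

#' Full instrument-selection pipeline
#'
#' Applies, in order: the significance filter, optional MHC exclusion,
#' greedy LD clumping and (when an outcome set is supplied) proxy
#' substitution for kept SNPs missing from the outcome. All removals are
#' recorded with a reason so that
#' `kept + removed == input` (conservation).
#'
#' @param s exposure [sumstats_set].
#' @param ld an `ld_provider`, or `NULL` to skip clumping.
#' @param p_threshold significance threshold (see [filter_significant()]).
#' @param mhc_exclude drop chr6:26-34 Mb (default `TRUE`).
#' @param r2_max,window_bp clumping parameters (see [clump()]).
#' @param outcome optional outcome [sumstats_set] for proxy lookup.
#' @param proxy_r2_min minimum proxy r2 (see [find_proxy()]).
#' @return `list(exposure = filtered sumstats_set, selection =
#'   instrument_selection)`. Kept SNPs replaced by a proxy remain listed
#'   under their original id in `selection$proxies`.
#' @export
select_instruments <- function(s, ld = NULL, p_threshold = 5e-8,
                               mhc_exclude = TRUE, r2_max = 0.001,
                               window_bp = 1e7, outcome = NULL,
                               proxy_r2_min = 0.8) {
  stopifnot(inherits(s, "sumstats_set"))
  rm_df <- function(ids, reason) data.frame(
    snp_id = ids, reason = rep_len(reason, length(ids)),
    stringsAsFactors = FALSE)
  all_ids <- s$records$snp_id
  cur <- filter_significant(s, p_threshold)
  removed <- rm_df(setdiff(all_ids, cur$records$snp_id), "above_p_threshold")
  if (mhc_exclude) {
    nxt <- exclude_mhc(cur)
    gone <- setdiff(cur$records$snp_id, nxt$records$snp_id)
    removed <- rbind(removed, rm_df(gone, "mhc_region"))
    cur <- nxt
  }
  if (!is.null(ld)) {
    cl <- clump(cur, ld, r2_max = r2_max, window_bp = window_bp)
    removed <- rbind(removed, cl$removed)
    cur <- replace_records(cur,
      cur$records[cur$records$snp_id %in% cl$kept, , drop = FALSE])
  }
  proxies <- data.frame(snp_id = character(), proxy_snp_id = character(),
                        r2 = numeric())
  if (!is.null(outcome)) {
    missing_ids <- setdiff(cur$records$snp_id, outcome$records$snp_id)
    for (id in missing_ids) {
      px <- if (is.null(ld)) NULL else find_proxy(id, outcome, ld, proxy_r2_min)
      if (is.null(px)) {
        removed <- rbind(removed, data.frame(
          snp_id = id, reason = "missing_in_outcome_no_proxy"))
        cur <- replace_records(cur,
          cur$records[cur$records$snp_id != id, , drop = FALSE])
      } else {
        proxies <- rbind(proxies, data.frame(
          snp_id = id, proxy_snp_id = px$snp_id, r2 = px$r2))
      }
    }
  }
  list(exposure = cur,
       selection = new_instrument_selection(cur$records$snp_id, removed,
                                            proxies))
}

#' Substitute proxy outcome records under the original instrument ids
#'
#' For each (original, proxy) pair, grafts the proxy's outcome summary
#' statistics onto the original snp_id so downstream harmonization can
#' match it against the exposure record. The proxy's alleles are replaced
#' by the exposure record's alleles; this is valid only because
#' [find_proxy()] accepts candidates with a resolved same-orientation
#' phase flag.
#'
#' @param outcome outcome [sumstats_set].
#' @param exposure exposure [sumstats_set] (allele source).
#' @param proxies data.frame from `instrument_selection$proxies`.
#' @return outcome [sumstats_set] with grafted records appended.
#' @export
substitute_proxies <- function(outcome, exposure, proxies) {
  stopifnot(inherits(outcome, "sumstats_set"), inherits(exposure, "sumstats_set"))
  if (is.null(proxies) || nrow(proxies) == 0) return(outcome)
  out_rec <- outcome$records
  exp_rec <- exposure$records
  for (i in seq_len(nrow(proxies))) {
    orig <- proxies$snp_id[i]
    prox <- proxies$proxy_snp_id[i]
    src <- out_rec[out_rec$snp_id == prox, , drop = FALSE]
    al <- exp_rec[exp_rec$snp_id == orig, , drop = FALSE]
    if (nrow(src) != 1 || nrow(al) != 1) next
    src$snp_id <- orig
    src$effect_allele <- al$effect_allele
    src$other_allele <- al$other_allele
    out_rec <- rbind(out_rec, src)
  }
  replace_records(outcome, out_rec)
}
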