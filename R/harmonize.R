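#' Allele harmonization
#'
#' Two-sample MR combines per-SNP effects estimated in different GWAS,
#' which may report them against different alleles or strands. Before
#' estimation, each outcome effect must be re-expressed against the
#' exposure's effect allele. Three strategies handle palindromic SNPs
#' (A/T and C/G variants, whose alleles are their own strand
#' complements): mode 1 assumes all alleles are reported on the forward
#' strand and aligns labels directly; mode 2 infers strand from
#' effect-allele frequencies, dropping SNPs whose frequency is too close
#' to 0.5 to be informative; mode 3 drops all palindromic SNPs.
#' Non-palindromic SNPs are aligned by label, with strand complementing
#' applied when the outcome alleles match only after complementation.
#'
#' @name harmonization
NULL

HARMONIZE_ACTIONS <- c("aligned", "sign_flipped", "strand_flipped",
                       "strand_flipped_and_sign_flipped",
                       "dropped_palindromic", "dropped_ambiguous_freq",
                       "dropped_incompatible")

#' Harmonize one exposure/outcome record pair
#'
#' @param exp,out single-row association records (data.frame or list
#'   with fields `snp_id`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `n`) for the same SNP.
#' @param mode palindromic-SNP strategy: 1 (forward-strand assumption),
#'   2 (frequency inference; default) or 3 (drop palindromic).
#' @param ambiguity_window half-width `w` of the frequency dead zone for
#'   mode 2: palindromic SNPs with either EAF in `[0.5-w, 0.5+w]` are
#'   dropped as ambiguous. Default 0.08.
#' @return one-row data.frame with columns `snp_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `n_exp`,
#'   `n_out`, `action`. When `action` is a `dropped_*` value the outcome
#'   fields are passed through unmodified and the pair must not be used
#'   for estimation. Otherwise `beta_out` (and `eaf_out`) refer to the
#'   exposure's effect allele; a sign flip negates `beta_out` and
#'   reflects `eaf_out` to `1 - eaf_out`, leaving `se_out` untouched.
#' @export
harmonize_pair <- function(exp, out, mode = 2, ambiguity_window = 0.08) {
  exp <- as.list(exp); out <- as.list(out)
  if (!identical(as.character(exp$snp_id), as.character(out$snp_id))) {
    stop_param("harmonize_pair: snp_id mismatch (",
               exp$snp_id, " vs ", out$snp_id, ")")
  }
  if (!mode %in% 1:3) stop_param("mode must be 1, 2 or 3")
  ea <- exp$effect_allele; oa <- exp$other_allele
  eb <- out$effect_allele; ob <- out$other_allele

  flip <- FALSE
  action <- NULL
  if (!all(is_snv_allele(c(ea, oa, eb, ob)))) {
    action <- "dropped_incompatible"
  } else if (is_palindromic(ea, oa)) {
    if (!setequal(c(eb, ob), c(ea, oa))) {
      action <- "dropped_incompatible"
    } else if (mode == 3) {
      action <- "dropped_palindromic"
    } else if (mode == 1) {
      # labels taken at face value, same-strand
      if (eb == ea) { action <- "aligned" } else { action <- "sign_flipped"; flip <- TRUE }
    } else {
      # mode 2: strand inferred from which side of 0.5 each frequency sits
      w <- ambiguity_window
      fe <- exp$eaf; fo <- out$eaf
      if (is.na(fe) || is.na(fo) ||
          (fe >= 0.5 - w && fe <= 0.5 + w) ||
          (fo >= 0.5 - w && fo <= 0.5 + w)) {
        action <- "dropped_ambiguous_freq"
      } else if ((fe < 0.5) == (fo < 0.5)) {
        action <- "aligned"
      } else {
        action <- "sign_flipped"; flip <- TRUE
      }
    }
  } else if (eb == ea && ob == oa) {
    action <- "aligned"
  } else if (eb == oa && ob == ea) {
    action <- "sign_flipped"; flip <- TRUE
  } else {
    ebc <- complement_allele(eb); obc <- complement_allele(ob)
    if (ebc == ea && obc == oa) {
      action <- "strand_flipped"
    } else if (ebc == oa && obc == ea) {
      action <- "strand_flipped_and_sign_flipped"; flip <- TRUE
    } else {
      action <- "dropped_incompatible"
    }
  }

  beta_out <- out$beta
  eaf_out <- out$eaf
  if (flip) {
    beta_out <- -beta_out
    eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
  }
  data.frame(
    snp_id = as.character(exp$snp_id),
    beta_exp = exp$beta, se_exp = exp$se,
    beta_out = beta_out, se_out = out$se,
    eaf_exp = exp$eaf %||% NA_real_, eaf_out = eaf_out %||% NA_real_,
    n_exp = as.numeric(exp$n %||% NA_real_),
    n_out = as.numeric(out$n %||% NA_real_),
    action = action,
    stringsAsFactors = FALSE
  )
}

#' Harmonize an exposure set against an outcome set
#'
#' Intersects the two sets on snp_id (apply [substitute_proxies()] first
#' if proxies are in play) and applies [harmonize_pair()] per SNP.
#'
#' @param exposure,outcome [sumstats_set] objects.
#' @inheritParams harmonize_pair
#' @return a `harmonized_set`: list with `pairs` (all pairs, including
#'   dropped ones, with action flags), `mode`, `ambiguity_window`,
#'   `exposure_id`, `outcome_id`, and per-set sample sizes when uniform.
#'   `retained_pairs(h)` extracts the pairs usable for estimation.
#' @export
harmonize <- function(exposure, outcome, mode = 2, ambiguity_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats_set"), inherits(outcome, "sumstats_set"))
  shared <- intersect(exposure$records$snp_id, outcome$records$snp_id)
  if (length(shared) == 0) {
    warning("harmonize: no shared SNPs between exposure and outcome")
  }
  er <- exposure$records[match(shared, exposure$records$snp_id), , drop = FALSE]
  or <- outcome$records[match(shared, outcome$records$snp_id), , drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_along(shared), function(i) {
    harmonize_pair(er[i, ], or[i, ], mode = mode,
                   ambiguity_window = ambiguity_window)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(snp_id = character(), beta_exp = numeric(),
                        se_exp = numeric(), beta_out = numeric(),
                        se_out = numeric(), eaf_exp = numeric(),
                        eaf_out = numeric(), n_exp = numeric(),
                        n_out = numeric(), action = character())
  }
  structure(
    list(pairs = pairs, mode = mode, ambiguity_window = ambiguity_window,
         exposure_id = exposure$trait_id, outcome_id = outcome$trait_id),
    class = "harmonized_set"
  )
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where the
#' pairs are already aligned.
#'
#' @param beta_exp,se_exp,beta_out,se_out numeric vectors.
#' @param snp_id SNP ids (default `snp1..snpJ`).
#' @param eaf_exp,eaf_out optional frequencies.
#' @param n_exp,n_out optional sample sizes (scalar or vector).
#' @param exposure_id,outcome_id trait labels.
#' @return a `harmonized_set` with all pairs `aligned`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = NULL, eaf_exp = NA_real_,
                           eaf_out = NA_real_, n_exp = NA_real_,
                           n_out = NA_real_, exposure_id = "exposure",
                           outcome_id = "outcome") {
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J)
  if (any(se_exp <= 0) || any(se_out <= 0)) stop_param("SEs must be positive")
  snp_id <- snp_id %||% sprintf("snp%d", seq_len(J))
  pairs <- data.frame(
    snp_id = snp_id, beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf_exp = rep_len(eaf_exp, J), eaf_out = rep_len(eaf_out, J),
    n_exp = rep_len(as.numeric(n_exp), J),
    n_out = rep_len(as.numeric(n_out), J),
    action = "aligned", stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs, mode = NA_integer_, ambiguity_window = NA_real_,
         exposure_id = exposure_id, outcome_id = outcome_id),
    class = "harmonized_set"
  )
}

#' Pairs retained for estimation
#'
#' @param h a `harmonized_set`.
#' @return data.frame of pairs whose action is not a `dropped_*` flag.
#' @export
retained_pairs <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h$pairs[!startsWith(h$pairs$action, "dropped"), , drop = FALSE]
}

# Subset a harmonized_set to the given retained-pair row indices.
subset_harmonized <- function(h, keep_ids) {
  h$pairs <- h$pairs[startsWith(h$pairs$action, "dropped") |
                       h$pairs$snp_id %in% keep_ids, , drop = FALSE]
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set> ", x$exposure_id, " -> ", x$outcome_id, ": ",
      nrow(retained_pairs(x)), "/", nrow(x$pairs), " pairs retained\n", sep = "")
  tab <- table(x$pairs$action)
  for (a in names(tab)) cat("  ", a, ": ", tab[[a]], "\n", sep = "")
  invisible(x)
}

#' Harmonization audit table
#'
#' @param h a `harmonized_set`.
#' @return data.frame `(snp_id, action)` suitable for [write_results()].
#' @export
harmonization_audit <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h$pairs[, c("snp_id", "action")]
}
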