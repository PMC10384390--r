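#' Synthetic summary-statistics generator
#'
#' Generates paired exposure/outcome GWAS summary statistics under a
#' linear instrumental-variable model, directly on the summary-statistic
#' scale (no individual-level genotypes): per SNP j, the SNP-exposure
#' effect gamma_j and pleiotropic effect alpha_j are drawn, sampling
#' error is added with SEs determined by allele frequency and sample
#' size, and the SNP-outcome effect is theta * gamma_j + alpha_j plus
#' noise. Exposure and outcome samples are non-overlapping by
#' construction, matching the two-sample design assumption.
#'
#' @name synthgen
NULL

#' Simulation configuration
#'
#' Defaults describe a realistic desk-scale metabolite GWAS: 50
#' instruments, 50,000 samples per side, per-allele SNP-exposure effects
#' of about 0.08 SD (strongly significant at n = 50,000, as mQTLs
#' typically are), allele frequencies uniform on (0.1, 0.9), no
#' pleiotropy and no causal effect unless requested.
#'
#' @param J number of SNPs (>= 1).
#' @param n_exp,n_out GWAS sample sizes (>= 10).
#' @param theta true causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd SNP-exposure effect distribution
#'   (normal); effect alleles are conventionally oriented to increase
#'   the exposure, hence a positive mean.
#' @param gamma_values optional fixed gamma vector overriding the
#'   distribution (length J).
#' @param eaf_lo,eaf_hi allele-frequency bounds, within (0,1).
#' @param mu_alpha,sd_alpha pleiotropy distribution: alpha_j ~
#'   N(mu_alpha, sd_alpha^2). `mu_alpha != 0` is directional pleiotropy.
#' @param correlated_pleiotropy if `TRUE`, alpha_j gains a component
#'   proportional to gamma_j (violates InSIDE).
#' @param reverse_causation if `TRUE`, the generative roles swap: SNPs
#'   act directly on the outcome and the exposure inherits `theta` times
#'   the outcome effect (for testing directionality filters).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(J = 50, n_exp = 50000, n_out = 50000, theta = 0,
                       gamma_mean = 0.08, gamma_sd = 0.02,
                       gamma_values = NULL, eaf_lo = 0.1, eaf_hi = 0.9,
                       mu_alpha = 0, sd_alpha = 0,
                       correlated_pleiotropy = FALSE,
                       reverse_causation = FALSE, seed = 1L) {
  if (J < 1) stop_param("J must be >= 1")
  if (n_exp < 10 || n_out < 10) stop_param("sample sizes must be >= 10")
  if (!(eaf_lo > 0 && eaf_hi < 1 && eaf_lo < eaf_hi)) {
    stop_param("eaf bounds must satisfy 0 < lo < hi < 1")
  }
  if (!is.null(gamma_values) && length(gamma_values) != J) {
    stop_param("gamma_values must have length J")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate paired exposure/outcome summary statistics
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure` and `outcome` ([sumstats_set]s sharing
#'   snp_ids, alleles and positions) and `truth` (theta, per-SNP gamma,
#'   alpha, eaf). Standard errors follow the standardized-trait GWAS
#'   formula se = (2 EAF (1-EAF) n)^(-1/2); p-values are two-sided
#'   normal.
#' @export
simulate_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    J <- cfg$J
    snp_id <- sprintf("rs%06d", seq_len(J))
    # spread SNPs across chromosomes 1-22, far apart (independent by design)
    chrom <- as.character(rep_len(1:22, J))
    pos <- 1e6 + 2e6 * (seq_len(J) - 1) %/% 22
    alleles <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                      ncol = 2, byrow = TRUE)
    al <- alleles[rep_len(1:4, J), , drop = FALSE]
    eaf <- stats::runif(J, cfg$eaf_lo, cfg$eaf_hi)
    gamma <- cfg$gamma_values %||% stats::rnorm(J, cfg$gamma_mean, cfg$gamma_sd)
    alpha <- stats::rnorm(J, cfg$mu_alpha, cfg$sd_alpha)
    if (cfg$correlated_pleiotropy) alpha <- alpha + 0.3 * (gamma - mean(gamma))
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_exp)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_out)
    if (!cfg$reverse_causation) {
      mu_exp <- gamma
      mu_out <- cfg$theta * gamma + alpha
    } else {
      # SNPs act on the outcome; the exposure is downstream
      mu_out <- gamma
      mu_exp <- cfg$theta * gamma + alpha
    }
    beta_exp <- stats::rnorm(J, mu_exp, se_exp)
    beta_out <- stats::rnorm(J, mu_out, se_out)
    mk <- function(beta, se, n, id, role) {
      sumstats_set(data.frame(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = al[, 1], other_allele = al[, 2],
        eaf = eaf, beta = beta, se = se,
        # clamp: strong instruments underflow 2*pnorm to 0, which the
        # (0,1] p-value invariant rejects
        pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n
      ), trait_id = id, role = role)
    }
    list(
      exposure = mk(beta_exp, se_exp, cfg$n_exp, "sim_exposure", "exposure"),
      outcome = mk(beta_out, se_out, cfg$n_out, "sim_outcome", "outcome"),
      truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                   eaf = eaf, snp_id = snp_id)
    )
  })
}

#' Simulate a block-diagonal LD reference
#'
#' SNPs within a block share a common r-squared; cross-block pairs are
#' independent. Blocks are laid out contiguously on chromosome 1 at
#' 10 kb spacing so they fall within any realistic clumping window.
#'
#' @param blocks list of `c(size, within_r2)` pairs (or a 2-column
#'   matrix); `within_r2` in \[0,1\].
#' @param seed RNG seed (reserved; the layout is deterministic).
#' @param snp_prefix id prefix (default `"ld"`).
#' @return list with `ld` (an `ld_provider`) and `placement`
#'   (data.frame `snp_id`, `chrom`, `pos`, `block`).
#' @export
simulate_ld <- function(blocks, seed = 1L, snp_prefix = "ld") {
  if (is.matrix(blocks)) blocks <- asplit(blocks, 1)
  sizes <- vapply(blocks, function(b) as.integer(b[1]), integer(1))
  r2s <- vapply(blocks, function(b) as.numeric(b[2]), numeric(1))
  if (any(r2s < 0 | r2s > 1)) stop_param("within_r2 must lie in [0,1]")
  ids <- character(); pos <- integer(); block <- integer()
  pairs <- list()
  cursor <- 1e6
  for (k in seq_along(sizes)) {
    bid <- sprintf("%s_b%02d_s%02d", snp_prefix, k, seq_len(sizes[k]))
    bpos <- cursor + 1e4 * (seq_len(sizes[k]) - 1)
    cursor <- max(bpos) + 1e6
    ids <- c(ids, bid); pos <- c(pos, as.integer(bpos))
    block <- c(block, rep(k, sizes[k]))
    if (sizes[k] > 1 && r2s[k] > 0) {
      cmb <- utils::combn(bid, 2)
      pairs[[k]] <- data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                               r2 = r2s[k], aligned = TRUE)
    }
  }
  ptab <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snp_a = character(), snp_b = character(), r2 = numeric(),
               aligned = logical())
  list(
    ld = new_ld_provider(ptab, ids = ids),
    placement = data.frame(snp_id = ids, chrom = "1", pos = pos,
                           block = block, stringsAsFactors = FALSE)
  )
}

#' Generate a planted-overlap semantic-triple fixture
#'
#' Builds exposure- and outcome-side triple tables with exactly
#' `n_overlap` shared terms (each appearing as an exposure object and an
#' outcome subject) plus `n_noise` non-overlapping triples per side.
#' Planted overlap k receives enrichment counts making its Fisher
#' p-value strictly increase with k, so the construction-time ordering
#' is known.
#'
#' @param n_overlap,n_noise counts (>= 0).
#' @param seed RNG seed.
#' @param exposure_term,outcome_term anchor terms.
#' @return list with `exposure`, `outcome` (triple data.frames with
#'   columns `subject`, `predicate`, `object`, `local_count`,
#'   `local_total`, `global_count`, `global_total`) and
#'   `planted_terms` in enrichment order (strongest first).
#' @export
make_triple_fixture <- function(n_overlap, n_noise, seed = 1L,
                                exposure_term = "exposure_x",
                                outcome_term = "outcome_y") {
  if (n_overlap < 0 || n_noise < 0) stop_param("counts must be >= 0")
  with_seed(seed, {
    terms <- if (n_overlap) sprintf("shared_term_%02d", seq_len(n_overlap)) else character()
    preds <- c("INTERACTS_WITH", "PREDISPOSES", "AFFECTS", "CAUSES",
               "ASSOCIATED_WITH")
    # decreasing local counts -> increasing Fisher p down the list
    lc <- if (n_overlap) pmax(2, 40 - 6 * (seq_len(n_overlap) - 1)) else integer()
    mk <- function(subj, obj, local_count) {
      n <- max(length(subj), length(obj), length(local_count), 0)
      data.frame(
        subject = rep_len(subj, n),
        predicate = sample(preds, n, replace = TRUE),
        object = rep_len(obj, n),
        local_count = rep_len(local_count, n),
        local_total = rep_len(100L, n),
        global_count = rep_len(50L, n),
        global_total = rep_len(100000L, n), stringsAsFactors = FALSE
      )
    }
    empty <- mk(character(), character(), integer())
    exposure <- if (n_overlap) mk(exposure_term, terms, lc) else empty
    outcome <- if (n_overlap) mk(terms, outcome_term, lc) else empty
    if (n_noise > 0) {
      noise_e <- sprintf("noise_obj_e%02d", seq_len(n_noise))
      noise_o <- sprintf("noise_subj_o%02d", seq_len(n_noise))
      exposure <- rbind(exposure, mk(exposure_term, noise_e,
                                     sample(1:5, n_noise, TRUE)))
      outcome <- rbind(outcome, mk(noise_o, outcome_term,
                                   sample(1:5, n_noise, TRUE)))
    }
    list(exposure = exposure, outcome = outcome, planted_terms = terms)
  })
}
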