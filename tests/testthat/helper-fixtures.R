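# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths: lm() for weighted regressions, phyper() for Fisher
# tails, a standalone greedy recursion for clumping.

make_records <- function(n, seed = 1, chrom = "1", pos = NULL) {
  set.seed(seed)
  eaf <- runif(n, 0.1, 0.9)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.005, 0.02)
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = pos %||% (1e6 + (seq_len(n) - 1) * 1e4),
    effect_allele = rep_len(c("A", "C", "G", "T"), n),
    other_allele = rep_len(c("G", "T", "A", "C"), n),
    eaf = eaf, beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = 10000,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonized set from plain vectors (aligned), for estimator tests.
hset <- function(bx, sx, by, sy, ...) {
  harmonized_set(bx, sx, by, sy, ...)
}

# Simulate and align directly (simulated pairs share alleles by design).
sim_hset <- function(cfg) {
  sim <- simulate_sumstats(cfg)
  pe <- sim$exposure$records
  po <- sim$outcome$records
  list(h = harmonized_set(pe$beta, pe$se, po$beta, po$se,
                          snp_id = pe$snp_id, eaf_exp = pe$eaf,
                          eaf_out = po$eaf, n_exp = pe$n, n_out = po$n),
       truth = sim$truth, sim = sim)
}

# --- independent oracles ------------------------------------------------

# Zero-intercept weighted LS via lm(); oracle for IVW.
oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  est <- unname(coef(fit)[1])
  # fixed-effect SE: unscaled (sigma set to 1)
  se <- unname(sqrt(diag(vcov(fit)))[1]) / summary(fit)$sigma
  list(estimate = est, se_fixed = se)
}

# Weighted regression with intercept via lm(), beta_x oriented positive;
# oracle for MR-Egger.
oracle_egger <- function(bx, by, sy) {
  s <- sign(bx); s[s == 0] <- 1
  x <- bx * s; y <- by * s
  fit <- lm(y ~ x, weights = 1 / sy^2)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       se_slope = unname(sm$coefficients[2, 2]) / sm$sigma * scale,
       se_intercept = unname(sm$coefficients[1, 2]) / sm$sigma * scale)
}

# Hand-rolled weighted-median interpolation (loop form).
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(b[1])
  for (i in seq_along(b)[-1]) {
    if (p[i] >= 0.5) {
      return(b[i - 1] + (0.5 - p[i - 1]) / (p[i] - p[i - 1]) * (b[i] - b[i - 1]))
    }
  }
  b[length(b)]
}

# Standalone greedy clumping recursion over a dense r2 matrix.
oracle_clump <- function(rec, r2mat, r2_max, window_bp) {
  kept <- character()
  rec <- rec[order(rec$pval, rec$snp_id), , drop = FALSE]
  while (nrow(rec) > 0) {
    top <- rec[1, ]
    kept <- c(kept, top$snp_id)
    drop <- rec$chrom == top$chrom &
      abs(rec$pos - top$pos) <= window_bp &
      r2mat[top$snp_id, rec$snp_id] >= r2_max
    drop[1] <- TRUE
    rec <- rec[!drop, , drop = FALSE]
  }
  kept
}

random_clump_instance <- function(seed, n = 6) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  diag(m) <- 1
  ids <- sprintf("rs%03d", sample(100, n))
  dimnames(m) <- list(ids, ids)
  rec <- make_records(n, seed = seed + 1000)
  rec$snp_id <- ids
  list(records = rec, r2 = m)
}

# Exposure x outcome grids of independent null (or planted-effect) GWAS
# pairs: each exposure has its own J instruments; outcomes carry records
# for every exposure's SNPs. theta_map[exposure, outcome] plants effects.
make_grid <- function(seed, n_exposures = 5, n_outcomes = 5, J = 10,
                      n = 50000, theta_map = NULL) {
  set.seed(seed)
  if (is.null(theta_map)) theta_map <- matrix(0, n_exposures, n_outcomes)
  exposures <- list(); meta <- list()
  for (i in seq_len(n_exposures)) {
    ids <- sprintf("e%d_rs%03d", i, seq_len(J))
    eaf <- runif(J, 0.1, 0.9)
    se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
    gamma <- rnorm(J, 0.08, 0.02)
    beta <- rnorm(J, gamma, se)
    exposures[[i]] <- sumstats_set(data.frame(
      snp_id = ids, chrom = as.character(rep_len(1:22, J)),
      pos = 1e6 + seq_len(J), effect_allele = "A", other_allele = "G",
      eaf = eaf, beta = beta, se = se,
      pval = 2 * pnorm(-abs(beta / se)), n = n),
      trait_id = paste0("exp", i), role = "exposure")
    meta[[i]] <- data.frame(snp_id = ids, eaf = eaf, gamma = gamma,
                            exposure = i)
  }
  snps <- do.call(rbind, meta)
  outcomes <- lapply(seq_len(n_outcomes), function(j) {
    se <- 1 / sqrt(2 * snps$eaf * (1 - snps$eaf) * n)
    mu <- theta_map[cbind(snps$exposure, j)] * snps$gamma
    beta <- rnorm(nrow(snps), mu, se)
    sumstats_set(data.frame(
      snp_id = snps$snp_id, chrom = "1", pos = 1e6 + seq_len(nrow(snps)),
      effect_allele = "A", other_allele = "G", eaf = snps$eaf, beta = beta,
      se = se, pval = 2 * pnorm(-abs(beta / se)), n = n),
      trait_id = paste0("out", j), role = "outcome")
  })
  list(exposures = exposures, outcomes = outcomes)
}
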