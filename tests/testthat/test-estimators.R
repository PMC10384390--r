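test_that("wald ratio: arithmetic, null case, zero-exposure error", {
  r <- mr_wald_ratio(list(beta_exp = 0.5, beta_out = 0.25, se_out = 0.05))
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(mr_wald_ratio(list(beta_exp = 1, beta_out = 0,
                                  se_out = 0.1))$estimate, 0)
  expect_error(mr_wald_ratio(list(beta_exp = 0, beta_out = 1, se_out = 0.1)),
               class = "mrtriad_param_error")
})

test_that("wald delta-method SE agrees with a Monte-Carlo oracle", {
  set.seed(99)
  bx <- rnorm(1e6, 0.2, 0.01)
  by <- rnorm(1e6, 0.1, 0.02)
  mc_sd <- sd(by / bx)
  r <- mr_wald_ratio(list(beta_exp = 0.2, beta_out = 0.1, se_out = 0.02))
  expect_lt(abs(r$se - mc_sd) / mc_sd, 0.10)
})

test_that("IVW: consensus, Wald reduction, closed-form example, lm oracle", {
  # exact consensus: all ratios 0.5 -> fixed == random == 0.5
  h <- hset(c(0.1, 0.2, 0.4), c(0.01, 0.01, 0.01),
            c(0.05, 0.10, 0.20), c(0.01, 0.01, 0.01))
  expect_equal(mr_ivw(h, "fixed")$estimate, 0.5)
  expect_equal(mr_ivw(h, "random")$estimate, 0.5)
  expect_equal(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se)
  # single SNP reduces to the Wald ratio exactly
  h1 <- hset(0.3, 0.01, 0.12, 0.02)
  r1 <- mr_ivw(h1)
  w1 <- mr_wald_ratio(list(beta_exp = 0.3, beta_out = 0.12, se_out = 0.02))
  expect_identical(r1$estimate, w1$estimate)
  expect_identical(r1$se, w1$se)
  # spec'd closed form
  h2 <- hset(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01),
             c(0.05, 0.08, 0.18), c(0.01, 0.01, 0.01))
  expect_equal(mr_ivw(h2, "fixed")$estimate, 0.075 / 0.14, tolerance = 1e-12)
  # weighted-least-squares oracle, heterogeneous SEs
  set.seed(11)
  bx <- rnorm(10, 0.1, 0.03); sy <- runif(10, 0.005, 0.03)
  by <- 0.4 * bx + rnorm(10, 0, sy)
  h3 <- hset(bx, rep(0.01, 10), by, sy)
  o <- oracle_ivw(bx, by, sy)
  expect_equal(mr_ivw(h3, "fixed")$estimate, o$estimate, tolerance = 1e-10)
  expect_equal(mr_ivw(h3, "fixed")$se, o$se_fixed, tolerance = 1e-10)
})

test_that("Egger: exact fits and the weighted-regression oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h_exact <- hset(bx, rep(0.01, 4), 0.3 * bx, rep(0.01, 4))
  r <- mr_egger(h_exact)
  expect_equal(r$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r$extra$intercept, 0, tolerance = 1e-10)
  h_affine <- hset(bx, rep(0.01, 4), 0.1 + 0.3 * bx, rep(0.01, 4))
  r2 <- mr_egger(h_affine)
  expect_equal(r2$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r2$extra$intercept, 0.1, tolerance = 1e-10)
  # saturated J = 3 affine fit is exact
  h_sat <- hset(bx[1:3], rep(0.01, 3), 0.05 + 0.7 * bx[1:3], rep(0.02, 3))
  expect_equal(mr_egger(h_sat)$extra$intercept, 0.05, tolerance = 1e-10)
  # random fixture vs lm() oracle (including sign orientation)
  set.seed(21)
  bx10 <- rnorm(10, 0, 0.1)
  sy10 <- runif(10, 0.005, 0.03)
  by10 <- 0.02 + 0.3 * bx10 + rnorm(10, 0, sy10)
  h10 <- hset(bx10, rep(0.01, 10), by10, sy10)
  o <- oracle_egger(bx10, by10, sy10)
  r10 <- mr_egger(h10)
  expect_equal(r10$estimate, o$slope, tolerance = 1e-10)
  expect_equal(r10$extra$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(r10$se, o$se_slope, tolerance = 1e-10)
  expect_equal(r10$extra$intercept_se, o$se_intercept, tolerance = 1e-10)
  expect_error(mr_egger(hset(1:2 / 10, c(0.01, 0.01), 1:2 / 20,
                             c(0.01, 0.01))),
               class = "mrtriad_insufficient_instruments")
})

test_that("weighted median: middle element, interpolation, oracle equality", {
  # equal weights, odd count -> middle element
  h <- hset(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.5, 0.9), rep(0.01, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$estimate, 0.5)
  # hand evaluation: ratios (0, 1), weights (0.9, 0.1) -> 0.1
  b <- c(0, 1); w <- c(0.9, 0.1)
  expect_equal(oracle_weighted_median(b, w), 0.1)
  # implementation matches the loop-form oracle on random instances
  for (seed in 1:20) {
    set.seed(seed)
    J <- sample(3:12, 1)
    bx <- rnorm(J, 0.2, 0.05); sy <- runif(J, 0.005, 0.03)
    by <- rnorm(J, 0.06, 0.02)
    h <- hset(bx, rep(0.01, J), by, sy)
    r <- ratio_estimates(h)
    expect_equal(mr_weighted_median(h, n_boot = 2, seed = 1)$estimate,
                 oracle_weighted_median(r$b, r$w), tolerance = 1e-10)
  }
})

test_that("median/mode bootstrap SEs are deterministic given the seed", {
  hs <- sim_hset(sim_config(J = 10, theta = 0.2, seed = 5))$h
  a <- mr_weighted_median(hs, n_boot = 200, seed = 42)
  b <- mr_weighted_median(hs, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c1 <- mr_weighted_mode(hs, n_boot = 100, seed = 7)
  c2 <- mr_weighted_mode(hs, n_boot = 100, seed = 7)
  expect_identical(c1$se, c2$se)
})

test_that("mode estimator: dominant cluster, degenerate, fine-grid oracle", {
  h <- hset(rep(1, 4), rep(0.01, 4), c(0.2, 0.2, 0.2, 0.8), rep(0.01, 4))
  expect_equal(mr_mode(h, n_boot = 20, seed = 1)$estimate, 0.2,
               tolerance = 0.02)
  h_same <- hset(rep(1, 3), rep(0.01, 3), rep(0.37, 3), rep(0.01, 3))
  expect_equal(mr_mode(h_same, n_boot = 10, seed = 1)$estimate, 0.37)
  # bimodal fixture: argmax within one grid step of a dense brute-force scan
  set.seed(31)
  b <- c(rnorm(8, 0.1, 0.01), rnorm(4, 0.9, 0.01))
  h_bi <- hset(rep(1, 12), rep(0.01, 12), b, rep(0.01, 12))
  r <- ratio_estimates(h_bi)
  bw <- 1 * 0.9 * min(sd(r$b), IQR(r$b) / 1.34) * length(r$b)^(-0.2)
  grid <- seq(min(r$b) - 3 * bw, max(r$b) + 3 * bw, length.out = 50001)
  wn <- r$w / sum(r$w)
  dens <- vapply(grid, function(g) sum(wn * dnorm(g, r$b, bw)), numeric(1))
  brute <- grid[which.max(dens)]
  est <- mr_mode(h_bi, n_boot = 2, seed = 1)$estimate
  step <- diff(range(grid)) / 511
  expect_lt(abs(est - brute), step)
})

test_that("run_mr dispatches, skips below-minimum methods, errors when empty", {
  h1 <- hset(0.3, 0.01, 0.12, 0.02)
  expect_message(res <- run_mr(h1, c("ivw", "egger")), "skipping egger")
  expect_named(res, "ivw_re")
  expect_equal(res$ivw_re$n_snp, 1L)
  expect_error(run_mr(h1, character()), class = "mrtriad_param_error")
  expect_error(run_mr(h1, "not_a_method"), class = "mrtriad_param_error")
  expect_error(suppressMessages(run_mr(h1, "egger")),
               class = "mrtriad_insufficient_instruments")
})

test_that("estimates are sign- and scale-equivariant", {
  hs <- sim_hset(sim_config(J = 12, theta = 0.25, seed = 9))$h
  methods <- c("ivw", "egger", "weighted_median", "weighted_mode")
  base <- mr_results_table(run_mr(hs, methods, n_boot = 100, seed = 2))
  flip_out <- hs; flip_out$pairs$beta_out <- -hs$pairs$beta_out
  neg <- mr_results_table(run_mr(flip_out, methods, n_boot = 100, seed = 2))
  expect_equal(neg$estimate, -base$estimate, tolerance = 1e-8)
  flip_exp <- hs; flip_exp$pairs$beta_exp <- -hs$pairs$beta_exp
  neg2 <- mr_results_table(run_mr(flip_exp, methods, n_boot = 100, seed = 2))
  expect_equal(neg2$estimate, -base$estimate, tolerance = 1e-8)
  sc <- hs
  sc$pairs$beta_out <- 3 * hs$pairs$beta_out
  sc$pairs$se_out <- 3 * hs$pairs$se_out
  scaled <- mr_results_table(run_mr(sc, methods, n_boot = 100, seed = 2))
  expect_equal(scaled$estimate, 3 * base$estimate, tolerance = 1e-8)
  expect_equal(scaled$se, 3 * base$se, tolerance = 1e-8)
})

test_that("fixed-effect SE never exceeds random-effect SE", {
  for (seed in 1:10) {
    hs <- sim_hset(sim_config(J = 15, theta = 0.1, mu_alpha = 0,
                              sd_alpha = 0.02, seed = seed))$h
    expect_lte(mr_ivw(hs, "fixed")$se, mr_ivw(hs, "random")$se)
  }
})

test_that("homogeneous, pleiotropy-free instruments: methods agree", {
  hs <- sim_hset(sim_config(J = 30, theta = 0.2, seed = 13))$h
  res <- run_mr(hs, c("ivw", "egger", "weighted_median", "weighted_mode"),
                n_boot = 200, seed = 3)
  tab <- mr_results_table(res)
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      comb_se <- sqrt(tab$se[i]^2 + tab$se[j]^2)
      expect_lt(abs(tab$estimate[i] - tab$estimate[j]), 3 * comb_se)
    }
  }
})

test_that("weighted median resists a minority of invalid instruments", {
  # 40% of instruments carry gross directional pleiotropy: the median
  # should land nearer the truth than IVW
  err_med <- err_ivw <- numeric(30)
  for (i in 1:30) {
    set.seed(700 + i)
    J <- 15
    gamma <- rnorm(J, 0.1, 0.01)
    alpha <- c(rep(0.08, 6), rep(0, 9))
    se <- rep(0.005, J)
    bx <- rnorm(J, gamma, se)
    by <- rnorm(J, 0.2 * gamma + alpha, se)
    h <- hset(bx, se, by, se)
    err_med[i] <- abs(mr_weighted_median(h, n_boot = 2, seed = 1)$estimate - 0.2)
    err_ivw[i] <- abs(mr_ivw(h)$estimate - 0.2)
  }
  expect_lt(mean(err_med), mean(err_ivw))
})
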