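rec1 <- function(snp = "rs1", ea, oa, beta = 0.1, se = 0.01, eaf = NA,
                 n = 10000) {
  list(snp_id = snp, chrom = "1", pos = 100L, effect_allele = ea,
       other_allele = oa, eaf = eaf, beta = beta, se = se,
       pval = 2 * pnorm(-abs(beta / se)), n = n)
}

test_that("allele/strand/palindrome truth table matches the hand-derived oracle", {
  exp_ag <- rec1(ea = "A", oa = "G", beta = 0.1, eaf = 0.3)
  # hand-derived: outcome alleles, mode -> (action, sign of beta_out)
  cases <- list(
    list(out = c("A", "G"), mode = 1, action = "aligned", sgn = +1),
    list(out = c("G", "A"), mode = 1, action = "sign_flipped", sgn = -1),
    list(out = c("T", "C"), mode = 1, action = "strand_flipped", sgn = +1),
    list(out = c("C", "T"), mode = 1,
         action = "strand_flipped_and_sign_flipped", sgn = -1),
    list(out = c("A", "C"), mode = 1, action = "dropped_incompatible"),
    # identical outcomes under modes 2 and 3: non-palindromic SNPs are
    # mode-independent
    list(out = c("G", "A"), mode = 2, action = "sign_flipped", sgn = -1),
    list(out = c("T", "C"), mode = 3, action = "strand_flipped", sgn = +1)
  )
  for (cs in cases) {
    out <- rec1(ea = cs$out[1], oa = cs$out[2], beta = 0.2, eaf = 0.3)
    hp <- harmonize_pair(exp_ag, out, mode = cs$mode)
    expect_equal(hp$action, cs$action, info = paste(cs$out, collapse = "/"))
    if (!startsWith(cs$action, "dropped")) {
      expect_equal(hp$beta_out, cs$sgn * 0.2)
      expect_equal(hp$se_out, out$se)  # sign flips never touch the SE
    }
  }
})

test_that("palindromic SNPs: the three modes behave as specified", {
  pal <- function(eaf_exp, eaf_out, mode, w = 0.08) {
    harmonize_pair(rec1(ea = "A", oa = "T", beta = 0.1, eaf = eaf_exp),
                   rec1(ea = "A", oa = "T", beta = 0.3, eaf = eaf_out),
                   mode = mode, ambiguity_window = w)
  }
  # mode 3 always drops palindromic SNPs
  expect_equal(pal(0.1, 0.1, 3)$action, "dropped_palindromic")
  # mode 1 takes labels at face value
  expect_equal(pal(0.1, 0.9, 1)$action, "aligned")
  m1 <- harmonize_pair(rec1(ea = "A", oa = "T", eaf = 0.1),
                       rec1(ea = "T", oa = "A", beta = 0.3, eaf = 0.9),
                       mode = 1)
  expect_equal(m1$action, "sign_flipped")
  expect_equal(m1$beta_out, -0.3)
  # mode 2, 2x2 frequency-side enumeration
  expect_equal(pal(0.10, 0.12, 2)$action, "aligned")       # low/low
  expect_equal(pal(0.88, 0.90, 2)$action, "aligned")       # high/high
  expect_equal(pal(0.10, 0.88, 2)$action, "sign_flipped")  # low/high
  expect_equal(pal(0.88, 0.10, 2)$action, "sign_flipped")  # high/low
  hp <- pal(0.10, 0.88, 2)
  expect_equal(hp$beta_out, -0.3)
  expect_equal(hp$eaf_out, 1 - 0.88)
  # ambiguity dead zone [0.42, 0.58] inclusive, either side, and missing EAF
  expect_equal(pal(0.42, 0.1, 2)$action, "dropped_ambiguous_freq")
  expect_equal(pal(0.1, 0.58, 2)$action, "dropped_ambiguous_freq")
  expect_equal(pal(0.1, NA, 2)$action, "dropped_ambiguous_freq")
  expect_equal(pal(NA, 0.1, 2)$action, "dropped_ambiguous_freq")
  # just outside the window is decidable
  expect_equal(pal(0.41, 0.1, 2)$action, "aligned")
})

test_that("mismatched ids and irreconcilable alleles are handled", {
  expect_error(harmonize_pair(rec1(ea = "A", oa = "G"),
                              rec1(snp = "rs2", ea = "A", oa = "G")),
               class = "mrtriad_param_error")
  hp <- harmonize_pair(rec1(ea = "A", oa = "G"),
                       rec1(ea = "AT", oa = "G"))
  expect_equal(hp$action, "dropped_incompatible")
  # palindromic exposure against non-matching outcome alleles
  hp2 <- harmonize_pair(rec1(ea = "A", oa = "T"), rec1(ea = "A", oa = "G"))
  expect_equal(hp2$action, "dropped_incompatible")
})

test_that("harmonizing an already-aligned pair is the identity (involution)", {
  e <- rec1(ea = "A", oa = "G", beta = 0.17, eaf = 0.3)
  o <- rec1(ea = "G", oa = "A", beta = 0.4, eaf = 0.65)
  hp <- harmonize_pair(e, o, mode = 2)
  o2 <- o
  o2$effect_allele <- "A"; o2$other_allele <- "G"
  o2$beta <- hp$beta_out; o2$eaf <- hp$eaf_out
  hp2 <- harmonize_pair(e, o2, mode = 2)
  expect_equal(hp2$action, "aligned")
  expect_equal(hp2$beta_out, hp$beta_out)
  expect_equal(hp2$eaf_out, hp$eaf_out)
})

mixed_fixture <- function() {
  mk <- function(ids, ea, oa, eaf, beta = 0.1) data.frame(
    snp_id = ids, chrom = "1", pos = seq_along(ids) * 1000L,
    effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
    se = 0.01, pval = 1e-10, n = 10000, stringsAsFactors = FALSE)
  exposure <- sumstats_set(mk(
    c("rs1", "rs2", "rs3", "rs4", "rs5"),
    c("A", "A", "A", "A", "C"),
    c("G", "G", "C", "T", "G"),
    c(0.3, 0.3, 0.2, 0.1, 0.5)), "exp", role = "exposure")
  outcome <- sumstats_set(mk(
    c("rs1", "rs2", "rs3", "rs4", "rs5"),
    c("A", "G", "T", "A", "C"),
    c("G", "A", "G", "T", "G"),
    c(0.31, 0.72, 0.21, 0.88, 0.5), beta = 0.2), "out", role = "outcome")
  list(exposure = exposure, outcome = outcome)
}

test_that("set-level harmonization: action multiset matches the manual oracle", {
  fx <- mixed_fixture()
  h <- harmonize(fx$exposure, fx$outcome, mode = 2)
  # manual case-by-case: rs1 aligned; rs2 label-swapped; rs3 strand flip;
  # rs4 palindromic A/T with 0.1 vs 0.88 -> sign flip; rs5 palindromic C/G
  # with eaf 0.5 -> ambiguous
  want <- c(rs1 = "aligned", rs2 = "sign_flipped", rs3 = "strand_flipped",
            rs4 = "sign_flipped", rs5 = "dropped_ambiguous_freq")
  expect_equal(setNames(h$pairs$action, h$pairs$snp_id), want)
  expect_equal(nrow(retained_pairs(h)), 4)
  # audit table mirrors the pairs
  expect_equal(harmonization_audit(h)$action, unname(want))
})

test_that("mode-3 and mode-2 retained sets are subsets of mode 1", {
  fx <- mixed_fixture()
  kept <- function(mode) retained_pairs(
    harmonize(fx$exposure, fx$outcome, mode = mode))$snp_id
  expect_true(all(kept(3) %in% kept(1)))
  expect_true(all(kept(2) %in% kept(1)))
})

test_that("single shared palindromic SNP under mode 3 leaves nothing", {
  mk1 <- function(role) sumstats_set(data.frame(
    snp_id = "rs9", chrom = "1", pos = 1L, effect_allele = "C",
    other_allele = "G", eaf = 0.2, beta = 0.1, se = 0.01, pval = 1e-9,
    n = 1000), "t", role = role)
  h <- harmonize(mk1("exposure"), mk1("outcome"), mode = 3)
  expect_equal(nrow(retained_pairs(h)), 0)
  # estimators refuse an empty set
  expect_error(mr_ivw(h), class = "mrtriad_insufficient_instruments")
})

test_that("empty intersection warns and yields an empty set", {
  rec <- make_records(2)
  e <- sumstats_set(rec, "e", role = "exposure")
  rec2 <- make_records(2)
  rec2$snp_id <- c("zz1", "zz2")
  o <- sumstats_set(rec2, "o", role = "outcome")
  expect_warning(h <- harmonize(e, o), "no shared SNPs")
  expect_equal(nrow(h$pairs), 0)
})
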