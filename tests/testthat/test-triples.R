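glycine_fixture <- function() {
  exposure <- data.frame(
    subject = "Glycine", predicate = "INTERACTS_WITH",
    object = "homocysteine", local_count = 12, local_total = 100,
    global_count = 40, global_total = 100000, stringsAsFactors = FALSE)
  outcome <- data.frame(
    subject = "homocysteine", predicate = "PREDISPOSES",
    object = "Coronary Arteriosclerosis", local_count = 80,
    local_total = 100, global_count = 60, global_total = 100000,
    stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome)
}

test_that("exposure-object / outcome-subject overlap builds the 2-edge path", {
  fx <- glycine_fixture()
  net <- overlap_triples(fx$exposure, fx$outcome)
  expect_equal(net$overlap, "homocysteine")
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$side, c("exposure", "outcome"))
  # the path glycine -> homocysteine -> coronary arteriosclerosis
  e_exp <- net$edges[net$edges$side == "exposure", ]
  e_out <- net$edges[net$edges$side == "outcome", ]
  expect_equal(e_exp$source, "glycine")
  expect_equal(e_exp$target, "homocysteine")
  expect_equal(e_out$source, "homocysteine")
  expect_equal(e_out$target, "coronary arteriosclerosis")
  expect_setequal(net$nodes$role,
                  c("exposure_subject", "overlap", "outcome_object"))
})

test_that("disjoint term sets give an empty overlap and empty network", {
  e <- data.frame(subject = "a", predicate = "AFFECTS", object = "b",
                  local_count = NA, local_total = NA, global_count = NA,
                  global_total = NA)
  o <- data.frame(subject = "c", predicate = "AFFECTS", object = "d",
                  local_count = NA, local_total = NA, global_count = NA,
                  global_total = NA)
  net <- overlap_triples(e, o)
  expect_length(net$overlap, 0)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(rank_overlaps(net)), 0)
})

test_that("planted overlaps are recovered exactly (vs set-intersection oracle)", {
  fx <- make_triple_fixture(n_overlap = 3, n_noise = 17, seed = 5)
  net <- overlap_triples(fx$exposure, fx$outcome)
  oracle <- sort(intersect(tolower(fx$exposure$object),
                           tolower(fx$outcome$subject)))
  expect_equal(net$overlap, oracle)
  expect_length(net$overlap, 3)
  # adding a triple sharing no terms with the overlap set leaves the
  # network unchanged
  extra <- data.frame(subject = "unrelated_s", predicate = "AFFECTS",
                      object = "unrelated_o", local_count = 1,
                      local_total = 10, global_count = 1,
                      global_total = 1000)
  net2 <- overlap_triples(rbind(fx$exposure, extra), fx$outcome)
  expect_equal(net2$overlap, net$overlap)
  expect_equal(net2$edges, net$edges)
})

test_that("overlap size is bounded by both distinct-term counts", {
  for (seed in c(2, 9, 14)) {
    fx <- make_triple_fixture(n_overlap = seed %% 4, n_noise = 6, seed = seed)
    net <- overlap_triples(fx$exposure, fx$outcome)
    expect_lte(length(net$overlap),
               min(length(unique(tolower(fx$exposure$object))),
                   length(unique(tolower(fx$outcome$subject)))))
  }
})

test_that("term matching is case-insensitive and whitespace-normalized", {
  e <- data.frame(subject = "Glycine", predicate = "X",
                  object = "  TNF   protein ", local_count = NA,
                  local_total = NA, global_count = NA, global_total = NA)
  o <- data.frame(subject = "tnf Protein", predicate = "Y", object = "CHD",
                  local_count = NA, local_total = NA, global_count = NA,
                  global_total = NA)
  expect_equal(overlap_triples(e, o)$overlap, "tnf protein")
})

test_that("Fisher enrichment agrees with the hypergeometric tail oracle", {
  cases <- list(c(10, 10, 10, 10000), c(5, 50, 500, 5000),
                c(3, 20, 100, 100000), c(0, 10, 50, 1000))
  for (cs in cases) {
    got <- triple_enrichment(cs[1], cs[2], cs[3], cs[4])
    # one-sided Fisher = hypergeometric upper tail at the observed count
    want <- phyper(cs[1] - 1, cs[1] + cs[3],
                   (cs[2] - cs[1]) + (cs[4] - cs[3]), cs[2],
                   lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-12, info = paste(cs, collapse = ","))
  }
  # strong enrichment
  expect_lt(triple_enrichment(10, 10, 10, 10000), 1e-3)
  # proportions equal on a balanced table: no enrichment signal
  expect_gt(triple_enrichment(5, 50, 100, 1000), 0.5)
  # zero local count cannot be over-represented
  expect_equal(triple_enrichment(0, 10, 50, 1000), 1)
  # missing counts: p unset, no error
  expect_true(is.na(triple_enrichment(NA, 10, 5, 100)))
  expect_error(triple_enrichment(11, 10, 5, 100),
               class = "mrtriad_param_error")
})

test_that("enrichment p is monotone non-increasing in local_count", {
  p <- triple_enrichment(0:10, 20, 50, 10000)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("overlap ranking orders by best-side p, deterministically", {
  # two overlap terms with paper-like p magnitudes: homocysteine's best
  # side (4.38e-120) must rank above a term whose best p is 1e-3
  e <- data.frame(
    subject = "glycine", predicate = "INTERACTS_WITH",
    object = c("homocysteine", "ethanol"),
    local_count = c(30, 8), local_total = 100,
    global_count = c(40, 600), global_total = 1e5)
  o <- data.frame(
    subject = c("homocysteine", "ethanol"), predicate = "PREDISPOSES",
    object = "coronary arteriosclerosis",
    local_count = c(95, 3), local_total = 100,
    global_count = c(30, 900), global_total = 1e5)
  net <- overlap_triples(e, o)
  rk <- rank_overlaps(net)
  expect_equal(rk$term, c("homocysteine", "ethanol"))
  expect_lt(rk$score[1], rk$score[2])
  # permutation invariance
  net2 <- overlap_triples(e[2:1, ], o[2:1, ])
  expect_equal(rank_overlaps(net2), rk)
  # single overlap -> rank 1
  fx <- glycine_fixture()
  expect_equal(nrow(rank_overlaps(overlap_triples(fx$exposure, fx$outcome))), 1)
})

test_that("fixture construction yields the planted enrichment ordering", {
  fx <- make_triple_fixture(n_overlap = 4, n_noise = 10, seed = 3)
  rk <- rank_overlaps(overlap_triples(fx$exposure, fx$outcome))
  expect_equal(rk$term, fx$planted_terms)
})

test_that("triple I/O and network export round-trip", {
  fx <- make_triple_fixture(n_overlap = 2, n_noise = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(fx$exposure, path)
  back <- read_triples(path)
  expect_equal(back$object, fx$exposure$object)
  net <- overlap_triples(fx$exposure, fx$outcome)
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  j <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(sort(j$overlap), net$overlap)
  # missing required columns raise a config error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("subject\tpredicate\nx\ty", bad)
  expect_error(read_triples(bad), class = "mrtriad_config_error")
})
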