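test_that("reciprocal best hits require mutual best status", {
  ab <- data.frame(query = c("a1", "a1", "a2"),
                   subject = c("b1", "b2", "b2"),
                   bitscore = c(100, 90, 70), evalue = c(1e-20, 1e-10, 1e-8))
  ba <- data.frame(query = c("b1", "b2"),
                   subject = c("a1", "a3"),
                   bitscore = c(95, 60), evalue = c(1e-20, 1e-6))
  p <- rbh_pairs(ab, ba)
  expect_equal(p$a_id, "a1")   # mutual best
  expect_equal(p$b_id, "b1")   # a2 -> b2 but b2 -> a3: no pair
})

test_that("rbh selection matches the brute-force definition on random tables", {
  set.seed(7)
  for (rep in 1:10) {
    ab <- random_hit_table(15, 15)
    ba <- random_hit_table(15, 15, prefix_q = "b", prefix_s = "a")
    got <- rbh_pairs(ab, ba)
    want <- oracle_rbh(ab, ba)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # partial matching: every id participates in at most one pair
    expect_false(anyDuplicated(got$a_id) > 0)
    expect_false(anyDuplicated(got$b_id) > 0)
  }
})

test_that("e-value cutoff applies before best-hit selection", {
  ab <- data.frame(query = "a1", subject = c("b1", "b2"),
                   bitscore = c(200, 100), evalue = c(0.5, 1e-10))
  ba <- data.frame(query = c("b1", "b2"), subject = "a1",
                   bitscore = c(90, 95), evalue = c(1e-9, 1e-9))
  # b1 is the raw best hit but fails the cutoff; b2 is best after filtering
  p <- rbh_pairs(ab, ba, evalue_max = 1e-3)
  expect_equal(p$b_id, "b2")
})

family_defs_demo <- list(
  flag = list(ko = c("K02400", "K02401"), ref = "CC_1111"),
  chem = list(ko = "K03406", ref = character(0)))

test_that("evidence channels combine into the four cell codes", {
  m <- build_matrix(
    ko_tables = list(g1 = "K02400", g2 = character(0), g3 = "K03406"),
    rbh_maps = list(g1 = "CC_1111", g2 = "CC_1111"),
    family_defs = family_defs_demo)
  expect_equal(unname(m["g1", "flag"]), 3L)  # both
  expect_equal(unname(m["g2", "flag"]), 2L)  # rbh only
  expect_equal(unname(m["g3", "chem"]), 1L)  # ko only
  expect_equal(unname(m["g2", "chem"]), 0L)
  expect_equal(unname(presence(m)["g2", "flag"]), 1L)
  expect_error(build_matrix(list(g1 = "K1"), list(),
                            list(bad = list(ko = character(0)))), "bad")
})

test_that("adding evidence never flips a cell toward absent", {
  base <- build_matrix(list(g1 = "K02400"), list(),
                       family_defs_demo)
  more <- build_matrix(list(g1 = "K02400"), list(g1 = "CC_1111"),
                       family_defs_demo)
  expect_true(all(presence(more) >= presence(base)))
})

test_that("clade aggregation equals brute-force group means", {
  set.seed(11)
  m <- matrix(rbinom(50 * 20, 1, 0.6), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("f", 1:20)))
  clades <- setNames(sample(paste0("c", 1:5), 50, replace = TRUE),
                     rownames(m))
  agg <- aggregate_by_clade(m, clades)
  for (cl in unique(clades)) {
    manual <- colMeans(m[names(clades)[clades == cl], , drop = FALSE])
    expect_equal(unname(agg[cl, ]), unname(manual))
  }
  expect_true(all(agg >= 0 & agg <= 1))
  # a singleton clade reproduces its genome's binary row
  single <- setNames(rownames(m), rownames(m))
  expect_equal(unname(aggregate_by_clade(m, single)[rownames(m)[3], ]),
               unname(m[3, ]))
  expect_error(aggregate_by_clade(m, clades[-1]), "without a clade")
})

test_that("estimated genome size divides assembly size by completeness", {
  expect_equal(estimated_genome_size(4e6, 1.0), 4e6)
  expect_equal(estimated_genome_size(2e6, 0.5), 4e6)
  expect_error(estimated_genome_size(1e6, 0), "completeness")
  expect_warning(est <- estimated_genome_size(2e6, 50), "percent")
  expect_equal(est, 4e6)
  # estimated >= assembly, equality iff complete
  set.seed(2)
  sz <- runif(20, 1e6, 6e6); comp <- runif(20, 0.5, 1)
  expect_true(all(estimated_genome_size(sz, comp) >= sz))
})

test_that("environment summaries tally fractions over a controlled vocabulary", {
  rec <- data.frame(
    genome_id = paste0("g", 1:10),
    assembly_size = rep(3e6, 10),
    completeness = rep(1, 10),
    environment_category = c(rep("terrestrial", 3), rep("aquatic", 5),
                             "weird", "marine"),
    family = "Caulobacteraceae",
    stringsAsFactors = FALSE)
  s <- environment_summary(rec, group_by = "family")
  terr <- s$fractions$fraction[s$fractions$category == "terrestrial"]
  expect_equal(terr, 0.3)
  expect_equal(sum(s$fractions$fraction), 1)  # includes "unclassified"
  expect_true("unclassified" %in% s$fractions$category)
  expect_error(environment_summary(rec[0, ]), "empty")
  # single category gives fraction 1
  rec2 <- rec; rec2$environment_category <- "aquatic"
  s2 <- environment_summary(rec2, group_by = "family")
  expect_equal(s2$fractions$fraction[s2$fractions$category == "aquatic"], 1)
})
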