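rules <- load_phototrophy_rules()
full_set <- c(default_pgc_order(), cbb_block())

test_that("pathway completeness counts satisfied steps", {
  cbb <- rules$cbb
  expect_equal(pathway_completeness(character(0), cbb)$completeness, 0)
  full <- pathway_completeness(full_set, cbb)
  expect_equal(full$completeness, 1)
  expect_true(full$required_ok)
  # multi-subunit RuBisCO step requires both subunits
  expect_false(pathway_completeness(
    setdiff(full_set, "cbbS"), cbb)$step_present[["rubisco"]])
  expect_error(pathway_def("x", list()), "no steps")
})

test_that("completeness matches brute-force step evaluation on random subsets", {
  cbb <- rules$cbb
  set.seed(4)
  for (rep in 1:25) {
    ko <- sample(full_set, sample(0:length(full_set), 1))
    got <- pathway_completeness(ko, cbb)
    sat <- vapply(cbb$steps, function(stp)
      any(vapply(stp$alternatives, function(alt) all(alt %in% ko),
                 logical(1))), logical(1))
    expect_equal(unname(got$step_present), sat)
    expect_equal(got$completeness, sum(sat) / length(sat))
  }
})

test_that("completeness is monotone under KO-set union", {
  cbb <- rules$cbb
  set.seed(5)
  for (rep in 1:10) {
    a <- sample(full_set, 10)
    b <- union(a, sample(full_set, 10))
    expect_gte(pathway_completeness(b, cbb)$completeness,
               pathway_completeness(a, cbb)$completeness)
  }
})

test_that("phototrophy levels follow the reaction-center, bch, and CBB rules", {
  # complete gene complement: photoautotrophic potential
  expect_equal(call_phototroph(full_set, rules)$level,
               "photoautotroph_potential")
  # everything but RuBisCO: still a phototroph, near-complete CBB flagged
  no_rubisco <- call_phototroph(setdiff(full_set, c("cbbL", "cbbS")), rules)
  expect_equal(no_rubisco$level, "phototroph")
  expect_true("near_complete_cbb_missing_rubisco" %in% no_rubisco$flags)
  expect_lt(no_rubisco$cbb_completeness, 1)
  # losing one RC core subunit voids the call entirely
  expect_equal(call_phototroph(setdiff(full_set, "pufL"), rules)$level,
               "none")
  expect_equal(call_phototroph(setdiff(full_set, "pufM"), rules)$level,
               "none")
  # too few bch families also voids it
  few_bch <- c("pufL", "pufM", "bchB", "bchC")
  expect_equal(call_phototroph(few_bch, rules)$level, "none")
})

test_that("LH2 and carotenoid genes are evidence but never gate the call", {
  with_acc <- call_phototroph(full_set, rules)
  without_acc <- call_phototroph(
    setdiff(full_set, c("pucA", "pucB", "crtC", "crtD", "crtF")), rules)
  expect_equal(with_acc$level, without_acc$level)
  expect_true(all(with_acc$evidence$lh2))
  expect_false(any(without_acc$evidence$carotenoid))
})

test_that("cohort screening reports the phototroph fraction", {
  g <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 20, genes_per_genome = 300, n_with_pgc = 2, seed = 17))
  scr <- screen_genomes(g$annotations)
  expect_equal(scr$fraction_phototrophic, 0.10)
  expect_equal(scr$n_genomes, 20)
  none <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 5, genes_per_genome = 100, n_with_pgc = 0, seed = 18))
  expect_equal(screen_genomes(none$annotations)$fraction_phototrophic, 0)
  all_p <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 5, genes_per_genome = 100, seed = 19))
  expect_equal(screen_genomes(all_p$annotations)$fraction_phototrophic, 1)
  expect_error(screen_genomes(list(a = "pufL", a = "pufM")), "duplicate")
})

test_that("with_cbb = FALSE genomes carry no CBB-step families", {
  g <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 3, genes_per_genome = 200, with_cbb = FALSE, seed = 20))
  cbb_fams <- unique(unlist(lapply(rules$cbb$steps, `[[`, "alternatives")))
  expect_length(intersect(g$annotations$family_id, cbb_fams), 0)
  scr <- screen_genomes(g$annotations)
  expect_true(all(scr$calls$level == "phototroph"))
})

test_that("planted clusters are detected with exact boundaries", {
  g <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 3, genes_per_genome = 400, seed = 21))
  regs <- detect_gene_cluster(g$annotations, g$cluster_families)
  expect_length(regs, 3)
  for (i in 1:3) {
    tr <- g$truth[[i]]$regions
    r <- regs[[which(vapply(regs, function(x)
      x$genome_id == g$truth[[i]]$genome_id, logical(1)))]]
    expect_equal(r$first_index, tr$first_index)
    expect_equal(r$last_index, tr$last_index)
    expect_false(r$left_at_contig_end || r$right_at_contig_end)
    expect_equal(r$families, g$cluster_families)
  }
})

test_that("split clusters yield two regions, each flagged at a contig edge", {
  g <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 1, genes_per_genome = 400, split_at = 12, seed = 22))
  regs <- detect_gene_cluster(g$annotations, g$cluster_families)
  expect_length(regs, 2)
  r1 <- regs[[which(vapply(regs, function(r)
    grepl("_c1$", r$contig_id), logical(1)))]]
  r2 <- regs[[which(vapply(regs, function(r)
    grepl("_c2$", r$contig_id), logical(1)))]]
  expect_true(r1$right_at_contig_end && !r1$left_at_contig_end)
  expect_true(r2$left_at_contig_end && !r2$right_at_contig_end)
  # both fragments keep the original internal gene order
  expect_equal(c(r1$families, r2$families), g$cluster_families)
  expect_error(planted_pgc_spec(split_at = 1000), "split_at")
})

test_that("scattered gene content produces no cluster", {
  g <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 1, genes_per_genome = 1000, scatter = TRUE, seed = 23))
  expect_equal(nrow(g$truth[[1]]$regions), 0)
  regs <- detect_gene_cluster(g$annotations, g$cluster_families,
                              min_members = 5)
  expect_length(regs, 0)
})

test_that("growing max_gap never shrinks cluster coverage", {
  g <- simulate_annotated_genomes(planted_pgc_spec(
    n_genomes = 1, genes_per_genome = 500, seed = 24))
  covered <- function(gap) {
    regs <- detect_gene_cluster(g$annotations, g$cluster_families,
                                max_gap = gap, min_members = 2)
    sum(vapply(regs, `[[`, integer(1), "n_members"))
  }
  expect_gte(covered(5), covered(1))
  expect_gte(covered(10), covered(5))
})

test_that("synteny scoring matches brute-force adjacency and orientation", {
  mk_region <- function(fams, strands) {
    structure(list(genome_id = "G", contig_id = "c", first_index = 1,
                   last_index = length(fams), families = fams,
                   strands = strands, n_members = length(fams),
                   left_at_contig_end = FALSE,
                   right_at_contig_end = FALSE),
              class = "cluster_region")
  }
  a <- mk_region(letters[1:6], rep("+", 6))
  self <- cluster_synteny(a, a)
  expect_equal(self$adjacency_conservation, 1)
  expect_equal(self$orientation_agreement, 1)
  # disjoint content
  b <- mk_region(letters[7:12], rep("+", 6))
  disj <- cluster_synteny(a, b)
  expect_equal(disj$shared_families, 0)
  expect_equal(disj$adjacency_conservation, 0)
  # internal inversion of a 3-gene block
  inv <- mk_region(c("a", "d", "c", "b", "e", "f"),
                   c("+", "-", "-", "-", "+", "+"))
  got <- cluster_synteny(a, inv)
  want <- oracle_synteny(a, inv)
  expect_equal(got$shared_families, want$shared)
  expect_equal(got$adjacency_conservation, want$adjacency)
  expect_equal(got$orientation_agreement, want$orientation)
  # random permutations against the oracle
  set.seed(6)
  for (rep in 1:10) {
    fams <- sample(letters[1:8])
    r <- mk_region(fams, sample(c("+", "-"), 8, replace = TRUE))
    got <- cluster_synteny(a, r)
    want <- oracle_synteny(a, r)
    expect_equal(got$adjacency_conservation, want$adjacency)
    expect_equal(got$orientation_agreement, want$orientation)
  }
})
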