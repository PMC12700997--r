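#' Default photosynthesis gene-cluster gene order
#'
#' A type II anoxygenic photosynthesis gene cluster (PGC) layout of the
#' kind found in purple alphaproteobacteria: carotenoid biosynthesis
#' (`crtCDF`), bacteriochlorophyll biosynthesis (`bch` genes, `acsF`),
#' reaction-center and light-harvesting I subunits (`pufBALM`, `pufH`),
#' and the chlorophyll transporter `pucC`.
#'
#' @return Character vector of family labels in gene order.
#' @export
default_pgc_order <- function() {
  c("crtF", "crtC", "crtD", "bchC", "bchX", "bchY", "bchZ",
    "pufB", "pufA", "pufL", "pufM", "pufH",
    "bchF", "bchN", "bchB", "bchH", "bchL", "bchM", "acsF",
    "bchG", "bchP", "pucC", "bchI", "bchD", "bchO")
}

#' Calvin-Benson-Bassham gene block
#'
#' CBB-cycle genes (plus the LH2 subunits `pucAB`) appended inside the
#' planted PGC when `with_cbb = TRUE`, mirroring photoautotrophic
#' Caulobacterales whose carbon-fixation genes sit inside the PGC:
#' RuBisCO (`cbbL`, `cbbS`), red-type RuBisCO activase (`cbbX`), XuBP
#' phosphatase (`cbbY`), and the remaining cycle enzymes.
#'
#' @return Character vector of family labels in gene order.
#' @export
cbb_block <- function() {
  c("pucA", "pucB",
    "cbbL", "cbbS", "cbbX", "cbbY",
    "cbbP", "cbbF", "cbbA", "cbbT", "cbbG", "cbbE", "cbbI", "tpiA", "pgk")
}

#' Specification of planted photosynthesis gene clusters
#'
#' Parameters for [simulate_annotated_genomes()], which generates ordered,
#' coordinate-annotated synthetic genomes carrying (or lacking) a planted
#' PGC — optionally split across a contig edge, or scattered gene-by-gene
#' across the chromosome while retaining gene content.
#'
#' @param n_genomes Number of genomes to generate.
#' @param genes_per_genome Background (non-cluster) genes per genome.
#'   The default, 3800, matches the gene count of a typical ~4 Mb
#'   Caulobacterales genome at ~1 kb gene spacing; the background gene
#'   density sets the chance-clustering null for scattered cluster genes.
#' @param pgc_gene_order Family labels of the planted cluster, in order.
#' @param with_cbb If `TRUE`, the LH2 + CBB block ([cbb_block()]) is
#'   appended inside the cluster; if `FALSE`, generated genomes carry no
#'   CBB-step families at all.
#' @param split_at Optional index (1 to cluster length - 1): the cluster is
#'   split after this many genes across two contigs, each fragment abutting
#'   a contig end (the contig-edge assembly case).
#' @param scatter If `TRUE`, cluster genes are placed at random positions
#'   across the genome instead of contiguously (gene content preserved,
#'   clustering destroyed).
#' @param n_with_pgc How many of the genomes carry the planted cluster
#'   (default: all); the remainder are background-only.
#' @param seed Integer seed.
#' @return A validated list of class `planted_pgc_spec`.
#' @export
planted_pgc_spec <- function(n_genomes = 20,
                             genes_per_genome = 3800,
                             pgc_gene_order = default_pgc_order(),
                             with_cbb = TRUE,
                             split_at = NULL,
                             scatter = FALSE,
                             n_with_pgc = n_genomes,
                             seed = 1L) {
  if (n_genomes < 1) stop_param("n_genomes must be >= 1")
  if (genes_per_genome < 1) stop_param("genes_per_genome must be >= 1")
  if (n_with_pgc < 0 || n_with_pgc > n_genomes)
    stop_param("n_with_pgc must lie in [0, n_genomes]")
  cluster <- as.character(pgc_gene_order)
  if (with_cbb) cluster <- c(cluster, cbb_block())
  if (n_with_pgc > 0 && !length(cluster))
    stop_param("pgc_gene_order must be non-empty when planting")
  if (!is.null(split_at)) {
    if (scatter) stop_param("split_at and scatter are mutually exclusive")
    if (split_at < 1 || split_at >= length(cluster))
      stop_param("split_at must lie within the cluster (1 to %d)",
                 length(cluster) - 1L)
  }
  p <- list(n_genomes = n_genomes, genes_per_genome = genes_per_genome,
            pgc_gene_order = pgc_gene_order, with_cbb = with_cbb,
            cluster_families = cluster,
            split_at = split_at, scatter = scatter,
            n_with_pgc = n_with_pgc, seed = seed)
  class(p) <- "planted_pgc_spec"
  p
}

# lay out `fams` as consecutive genes on `contig`, starting at gene index
# `idx0` (1-based); coordinates are 0-based half-open, 900 bp genes on a
# 1 kb grid
layout_genes <- function(genome_id, contig, fams, strands, idx0 = 1L) {
  n <- length(fams)
  if (!n) return(NULL)
  idx <- idx0:(idx0 + n - 1L)
  data.frame(genome_id = genome_id,
             contig_id = contig,
             gene_index = idx,
             start = (idx - 1L) * 1000L,
             end = (idx - 1L) * 1000L + 900L,
             strand = strands,
             family_id = fams,
             stringsAsFactors = FALSE)
}

#' Simulate annotated genomes with planted photosynthesis gene clusters
#'
#' Each genome is one or more contigs of ordered genes with family (KO-like)
#' labels. Genomes selected to carry the PGC have its genes planted
#' contiguously (internal gap 0) at a random position — or split across two
#' contig ends when `split_at` is set, or scattered across the chromosome
#' when `scatter = TRUE`. The truth record gives, per genome, the exact
#' cluster regions (contig, gene-index span, edge flags), empty when
#' scattered or unplanted.
#'
#' @param spec A [planted_pgc_spec()].
#' @return A list with `annotations` (data.frame: `genome_id`, `contig_id`,
#'   `gene_index`, `start`, `end`, `strand`, `family_id`), `truth` (list per
#'   genome: `has_pgc`, `regions` data.frame with `contig_id`,
#'   `first_index`, `last_index`, `left_at_contig_end`,
#'   `right_at_contig_end`), and `cluster_families`.
#' @examples
#' g <- simulate_annotated_genomes(planted_pgc_spec(n_genomes = 2,
#'   genes_per_genome = 100, seed = 3))
#' g$truth[[1]]$regions
#' @export
simulate_annotated_genomes <- function(spec) {
  stopifnot(inherits(spec, "planted_pgc_spec"))
  with_seed(spec$seed, {
    cluster <- spec$cluster_families
    L <- length(cluster)
    planted <- seq_len(spec$n_genomes) <= spec$n_with_pgc
    ann <- vector("list", spec$n_genomes)
    truth <- vector("list", spec$n_genomes)
    for (g in seq_len(spec$n_genomes)) {
      gid <- sprintf("G%03d", g)
      n_bg <- spec$genes_per_genome
      bg_fams <- sprintf("hk%04d", sample.int(5000L, n_bg, replace = TRUE))
      bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      if (!planted[g] || L == 0L) {
        ann[[g]] <- layout_genes(gid, paste0(gid, "_c1"), bg_fams, bg_strand)
        truth[[g]] <- list(genome_id = gid, has_pgc = FALSE,
                           regions = empty_regions())
        next
      }
      if (spec$scatter) {
        # interleave cluster genes at random positions; content kept,
        # clustering destroyed
        slots <- sort(sample.int(n_bg + L, L))
        fams <- character(n_bg + L)
        strands <- character(n_bg + L)
        fams[slots] <- cluster
        strands[slots] <- "+"
        fams[-slots] <- bg_fams
        strands[-slots] <- bg_strand
        ann[[g]] <- layout_genes(gid, paste0(gid, "_c1"), fams, strands)
        truth[[g]] <- list(genome_id = gid, has_pgc = TRUE,
                           regions = empty_regions())
      } else if (!is.null(spec$split_at)) {
        s <- spec$split_at
        n1 <- n_bg %/% 2L
        c1_f <- c(bg_fams[seq_len(n1)], cluster[seq_len(s)])
        c1_s <- c(bg_strand[seq_len(n1)], rep("+", s))
        c2_f <- c(cluster[(s + 1L):L], bg_fams[(n1 + 1L):n_bg])
        c2_s <- c(rep("+", L - s), bg_strand[(n1 + 1L):n_bg])
        ann[[g]] <- rbind(
          layout_genes(gid, paste0(gid, "_c1"), c1_f, c1_s),
          layout_genes(gid, paste0(gid, "_c2"), c2_f, c2_s))
        truth[[g]] <- list(genome_id = gid, has_pgc = TRUE,
          regions = data.frame(
            contig_id = paste0(gid, c("_c1", "_c2")),
            first_index = c(n1 + 1L, 1L),
            last_index = c(n1 + s, L - s),
            left_at_contig_end = c(FALSE, TRUE),
            right_at_contig_end = c(TRUE, FALSE),
            stringsAsFactors = FALSE))
      } else {
        at <- sample.int(n_bg - 1L, 1L)  # insert after background gene `at`
        fams <- c(bg_fams[seq_len(at)], cluster, bg_fams[(at + 1L):n_bg])
        strands <- c(bg_strand[seq_len(at)], rep("+", L),
                     bg_strand[(at + 1L):n_bg])
        ann[[g]] <- layout_genes(gid, paste0(gid, "_c1"), fams, strands)
        truth[[g]] <- list(genome_id = gid, has_pgc = TRUE,
          regions = data.frame(
            contig_id = paste0(gid, "_c1"),
            first_index = at + 1L,
            last_index = at + L,
            left_at_contig_end = FALSE,
            right_at_contig_end = FALSE,
            stringsAsFactors = FALSE))
      }
    }
    list(annotations = do.call(rbind, ann),
         truth = truth,
         cluster_families = cluster)
  })
}

empty_regions <- function() {
  data.frame(contig_id = character(0), first_index = integer(0),
             last_index = integer(0), left_at_contig_end = logical(0),
             right_at_contig_end = logical(0), stringsAsFactors = FALSE)
}
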