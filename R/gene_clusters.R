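#' Detect gene clusters of a functional category
#'
#' Scans each contig of an annotation for maximal runs of category genes
#' in which consecutive members are separated by at most `max_gap`
#' intervening non-category genes; runs with at least `min_members`
#' members are reported. Distance is measured in intervening gene count,
#' not base pairs, matching the gene-cluster granularity of synteny maps.
#' Edge flags mark runs whose first/last member lies within `max_gap`
#' genes of a contig end — the signature of a cluster truncated by an
#' assembly break.
#'
#' @param annotation Annotation data.frame (`genome_id`, `contig_id`,
#'   `gene_index`, `start`, `end`, `strand`, `family_id`).
#' @param category_families Character vector of family ids defining the
#'   category (e.g. photosynthesis gene families).
#' @param max_gap Maximum intervening non-category genes between
#'   consecutive members (default 5).
#' @param min_members Minimum member count of a reported region
#'   (default 5).
#' @return A list of `cluster_region` objects: `genome_id`, `contig_id`,
#'   `first_index`/`last_index` (member gene indices), `families` and
#'   `strands` in gene order, `n_members`, `left_at_contig_end`,
#'   `right_at_contig_end`. Possibly empty.
#' @examples
#' g <- simulate_annotated_genomes(planted_pgc_spec(n_genomes = 1,
#'   genes_per_genome = 200, seed = 5))
#' regs <- detect_gene_cluster(g$annotations, g$cluster_families)
#' length(regs)
#' @export
detect_gene_cluster <- function(annotation, category_families,
                                max_gap = 5, min_members = 5) {
  stopifnot(is.data.frame(annotation),
            all(c("contig_id", "gene_index", "family_id") %in%
                  names(annotation)))
  regions <- list()
  for (ct in unique(annotation$contig_id)) {
    genes <- annotation[annotation$contig_id == ct, , drop = FALSE]
    genes <- genes[order(genes$gene_index), , drop = FALSE]
    n_ct <- nrow(genes)
    memb <- which(genes$family_id %in% category_families)
    if (!length(memb)) next
    run_id <- cumsum(c(1L, diff(memb) - 1L > max_gap))
    for (r in split(memb, run_id)) {
      if (length(r) < min_members) next
      regions[[length(regions) + 1L]] <- structure(list(
        genome_id = genes$genome_id[1] %||% NA_character_,
        contig_id = ct,
        first_index = genes$gene_index[r[1]],
        last_index = genes$gene_index[r[length(r)]],
        families = genes$family_id[r],
        strands = genes$strand[r],
        n_members = length(r),
        left_at_contig_end = (r[1] - 1L) <= max_gap,
        right_at_contig_end = (n_ct - r[length(r)]) <= max_gap
      ), class = "cluster_region")
    }
  }
  regions
}

#' Synteny score between two gene-cluster regions
#'
#' Compares two cluster regions by gene content, gene-order conservation,
#' and strand agreement:
#'
#' * `shared_families` — number of families occurring in both regions.
#' * `adjacency_conservation` — among pairs of shared families that are
#'   adjacent (consecutive members) in `a`, the fraction that are also
#'   adjacent in `b`, in either orientation.
#' * `orientation_agreement` — fraction of shared families whose strand
#'   relative to their region's majority frame matches between the two
#'   regions (robust to whole-cluster inversions).
#'
#' Fractions are defined as 0 when the relevant denominator is empty.
#'
#' @param a,b `cluster_region` objects (see [detect_gene_cluster()]).
#' @return A list: `shared_families`, `adjacency_conservation`,
#'   `orientation_agreement`.
#' @export
cluster_synteny <- function(a, b) {
  stopifnot(inherits(a, "cluster_region"), inherits(b, "cluster_region"))
  if (!length(a$families) || !length(b$families))
    stop_param("cluster regions must be non-empty")
  shared <- intersect(a$families, b$families)
  if (!length(shared))
    return(list(shared_families = 0L, adjacency_conservation = 0,
                orientation_agreement = 0))

  adj_pairs <- function(fams) {
    ok <- fams %in% shared
    pairs <- list()
    for (i in seq_len(length(fams) - 1L))
      if (ok[i] && ok[i + 1L])
        pairs[[length(pairs) + 1L]] <- sort(c(fams[i], fams[i + 1L]))
    unique(lapply(pairs, identity))
  }
  pa <- adj_pairs(a$families)
  pb <- adj_pairs(b$families)
  adjacency <- if (!length(pa)) 0 else
    mean(vapply(pa, function(p)
      any(vapply(pb, identical, logical(1), p)), logical(1)))

  rel_strand <- function(reg) {
    maj <- names(sort(table(reg$strands), decreasing = TRUE))[1]
    st <- stats::setNames(reg$strands == maj, reg$families)
    st[!duplicated(names(st))]
  }
  ra <- rel_strand(a)
  rb <- rel_strand(b)
  orientation <- mean(ra[shared] == rb[shared])

  list(shared_families = length(shared),
       adjacency_conservation = adjacency,
       orientation_agreement = orientation)
}
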