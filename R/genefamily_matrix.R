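#' Reciprocal best hits from tabular homology results
#'
#' Selects reciprocal best hit (RBH) ortholog pairs from two directed hit
#' tables (e.g. blastp tabular output of proteome A vs B and B vs A). Both
#' tables are first filtered to `evalue <= evalue_max` (the search
#' convention `-max_target_seqs 1 -evalue 1e-3`); a pair `(a, b)` is
#' emitted iff `b` is `a`'s unique best hit in `ab` and `a` is `b`'s
#' unique best hit in `ba`. Best = maximal bitscore, ties broken by
#' minimal e-value, then lexicographically smallest subject id, so the
#' selection is deterministic.
#'
#' @param ab,ba Data frames with columns `query`, `subject`, `bitscore`,
#'   `evalue`.
#' @param evalue_max E-value cutoff applied before best-hit selection.
#' @return Data frame with columns `a_id`, `b_id`, one row per RBH pair,
#'   sorted by `a_id`. The output is a partial matching: each id occurs in
#'   at most one pair.
#' @export
rbh_pairs <- function(ab, ba, evalue_max = 1e-3) {
  best_hits <- function(tab, label) {
    req <- c("query", "subject", "bitscore", "evalue")
    miss <- setdiff(req, names(tab))
    if (length(miss))
      stop_param("%s hit table is missing columns: %s", label,
                 paste(miss, collapse = ", "))
    bad <- !is.finite(tab$bitscore) | is.na(tab$evalue) | tab$evalue < 0
    if (any(bad))
      stop_param("%s hit table has malformed rows at lines: %s", label,
                 paste(utils::head(which(bad), 5), collapse = ", "))
    tab <- tab[tab$evalue <= evalue_max, , drop = FALSE]
    if (!nrow(tab)) return(character(0))
    ord <- order(tab$query, -tab$bitscore, tab$evalue, tab$subject)
    tab <- tab[ord, , drop = FALSE]
    keep <- !duplicated(tab$query)
    stats::setNames(tab$subject[keep], tab$query[keep])
  }
  fwd <- best_hits(ab, "ab")
  rev_ <- best_hits(ba, "ba")
  a_ids <- names(fwd)
  mutual <- !is.na(rev_[fwd[a_ids]]) & rev_[fwd[a_ids]] == a_ids
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(a_id = a_ids[mutual],
                    b_id = unname(fwd[a_ids][mutual]),
                    stringsAsFactors = FALSE)
  out[order(out$a_id), , drop = FALSE]
}

#' Build a presence/absence matrix with per-cell evidence codes
#'
#' Combines two evidence channels per genome — KEGG-ortholog annotations
#' and reciprocal-best-hit matches against a reference proteome — into a
#' genome-by-family matrix. A family is present in a genome if any of its
#' defining KO ids occurs in the genome's KO set or any of its reference
#' locus ids occurs in the genome's RBH map (evidence union); the cell
#' code preserves which channel(s) contributed.
#'
#' @param ko_tables Named list (by genome id) of character vectors of KO
#'   ids present in each genome.
#' @param rbh_maps Named list (by genome id) of character vectors of
#'   reference locus ids matched by RBH. Genomes missing here are treated
#'   as having no RBH evidence.
#' @param family_defs Named list: per family, a list with elements `ko`
#'   (character vector of KO ids) and/or `ref` (reference locus ids); each
#'   family needs at least one defining id.
#' @return An integer matrix of class `presence_matrix` (rows = genomes,
#'   columns = families) with codes 0 = absent, 1 = ko_only, 2 = rbh_only,
#'   3 = both. Use [presence()] for the binary view.
#' @export
build_matrix <- function(ko_tables, rbh_maps = list(), family_defs) {
  if (!length(family_defs)) stop_param("family_defs must be non-empty")
  genomes <- names(ko_tables)
  if (is.null(genomes) || anyDuplicated(genomes))
    stop_param("ko_tables must be a named list with unique genome ids")
  fams <- names(family_defs)
  empty <- vapply(family_defs, function(d)
    !length(d$ko %||% character(0)) && !length(d$ref %||% character(0)),
    logical(1))
  if (any(empty))
    stop_param("families with no defining ids: %s",
               paste(fams[empty], collapse = ", "))
  m <- matrix(0L, nrow = length(genomes), ncol = length(fams),
              dimnames = list(genomes, fams))
  for (g in genomes) {
    kos <- ko_tables[[g]]
    refs <- rbh_maps[[g]] %||% character(0)
    for (f in fams) {
      ko_hit <- length(intersect(family_defs[[f]]$ko %||% character(0),
                                 kos)) > 0
      rbh_hit <- length(intersect(family_defs[[f]]$ref %||% character(0),
                                  refs)) > 0
      m[g, f] <- ko_hit + 2L * rbh_hit
    }
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Binary presence view of an evidence-coded matrix
#'
#' @param matrix A `presence_matrix` (evidence codes 0-3) or an already
#'   binary 0/1 matrix.
#' @return Integer 0/1 matrix: present iff the evidence code is non-zero.
#' @export
presence <- function(matrix) {
  m <- unclass(matrix)
  storage.mode(m) <- "integer"
  (m != 0L) * 1L
}

#' Average presence per clade
#'
#' Collapses a genome-by-family presence matrix to clade-by-family
#' fractions: the share of each clade's genomes in which the family is
#' present (the linear color-gradient display convention for genus/family
#' rows in presence heatmaps).
#'
#' @param matrix Presence matrix (evidence codes or binary).
#' @param clade_map Named character vector mapping every genome id (row)
#'   to exactly one clade label.
#' @return Numeric matrix, rows = clades, columns = families, values in
#'   `[0, 1]`.
#' @export
aggregate_by_clade <- function(matrix, clade_map) {
  bin <- presence(matrix)
  unmapped <- setdiff(rownames(bin), names(clade_map))
  if (length(unmapped))
    stop_param("genomes without a clade mapping: %s",
               paste(utils::head(unmapped, 5), collapse = ", "))
  clades <- clade_map[rownames(bin)]
  sums <- rowsum(bin, group = clades)        # rows sorted by clade label
  counts <- as.integer(table(clades)[rownames(sums)])
  sweep(sums, 1, counts, "/")
}

#' Estimated genome size from assembly size and completeness
#'
#' Divides the assembly size by the estimated completeness, giving the
#' expected full-genome size of an incomplete assembly (e.g. a MAG).
#' Completeness is accepted either as a fraction in `(0, 1]` or as a
#' percentage in `(1, 100]` (auto-detected and normalized with a warning).
#'
#' @param assembly_size Assembly size in bp (vectorized).
#' @param completeness Estimated completeness, fraction or percent.
#' @return Estimated genome size(s) in bp; always `>=` the assembly size,
#'   with equality iff completeness is 1.
#' @export
estimated_genome_size <- function(assembly_size, completeness) {
  stopifnot(length(assembly_size) == length(completeness))
  if (any(!is.finite(completeness)) || any(completeness <= 0))
    stop_param("completeness must be > 0")
  if (any(completeness > 1)) {
    if (any(completeness > 100))
      stop_param("completeness must be <= 1 (fraction) or <= 100 (percent)")
    warning("completeness > 1 detected; interpreting as percent",
            call. = FALSE)
    completeness <- ifelse(completeness > 1, completeness / 100,
                           completeness)
  }
  assembly_size / completeness
}

#' Per-clade environmental and genome-size summaries
#'
#' Tallies environment-category fractions and genome-size distributions
#' per clade. Categories outside the controlled vocabulary map to
#' `"unclassified"`, and fractions per clade sum to 1 over all categories
#' including `"unclassified"`.
#'
#' @param records Data frame with columns `genome_id`, `assembly_size`,
#'   `completeness`, `environment_category`, and the clade column named by
#'   `group_by`.
#' @param group_by Name of the clade column (e.g. `"genus"` or
#'   `"family"`).
#' @param vocabulary Controlled vocabulary of environment categories.
#' @return A list: `fractions` (data.frame clade x category fraction, long
#'   form) and `sizes` (per clade and category: `n`, `q1`, `median`, `q3`
#'   of estimated genome size).
#' @export
environment_summary <- function(records, group_by = "family",
                                vocabulary = c("aquatic", "marine",
                                               "terrestrial", "host",
                                               "engineered")) {
  if (!nrow(records)) stop_param("empty metadata table")
  req <- c("genome_id", "assembly_size", "completeness",
           "environment_category", group_by)
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop_param("metadata table is missing columns: %s",
               paste(miss, collapse = ", "))
  cat_ <- ifelse(records$environment_category %in% vocabulary,
                 records$environment_category, "unclassified")
  clade <- records[[group_by]]
  est <- estimated_genome_size(records$assembly_size, records$completeness)

  tab <- table(clade, cat_)
  frac <- as.data.frame(prop.table(tab, margin = 1), stringsAsFactors = FALSE)
  names(frac) <- c("clade", "category", "fraction")

  key <- interaction(clade, cat_, drop = TRUE)
  sizes <- do.call(rbind, lapply(split(seq_along(est), key), function(idx) {
    q <- stats::quantile(est[idx], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(clade = clade[idx[1]], category = cat_[idx[1]],
               n = length(idx), q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(sizes) <- NULL
  list(fractions = frac[order(frac$clade, frac$category), ],
       sizes = sizes[order(sizes$clade, sizes$category), ])
}
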