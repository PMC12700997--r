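#' Screen for gene modules convergently lost in focal lineages
#'
#' Finds gene families that (a) are conserved in the background — present
#' in at least `conservation_min` of the genomes outside every focal set,
#' (b) are absent from every genome of every focal set, and (c) show at
#' least as many phylogenetically independent Dollo loss events as there
#' are focal sets. This formalizes the convergent-loss signature: a module
#' of families specifically and repeatedly lost by evolutionarily
#' independent lineages while staying conserved in their relatives.
#'
#' @param matrix Presence matrix (evidence codes or binary 0/1; rows =
#'   genomes, columns = families). Every row name must map to a tree tip.
#' @param tree Rooted `phylo` species tree.
#' @param focal_sets List (length >= 2) of disjoint character vectors of
#'   genome ids — the candidate convergently reduced lineages.
#' @param conservation_min Minimum background presence fraction
#'   (default 0.75).
#' @return A list of class `convergent_module`: `family_ids`, `report`
#'   (data.frame: `family_id`, `background_conservation`,
#'   `n_independent_losses`), `focal_stems` (MRCA node id per focal set),
#'   and `n_background`.
#' @examples
#' sim <- simulate_loss_matrix(planted_loss_spec(n_tips = 30,
#'   n_background_families = 40, module_size = 4, seed = 2))
#' mod <- co_loss_screen(sim$matrix, sim$tree, sim$truth$focal_tips)
#' setequal(mod$family_ids, sim$truth$module_families)
#' @export
co_loss_screen <- function(matrix, tree, focal_sets,
                           conservation_min = 0.75) {
  bin <- presence(matrix)
  if (length(focal_sets) < 2)
    stop_param("co_loss_screen needs >= 2 focal sets")
  focal_all <- unlist(focal_sets, use.names = FALSE)
  if (anyDuplicated(focal_all))
    stop_param("focal sets must be disjoint")
  unknown <- setdiff(focal_all, rownames(bin))
  if (length(unknown))
    stop_param("focal genomes not in the matrix: %s",
               paste(utils::head(unknown, 5), collapse = ", "))
  background <- setdiff(rownames(bin), focal_all)
  if (!length(background)) stop_param("background genome set is empty")

  bg_frac <- colMeans(bin[background, , drop = FALSE])
  focal_absent <- colSums(bin[focal_all, , drop = FALSE]) == 0L
  cand <- colnames(bin)[bg_frac >= conservation_min & focal_absent]

  n_req <- length(focal_sets)
  rows <- lapply(cand, function(f) {
    st <- stats::setNames(bin[, f], rownames(bin))
    dl <- dollo_losses(tree, st)
    n_ind <- independent_loss_count(dl$events, tree)
    if (n_ind >= n_req)
      data.frame(family_id = f,
                 background_conservation = unname(bg_frac[f]),
                 n_independent_losses = n_ind,
                 stringsAsFactors = FALSE)
    else NULL
  })
  report <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(report))
    report <- data.frame(family_id = character(0),
                         background_conservation = numeric(0),
                         n_independent_losses = integer(0),
                         stringsAsFactors = FALSE)
  stems <- vapply(focal_sets, function(tips) {
    if (length(tips) == 1L) match(tips, tree$tip.label)
    else ape::getMRCA(tree, tips)
  }, integer(1))
  structure(list(family_ids = report$family_id,
                 report = report,
                 focal_stems = stems,
                 n_background = length(background)),
            class = "convergent_module")
}

#' Classify the breadth of a family's absence pattern
#'
#' Distinguishes families absent only from the focal (reduced) lineages
#' from families whose absence extends to the focal lineages' close
#' relatives — the red/yellow display categories of absence heatmaps.
#'
#' @param family_id Family (column) to classify.
#' @param matrix Presence matrix.
#' @param focal_sets List of disjoint focal genome-id sets.
#' @param relative_sets List, parallel to `focal_sets`, of each lineage's
#'   close relatives (e.g. the remaining members of its genus); must not
#'   overlap the focal sets.
#' @return One of `"focal_only"` (absent from all focal genomes, present
#'   in at least one relative of each lineage), `"focal_and_relatives"`
#'   (absent from focal genomes and all relatives), or `"other"`.
#' @export
classify_absence <- function(family_id, matrix, focal_sets, relative_sets) {
  bin <- presence(matrix)
  if (!family_id %in% colnames(bin))
    stop_param("unknown family: %s", family_id)
  stopifnot(length(focal_sets) == length(relative_sets))
  focal_all <- unlist(focal_sets, use.names = FALSE)
  rel_all <- unlist(relative_sets, use.names = FALSE)
  if (length(intersect(focal_all, rel_all)))
    stop_param("focal and relative sets overlap")
  v <- bin[, family_id]
  if (any(v[focal_all] != 0L)) return("other")
  present_in_some_rel_each <- vapply(relative_sets, function(r)
    length(r) > 0 && any(v[r] != 0L), logical(1))
  if (all(vapply(relative_sets, length, integer(1)) > 0) &&
      all(v[rel_all] == 0L)) return("focal_and_relatives")
  if (all(present_in_some_rel_each)) return("focal_only")
  "other"
}

#' Discover candidate focal lineages from marker-family absence
#'
#' Finds the maximal monophyletic tip sets in which every genome lacks
#' every marker family (e.g. all flagellar-category families) — the
#' pattern that defines candidate convergently reduced lineages. At least
#' two such clades are needed downstream for any convergence claim.
#'
#' @param matrix Presence matrix.
#' @param tree Rooted `phylo` species tree.
#' @param marker_families Non-empty character vector of marker family ids.
#' @param min_clade_size Minimum tip count of a reported clade (default 1:
#'   single absent genomes nested in present clades are candidates too).
#' @return A list of candidates, each a list with `stem` (node id) and
#'   `tips` (genome ids); may be empty.
#' @export
discover_focal_sets <- function(matrix, tree, marker_families,
                                min_clade_size = 1) {
  if (!length(marker_families)) stop_param("marker_families must be non-empty")
  bin <- presence(matrix)
  miss <- setdiff(marker_families, colnames(bin))
  if (length(miss))
    stop_param("marker families not in the matrix: %s",
               paste(utils::head(miss, 5), collapse = ", "))
  lacking <- rownames(bin)[rowSums(bin[, marker_families, drop = FALSE]) == 0L]
  if (!length(lacking)) return(list())
  n_tip <- length(tree$tip.label)
  # all_lacking[node]: every tip below the node lacks all markers
  all_lack <- logical(n_tip + tree$Nnode)
  all_lack[seq_len(n_tip)] <- tree$tip.label %in% lacking
  kids <- node_children(tree)
  for (nd in postorder_nodes(tree))
    all_lack[nd] <- all(all_lack[kids[[nd]]])
  # maximal qualifying nodes: qualify but parent does not
  par <- node_parents(tree)
  nodes <- which(all_lack)
  maximal <- nodes[par[nodes] == 0L | !all_lack[pmax(par[nodes], 1L)]]
  out <- lapply(maximal, function(nd) {
    tips <- if (nd <= n_tip) tree$tip.label[nd]
            else tree$tip.label[extract_clade_tips(tree, nd)]
    list(stem = as.integer(nd), tips = tips)
  })
  out[vapply(out, function(x) length(x$tips), integer(1)) >= min_clade_size]
}
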