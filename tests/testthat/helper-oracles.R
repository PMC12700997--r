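# Independent brute-force oracles used to verify the package's
# implementations on small instances. These deliberately re-derive each
# quantity from its definition by exhaustive enumeration or double loops,
# sharing no code with the implementation under test.

# --- Fitch: minimum changes over ALL ancestral labelings -------------------
oracle_fitch <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  s <- as.integer(tip_states[tree$tip.label])
  labelings <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  full <- cbind(matrix(s, nrow = nrow(labelings), ncol = n_tip,
                       byrow = TRUE), labelings)
  changes <- rowSums(full[, tree$edge[, 1], drop = FALSE] !=
                       full[, tree$edge[, 2], drop = FALSE])
  min(changes)
}

# --- Dollo: single gain at the MRCA of present tips; enumerate all valid
# histories (no 0 -> 1 edge below the gain; everything outside the gain
# subtree absent) and take the minimum-loss one ----------------------------
oracle_dollo <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  s <- as.integer(tip_states[tree$tip.label])
  present <- tree$tip.label[s == 1L]
  if (!length(present)) return(list(min_losses = NA, loss_sets = list()))
  gain <- if (length(present) == 1L) match(present, tree$tip.label)
          else ape::getMRCA(tree, present)
  # nodes in the gain subtree
  in_sub <- function(nd) {
    repeat {
      if (nd == gain) return(TRUE)
      p <- tree$edge[tree$edge[, 2] == nd, 1]
      if (!length(p)) return(FALSE)
      nd <- p
    }
  }
  all_nodes <- seq_len(n_tip + tree$Nnode)
  sub_nodes <- all_nodes[vapply(all_nodes, in_sub, logical(1))]
  free <- setdiff(sub_nodes, c(seq_len(n_tip), gain))  # internal, not gain
  k <- length(free)
  grids <- if (k) as.matrix(expand.grid(rep(list(0:1), k))) else
    matrix(0L, nrow = 1, ncol = 0)
  # full node-state matrix per candidate labeling
  full <- matrix(0L, nrow = nrow(grids), ncol = n_tip + tree$Nnode)
  full[, seq_len(n_tip)] <- matrix(s, nrow = nrow(grids), ncol = n_tip,
                                   byrow = TRUE)
  full[, gain] <- 1L
  if (k) full[, free] <- grids
  edges_in <- tree$edge[tree$edge[, 1] %in% sub_nodes &
                          tree$edge[, 2] %in% sub_nodes, , drop = FALSE]
  ps <- full[, edges_in[, 1], drop = FALSE]
  cs <- full[, edges_in[, 2], drop = FALSE]
  valid <- rowSums(ps == 0L & cs == 1L) == 0L  # no regain below the gain
  loss_mat <- ps == 1L & cs == 0L
  n_losses <- rowSums(loss_mat)
  best <- min(n_losses[valid])
  arg <- which(valid & n_losses == best)
  loss_sets <- unique(lapply(arg, function(r)
    sort(edges_in[loss_mat[r, ], 2])))
  list(min_losses = best, loss_sets = loss_sets)
}

# --- independent losses: pairwise ancestry filtering ----------------------
oracle_independent <- function(events, tree) {
  is_anc <- function(a, b) {  # is a an ancestor of b
    repeat {
      p <- tree$edge[tree$edge[, 2] == b, 1]
      if (!length(p)) return(FALSE)
      if (p == a) return(TRUE)
      b <- p
    }
  }
  keep <- vapply(events, function(e)
    !any(vapply(setdiff(events, e), is_anc, logical(1), b = e)),
    logical(1))
  sum(keep)
}

# --- histogram tally from the definition ----------------------------------
oracle_bin <- function(values, width, threshold) {
  n_bins <- ceiling(threshold / width - 1e-9)
  counts <- integer(n_bins)
  overflow <- 0L
  for (v in values) {
    if (v > threshold) overflow <- overflow + 1L
    else {
      b <- min(floor(v / width) + 1L, n_bins)
      counts[b] <- counts[b] + 1L
    }
  }
  list(counts = counts, overflow = overflow)
}

# --- RBH from the definition: double loop over queries --------------------
oracle_rbh <- function(ab, ba, evalue_max = 1e-3) {
  best <- function(tab, q) {
    h <- tab[tab$query == q & tab$evalue <= evalue_max, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    h <- h[h$evalue == min(h$evalue), , drop = FALSE]
    sort(h$subject)[1]
  }
  pairs <- list()
  for (a in unique(ab$query)) {
    b <- best(ab, a)
    if (is.na(b)) next
    if (identical(best(ba, b), a))
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (!length(pairs))
    return(data.frame(a_id = character(0), b_id = character(0)))
  df <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(df) <- c("a_id", "b_id")
  df[order(df$a_id), , drop = FALSE]
}

# random directed hit table over na x nb proteins
random_hit_table <- function(na, nb, prefix_q = "a", prefix_s = "b",
                             n_hits = 4 * na) {
  data.frame(
    query = paste0(prefix_q, sample.int(na, n_hits, replace = TRUE)),
    subject = paste0(prefix_s, sample.int(nb, n_hits, replace = TRUE)),
    bitscore = round(runif(n_hits, 30, 300), 1),
    evalue = 10^runif(n_hits, -50, 0),
    stringsAsFactors = FALSE)
}

# --- adjacency / orientation counts from the definition -------------------
oracle_synteny <- function(a, b) {
  shared <- intersect(a$families, b$families)
  adj <- function(fams) {
    out <- list()
    for (i in seq_len(length(fams) - 1))
      if (fams[i] %in% shared && fams[i + 1] %in% shared)
        out[[length(out) + 1]] <- sort(c(fams[i], fams[i + 1]))
    unique(out)
  }
  pa <- adj(a$families); pb <- adj(b$families)
  n_match <- sum(vapply(pa, function(p)
    any(vapply(pb, identical, logical(1), p)), logical(1)))
  maj <- function(r) names(which.max(table(r$strands)))
  rel <- function(r, f) r$strands[match(f, r$families)] == maj(r)
  ori <- if (length(shared))
    mean(vapply(shared, function(f) rel(a, f) == rel(b, f), logical(1)))
    else 0
  list(shared = length(shared),
       adjacency = if (length(pa)) n_match / length(pa) else 0,
       orientation = ori)
}

# small random rooted binary tree with deterministic labels
random_tree <- function(n_tips) {
  ape::rcoal(n_tips, tip.label = paste0("t", seq_len(n_tips)))
}

# all 2^n binary tip-state patterns for a tree, as a list of named vectors
all_patterns <- function(tree) {
  n <- length(tree$tip.label)
  g <- as.matrix(expand.grid(rep(list(0:1), n)))
  lapply(seq_len(nrow(g)), function(i)
    stats::setNames(as.integer(g[i, ]), tree$tip.label))
}
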