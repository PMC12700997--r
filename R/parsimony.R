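# --- small utilities over rooted ape::phylo trees -------------------------

# parent of every node (0 for the root), indexed by node id
node_parents <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  par <- integer(n_node)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# children list indexed by node id
node_children <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

root_node <- function(tree) length(tree$tip.label) + 1L

# internal nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

# logical: does each node have a present (state 1) tip in its subtree
has_present_below <- function(tree, states01) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  hp <- logical(n_node)
  hp[seq_len(n_tip)] <- states01[tree$tip.label] == 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    hp[po[i, 1]] <- hp[po[i, 1]] || hp[po[i, 2]]
  hp
}

check_tip_states <- function(tree, tip_states) {
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss))
    stop_param("missing tip states (no imputation): %s",
               paste(utils::head(miss, 5), collapse = ", "))
  s <- tip_states[tree$tip.label]
  if (!all(s %in% c(0L, 1L)))
    stop_param("tip states must be 0/1")
  s
}

#' Fitch small-parsimony score with one optimal ancestral labeling
#'
#' Computes the minimum number of binary state changes needed to explain
#' the tip states on a rooted tree (Fitch parsimony), together with one
#' ancestral labeling achieving that minimum. Multifurcations are handled
#' by taking the intersection of the children's state sets when non-empty
#' and their union (counting one change) otherwise.
#'
#' @param tree A rooted `phylo` tree.
#' @param tip_states Named 0/1 vector over all tip labels; missing tips
#'   are an error.
#' @return A list: `score` (minimal change count) and `labeling` (named
#'   0/1 vector over node ids `1..Ntip+Nnode`, tips first).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_score(tr, c(A = 1, B = 1, C = 0, D = 0))$score
#' @export
fitch_score <- function(tree, tip_states) {
  s <- check_tip_states(tree, tip_states)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  mask <- integer(n_node)
  mask[seq_len(n_tip)] <- ifelse(s == 1L, 2L, 1L)
  kids <- node_children(tree)
  score <- 0L
  for (nd in postorder_nodes(tree)) {
    ch <- kids[[nd]]
    inter <- Reduce(bitwAnd, mask[ch])
    if (inter != 0L) {
      mask[nd] <- inter
    } else {
      mask[nd] <- Reduce(bitwOr, mask[ch])
      score <- score + 1L
    }
  }
  # top-down refinement: keep the parent's state when allowed
  lab <- integer(n_node)
  rt <- root_node(tree)
  lab[rt] <- if (bitwAnd(mask[rt], 2L)) 1L else 0L
  pre <- rev(postorder_nodes(tree))
  for (nd in pre) {
    for (ch in kids[[nd]]) {
      want <- bitwShiftL(1L, lab[nd])
      lab[ch] <- if (bitwAnd(mask[ch], want)) lab[nd]
                 else if (bitwAnd(mask[ch], 2L)) 1L else 0L
    }
  }
  names(lab) <- c(tree$tip.label, rep(NA, tree$Nnode))
  list(score = score, labeling = lab)
}

#' Dollo parsimony loss events for one gene family
#'
#' Under the Dollo model (a single gain, any number of losses), places the
#' gain at the most recent common ancestor of the present tips and returns
#' the unique minimal set of loss edges below it: each loss edge is the
#' stem of a maximal subtree containing no present tip, so no reported
#' event is nested under another.
#'
#' @param tree A rooted `phylo` tree.
#' @param tip_states Named 0/1 vector over all tip labels.
#' @return A list: `events` (integer vector of loss-edge child node ids,
#'   possibly empty), `gain_node` (node id, `NA` if never gained), and
#'   `flag` (`"ok"` or `"never_gained"` when no tip is present).
#' @export
dollo_losses <- function(tree, tip_states) {
  s <- check_tip_states(tree, tip_states)
  present <- tree$tip.label[s == 1L]
  if (!length(present))
    return(list(events = integer(0), gain_node = NA_integer_,
                flag = "never_gained"))
  gain <- if (length(present) == 1L) {
    match(present, tree$tip.label)
  } else {
    ape::getMRCA(tree, present)
  }
  hp <- has_present_below(tree, s)
  # nodes strictly below the gain whose subtree has no present tip but
  # whose parent still does: stems of maximal absent subtrees
  par <- node_parents(tree)
  below <- descendants_of(tree, gain)
  ev <- below[!hp[below] & hp[par[below]]]
  list(events = sort(ev), gain_node = as.integer(gain), flag = "ok")
}

# all node ids strictly below `node`
descendants_of <- function(tree, node) {
  kids <- node_children(tree)
  out <- integer(0)
  stack <- kids[[node]]
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, nd)
    if (!is.null(kids[[nd]])) stack <- c(stack, kids[[nd]])
  }
  out
}

#' Count phylogenetically independent loss events
#'
#' Collapses ancestor-descendant pairs among loss-edge events: an event
#' nested inside the subtree of another is not an independent loss. For
#' [dollo_losses()] output the events are incomparable by construction,
#' so the count equals the event count (asserted here).
#'
#' @param events Integer vector of loss-edge child node ids (one family).
#' @param tree The rooted `phylo` tree the events refer to.
#' @return Number of independent losses.
#' @export
independent_loss_count <- function(events, tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  events <- as.integer(events)
  if (any(events < 1L | events > n_node))
    stop_param("events reference unknown node ids")
  if (!length(events)) return(0L)
  par <- node_parents(tree)
  has_anc_event <- vapply(events, function(nd) {
    p <- par[nd]
    while (p != 0L) {
      if (p %in% events) return(TRUE)
      p <- par[p]
    }
    FALSE
  }, logical(1))
  sum(!has_anc_event)
}
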