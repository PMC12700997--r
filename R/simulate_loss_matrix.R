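#' Specification of a planted convergent-loss experiment
#'
#' Parameters for [simulate_loss_matrix()], which generates a random rooted
#' species tree plus a genome-by-family presence/absence matrix in which a
#' module of gene families has been deleted from every tip of two or more
#' non-overlapping focal clades — the signature of convergent loss — over a
#' background of conserved and sporadically lost families.
#'
#' @param n_tips Number of tips (genomes) when the tree is generated.
#' @param n_background_families Number of background families.
#' @param background_conservation Per-tip presence probability of a
#'   background family, in `(0, 1]`.
#' @param sporadic_loss_rate Probability that a present background cell is
#'   flipped absent, in `[0, 1)`.
#' @param focal_clades Number of planted focal clades (>= 1).
#' @param module_size Number of families in the planted co-lost module
#'   (0 gives a pure background matrix).
#' @param clade_size_min,clade_size_max Allowed focal-clade tip counts;
#'   defaults pick small clades (3 tips up to ~5% of the tree) so focal
#'   lineages stay a minority of genomes.
#' @param noise_on_module If `TRUE`, sporadic loss noise is also applied to
#'   module families outside the focal clades (for robustness experiments);
#'   default `FALSE` keeps the planted truth exact.
#' @param seed Integer seed.
#' @return A validated list of class `planted_loss_spec`.
#' @export
planted_loss_spec <- function(n_tips = 200,
                              n_background_families = 2000,
                              background_conservation = 1,
                              sporadic_loss_rate = 0,
                              focal_clades = 2,
                              module_size = 26,
                              clade_size_min = 3,
                              clade_size_max = max(3L, n_tips %/% 20L),
                              noise_on_module = FALSE,
                              seed = 1L) {
  if (n_tips < 4) stop_param("n_tips must be >= 4")
  if (background_conservation <= 0 || background_conservation > 1)
    stop_param("background_conservation must lie in (0, 1]")
  if (sporadic_loss_rate < 0 || sporadic_loss_rate >= 1)
    stop_param("sporadic_loss_rate must lie in [0, 1)")
  if (focal_clades < 1) stop_param("focal_clades must be >= 1")
  if (module_size < 0) stop_param("module_size must be >= 0")
  if (clade_size_min < 1 || clade_size_max < clade_size_min)
    stop_param("invalid clade size range")
  p <- list(n_tips = n_tips,
            n_background_families = n_background_families,
            background_conservation = background_conservation,
            sporadic_loss_rate = sporadic_loss_rate,
            focal_clades = focal_clades,
            module_size = module_size,
            clade_size_min = clade_size_min,
            clade_size_max = clade_size_max,
            noise_on_module = noise_on_module,
            seed = seed)
  class(p) <- "planted_loss_spec"
  p
}

# tip sets of every internal node (node id -> tip labels)
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  sets <- lapply(nodes, function(nd) {
    tips <- extract_clade_tips(tree, nd)
    tree$tip.label[tips]
  })
  names(sets) <- as.character(nodes)
  sets
}

# tip indices below a node, iterative post-order expansion
extract_clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd <= n_tip) {
      tips <- c(tips, nd)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
    }
  }
  sort(tips)
}

# choose `k` pairwise disjoint clades with sizes in [smin, smax];
# NULL if impossible for this topology
pick_disjoint_clades <- function(tree, k, smin, smax) {
  sets <- clade_tip_sets(tree)
  sizes <- lengths(sets)
  cand <- names(sets)[sizes >= smin & sizes <= smax]
  if (length(cand) < k) return(NULL)
  cand <- sample(cand)
  chosen <- character(0)
  used <- character(0)
  for (nd in cand) {
    if (!length(intersect(sets[[nd]], used))) {
      chosen <- c(chosen, nd)
      used <- c(used, sets[[nd]])
      if (length(chosen) == k) break
    }
  }
  if (length(chosen) < k) return(NULL)
  list(stems = as.integer(chosen), tip_sets = sets[chosen])
}

#' Simulate a tree with a planted convergently lost gene module
#'
#' Generates (or accepts) a rooted species tree, selects non-overlapping
#' focal clades, and builds a binary presence/absence matrix: background
#' families are present per tip with probability `background_conservation`
#' and then sporadically flipped absent; module families are present
#' everywhere except in every tip of every focal clade. The planted truth
#' (module family ids, focal clade stems and tip sets) is returned
#' alongside, so downstream screens can be scored exactly.
#'
#' @param spec A [planted_loss_spec()].
#' @param tree Optional rooted `phylo` tree to use instead of generating a
#'   coalescent tree; focal clades must then be selectable from its
#'   topology (error otherwise). When the tree is generated internally,
#'   topologies without selectable disjoint clades are redrawn.
#' @return A list with elements `tree` (rooted `phylo`), `matrix` (integer
#'   0/1 matrix, rows = genomes, columns = families), and `truth` (list:
#'   `module_families`, `focal_stems`, `focal_tips`).
#' @examples
#' sim <- simulate_loss_matrix(planted_loss_spec(n_tips = 30,
#'   n_background_families = 50, module_size = 5, seed = 7))
#' dim(sim$matrix)
#' @export
simulate_loss_matrix <- function(spec, tree = NULL) {
  stopifnot(inherits(spec, "planted_loss_spec"))
  with_seed(spec$seed, {
    user_tree <- !is.null(tree)
    pick <- NULL
    for (attempt in seq_len(if (user_tree) 1L else 100L)) {
      if (!user_tree) {
        tree <- ape::rcoal(spec$n_tips,
                           tip.label = sprintf("g%03d", seq_len(spec$n_tips)))
      } else if (is.null(tree$tip.label) || anyDuplicated(tree$tip.label)) {
        stop_param("supplied tree must have unique tip labels")
      }
      pick <- pick_disjoint_clades(tree, spec$focal_clades,
                                   spec$clade_size_min, spec$clade_size_max)
      if (!is.null(pick)) break
    }
    if (is.null(pick))
      stop_param("could not select %d disjoint focal clades with %d-%d tips",
                 spec$focal_clades, spec$clade_size_min, spec$clade_size_max)

    genomes <- tree$tip.label
    n_g <- length(genomes)
    focal_tips <- pick$tip_sets
    focal_all <- unlist(focal_tips, use.names = FALSE)

    n_bg <- spec$n_background_families
    bg_ids <- if (n_bg > 0) sprintf("bg%04d", seq_len(n_bg)) else character(0)
    mod_ids <- if (spec$module_size > 0)
      sprintf("mod%02d", seq_len(spec$module_size)) else character(0)

    mat <- matrix(0L, nrow = n_g, ncol = n_bg + length(mod_ids),
                  dimnames = list(genomes, c(bg_ids, mod_ids)))
    if (n_bg > 0) {
      bg <- matrix(rbinom(n_g * n_bg, 1L, spec$background_conservation),
                   nrow = n_g)
      if (spec$sporadic_loss_rate > 0) {
        flip <- matrix(rbinom(n_g * n_bg, 1L, spec$sporadic_loss_rate),
                       nrow = n_g)
        bg <- bg * (1L - flip)
      }
      mat[, bg_ids] <- bg
    }
    if (length(mod_ids)) {
      mod <- matrix(1L, nrow = n_g, ncol = length(mod_ids))
      mod[genomes %in% focal_all, ] <- 0L
      if (spec$noise_on_module && spec$sporadic_loss_rate > 0) {
        flip <- matrix(rbinom(n_g * length(mod_ids), 1L,
                              spec$sporadic_loss_rate), nrow = n_g)
        mod <- mod * (1L - flip)
      }
      mat[, mod_ids] <- mod
    }

    list(tree = tree,
         matrix = mat,
         truth = list(module_families = mod_ids,
                      focal_stems = pick$stems,
                      focal_tips = focal_tips))
  })
}
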