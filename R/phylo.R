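# Discrete-character mapping on phylogenies: generalized Fitch parsimony
# (multifurcation-safe), a tip-permutation test of phylogenetic clustering,
# and pattern-by-habitat concordance.

#' Parse a newick tree
#'
#' Thin wrapper over \code{ape::read.tree} adding the checks this package
#' relies on: at least two uniquely labeled tips. Branch lengths are ignored
#' by all parsimony computations. Multifurcations are accepted.
#'
#' @param text newick string or path to a newick file
#' @return an \code{ape::phylo} tree
#' @export
parse_newick <- function(text) {
  tr <- if (length(text) == 1 && !grepl("[();]", text) && file.exists(text)) {
    ape::read.tree(text)
  } else {
    ape::read.tree(text = paste(text, collapse = ""))
  }
  if (is.null(tr)) stop("could not parse newick input")
  if (ape::Ntip(tr) < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

.tip_states <- function(tree, states) {
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    stop("no character state for tip(s): ", paste(miss, collapse = ", "))
  }
  as.character(states[tree$tip.label])
}

#' Minimum state changes of a discrete character on a tree
#'
#' Generalized (Hartigan-style) Fitch parsimony: a postorder pass assigns to
#' each internal node the set of states attaining the maximum vote count
#' among its children's sets, adding (number of children - maximum count)
#' changes; this yields the exact minimum number of state changes on rooted
#' trees with multifurcations.
#'
#' @param tree an \code{ape::phylo} tree (rooted; multifurcations allowed)
#' @param states named character vector mapping every tip label to a state
#' @return list of class \code{parsimony_result}: \code{steps} (integer
#'   minimum changes) and \code{node_sets} (list of candidate ancestral state
#'   sets per internal node, indexed by ape node number)
#' @export
fitch_parsimony <- function(tree, states) {
  x <- .tip_states(tree, states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- x[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  steps <- 0L
  parents <- unique(edge[, 1])  # postorder: children before parents
  for (p in parents) {
    kids <- edge[edge[, 1] == p, 2]
    votes <- table(unlist(lapply(kids, function(k) unique(sets[[k]]))))
    mx <- max(votes)
    sets[[p]] <- names(votes)[votes == mx]
    steps <- steps + length(kids) - mx
  }
  node_sets <- sets[(ntip + 1):(ntip + nnode)]
  names(node_sets) <- as.character((ntip + 1):(ntip + nnode))
  structure(list(steps = as.integer(steps), node_sets = node_sets),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> minimum steps:", x$steps, "\n")
  invisible(x)
}

#' Tip-permutation test of phylogenetic clustering of a character
#'
#' Tests whether the observed character requires fewer parsimony steps than
#' expected if states were shuffled at random across tips: p = (1 + number of
#' permutations with steps <= observed) / (1 + n_perm). Small p indicates the
#' states are phylogenetically clustered.
#'
#' @param tree an \code{ape::phylo} tree
#' @param states named character vector of tip states
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed; the test is reproducible for a fixed seed and
#'   leaves the global RNG state untouched
#' @return list: p_value, observed_steps, n_perm, permuted_steps
#' @export
tip_permutation_test <- function(tree, states, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  x <- .tip_states(tree, states)
  if (length(unique(x)) < 2) {
    warning("constant character: no clustering signal is possible")
    return(list(p_value = 1, observed_steps = 0L, n_perm = n_perm,
                permuted_steps = rep(0L, n_perm)))
  }
  obs <- fitch_parsimony(tree, stats::setNames(x, tree$tip.label))$steps
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    fitch_parsimony(tree, stats::setNames(sample(x), tree$tip.label))$steps
  }, integer(1))
  list(p_value = (1 + sum(perm <= obs)) / (1 + n_perm),
       observed_steps = obs, n_perm = n_perm, permuted_steps = perm)
}

#' Concordance between two tip characters
#'
#' Cross-tabulates two characters (e.g. rearrangement pattern by habitat
#' depth class) over their shared tips and flags perfect association: every
#' state of the first character co-occurring with exactly one state of the
#' second.
#'
#' @param c1,c2 named character vectors (tip -> state)
#' @return list: \code{table} (contingency table, c1 states in rows),
#'   \code{perfect_association} (logical), \code{tips} (shared tips used)
#' @export
character_concordance <- function(c1, c2) {
  shared <- intersect(names(c1), names(c2))
  if (length(shared) == 0) stop("character maps share no tips")
  tab <- table(c1 = as.character(c1[shared]), c2 = as.character(c2[shared]))
  perfect <- all(rowSums(tab > 0) == 1)
  list(table = tab, perfect_association = perfect, tips = shared)
}
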