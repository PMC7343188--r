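#' Simulate a continuous trait evolving by Brownian motion on a tree
#'
#' Starting from `root_value`, each child node's value is its parent's value
#' plus Normal(0, sigma2 * branch length). All node values (internal and
#' tip) are returned so reconstruction methods can be scored against truth.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param root_value trait value at the root.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param seed optional integer seed.
#' @return list with `tips` (named by tip label), `nodes` (internal nodes,
#'   named by ape node number) and `all` (full node-value vector).
#' @export
simulate_tree_tips <- function(tree, root_value = 0, sigma2 = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length")
  if (sigma2 < 0) stopf("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- reorder(tree, "cladewise")  # parents precede children
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  val <- numeric(ntip + nnode)
  root <- ntip + 1L
  val[root] <- root_value
  eps <- rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
  for (e in seq_len(nrow(tr$edge)))
    val[tr$edge[e, 2L]] <- val[tr$edge[e, 1L]] + eps[e]
  tips <- setNames(val[seq_len(ntip)], tr$tip.label)
  nodes <- setNames(val[(ntip + 1L):(ntip + nnode)], as.character((ntip + 1L):(ntip + nnode)))
  list(tips = tips, nodes = nodes, all = val)
}
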