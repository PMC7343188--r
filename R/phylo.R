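#' Read and validate a Newick tree
#'
#' Thin wrapper over ape's parser that enforces the contract the comparative
#' methods need: branch lengths present and non-negative, tip labels unique.
#' Polytomies are allowed.
#'
#' @param path Newick file path.
#' @return an ape `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse Newick file %s", path)
  if (is.null(tr$edge.length)) stopf("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stopf("negative branch length")
  if (anyDuplicated(tr$tip.label)) stopf("duplicate tip label(s): %s",
    paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree to Newick, optionally with node labels
#' @param tree a `phylo`.
#' @param path output path.
#' @param node_labels optional character vector of internal node labels.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, node_labels = NULL) {
  if (!is.null(node_labels)) tree$node.label <- node_labels
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Maximum-likelihood Brownian-motion ancestral state reconstruction
#'
#' Estimates the trait value at every internal node of a rooted tree under
#' Brownian motion, by Gaussian message passing (belief propagation) along
#' the tree: each node's estimate is the inverse-path-variance weighted
#' combination of the information arriving from all its neighbours, which
#' equals the GLS root estimate of the tree re-rooted at that node. The rate
#' sigma^2 is estimated by ML (`Q/n`, with `Q` the contrast sum of squares)
#' or REML (`Q/(n-1)`); node variances are `sigma2 * v_node` with `v_node`
#' the combined message variance, and the 95% CI is `estimate +/- 1.96 * sqrt(var)`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @param method `"ML"` (default) or `"REML"` for sigma^2.
#' @return list with `estimates` (data.table `node`, `estimate`, `variance`,
#'   `ci_lo`, `ci_hi`), `sigma2`, `root` (root estimate), `method`.
#' @export
asr_bm <- function(tree, tip_values, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stopf("need at least 2 tips")
  if (is.null(names(tip_values)) || !all(tree$tip.label %in% names(tip_values)))
    stopf("tip_values must be named and cover every tip")
  if (any(tree$edge.length <= 0)) stopf("branch lengths must be > 0")
  x <- unname(tip_values[tree$tip.label])
  nnode <- tree$Nnode
  root <- ntip + 1L
  parent <- integer(ntip + nnode); parent[root] <- NA_integer_
  blen <- numeric(ntip + nnode)
  children <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    parent[c] <- p; blen[c] <- tree$edge.length[e]
    children[[p]] <- c(children[[p]], c)
  }
  post <- rev(unique(reorder(tree, "cladewise")$edge[, 1L]))  # leaves-first internal order
  # upward pass: message from each node towards its parent
  up_m <- numeric(ntip + nnode); up_v <- numeric(ntip + nnode)
  up_m[seq_len(ntip)] <- x; up_v[seq_len(ntip)] <- 0
  Q <- 0
  for (nd in post) {
    ch <- children[[nd]]
    m <- up_m[ch[1L]]; v <- up_v[ch[1L]] + blen[ch[1L]]
    for (j in ch[-1L]) {
      mj <- up_m[j]; vj <- up_v[j] + blen[j]
      Q <- Q + (m - mj)^2 / (v + vj)
      w <- 1 / v + 1 / vj
      m <- (m / v + mj / vj) / w
      v <- 1 / w
    }
    up_m[nd] <- m; up_v[nd] <- v
  }
  sigma2 <- Q / if (method == "ML") ntip else ntip - 1L
  # downward pass: message from the parent side into each node
  down_m <- rep(NA_real_, ntip + nnode); down_v <- rep(Inf, ntip + nnode)
  pre <- unique(reorder(tree, "cladewise")$edge[, 1L])  # root-first internal order
  for (nd in pre) {
    ch <- children[[nd]]
    for (cc in ch) {
      # combine parent-side message at nd with nd's other children
      m <- down_m[nd]; v <- down_v[nd]
      for (j in setdiff(ch, cc)) {
        mj <- up_m[j]; vj <- up_v[j] + blen[j]
        if (is.infinite(v)) { m <- mj; v <- vj }
        else { w <- 1 / v + 1 / vj; m <- (m / v + mj / vj) / w; v <- 1 / w }
      }
      down_m[cc] <- m; down_v[cc] <- v + blen[cc]
    }
  }
  nodes <- root:(ntip + nnode)
  est <- vv <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    msgs_m <- up_m[children[[nd]]]
    msgs_v <- up_v[children[[nd]]] + blen[children[[nd]]]
    if (!is.infinite(down_v[nd])) {
      msgs_m <- c(msgs_m, down_m[nd]); msgs_v <- c(msgs_v, down_v[nd])
    }
    w <- 1 / msgs_v
    est[i] <- sum(w * msgs_m) / sum(w)
    vv[i] <- 1 / sum(w)
  }
  variance <- sigma2 * vv
  half <- 1.96 * sqrt(variance)
  estimates <- data.table(node = nodes, estimate = est, variance = variance,
                          ci_lo = est - half, ci_hi = est + half)
  list(estimates = estimates, sigma2 = sigma2,
       root = est[1L], method = method)
}

#' Phylogenetic generalized least squares regression
#'
#' GLS with residual covariance `sigma2 * C`, where `C[i, j]` is the shared
#' path length from the root to the most recent common ancestor of tips i
#' and j (the Brownian-motion covariance). Coefficient t-tests use `n - k`
#' degrees of freedom. This is the deterministic ML counterpart of a
#' Bayesian phylogenetic mixed model with the same covariance structure.
#'
#' @param formula model formula.
#' @param data data.frame with one row per tip; rownames (or a `tip` column)
#'   identify tips.
#' @param tree a rooted `phylo` covering every data row.
#' @return list with `coefficients` (data.table `term`, `estimate`, `se`,
#'   `t`, `p`), `sigma2`, `df`, `n`, `logdetC`.
#' @export
pgls <- function(formula, data, tree) {
  tips <- if ("tip" %in% names(data)) as.character(data$tip) else rownames(data)
  if (is.null(tips) || !all(tips %in% tree$tip.label))
    stopf("data rows must match tree tips (rownames or a `tip` column)")
  C <- ape::vcv(tree)[tips, tips]
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  n <- nrow(X); k <- ncol(X)
  if (qr(X)$rank < k) stopf("design matrix is rank deficient")
  if (n <= k) stopf("more coefficients than tips")
  L <- chol(C)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  res <- ys - Xs %*% beta
  sigma2 <- sum(res^2) / (n - k)
  covB <- sigma2 * solve(XtX)
  se <- sqrt(diag(covB))
  tval <- beta[, 1L] / se
  pval <- 2 * pt(-abs(tval), n - k)
  list(coefficients = data.table(term = colnames(X), estimate = beta[, 1L],
                                 se = se, t = tval, p = pval),
       sigma2 = sigma2, df = n - k, n = n, logdetC = 2 * sum(log(diag(L))))
}
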