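# Shared fixtures and independent oracles, built in code at test time.

# Rescale a tree to unit root-to-tip height (so simulated rate matrices are on
# the same scale the sampler reports).
unit_height <- function(tree) {
  h <- max(ape::vcv.phylo(tree)[cbind(seq_along(tree$tip.label),
                                      seq_along(tree$tip.label))])
  tree$edge.length <- tree$edge.length / h
  tree
}

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr
}

# --- brute-force tree oracles (independent of package internals) ------------

# Path of node ids from a tip up to the root.
oracle_root_path <- function(tree, tip_idx) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- tip_idx
  nd <- tip_idx
  root <- length(tree$tip.label) + 1L
  while (nd != root) {
    nd <- parent[nd]
    path <- c(path, nd)
  }
  path
}

# Shared root-to-MRCA path length of two tips by naive path enumeration.
oracle_shared_path <- function(tree, i, j) {
  depth <- numeric(max(tree$edge))
  for (r in seq_len(nrow(tree$edge)))
    depth[tree$edge[r, 2]] <- NA
  # compute depths by walking down from the root
  root <- length(tree$tip.label) + 1L
  depth[root] <- 0
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + tree$edge.length[r]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  common <- intersect(oracle_root_path(tree, i), oracle_root_path(tree, j))
  max(depth[common])
}

# All tips descending from a node, by naive edge recursion.
oracle_descendant_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  sort(unlist(lapply(kids, function(k) oracle_descendant_tips(tree, k))))
}

# Monophyly by brute force: MRCA as the deepest common node of all members'
# root paths, then exact descendant-set comparison.
oracle_is_monophyletic <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  paths <- lapply(idx, function(i) oracle_root_path(tree, i))
  common <- Reduce(intersect, paths)
  # deepest common node = the one whose own root path is longest
  depths <- vapply(common, function(nd)
    length(oracle_root_path_node(tree, nd)), numeric(1))
  mrca <- common[which.max(depths)]
  setequal(oracle_descendant_tips(tree, mrca), sort(idx))
}

oracle_root_path_node <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  path <- node
  while (node != root) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

# Clade (tip-set) keys of all internal edges of a tree.
oracle_clade_keys <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- unique(tree$edge[, 2])
  nodes <- nodes[nodes > n]
  vapply(nodes, function(nd)
    paste(sort(tree$tip.label[oracle_descendant_tips(tree, nd)]),
          collapse = "|"), character(1))
}

# Random symmetric PSD matrix.
random_psd <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(k * k), k)
  crossprod(M) + 0.1 * diag(k)
}

# Noisy posterior around a fixed matrix: Wishart draws with mean R.
noisy_posterior <- function(R, n = 50, df = 500, term = "term", seed = 1) {
  set.seed(seed)
  k <- nrow(R)
  arr <- stats::rWishart(n, df = df, Sigma = R / df)
  rate_posterior(arr, term = term)
}
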