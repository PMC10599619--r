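# Phylogenetic covariance structure and the consensus tree of a tree set.

#' Shared-path-length (phylogenetic) covariance matrix
#'
#' Entry (i, j) is the root-to-MRCA path length shared by tips i and j; the
#' diagonal holds root-to-tip depths. This is the covariance structure a
#' Brownian process on the tree induces on tip values.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tips optional subset of tip labels (order preserved).
#' @param scale_height if `TRUE`, divide by the maximum root-to-tip depth so
#'   rate matrices estimated against the structure are comparable across trees.
#' @return symmetric PSD matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, tips = NULL, scale_height = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  A <- ape::vcv.phylo(tree)
  if (!is.null(tips)) {
    bad <- setdiff(tips, rownames(A))
    if (length(bad)) stop("unknown tips: ", paste(bad, collapse = ", "))
    A <- A[tips, tips, drop = FALSE]
  }
  if (scale_height) A <- A / max(diag(A))
  A
}

#' Majority-rule consensus tree with averaged branch lengths
#'
#' Topology is the rooted majority-rule consensus of the set; each retained
#' clade's subtending branch length is the mean over the trees containing that
#' clade, and tip branch lengths are means over all trees. Polytomies are
#' resolved deterministically (in tip-label order) with zero-length edges.
#'
#' @param tree_set a `multiPhylo` or list of `phylo` objects sharing a tip set.
#' @return a rooted, bifurcating `phylo`.
#' @export
consensus_tree <- function(tree_set) {
  if (inherits(tree_set, "phylo")) return(tree_set)
  if (length(tree_set) == 0) stop("empty tree set")
  tree_set <- lapply(tree_set, identity)
  tips0 <- sort(tree_set[[1]]$tip.label)
  for (tr in tree_set)
    if (!identical(sort(tr$tip.label), tips0))
      stop("all trees must share the same tip set")
  if (length(tree_set) == 1) return(tree_set[[1]])

  class(tree_set) <- "multiPhylo"
  cons <- ape::consensus(tree_set, p = 0.5, rooted = TRUE)
  cons <- ape::multi2di(cons, random = FALSE)
  cons <- ape::reorder.phylo(cons, "cladewise")

  # clade key -> average branch length over trees containing the clade
  edge_table <- function(tr) {
    sets <- node_tip_sets(tr)
    keys <- vapply(tr$edge[, 2], function(nd)
      paste(sort(tr$tip.label[sets[[nd]]]), collapse = "|"), character(1))
    stats::setNames(tr$edge.length, keys)
  }
  tabs <- lapply(tree_set, edge_table)
  sets_c <- node_tip_sets(cons)
  elen <- numeric(nrow(cons$edge))
  for (r in seq_len(nrow(cons$edge))) {
    key <- paste(sort(cons$tip.label[sets_c[[cons$edge[r, 2]]]]), collapse = "|")
    vals <- unlist(lapply(tabs, function(tb) unname(tb[key])))
    vals <- vals[!is.na(vals)]
    elen[r] <- if (length(vals)) mean(vals) else 0
  }
  cons$edge.length <- elen
  cons
}
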