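# File interfaces: Newick trees, delimited trait and hierarchy tables, with
# strict cross-validation of labels.

#' Read one or several trees from a Newick file
#'
#' @param path Newick file; multi-tree files yield a `multiPhylo` whose trees
#'   are checked for a shared tip set.
#' @return `phylo` or `multiPhylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("malformed Newick in ", path, ": ",
                                             conditionMessage(e)))
  if (is.null(trees)) stop("malformed Newick in ", path)
  if (inherits(trees, "multiPhylo")) {
    tips0 <- sort(trees[[1]]$tip.label)
    for (i in seq_along(trees))
      if (!identical(sort(trees[[i]]$tip.label), tips0))
        stop("tree ", i, " in ", path, " has a different tip set")
  }
  trees
}

#' Write a tree or tree set to Newick
#' @param tree `phylo` or `multiPhylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read a species x traits table
#'
#' Delimited text with a header; the `label` column (default: the first)
#' holds tip labels, all remaining columns must be numeric.
#'
#' @param path CSV/TSV file (delimiter sniffed from the extension).
#' @param label_col name or index of the label column.
#' @return numeric matrix with tip labels as rownames.
#' @export
read_traits <- function(path, label_col = 1L) {
  d <- utils::read.csv(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                       check.names = FALSE, comment.char = "#")
  labs <- as.character(d[[label_col]])
  d[[label_col]] <- NULL
  X <- as.matrix(d)
  if (!is.numeric(X)) stop("non-numeric trait columns in ", path)
  if (anyNA(X)) stop("missing trait values in ", path)
  if (anyDuplicated(labs)) stop("duplicate tip labels in ", path)
  rownames(X) <- labs
  X
}

#' Write a trait matrix with a label key column
#' @param traits matrix with rownames.
#' @param path output CSV.
#' @export
write_traits <- function(traits, path) {
  d <- data.frame(label = rownames(traits), as.data.frame(unclass(traits)),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a clade hierarchy table
#'
#' Delimited text: a label column followed by one column per level holding
#' clade labels (empty or NA for unassigned tips).
#'
#' @param path CSV file.
#' @param min_size strict clade-size threshold passed to [clade_hierarchy()].
#' @return a [clade_hierarchy()].
#' @export
read_hierarchy <- function(path, min_size = 15L) {
  d <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                       stringsAsFactors = FALSE)
  for (j in 2:ncol(d)) d[[j]][d[[j]] %in% c("", "NA")] <- NA
  clade_hierarchy(d, min_size = min_size)
}

#' Cross-validate tree, traits and hierarchy labels
#'
#' @param tree `phylo`.
#' @param traits matrix with tip-label rownames.
#' @param hierarchy optional [clade_hierarchy()].
#' @return invisibly `TRUE`; errors list every offending label.
#' @export
validate_inputs <- function(tree, traits, hierarchy = NULL) {
  extra <- setdiff(rownames(traits), tree$tip.label)
  if (length(extra))
    stop("trait rows absent from the tree: ", paste(extra, collapse = ", "))
  missing <- setdiff(tree$tip.label, rownames(traits))
  if (length(missing))
    stop("tree tips without trait rows: ", paste(missing, collapse = ", "))
  if (!is.null(hierarchy)) validate_hierarchy(tree, hierarchy)
  invisible(TRUE)
}
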