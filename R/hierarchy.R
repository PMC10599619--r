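#' Nested clade hierarchy
#'
#' A clade hierarchy assigns tips to nested monophyletic groups at one or more
#' levels (level 1 playing the role of superorders, level 2 the role of orders
#' nested within them). Level 0 is always the whole tree and is implicit.
#'
#' @param assignment data frame whose first column holds tip labels and whose
#'   remaining columns (`level1`, `level2`, ...) hold clade labels, `NA` for
#'   tips outside any modeled clade at that level.
#' @param min_size clades must contain strictly more than `min_size` tips to be
#'   modeled (the analysis convention is clades with more than 15 species; the
#'   default here follows it).
#' @return an object of class `clade_hierarchy` with elements `assignment`,
#'   `levels` (named list per level of clade -> tip labels) and `min_size`.
#' @export
clade_hierarchy <- function(assignment, min_size = 15L) {
  stopifnot(is.data.frame(assignment), ncol(assignment) >= 2)
  tips <- as.character(assignment[[1]])
  if (anyDuplicated(tips)) stop("tip labels in hierarchy must be unique")
  lv_cols <- names(assignment)[-1]
  levels <- lapply(lv_cols, function(cl) {
    a <- assignment[[cl]]
    split(tips[!is.na(a)], as.character(a[!is.na(a)]))
  })
  names(levels) <- lv_cols
  for (lv in names(levels))
    for (cl in names(levels[[lv]]))
      if (length(levels[[lv]][[cl]]) <= min_size)
        stop(sprintf("clade '%s' at %s has %d tips; more than min_size = %d required",
                     cl, lv, length(levels[[lv]][[cl]]), min_size))
  structure(list(assignment = assignment, levels = levels,
                 min_size = as.integer(min_size)),
            class = "clade_hierarchy")
}

#' @export
print.clade_hierarchy <- function(x, ...) {
  cat("Clade hierarchy:", nrow(x$assignment), "tips\n")
  for (lv in names(x$levels)) {
    sz <- vapply(x$levels[[lv]], length, integer(1))
    cat(" ", lv, ": ", length(sz), " clade(s) [",
        paste0(names(sz), " (n=", sz, ")", collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Test whether a tip set is monophyletic on a tree
#'
#' A set of tips is monophyletic when it equals the full descendant tip set of
#' its most recent common ancestor.
#'
#' @param tree a rooted `phylo` object.
#' @param tips character vector of tip labels.
#' @return logical scalar.
#' @export
is_monophyletic_set <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tips: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == length(tree$tip.label)) return(TRUE)
  if (length(idx) == 1) return(TRUE)
  mrca <- ape::getMRCA(tree, idx)
  sets <- node_tip_sets(tree)
  setequal(sets[[mrca]], idx)
}

#' Validate a hierarchy against a tree
#'
#' Checks label agreement, monophyly of every clade at every level, disjointness
#' within levels, and nesting of deeper levels inside shallower ones.
#'
#' @inheritParams is_monophyletic_set
#' @param hierarchy a [clade_hierarchy()].
#' @return invisibly `TRUE`; otherwise an error naming the offending clade.
#' @export
validate_hierarchy <- function(tree, hierarchy) {
  tips <- as.character(hierarchy$assignment[[1]])
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("hierarchy tips absent from tree: ", paste(missing, collapse = ", "))
  prev <- NULL
  for (lv in names(hierarchy$levels)) {
    clades <- hierarchy$levels[[lv]]
    all_members <- unlist(clades, use.names = FALSE)
    if (anyDuplicated(all_members))
      stop("clades within ", lv, " are not disjoint")
    for (cl in names(clades)) {
      if (!is_monophyletic_set(tree, clades[[cl]]))
        stop(sprintf("clade '%s' (%s) is not monophyletic on the tree", cl, lv))
      if (!is.null(prev)) {
        inside <- vapply(prev, function(p) all(clades[[cl]] %in% p), logical(1))
        if (!any(inside))
          stop(sprintf("clade '%s' (%s) is not nested inside any clade of the previous level", cl, lv))
      }
    }
    prev <- clades
  }
  invisible(TRUE)
}

# Parent clade label of a clade: the containing clade one level up, or
# "phylogeny" (the class-wide term) for level-1 clades.
parent_clade <- function(hierarchy, clade) {
  lvs <- names(hierarchy$levels)
  for (i in seq_along(lvs)) {
    if (clade %in% names(hierarchy$levels[[i]])) {
      if (i == 1) return("phylogeny")
      members <- hierarchy$levels[[i]][[clade]]
      up <- hierarchy$levels[[i - 1]]
      for (cl in names(up)) if (all(members %in% up[[cl]])) return(cl)
      return("phylogeny")
    }
  }
  stop("clade not found in hierarchy: ", clade)
}

# All modeled clade names, shallow to deep.
hierarchy_clades <- function(hierarchy) {
  unlist(lapply(hierarchy$levels, names), use.names = FALSE)
}

clade_members <- function(hierarchy, clade) {
  for (lv in hierarchy$levels)
    if (clade %in% names(lv)) return(lv[[clade]])
  stop("clade not found in hierarchy: ", clade)
}
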