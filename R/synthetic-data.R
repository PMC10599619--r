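# Synthetic-data module: trees, nested clade structures and multivariate
# traits generated under the same statistical structure the nested phylogenetic
# mixed model assumes, with recorded ground truth for recovery tests.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation of a pure-birth process: starting from the root split
#' (two lineages), waiting times between speciation events are exponential with
#' rate `birth_rate` times the current number of lineages, and a uniformly
#' chosen lineage splits at each event. After the `n_tips`-th lineage appears
#' the tree is extended by one further exponential waiting time so that tip
#' branches have positive length; all tips end at the same age (ultrametric).
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time (> 0).
#' @param seed optional integer seed; identical seeds give identical trees.
#' @return a rooted, bifurcating, ultrametric `phylo` object with tip labels
#'   `t1 ... tn`.
#' @examples
#' tr <- simulate_yule_tree(10, birth_rate = 1, seed = 1)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!(is.numeric(n_tips) && length(n_tips) == 1 && n_tips >= 2 &&
        n_tips == round(n_tips)))
    stop("n_tips must be an integer >= 2")
  stopifnot_scalar(birth_rate, "birth_rate")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  n_tips <- as.integer(n_tips)
  if (!is.null(seed)) set.seed(seed)

  # internal nodes in creation order; node 1 is the root at time 0
  node_time <- 0
  int_parent <- 0L                      # creation-order parent of each internal node
  act_parent <- c(1L, 1L)               # parent internal node of each active lineage
  m <- 2L
  t <- 0
  while (m < n_tips) {
    t <- t + stats::rexp(1, birth_rate * m)
    i <- sample.int(m, 1)
    node_time <- c(node_time, t)
    k <- length(node_time)
    int_parent <- c(int_parent, act_parent[i])
    act_parent[i] <- k
    act_parent <- c(act_parent, k)
    m <- m + 1L
  }
  t_end <- t + stats::rexp(1, birth_rate * n_tips)

  n_int <- length(node_time)            # = n_tips - 1
  edge <- matrix(0L, nrow = n_tips + n_int - 1L, ncol = 2)
  elen <- numeric(nrow(edge))
  r <- 1L
  if (n_int > 1) for (k in 2:n_int) {
    edge[r, ] <- c(n_tips + int_parent[k], n_tips + k)
    elen[r] <- node_time[k] - node_time[int_parent[k]]
    r <- r + 1L
  }
  for (j in seq_len(n_tips)) {
    edge[r, ] <- c(n_tips + act_parent[j], j)
    elen[r] <- t_end - node_time[act_parent[j]]
    r <- r + 1L
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_len(n_tips)),
                        Nnode = n_int),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Perturb a base tree into a tree set
#'
#' Produces a set of trees sharing the base topology and tip set, with branch
#' lengths jittered by independent lognormal multipliers. Topology is kept
#' fixed so that any clade monophyletic on the base tree remains monophyletic
#' in every tree of the set, mirroring how a published tree distribution
#' preserves named clades.
#'
#' @param tree base `phylo`.
#' @param n_trees number of perturbed trees.
#' @param jitter_sd standard deviation of the log-normal branch multiplier.
#' @param seed optional integer seed.
#' @return a `multiPhylo` list of `n_trees` trees.
#' @export
simulate_tree_set <- function(tree, n_trees, jitter_sd = 0.1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      exp(stats::rnorm(length(tr$edge.length), 0, jitter_sd))
    out[[i]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

#' Carve nested monophyletic clades out of a tree
#'
#' Selects, per level, the requested number of mutually disjoint monophyletic
#' clades each containing strictly more than `min_size` tips; clades at deeper
#' levels are nested inside clades of the level above. Selection is a seeded
#' randomized search over internal nodes; an infeasible request fails with an
#' explicit error rather than silently returning fewer clades.
#'
#' @param tree rooted `phylo`.
#' @param n_clades_per_level integer vector, e.g. `c(2, 4)` for two
#'   superorder-like and four order-like clades.
#' @param min_size strict lower bound on clade size.
#' @param seed optional integer seed.
#' @param max_tries number of randomized attempts before declaring the request
#'   infeasible.
#' @return a [clade_hierarchy()].
#' @export
carve_clades <- function(tree, n_clades_per_level, min_size = 15L, seed = NULL,
                         max_tries = 200L) {
  stopifnot(inherits(tree, "phylo"), length(n_clades_per_level) >= 1,
            all(n_clades_per_level >= 1))
  n <- length(tree$tip.label)
  if (min_size >= n)
    stop("min_size must be smaller than the number of tips")
  if (!is.null(seed)) set.seed(seed)
  sets <- node_tip_sets(tree)
  root <- n + 1L

  pick_disjoint <- function(cands, n_want) {
    # one seeded randomized greedy pass; NULL when it fails
    chosen <- integer(0)
    used <- integer(0)
    for (nd in sample(cands)) {
      if (!any(sets[[nd]] %in% used)) {
        chosen <- c(chosen, nd)
        used <- c(used, sets[[nd]])
        if (length(chosen) == n_want) return(chosen)
      }
    }
    NULL
  }

  sizes <- vapply(sets, length, integer(1))
  carve_once <- function() {
    levels <- list()
    parent_nodes <- root
    for (lv in seq_along(n_clades_per_level)) {
      want <- n_clades_per_level[lv]
      if (lv == 1 && want == 1) {
        # the whole tree as a single clade
        levels[["level1"]] <- root
        parent_nodes <- root
        next
      }
      cands <- setdiff(which(sizes > min_size & seq_along(sets) > n), root)
      # candidates must lie strictly inside a clade of the level above
      ok <- vapply(cands, function(nd) {
        any(vapply(parent_nodes, function(p)
          nd != p && all(sets[[nd]] %in% sets[[p]]), logical(1)))
      }, logical(1))
      cands_in <- cands[ok]
      if (length(cands_in) < want) return(NULL)
      chosen <- pick_disjoint(cands_in, want)
      if (is.null(chosen)) return(NULL)
      levels[[paste0("level", lv)]] <- sort(chosen)
      parent_nodes <- chosen
    }
    levels
  }
  # joint retries: a poor shallow-level draw is resampled rather than
  # dooming the deeper levels
  levels <- NULL
  for (try in seq_len(max_tries)) {
    levels <- carve_once()
    if (!is.null(levels)) break
  }
  if (is.null(levels))
    stop(sprintf("infeasible clade request %s with min_size %d: no nested disjoint selection found",
                 paste(n_clades_per_level, collapse = ","), min_size))

  assignment <- data.frame(tip = tree$tip.label, stringsAsFactors = FALSE)
  for (lv in names(levels)) {
    col <- rep(NA_character_, n)
    for (j in seq_along(levels[[lv]])) {
      nd <- levels[[lv]][j]
      col[sets[[nd]]] <- paste0(lv, "_c", j)
    }
    assignment[[lv]] <- col
  }
  h <- clade_hierarchy(assignment, min_size = min_size)
  validate_hierarchy(tree, h)
  h
}

#' Construct a rate matrix with a controlled major axis
#'
#' Builds a symmetric PSD matrix from prescribed eigenvalues and either a
#' seeded random orthogonal orientation or a leading eigenvector placed in the
#' plane of the first two coordinates at a given angle from axis 1.
#'
#' @param eigenvalues nonnegative reals sorted in decreasing order.
#' @param planar_angle optional angle in degrees; when given, the leading
#'   eigenvector is `(cos a, sin a, 0, ...)`.
#' @param orientation_seed optional integer seed for a random orthogonal
#'   orientation (ignored when `planar_angle` is given).
#' @return a `k x k` symmetric PSD matrix.
#' @export
make_rate_matrix <- function(eigenvalues, planar_angle = NULL,
                             orientation_seed = NULL) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < 0)) stop("eigenvalues must be nonnegative")
  if (is.unsorted(rev(ev))) stop("eigenvalues must be sorted in decreasing order")
  k <- length(ev)
  if (!is.null(planar_angle)) {
    if (k < 2) stop("planar_angle requires k >= 2")
    a <- planar_angle * pi / 180
    Q <- diag(k)
    Q[1:2, 1:2] <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  } else if (!is.null(orientation_seed)) {
    set.seed(orientation_seed)
    M <- matrix(stats::rnorm(k * k), k, k)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))), k)
  } else {
    Q <- diag(k)
  }
  R <- Q %*% (ev * t(Q))
  (R + t(R)) / 2
}

#' Ground truth for synthetic trait simulation
#'
#' Bundles the class-wide rate matrix, per-clade rate matrices, residual
#' covariance and root state, and records the folded angle between each
#' clade's major axis and its parent's (recomputable from the matrices).
#'
#' @param class_R `k x k` PSD rate matrix of the class-wide Brownian term.
#' @param clade_R named list of `k x k` PSD matrices, one per modeled clade
#'   (may be empty).
#' @param residual_E `k x k` PSD covariance of the i.i.d. residual term.
#' @param root_state numeric `k`-vector, the ancestral trait value.
#' @param hierarchy optional [clade_hierarchy()] used to resolve each clade's
#'   parent when recording major-axis angles.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(class_R, clade_R = list(), residual_E,
                         root_state = NULL, hierarchy = NULL) {
  k <- nrow(class_R)
  if (is.null(root_state)) root_state <- numeric(k)
  stopifnot(nrow(residual_E) == k, length(root_state) == k)
  for (M in c(list(class_R, residual_E), clade_R))
    if (!is_symmetric_psd(M)) stop("all ground-truth matrices must be symmetric PSD")
  angles <- NULL
  if (length(clade_R)) {
    angles <- vapply(names(clade_R), function(cl) {
      par <- if (!is.null(hierarchy)) parent_clade(hierarchy, cl) else "phylogeny"
      parR <- if (par == "phylogeny" || is.null(clade_R[[par]])) class_R else clade_R[[par]]
      if (max(eigen(clade_R[[cl]], symmetric = TRUE, only.values = TRUE)$values) == 0 ||
          max(eigen(parR, symmetric = TRUE, only.values = TRUE)$values) == 0)
        return(NA_real_)
      folded_angle(leading_eigenvector(clade_R[[cl]]), leading_eigenvector(parR))
    }, numeric(1))
  }
  structure(list(class_R = class_R, clade_R = clade_R, residual_E = residual_E,
                 root_state = root_state, major_axis_angles = angles, k = k),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: k =", x$k, "traits,", length(x$clade_R), "clade term(s)\n")
  if (length(x$major_axis_angles))
    cat("  clade major-axis angles vs parent (deg):",
        paste(sprintf("%s=%.1f", names(x$major_axis_angles), x$major_axis_angles),
              collapse = ", "), "\n")
  invisible(x)
}

# Matrix-normal draw with row covariance A (n x n) and column covariance
# R (k x k): X = A^{1/2} Z R^{1/2}, so Cov(X[i,a], X[j,b]) = A[i,j] R[a,b].
rmatnorm <- function(A_sqrt, R_sqrt) {
  n <- nrow(A_sqrt); k <- nrow(R_sqrt)
  A_sqrt %*% matrix(stats::rnorm(n * k), n, k) %*% R_sqrt
}

#' Simulate traits under nested multivariate Brownian motion
#'
#' The generative counterpart of the nested phylogenetic mixed model: traits
#' are the sum of a class-wide Brownian process with rate `class_R` over the
#' whole tree, per-clade Brownian deviation processes (each starting at zero at
#' the clade's most recent common ancestor, with rate `clade_R[[cl]]` on the
#' clade subtree and zero contribution elsewhere), an i.i.d. residual draw with
#' covariance `residual_E`, and the root state.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param hierarchy a [clade_hierarchy()] naming the clades in
#'   `truth$clade_R`; may be `NULL` when no clade terms are present.
#' @param truth a [ground_truth()].
#' @param seed optional integer seed.
#' @return an `n x k` matrix with rownames = tip labels.
#' @export
simulate_traits <- function(tree, hierarchy = NULL, truth, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(truth, "ground_truth"))
  k <- truth$k
  n <- length(tree$tip.label)
  if (length(truth$clade_R) && is.null(hierarchy))
    stop("hierarchy required when clade terms are present")
  if (!is.null(seed)) set.seed(seed)

  X <- matrix(rep(truth$root_state, each = n), n, k)
  rownames(X) <- tree$tip.label
  colnames(X) <- paste0("trait", seq_len(k))

  A <- ape::vcv.phylo(tree)
  X <- X + rmatnorm(psd_sqrt(A), psd_sqrt(truth$class_R))[match(tree$tip.label, rownames(A)), , drop = FALSE]

  for (cl in names(truth$clade_R)) {
    members <- clade_members(hierarchy, cl)
    miss <- setdiff(members, tree$tip.label)
    if (length(miss)) stop("clade members absent from tree: ", paste(miss, collapse = ", "))
    sub <- ape::keep.tip(tree, members)
    Ac <- ape::vcv.phylo(sub)          # shared path lengths from the clade MRCA
    D <- rmatnorm(psd_sqrt(Ac), psd_sqrt(truth$clade_R[[cl]]))
    X[rownames(Ac), ] <- X[rownames(Ac), , drop = FALSE] + D
  }

  X + matrix(stats::rnorm(n * k), n, k) %*% psd_sqrt(truth$residual_E)
}
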