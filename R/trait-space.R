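# Trait-space module: ordination of a raw trait table, dimensionality
# selection by per-clade variance content, and centroid distances.

#' Ordinate a raw trait table by principal components analysis
#'
#' Covariance-based PCA (the morphometric convention for Procrustes-type
#' coordinates): scores are column-centered and rotated onto orthogonal axes
#' ordered by decreasing variance. Axis signs are fixed by forcing the
#' largest-magnitude loading of each axis positive, so repeated runs produce
#' identical score signs.
#'
#' @param raw numeric matrix (species x raw dimensions) with unique rownames
#'   and no missing values.
#' @return an object of class `trait_pca`: list with `scores` (n x k matrix),
#'   `rotation`, `center`, `sdev` and `variance_explained` (per-axis fractions
#'   of total variance).
#' @export
pca_ordinate <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) <= 1) stop("at least two rows are required for ordination")
  if (anyNA(raw)) stop("trait table contains missing values")
  if (is.null(rownames(raw))) stop("trait table must have rownames (tip labels)")
  if (anyDuplicated(rownames(raw))) stop("trait table rownames must be unique")
  p <- stats::prcomp(raw, center = TRUE, scale. = FALSE)
  # deterministic axis signs: largest-magnitude loading positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, rotation = p$rotation, center = p$center,
                 sdev = p$sdev, variance_explained = ve),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA-ordinated trait space:", nrow(x$scores), "species x",
      ncol(x$scores), "axes\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(min(8, length(x$variance_explained)))]),
            collapse = " "), "\n")
  invisible(x)
}

# Accept either a plain matrix or a trait_pca where a score matrix is expected.
score_matrix <- function(x) {
  if (inherits(x, "trait_pca")) return(x$scores)
  as.matrix(x)
}

#' Select the retained dimensionality by per-clade variance content
#'
#' Returns the smallest number `m` of leading axes such that, for every clade
#' at the designated level, the first `m` axes hold at least `clade_threshold`
#' of that clade's total variance. Clade variances are computed on the globally
#' ordinated scores, centered within the clade; the rule guards against clades
#' whose variance concentrates on later global axes.
#'
#' @param scores a [pca_ordinate()] result or a score matrix with rownames.
#' @param hierarchy a [clade_hierarchy()] on the same labels.
#' @param clade_threshold fraction in (0, 1]; default 0.95.
#' @param level which hierarchy level to screen (default the first,
#'   superorder-like, level).
#' @return integer, the selected number of leading axes.
#' @export
select_dimensions <- function(scores, hierarchy, clade_threshold = 0.95,
                              level = 1L) {
  if (!(is.numeric(clade_threshold) && length(clade_threshold) == 1 &&
        clade_threshold > 0 && clade_threshold <= 1))
    stop("clade_threshold must lie in (0, 1]")
  S <- score_matrix(scores)
  clades <- hierarchy$levels[[level]]
  if (is.null(clades)) stop("hierarchy has no level ", level)
  k <- ncol(S)
  frac <- matrix(NA_real_, length(clades), k)
  for (i in seq_along(clades)) {
    rows <- S[clades[[i]], , drop = FALSE]
    v <- apply(rows, 2, stats::var)
    tot <- sum(v)
    frac[i, ] <- if (tot > 0) cumsum(v) / tot else rep(1, k)
  }
  need <- apply(frac, 1, function(f) which(f >= clade_threshold - 1e-12)[1])
  max(need)
}

#' Euclidean distance of each species from the trait-space centroid
#'
#' @param scores a [pca_ordinate()] result or a numeric matrix.
#' @return named nonnegative vector, one distance per species.
#' @export
distance_to_centroid <- function(scores) {
  S <- score_matrix(scores)
  ctr <- colMeans(S)
  d <- sqrt(rowSums(sweep(S, 2, ctr)^2))
  names(d) <- rownames(S)
  d
}
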