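# Elaboration / innovation scores: projection onto and rejection from the
# phylogenetic major axis of a rate matrix, at species and clade level, per
# posterior sample.

# Leading eigenvector with deterministic sign and tie-break (no warning).
leading_eigenvector <- function(R, tol = 1e-9) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (max(e$values) <= 0) stop("rate matrix has no positive eigenvalue")
  tied <- which(e$values >= e$values[1] * (1 - tol))
  v <- e$vectors[, 1]
  if (length(tied) > 1) {
    # prefer the lowest coordinate axis reachable inside the tied eigenspace
    Vt <- e$vectors[, tied, drop = FALSE]
    for (a in seq_len(nrow(R))) {
      p <- Vt %*% crossprod(Vt, diag(nrow(R))[, a])
      if (sqrt(sum(p^2)) > tol) { v <- p / sqrt(sum(p^2)); break }
    }
  }
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}

#' Phylogenetic major axis of a rate matrix
#'
#' The major axis is the leading eigenvector of the evolutionary rate matrix,
#' anchored at a centre in trait space, with a half-length giving the
#' confidence-level extent of the matrix along that direction:
#' `sqrt(lambda_1 * q)` with `q` the chi-square quantile at `level` with `df`
#' degrees of freedom (default the full trait dimension). Scores scaled by
#' this half-length read as "nonexceptional" inside `[0, 1]`.
#'
#' @param R symmetric PSD `k x k` matrix, nonzero.
#' @param centre numeric `k`-vector locating the axis (default the origin).
#' @param level confidence level of the extent (default 0.95).
#' @param df degrees of freedom of the chi-square quantile; `nrow(R)` by
#'   convention, `1` as a documented alternative.
#' @return object of class `major_axis`: list with `centre`, `direction`
#'   (unit vector, sign-fixed), `half_length`, `eigenvalue`, `level`.
#' @export
major_axis <- function(R, centre = NULL, level = 0.95, df = nrow(R)) {
  R <- as.matrix(R)
  k <- nrow(R)
  if (is.null(centre)) centre <- numeric(k)
  stopifnot(length(centre) == k, level > 0, level < 1)
  e <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) stop("zero rate matrix has no major axis")
  if (length(e) > 1 && e[2] >= e[1] * (1 - 1e-9))
    warning("tied leading eigenvalues; using the lowest-axis-index tie-break")
  v <- leading_eigenvector(R)
  hl <- sqrt(e[1] * stats::qchisq(level, df = df))
  structure(list(centre = as.numeric(centre), direction = as.numeric(v),
                 half_length = hl, eigenvalue = e[1], level = level, df = df),
            class = "major_axis")
}

#' @export
print.major_axis <- function(x, ...) {
  cat(sprintf("Major axis (k = %d): half-length %.3f at level %.2f\n",
              length(x$direction), x$half_length, x$level))
  invisible(x)
}

#' Project a point onto a major axis: elaboration and innovation
#'
#' With `d = point - centre`, elaboration is the absolute projection of `d`
#' onto the axis direction and innovation the norm of the rejection
#' (perpendicular residual), both divided by the axis half-length. Scores in
#' `[0, 1]` lie within the confidence extent of the rate matrix.
#'
#' @param point numeric `k`-vector.
#' @param axis a [major_axis()].
#' @return named numeric vector `c(elaboration =, innovation =)`.
#' @export
project_point <- function(point, axis) {
  if (length(point) != length(axis$direction))
    stop("dimension mismatch between point and axis")
  d <- point - axis$centre
  a <- sum(d * axis$direction)
  rej <- d - a * axis$direction
  c(elaboration = abs(a) / axis$half_length,
    innovation = sqrt(sum(rej^2)) / axis$half_length)
}

# Vectorized projection of the rows of X; returns an n x 2 matrix.
project_points <- function(X, axis) {
  D <- sweep(X, 2, axis$centre)
  a <- drop(D %*% axis$direction)
  rej2 <- pmax(rowSums(D^2) - a^2, 0)
  cbind(elaboration = abs(a) / axis$half_length,
        innovation = sqrt(rej2) / axis$half_length)
}

#' Project a clade's major axis onto its parent's
#'
#' The child axis is translated so its centre coincides with the parent's;
#' its endpoint (centre + half-length along its direction) is then projected
#' onto the parent axis, giving the clade-level elaboration and innovation.
#'
#' @param child,parent [major_axis()] objects of equal dimension.
#' @return named numeric vector `c(elaboration =, innovation =)`.
#' @export
project_clade_axis <- function(child, parent) {
  if (length(child$direction) != length(parent$direction))
    stop("dimension mismatch between child and parent axes")
  endpoint <- parent$centre + child$half_length * child$direction
  project_point(endpoint, parent)
}

#' Score species or clades against reference major axes across a posterior
#'
#' For every posterior sample of the reference term's rate matrix, builds the
#' sample's major axis and scores each entity against it; summaries over
#' samples are available through [summary.score_table()]. In species mode the
#' reference is either the class-wide term (every species scored) or a
#' hierarchy level (each species scored against its own clade's axis). In
#' clade mode each clade's axis is projected, sample by aligned sample, onto
#' its parent clade's axis (or the class-wide axis).
#'
#' @param traits `n x k` trait (score) matrix with species rownames.
#' @param posteriors named list of [rate_posterior()] objects: `"phylogeny"`
#'   plus one per clade (a [pglmm_rates()] or [run_mini_chains()] `posteriors`
#'   element works directly; a `"residual"` entry is ignored).
#' @param hierarchy a [clade_hierarchy()] (not needed for
#'   `reference = "class"` species scoring).
#' @param mode `"species"` or `"clade"`.
#' @param reference in species mode: `"class"` or a hierarchy level index to
#'   score species against their own clade at that level. In clade mode:
#'   `"parent"` (each clade vs its parent clade) or `"class"` (vs the
#'   class-wide axis).
#' @param centre `"clade-mean"` (a term's axis is anchored at the mean trait
#'   vector of its member species; the class-wide axis at the grand mean) or
#'   `"origin"`.
#' @param level,df confidence level and chi-square df of the axis extent, as
#'   in [major_axis()].
#' @return a `score_table`: data frame with columns `entity`, `reference`,
#'   `sample`, `elaboration`, `innovation`.
#' @export
score_all <- function(traits, posteriors, hierarchy = NULL,
                      mode = c("species", "clade"), reference = "class",
                      centre = c("clade-mean", "origin"), level = 0.95,
                      df = NULL) {
  mode <- match.arg(mode)
  centre <- match.arg(centre)
  X <- score_matrix(traits)
  k <- ncol(X)
  if (is.null(df)) df <- k
  posteriors <- posteriors[setdiff(names(posteriors), "residual")]

  centre_of <- function(term) {
    if (centre == "origin") return(numeric(k))
    if (term == "phylogeny") colMeans(X)
    else colMeans(X[clade_members(hierarchy, term), , drop = FALSE])
  }
  axis_of <- function(term, s) {
    R <- posteriors[[term]]$samples[, , s]
    ax <- suppressWarnings(major_axis(R, centre_of(term), level = level, df = df))
    ax
  }

  rows <- list()
  if (mode == "species") {
    groups <- if (identical(reference, "class")) {
      list(phylogeny = rownames(X))
    } else {
      lv <- hierarchy$levels[[reference]]
      if (is.null(lv)) stop("hierarchy has no level ", reference)
      lv
    }
    for (term in names(groups)) {
      if (is.null(posteriors[[term]])) {
        message("no posterior for term '", term, "'; skipped")
        next
      }
      members <- intersect(groups[[term]], rownames(X))
      N <- n_samples(posteriors[[term]])
      for (s in seq_len(N)) {
        sc <- project_points(X[members, , drop = FALSE], axis_of(term, s))
        rows[[length(rows) + 1L]] <- data.frame(
          entity = members, reference = term, sample = s,
          elaboration = sc[, 1], innovation = sc[, 2], row.names = NULL)
      }
    }
  } else {
    clades <- intersect(hierarchy_clades(hierarchy), names(posteriors))
    for (cl in clades) {
      par <- if (identical(reference, "class")) "phylogeny"
             else parent_clade(hierarchy, cl)
      if (is.null(posteriors[[par]])) {
        message("no posterior for parent term '", par, "'; clade '", cl, "' skipped")
        next
      }
      Np <- n_samples(posteriors[[par]]); Nc <- n_samples(posteriors[[cl]])
      if (Np != Nc) stop("posterior samples not aligned between '", cl,
                         "' and '", par, "'")
      sc <- t(vapply(seq_len(Nc), function(s)
        project_clade_axis(axis_of(cl, s), axis_of(par, s)), numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        entity = cl, reference = par, sample = seq_len(Nc),
        elaboration = sc[, 1], innovation = sc[, 2], row.names = NULL)
    }
  }
  if (!length(rows)) stop("nothing to score")
  out <- do.call(rbind, rows)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Summarize a score table over posterior samples
#'
#' @param object a `score_table` from [score_all()].
#' @param ... unused.
#' @return data frame with one row per (entity, reference): median, 50% and
#'   95% credible bounds of elaboration and innovation.
#' @export
summary.score_table <- function(object, ...) {
  qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75, 0.025, 0.975),
                                    names = FALSE)
  sp <- split(seq_len(nrow(object)),
              list(object$entity, object$reference), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(ix) {
    e <- qs(object$elaboration[ix]); i <- qs(object$innovation[ix])
    data.frame(entity = object$entity[ix][1],
               reference = object$reference[ix][1],
               elab_median = e[1], elab_q25 = e[2], elab_q75 = e[3],
               elab_q025 = e[4], elab_q975 = e[5],
               innov_median = i[1], innov_q25 = i[2], innov_q75 = i[3],
               innov_q025 = i[4], innov_q975 = i[5], row.names = NULL)
  }))
  out[order(out$reference, out$entity), , drop = FALSE]
}
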