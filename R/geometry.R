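# Axis-geometry module: folded angles between major axes, the orthogonality
# metric, between-clade vs within-clade angle distributions, and posterior
# probabilities of orthogonality.

#' Folded angle between two axes
#'
#' Axes are directionless, so the angle is folded into `[0, 90]` degrees:
#' 0 and 180 degrees both map to 0, 90 and 270 to 90.
#'
#' @param v,w nonzero numeric vectors of equal length.
#' @return angle in degrees in `[0, 90]`.
#' @export
folded_angle <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("zero vector has no direction")
  if (length(v) != length(w)) stop("vectors must have equal length")
  acos(min(1, abs(sum(v * w)) / (nv * nw))) * 180 / pi
}

#' Orthogonality metric
#'
#' Rescales a folded angle to `[0, 1]`: parallel axes score 0, perpendicular
#' axes score 1 (45 degrees gives 0.5, 67.5 degrees gives 0.75).
#'
#' @param angle folded angle(s) in degrees, in `[0, 90]`.
#' @return value(s) in `[0, 1]`.
#' @export
orthogonality <- function(angle) {
  if (any(angle < 0 | angle > 90))
    stop("angle must lie in [0, 90] degrees; fold first")
  angle / 90
}

angle_distribution <- function(angles, pair) {
  structure(list(pair = pair, angles = angles,
                 orthogonality = orthogonality(angles),
                 summary = c(median = stats::median(angles),
                             q025 = unname(stats::quantile(angles, 0.025)),
                             q975 = unname(stats::quantile(angles, 0.975)),
                             sd = stats::sd(angles))),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Angles %s vs %s: median %.1f deg (95%% CI %.1f-%.1f, SD %.1f); median orthogonality %.2f\n",
              x$pair[1], x$pair[2], s["median"], s["q025"], s["q975"], s["sd"],
              stats::median(x$orthogonality)))
  invisible(x)
}

#' Between-clade major-axis angles across aligned posteriors
#'
#' For each aligned pair of posterior samples, the folded angle between the
#' leading eigenvectors of the two terms' rate matrices.
#'
#' @param posterior_a,posterior_b [rate_posterior()] objects with equal sample
#'   counts and aligned provenance.
#' @return an `angle_distribution`: folded angles, orthogonality values, and a
#'   summary (median, 95% CI, SD in degrees).
#' @export
between_clade_angles <- function(posterior_a, posterior_b) {
  Na <- n_samples(posterior_a); Nb <- n_samples(posterior_b)
  if (Na != Nb) stop("posteriors have different sample counts")
  pa <- posterior_a$provenance; pb <- posterior_b$provenance
  if (!identical(pa[c("tree", "iteration")], pb[c("tree", "iteration")]))
    stop("posterior provenance is not aligned")
  angles <- vapply(seq_len(Na), function(s)
    folded_angle(leading_eigenvector(posterior_a$samples[, , s]),
                 leading_eigenvector(posterior_b$samples[, , s])), numeric(1))
  angle_distribution(angles, pair = c(posterior_a$term, posterior_b$term))
}

#' Within-clade null distribution of major-axis angles
#'
#' Folded angles between the leading eigenvectors of randomly drawn distinct
#' pairs of samples from the same term's posterior; the null against which
#' between-clade angles are judged.
#'
#' @param posterior a [rate_posterior()] with at least 2 samples.
#' @param n_pairs number of random pairs.
#' @param seed optional integer seed.
#' @return an `angle_distribution`.
#' @export
within_clade_null <- function(posterior, n_pairs = 1000L, seed = NULL) {
  N <- n_samples(posterior)
  if (N < 2) stop("need at least 2 posterior samples")
  if (!is.null(seed)) set.seed(seed)
  angles <- vapply(seq_len(n_pairs), function(p) {
    ij <- sample.int(N, 2)            # without replacement within the pair
    folded_angle(leading_eigenvector(posterior$samples[, , ij[1]]),
                 leading_eigenvector(posterior$samples[, , ij[2]]))
  }, numeric(1))
  angle_distribution(angles, pair = c(posterior$term, posterior$term))
}

#' Posterior probability that between-clade angles exceed the within-clade null
#'
#' The fraction of (between, within) draw pairs in which the between-clade
#' angle is strictly larger. When both sets are small (at most 2500 product
#' pairs) the comparison is exhaustive; otherwise randomly matched draws are
#' used. Significance labels follow the convention pp > 0.99 `***`,
#' > 0.95 `**`, > 0.9 `*`, > 0.8 `.`.
#'
#' @param between,within `angle_distribution` objects (or numeric angle
#'   vectors).
#' @param n_draws number of matched random draws when not exhaustive.
#' @param seed optional integer seed.
#' @return numeric posterior probability in `[0, 1]` with attributes
#'   `signif` (label) and `method`.
#' @export
orthogonality_pp <- function(between, within, n_draws = 10000L, seed = NULL) {
  b <- if (inherits(between, "angle_distribution")) between$angles else between
  w <- if (inherits(within, "angle_distribution")) within$angles else within
  if (!length(b) || !length(w)) stop("empty angle set")
  if (length(b) * length(w) <= 2500) {
    pp <- mean(outer(b, w, ">"))
    method <- "exhaustive"
  } else {
    if (!is.null(seed)) set.seed(seed)
    pp <- mean(b[sample.int(length(b), n_draws, replace = TRUE)] >
               w[sample.int(length(w), n_draws, replace = TRUE)])
    method <- "matched-draws"
  }
  lab <- if (pp > 0.99) "***" else if (pp > 0.95) "**" else if (pp > 0.9) "*"
         else if (pp > 0.8) "." else ""
  structure(pp, signif = lab, method = method)
}

#' Orthogonality report for every clade of a hierarchy
#'
#' For each modeled clade, folded angles of its major axis against its parent
#' clade's and against the class-wide axis across aligned posterior samples,
#' the within-clade null, and the posterior probabilities of orthogonality:
#' the column set of a clade-orthogonality figure.
#'
#' @param posteriors named list of [rate_posterior()] per term (including
#'   `"phylogeny"`).
#' @param hierarchy a [clade_hierarchy()].
#' @param n_null pairs drawn for each within-clade null.
#' @param seed integer seed for the null draws and pp matching.
#' @return data frame with one row per clade: median orthogonality and 95% CI
#'   vs parent and vs class, SD of angles in degrees, clade size, and pp
#'   values with significance labels.
#' @export
orthogonality_report <- function(posteriors, hierarchy, n_null = 1000L,
                                 seed = 1L) {
  clades <- intersect(hierarchy_clades(hierarchy), names(posteriors))
  rows <- lapply(seq_along(clades), function(i) {
    cl <- clades[i]
    par <- parent_clade(hierarchy, cl)
    vs_par <- between_clade_angles(posteriors[[cl]], posteriors[[par]])
    vs_cls <- between_clade_angles(posteriors[[cl]], posteriors[["phylogeny"]])
    nul <- within_clade_null(posteriors[[cl]], n_pairs = n_null,
                             seed = derive_seed(seed, i))
    pp_par <- orthogonality_pp(vs_par, nul, seed = derive_seed(seed, 5000L + i))
    pp_cls <- orthogonality_pp(vs_cls, nul, seed = derive_seed(seed, 9000L + i))
    data.frame(clade = cl, parent = par,
               n_species = length(clade_members(hierarchy, cl)),
               ortho_parent_median = stats::median(vs_par$orthogonality),
               ortho_parent_q025 = unname(stats::quantile(vs_par$orthogonality, 0.025)),
               ortho_parent_q975 = unname(stats::quantile(vs_par$orthogonality, 0.975)),
               sd_deg_parent = vs_par$summary["sd"],
               ortho_class_median = stats::median(vs_cls$orthogonality),
               ortho_class_q025 = unname(stats::quantile(vs_cls$orthogonality, 0.025)),
               ortho_class_q975 = unname(stats::quantile(vs_cls$orthogonality, 0.975)),
               sd_deg_class = vs_cls$summary["sd"],
               pp_parent = as.numeric(pp_par), pp_parent_signif = attr(pp_par, "signif"),
               pp_class = as.numeric(pp_cls), pp_class_signif = attr(pp_cls, "signif"),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
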