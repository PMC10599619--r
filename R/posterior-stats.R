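# Distribution-level posterior statistics: scaled score densities and their
# Bhattacharyya overlap, posterior elaboration-innovation correlations, and
# Pagel's lambda phylogenetic signal of median scores.

#' Scale scores by their group maximum
#'
#' Divides every score by the maximum score of its group, so each group's
#' scaled scores lie in `[0, 1]` with maximum exactly 1; the convention used
#' before comparing species-level and clade-level score densities.
#'
#' @param x numeric vector of nonnegative scores.
#' @param group grouping vector (one group label per score); a single group
#'   when omitted.
#' @return numeric vector of scaled scores.
#' @export
scale_by_group_max <- function(x, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(x))
  stopifnot(length(group) == length(x))
  mx <- tapply(x, group, max)
  if (any(mx <= 0)) stop("group maximum must be > 0 for scaling")
  x / as.numeric(mx[as.character(group)])
}

#' Bhattacharyya coefficient of two samples
#'
#' Histogram-based overlap: both samples are binned on shared equal-width bins
#' spanning the pooled range, and the coefficient is `sum(sqrt(p * q))` over
#' per-bin probability masses; 1 for identical distributions, 0 for disjoint
#' supports.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @param n_bins number of shared bins (default 100).
#' @return coefficient in `[0, 1]`.
#' @export
bhattacharyya <- function(sample_a, sample_b, n_bins = 100L) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  stopifnot(all(is.finite(sample_a)), all(is.finite(sample_b)), n_bins >= 1)
  lo <- min(sample_a, sample_b); hi <- max(sample_a, sample_b)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  p <- tabulate(findInterval(sample_a, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(sample_a)
  q <- tabulate(findInterval(sample_b, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(sample_b)
  sum(sqrt(p * q))
}

#' Posterior correlation between elaboration and innovation within a group
#'
#' Per posterior sample, the correlation across the group's species between
#' elaboration and innovation scores; summarized over samples and classified
#' as `"clear"` (95% CI excludes 0), `"somewhat"` (50% CI excludes 0) or
#' `"none"`. Samples in which either score has zero variance are skipped with
#' a log entry.
#'
#' @param scores a `score_table` from [score_all()] (species mode), restricted
#'   to one reference group, or any data frame with columns `entity`,
#'   `sample`, `elaboration`, `innovation`.
#' @param method correlation coefficient, `"pearson"` (default) or
#'   `"spearman"`.
#' @return object of class `posterior_cor`: list with `r` (per-sample values),
#'   `median`, `ci50`, `ci95`, `class`, `n_species`, `n_samples_used`.
#' @export
posterior_correlation <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(unique(scores$entity)) < 3)
    stop("need at least 3 species in the group")
  sp <- split(scores, scores$sample)
  if (length(sp) < 2) stop("need at least 2 posterior samples")
  r <- vapply(sp, function(d) {
    if (stats::var(d$elaboration) == 0 || stats::var(d$innovation) == 0)
      return(NA_real_)
    stats::cor(d$elaboration, d$innovation, method = method)
  }, numeric(1))
  skipped <- sum(is.na(r))
  if (skipped) message(skipped, " sample(s) skipped (zero-variance scores)")
  r <- r[!is.na(r)]
  if (!length(r)) stop("no usable posterior samples")
  ci50 <- stats::quantile(r, c(0.25, 0.75), names = FALSE)
  ci95 <- stats::quantile(r, c(0.025, 0.975), names = FALSE)
  cls <- if (prod(ci95) > 0) "clear" else if (prod(ci50) > 0) "somewhat" else "none"
  structure(list(r = r, median = stats::median(r), ci50 = ci50, ci95 = ci95,
                 class = cls, method = method,
                 n_species = length(unique(scores$entity)),
                 n_samples_used = length(r)),
            class = "posterior_cor")
}

#' @export
print.posterior_cor <- function(x, ...) {
  cat(sprintf("Posterior %s correlation (n = %d species, %d samples): median %.3f\n",
              x$method, x$n_species, x$n_samples_used, x$median))
  cat(sprintf("  50%% CI [%.3f, %.3f], 95%% CI [%.3f, %.3f] -> %s\n",
              x$ci50[1], x$ci50[2], x$ci95[1], x$ci95[2], x$class))
  invisible(x)
}

# Profile log-likelihood of a univariate trait under the lambda-transformed
# Brownian covariance, with the mean and rate profiled out analytically.
lambda_loglik <- function(lambda, y, A) {
  n <- length(y)
  C <- lambda * A
  diag(C) <- diag(A)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  one <- rep(1, n)
  yi <- backsolve(ch, y, transpose = TRUE)
  oi <- backsolve(ch, one, transpose = TRUE)
  mu <- sum(oi * yi) / sum(oi * oi)
  rss <- sum((yi - mu * oi)^2)
  s2 <- rss / n
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
}

#' Pagel's lambda phylogenetic signal of a univariate trait
#'
#' Maximum-likelihood lambda under the lambda-transformed Brownian covariance
#' (off-diagonal entries of the shared-path matrix multiplied by lambda), with
#' the mean and rate profiled out analytically and a bounded golden-section
#' search on `[0, 1]` (tolerance 1e-6). On a star tree the likelihood does not
#' depend on lambda; the fit is returned with a flat-likelihood flag.
#'
#' @param trait named numeric vector matched to tip labels (n >= 4), with
#'   nonzero variance.
#' @param tree rooted `phylo` (non-ultrametric allowed).
#' @return list with `lambda` (in `[0, 1]`), `logLik`, and `flat` (`TRUE`
#'   when the profile is constant in lambda).
#' @export
pagels_lambda <- function(trait, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(trait) < 4) stop("need at least 4 species")
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("trait must be named by tip labels")
    names(trait) <- tree$tip.label
  }
  bad <- setdiff(tree$tip.label, names(trait))
  if (length(bad)) stop("trait missing for tips: ", paste(bad, collapse = ", "))
  y <- trait[tree$tip.label]
  if (stats::var(y) == 0) stop("degenerate trait: zero variance")
  A <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  f <- function(l) lambda_loglik(l, y, A)
  l0 <- f(0); l1 <- f(1); lmid <- f(0.5)
  if (max(l0, l1, lmid) - min(l0, l1, lmid) < 1e-8) {
    return(list(lambda = 0, logLik = l0, flat = TRUE))
  }
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, l0), c(1, l1))
  best <- cand[which.max(cand[, 2]), ]
  list(lambda = best[1], logLik = best[2], flat = FALSE)
}
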