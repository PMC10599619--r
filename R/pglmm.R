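# Nested-rate-matrix estimation: a conjugate block-Gibbs sampler for the
# Bayesian phylogenetic mixed model with a multivariate response, a class-wide
# phylogenetic random term, per-clade nested phylogenetic random terms, and an
# estimated residual covariance.
#
# Model, for tip i with trait vector y_i (length k):
#   y_i = mu + u_class,i + sum_clades u_cl,i + e_i,    e_i ~ N(0, E)
# where the stacked effects of term t over its member tips follow a
# matrix-normal MN(0, A_t, R_t): A_t is the shared-path-length matrix of the
# term's subtree (the clade deviation process starts at zero at the clade
# MRCA) and R_t is the term's k x k evolutionary rate matrix. R_t and E carry
# inverse-Wishart priors with scale nu * V and degree of belief nu.

#' Inverse-Wishart prior specification
#'
#' The "belief" convention: a belief fraction `b` on `k` traits maps to an
#' inverse-Wishart degree of belief `nu = b * k` with scale matrix `nu * V`,
#' so small beliefs put very low weight on the prior.
#'
#' @param V symmetric PSD `k x k` scale matrix.
#' @param nu positive degree of belief.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(V, nu) {
  V <- as.matrix(V)
  if (!is_symmetric_psd(V)) stop("prior scale V must be symmetric PSD")
  stopifnot_scalar(nu, "nu")
  if (nu <= 0) stop("prior degree of belief nu must be > 0")
  structure(list(V = V, nu = nu), class = "prior_spec")
}

#' Flat prior with a belief fraction
#'
#' @param k trait dimension.
#' @param belief belief fraction (e.g. `0.02` for 2%).
#' @return a [prior_spec()] with identity scale and `nu = belief * k`.
#' @export
flat_prior <- function(k, belief = 0.02) prior_spec(diag(k), belief * k)

#' Container for a posterior sample of rate matrices
#'
#' @param samples `k x k x N` array of symmetric PSD matrix samples.
#' @param term label of the model term (`"phylogeny"`, a clade name, or
#'   `"residual"`).
#' @param provenance data frame with columns `tree`, `chain`, `iteration`, one
#'   row per sample.
#' @return object of class `rate_posterior`.
#' @export
rate_posterior <- function(samples, term = "term", provenance = NULL) {
  stopifnot(length(dim(samples)) == 3, dim(samples)[1] == dim(samples)[2])
  N <- dim(samples)[3]
  if (is.null(provenance))
    provenance <- data.frame(tree = 1L, chain = 1L, iteration = seq_len(N))
  stopifnot(nrow(provenance) == N)
  structure(list(samples = samples, term = term, provenance = provenance),
            class = "rate_posterior")
}

#' @export
print.rate_posterior <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("Rate-matrix posterior for term '%s': %d samples of %dx%d\n",
              x$term, d[3], d[1], d[2]))
  invisible(x)
}

#' Posterior mean matrix of a rate-matrix posterior
#' @param x a [rate_posterior()].
#' @return `k x k` matrix.
#' @export
posterior_mean <- function(x) {
  apply(x$samples, c(1, 2), mean)
}

#' Elementwise posterior median matrix, projected back onto the PSD cone
#' @param x a [rate_posterior()].
#' @return `k x k` symmetric PSD matrix.
#' @export
posterior_median_matrix <- function(x) {
  M <- apply(x$samples, c(1, 2), stats::median)
  psd_project((M + t(M)) / 2)
}

n_samples <- function(x) dim(x$samples)[3]

# Precompute the eigenstructure of a term's shared-path matrix.
term_structure <- function(tree, members, all_tips) {
  sub <- if (length(members) == length(all_tips)) tree else ape::keep.tip(tree, members)
  A <- ape::vcv.phylo(sub)
  A <- A[members, members, drop = FALSE]
  e <- eigen(A, symmetric = TRUE)
  lam <- pmax(e$values, max(e$values) * 1e-12)
  list(members = members, idx = match(members, all_tips), Q = e$vectors, lambda = lam)
}

#' Fit the nested phylogenetic mixed model by Gibbs sampling
#'
#' Conjugate block-Gibbs sampler alternating (a) matrix-normal updates of the
#' class-wide and per-clade tip-level random effects given the covariances and
#' (b) inverse-Wishart updates of each term's rate matrix and of the residual
#' covariance given the effects. The per-term effect update diagonalizes the
#' term's shared-path matrix once and solves a generalized eigenproblem of the
#' two k x k precisions per iteration, so each sweep costs a handful of dense
#' `n x k` products.
#'
#' @param traits numeric `n x k` matrix with rownames matching tip labels.
#' @param tree rooted `phylo`; `NULL` fits a residual-only model (no
#'   phylogenetic terms).
#' @param hierarchy optional [clade_hierarchy()]; when supplied, every clade at
#'   every level becomes a nested random term (each must be monophyletic with
#'   more than `min_size` members, which [clade_hierarchy()] enforces).
#' @param priors a [prior_spec()] applied to every term, or a named list with
#'   one entry per term (`"phylogeny"`, clade names, `"residual"`). Default:
#'   flat priors with a 2% belief.
#' @param n_iter total Gibbs iterations.
#' @param burnin iterations discarded before sampling.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed optional integer seed.
#' @param scale_height rescale the tree to unit root-to-tip depth before
#'   building covariances so rate matrices are comparable across trees
#'   (default `TRUE`).
#' @param tree_id,chain_id integers recorded in the sample provenance.
#' @return an object of class `pglmm_rates`; see [posterior_mean()],
#'   [summary.pglmm_rates()], [coef.pglmm_rates()], [plot.pglmm_rates()].
#' @examples
#' tr <- simulate_yule_tree(32, seed = 1)
#' gt <- ground_truth(class_R = make_rate_matrix(c(4, 1)),
#'                    residual_E = 0.1 * diag(2))
#' y <- simulate_traits(tr, truth = gt, seed = 2)
#' fit <- pglmm_rates(y, tr, n_iter = 200, burnin = 50, seed = 3)
#' coef(fit)$phylogeny
#' @export
pglmm_rates <- function(traits, tree = NULL, hierarchy = NULL, priors = NULL,
                        n_iter = 1000, burnin = 0, thin = 1, seed = NULL,
                        scale_height = TRUE, tree_id = 1L, chain_id = 1L) {
  Y <- as.matrix(traits)
  n <- nrow(Y); k <- ncol(Y)
  stopifnot(n > k, n_iter >= 1, burnin >= 0, burnin < n_iter, thin >= 1)
  if (!is.null(seed)) set.seed(seed)

  term_names <- character(0)
  structures <- list()
  if (!is.null(tree)) {
    if (is.null(rownames(Y))) stop("traits must have rownames matching tip labels")
    bad <- setdiff(tree$tip.label, rownames(Y))
    if (length(bad)) stop("traits missing for tips: ", paste(bad, collapse = ", "))
    Y <- Y[tree$tip.label, , drop = FALSE]
    tr <- tree
    if (scale_height) {
      ht <- max(ape::vcv.phylo(tr)[cbind(seq_len(n), seq_len(n))])
      tr$edge.length <- tr$edge.length / ht
    }
    term_names <- "phylogeny"
    structures$phylogeny <- term_structure(tr, tr$tip.label, tr$tip.label)
    if (!is.null(hierarchy)) {
      validate_hierarchy(tree, hierarchy)
      for (cl in hierarchy_clades(hierarchy)) {
        term_names <- c(term_names, cl)
        structures[[cl]] <- term_structure(tr, clade_members(hierarchy, cl),
                                           tr$tip.label)
      }
    }
  }

  all_terms <- c(term_names, "residual")
  if (is.null(priors)) priors <- flat_prior(k)
  if (inherits(priors, "prior_spec")) {
    priors <- stats::setNames(rep(list(priors), length(all_terms)), all_terms)
  }
  for (tm in all_terms) {
    if (is.null(priors[[tm]]) || !inherits(priors[[tm]], "prior_spec"))
      stop("missing or invalid prior for term '", tm, "'")
    if (nrow(priors[[tm]]$V) != k) stop("prior scale dimension mismatch for '", tm, "'")
  }
  Psi <- lapply(priors, function(p) p$nu * p$V)
  nu0 <- vapply(priors, function(p) p$nu, numeric(1))

  # state
  mu <- colMeans(Y)
  E <- diag(pmax(apply(Y, 2, stats::var), 1e-8) / 2, k)
  R <- stats::setNames(lapply(term_names, function(tm)
    diag(pmax(apply(Y, 2, stats::var), 1e-8) / 2, k)), term_names)
  U <- stats::setNames(lapply(term_names, function(tm)
    matrix(0, length(structures[[tm]]$members), k)), term_names)

  n_keep <- floor((n_iter - burnin) / thin)
  keep_at <- burnin + thin * seq_len(n_keep)
  out_R <- stats::setNames(lapply(all_terms, function(tm)
    array(NA_real_, c(k, k, n_keep))), all_terms)
  out_mu <- matrix(NA_real_, n_keep, k)
  loglik <- numeric(n_iter)

  effects_sum <- function() {
    Etot <- matrix(0, n, k)
    for (tm in term_names) {
      ix <- structures[[tm]]$idx
      Etot[ix, ] <- Etot[ix, , drop = FALSE] + U[[tm]]
    }
    Etot
  }

  s <- 0L
  for (it in seq_len(n_iter)) {
    Etot <- effects_sum()
    # intercept (flat prior)
    Z0 <- Y - Etot
    mu <- colMeans(Z0) + drop(t(chol(E)) %*% stats::rnorm(k)) / sqrt(n)

    Einv <- chol2inv(chol(E))
    Ue <- chol(Einv)
    for (tm in term_names) {
      st <- structures[[tm]]
      ix <- st$idx
      Zt <- Y[ix, , drop = FALSE] -
        matrix(mu, length(ix), k, byrow = TRUE) -
        (Etot[ix, , drop = FALSE] - U[[tm]])
      Rinv <- chol2inv(chol(R[[tm]]))
      # simultaneous diagonalization: W' Einv W = I, W' Rinv W = D
      tmp <- backsolve(Ue, Rinv, transpose = TRUE)
      B <- t(backsolve(Ue, t(tmp), transpose = TRUE))
      eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
      D <- pmax(eb$values, 0)
      W <- backsolve(Ue, eb$vectors)
      Zt_rot <- crossprod(st$Q, Zt)
      H <- Zt_rot %*% Einv %*% W
      S1 <- 1 / (outer(1 / st$lambda, D) + 1)
      Ut_rot <- (H * S1 + matrix(stats::rnorm(length(H)), nrow(H)) * sqrt(S1)) %*% t(W)
      U[[tm]] <- st$Q %*% Ut_rot
      # scatter in the rotated basis: U' A^{-1} U
      S_t <- crossprod(Ut_rot, Ut_rot / st$lambda)
      R[[tm]] <- riwish(nu0[[tm]] + length(ix), Psi[[tm]] + S_t)
      Etot <- effects_sum()
    }

    Resid <- Y - matrix(mu, n, k, byrow = TRUE) - Etot
    S_E <- crossprod(Resid)
    E <- riwish(nu0[["residual"]] + n, Psi[["residual"]] + S_E)

    Einv_new <- chol2inv(chol(E))
    ld <- as.numeric(determinant(E, logarithm = TRUE)$modulus)
    loglik[it] <- -0.5 * (n * k * log(2 * pi) + n * ld + sum(Einv_new * S_E))

    if (s < n_keep && it == keep_at[s + 1L]) {
      s <- s + 1L
      for (tm in term_names) out_R[[tm]][, , s] <- R[[tm]]
      out_R[["residual"]][, , s] <- E
      out_mu[s, ] <- mu
    }
  }

  prov <- data.frame(tree = as.integer(tree_id), chain = as.integer(chain_id),
                     iteration = keep_at)
  posteriors <- stats::setNames(lapply(all_terms, function(tm)
    rate_posterior(out_R[[tm]], term = tm, provenance = prov)), all_terms)

  structure(list(posteriors = posteriors, mu_samples = out_mu, loglik = loglik,
                 terms = term_names, k = k, n = n,
                 n_iter = n_iter, burnin = burnin, thin = thin,
                 priors = priors, seed = seed, scale_height = scale_height,
                 traits = Y),
            class = "pglmm_rates")
}

#' @export
print.pglmm_rates <- function(x, ...) {
  cat("Nested phylogenetic mixed model (Gibbs)\n")
  cat(sprintf("  %d species, %d traits; terms: %s + residual\n", x$n, x$k,
              if (length(x$terms)) paste(x$terms, collapse = ", ") else "(none)"))
  cat(sprintf("  %d iterations (burn-in %d, thin %d): %d kept samples per term\n",
              x$n_iter, x$burnin, x$thin, n_samples(x$posteriors[[1]])))
  invisible(x)
}

#' Posterior-mean rate matrices of a fitted model
#' @param object a [pglmm_rates()] fit.
#' @param ... unused.
#' @return named list of `k x k` posterior-mean matrices (terms + residual).
#' @export
coef.pglmm_rates <- function(object, ...) {
  lapply(object$posteriors, posterior_mean)
}

#' Summarize a fitted nested phylogenetic mixed model
#'
#' @param object a [pglmm_rates()] fit.
#' @param ... unused.
#' @return list with posterior means, leading eigenvalue share per term, and
#'   an effective-sample-size table over the distinct matrix entries.
#' @export
summary.pglmm_rates <- function(object, ...) {
  means <- coef(object)
  ess <- ess_table(object$posteriors)
  axis_share <- vapply(means, function(M) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ev[1] / sum(ev)
  }, numeric(1))
  out <- list(posterior_mean = means, leading_axis_share = axis_share,
              ess = ess, loglik = stats::median(object$loglik))
  class(out) <- "summary.pglmm_rates"
  out
}

#' @export
print.summary.pglmm_rates <- function(x, ...) {
  cat("Posterior summaries per term:\n")
  for (tm in names(x$posterior_mean)) {
    cat(sprintf("  %s: leading-axis share %.2f, min entry ESS %.0f\n",
                tm, x$leading_axis_share[[tm]],
                min(x$ess$ess[x$ess$term == tm])))
  }
  cat(sprintf("Median conditional log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

#' Trace plot of the conditional log-likelihood
#' @param x a [pglmm_rates()] fit.
#' @param ... passed to [plot()].
#' @export
plot.pglmm_rates <- function(x, ...) {
  plot(x$loglik, type = "l", xlab = "iteration", ylab = "log-likelihood", ...)
  if (x$burnin > 0) graphics::abline(v = x$burnin, lty = 2)
  invisible(x)
}

# ESS per distinct (upper-triangle) matrix entry for a list of posteriors.
ess_table <- function(posteriors) {
  rows <- list()
  for (tm in names(posteriors)) {
    sm <- posteriors[[tm]]$samples
    k <- dim(sm)[1]
    for (i in seq_len(k)) for (j in i:k) {
      x <- sm[i, j, ]
      e <- if (length(x) < 10 || stats::var(x) == 0) NA_real_
           else effective_sample_size(x)
      rows[[length(rows) + 1L]] <- data.frame(term = tm, row = i, col = j, ess = e)
    }
  }
  do.call(rbind, rows)
}
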