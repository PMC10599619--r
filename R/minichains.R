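# Mini-chains orchestration: parameterization chains on the consensus tree
# estimate a burn-in and informed priors; one short chain per tree of the
# distribution then contributes a fixed number of exploitable samples to a
# concatenated posterior that carries the phylogenetic uncertainty.

#' Configuration for the mini-chains protocol
#'
#' Defaults are the protocol's published operating point: three
#' parameterization chains of 50,000 generations with a 2% belief, burn-in
#' factor 1.1, mini-chain priors at 5% belief, 400 trees contributing 10
#' samples each, and an effective-sample-size target of 200. Analyses at demo
#' scale override the sizes explicitly.
#'
#' @param n_param_chains number of parameterization chains.
#' @param param_generations iterations per parameterization chain.
#' @param burnin_factor multiplier on the latest first-crossing of the median
#'   posterior likelihood.
#' @param param_belief belief fraction of the flat parameterization priors.
#' @param minichain_belief belief fraction of the informed mini-chain priors.
#' @param samples_per_tree exploitable posterior samples kept per tree.
#' @param n_trees number of trees (mini chains).
#' @param ess_target effective sample size the concatenated posterior should
#'   reach for every scalar parameter.
#' @param minichain_thin thinning interval inside each mini chain, so the kept
#'   samples span the post-burn-in window evenly.
#' @return object of class `minichain_config`.
#' @export
minichain_config <- function(n_param_chains = 3L, param_generations = 50000L,
                             burnin_factor = 1.1, param_belief = 0.02,
                             minichain_belief = 0.05, samples_per_tree = 10L,
                             n_trees = 400L, ess_target = 200,
                             minichain_thin = 5L) {
  cfg <- list(n_param_chains = as.integer(n_param_chains),
              param_generations = as.integer(param_generations),
              burnin_factor = burnin_factor, param_belief = param_belief,
              minichain_belief = minichain_belief,
              samples_per_tree = as.integer(samples_per_tree),
              n_trees = as.integer(n_trees), ess_target = ess_target,
              minichain_thin = as.integer(minichain_thin))
  stopifnot(all(vapply(cfg, function(v) is.numeric(v) && v > 0, logical(1))),
            cfg$samples_per_tree >= 1)
  structure(cfg, class = "minichain_config")
}

#' Autocorrelation-time effective sample size
#'
#' Geyer initial monotone positive sequence estimator: autocovariances are
#' summed in consecutive pairs until the first nonpositive pair sum, with the
#' running minimum enforced, giving the integrated autocorrelation time; the
#' ESS is `n` over that time, capped at `n`.
#'
#' @param x numeric sample sequence of length >= 10 with finite values.
#' @return estimated effective sample size in `[1, n]`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 values")
  if (!all(is.finite(x))) stop("non-finite values in sequence")
  if (stats::var(x) == 0) stop("effective sample size undefined for a zero-variance sequence")
  lag_max <- min(n - 1L, max(200L, floor(10 * sqrt(n))))
  ac <- stats::acf(x, lag.max = lag_max, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  g0 <- ac[1]
  M <- floor((length(ac) - 2) / 2)
  if (M < 0) return(n)
  gam <- vapply(0:M, function(m) ac[2 * m + 1] + ac[2 * m + 2], numeric(1))
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1] - 1)]
  if (length(gam) > 1) gam <- cummin(gam)    # initial monotone sequence
  sigma2 <- -g0 + 2 * sum(gam)
  if (sigma2 <= 0) return(n)
  min(n, max(1, n * g0 / sigma2))
}

# First iteration at which a likelihood trace reaches its own median.
first_median_crossing <- function(trace) {
  med <- stats::median(trace)
  which(trace >= med)[1]
}

# Conservative burn-in: factor times the latest first crossing across chains
# (tiny epsilon so 1.1 * 200 stays 220 under floating point).
burnin_from_crossings <- function(crossings, factor = 1.1) {
  as.integer(ceiling(factor * max(crossings) - 1e-9))
}

#' Run parameterization chains and derive burn-in and informed priors
#'
#' Runs independent chains with flat priors on the supplied (consensus) tree.
#' The burn-in estimate is the burn-in factor times the highest iteration
#' count any chain needed to first reach its median posterior likelihood,
#' taken conservatively across chains. Informed priors are the elementwise
#' median posterior matrices (pooled post-burn-in across chains, projected
#' onto the PSD cone) with the mini-chain belief.
#'
#' @param traits,tree,hierarchy as in [pglmm_rates()]; `tree` is normally the
#'   [consensus_tree()] of the distribution.
#' @param config a [minichain_config()].
#' @param seed master seed; per-chain seeds are derived with a counter-based
#'   splitter.
#' @return list with `burnin` (integer), `priors` (named list of
#'   [prior_spec()] per term), `first_crossings`, and `chains` (the fits).
#' @export
run_parameterization_chains <- function(traits, tree, hierarchy = NULL,
                                        config = minichain_config(),
                                        seed = 1L) {
  k <- ncol(traits)
  chains <- lapply(seq_len(config$n_param_chains), function(c_id) {
    pglmm_rates(traits, tree, hierarchy,
                priors = flat_prior(k, config$param_belief),
                n_iter = config$param_generations, burnin = 0, thin = 1,
                seed = derive_seed(seed, c_id), chain_id = c_id)
  })
  crossings <- vapply(chains, function(f) first_median_crossing(f$loglik),
                      numeric(1))
  if (anyNA(crossings)) stop("a chain never reached its median posterior likelihood")
  burnin <- burnin_from_crossings(crossings, config$burnin_factor)

  terms <- names(chains[[1]]$posteriors)
  priors <- stats::setNames(lapply(terms, function(tm) {
    pooled <- lapply(chains, function(f) {
      sm <- f$posteriors[[tm]]$samples
      keep <- f$posteriors[[tm]]$provenance$iteration > min(burnin, dim(sm)[3] - 1L)
      sm[, , keep, drop = FALSE]
    })
    arr <- array(unlist(pooled), dim = c(k, k, sum(vapply(pooled, function(a) dim(a)[3], numeric(1)))))
    V <- psd_project(apply(arr, c(1, 2), stats::median), floor_frac = 1e-8)
    prior_spec(V, config$minichain_belief * k)
  }), terms)

  list(burnin = burnin, priors = priors, first_crossings = crossings,
       chains = chains)
}

#' Run mini chains over a tree set and concatenate their posteriors
#'
#' One short chain per tree, each started past the pre-estimated burn-in with
#' the informed priors, keeping `samples_per_tree` thinned samples. The kept
#' samples are concatenated per term into a single posterior whose provenance
#' records (tree, chain, iteration) for every sample, and effective sample
#' sizes of all distinct rate-matrix entries are reported against the target.
#'
#' @param traits,hierarchy as in [pglmm_rates()].
#' @param tree_set `multiPhylo` or list of trees sharing a tip set.
#' @param config a [minichain_config()]; `config$n_trees` caps how many trees
#'   are used (all trees of the set if fewer).
#' @param priors named list of [prior_spec()] per term (from
#'   [run_parameterization_chains()]).
#' @param burnin iterations each mini chain discards.
#' @param seed master seed; per-tree seeds derived with the counter splitter.
#' @return object of class `mini_chains`: list with `posteriors` (named list
#'   of [rate_posterior()] per term), `ess` (diagnostics table), `ess_target`,
#'   and `config`.
#' @export
run_mini_chains <- function(traits, tree_set, hierarchy = NULL,
                            config = minichain_config(), priors, burnin,
                            seed = 1L) {
  if (inherits(tree_set, "phylo")) tree_set <- list(tree_set)
  if (length(tree_set) == 0) stop("empty tree set")
  tips0 <- sort(tree_set[[1]]$tip.label)
  for (tr in tree_set)
    if (!identical(sort(tr$tip.label), tips0))
      stop("all trees must share the same tip set")
  n_trees <- min(length(tree_set), config$n_trees)
  thin <- config$minichain_thin
  n_iter <- burnin + config$samples_per_tree * thin

  fits <- lapply(seq_len(n_trees), function(i) {
    pglmm_rates(traits, tree_set[[i]], hierarchy, priors = priors,
                n_iter = n_iter, burnin = burnin, thin = thin,
                seed = derive_seed(seed, 1000L + i),
                tree_id = i, chain_id = i)
  })

  terms <- names(fits[[1]]$posteriors)
  k <- fits[[1]]$k
  posteriors <- stats::setNames(lapply(terms, function(tm) {
    arrs <- lapply(fits, function(f) f$posteriors[[tm]]$samples)
    prov <- do.call(rbind, lapply(fits, function(f) f$posteriors[[tm]]$provenance))
    rate_posterior(array(unlist(arrs),
                         dim = c(k, k, n_trees * config$samples_per_tree)),
                   term = tm, provenance = prov)
  }), terms)

  ess <- ess_table(posteriors)
  structure(list(posteriors = posteriors, ess = ess,
                 ess_target = config$ess_target, config = config,
                 n_trees = n_trees, burnin = burnin, seed = seed),
            class = "mini_chains")
}

#' @export
print.mini_chains <- function(x, ...) {
  N <- n_samples(x$posteriors[[1]])
  cat(sprintf("Mini-chains posterior: %d trees x %d samples = %d concatenated samples per term\n",
              x$n_trees, x$config$samples_per_tree, N))
  ok <- x$ess$ess >= x$ess_target
  cat(sprintf("  ESS >= %g for %d / %d rate-matrix entries (min ESS %.0f)\n",
              x$ess_target, sum(ok, na.rm = TRUE), length(ok),
              min(x$ess$ess, na.rm = TRUE)))
  invisible(x)
}
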