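# The Gibbs sampler for nested rate matrices, the burn-in rule, informed
# priors, mini-chains bookkeeping, and the effective sample size estimator.

entry_se <- function(x) sd(x) / sqrt(effective_sample_size(x))

test_that("residual-only posterior mean matches the conjugate closed form", {
  set.seed(101)
  n <- 80; k <- 3
  Y <- matrix(rnorm(n * k), n, k) %*% chol(diag(c(2, 1, 0.5)))
  pr <- flat_prior(k, 0.02)
  fit <- pglmm_rates(Y, tree = NULL, n_iter = 6500, burnin = 500, seed = 102)
  post <- fit$posteriors$residual
  pm <- posterior_mean(post)
  # closed form: with a flat mean prior, E | Y ~ IW(Psi + centered scatter,
  # nu + n - 1), whose mean is the ratio below
  Sc <- crossprod(scale(Y, scale = FALSE))
  oracle <- (pr$nu * pr$V + Sc) / (pr$nu + n - 1 - k - 1)
  for (i in 1:k) for (j in i:k) {
    se <- entry_se(post$samples[i, j, ])
    expect_lt(abs(pm[i, j] - oracle[i, j]), 3 * se + 0.02 * abs(oracle[i, j]))
  }
})

test_that("every posterior sample is symmetric PSD with bijective provenance", {
  tr <- simulate_yule_tree(24, seed = 110)
  gt <- ground_truth(class_R = diag(2), residual_E = 0.2 * diag(2))
  y <- simulate_traits(unit_height(tr), truth = gt, seed = 111)
  fit <- pglmm_rates(y, tr, n_iter = 120, burnin = 20, seed = 112)
  for (tm in names(fit$posteriors)) {
    post <- fit$posteriors[[tm]]
    for (s in seq_len(dim(post$samples)[3]))
      expect_true(macroaxes:::is_symmetric_psd(post$samples[, , s]))
    expect_false(any(duplicated(post$provenance)))
  }
})

test_that("class term and residual collapse to the conjugate total on a star tree", {
  set.seed(120)
  n <- 60; k <- 2
  tr <- star_tree(n)
  Y <- matrix(rnorm(n * k), n, k) %*% chol(matrix(c(1.5, .5, .5, 1), 2))
  rownames(Y) <- tr$tip.label
  fit <- pglmm_rates(Y, tr, n_iter = 8500, burnin = 500, seed = 121)
  tot <- fit$posteriors$phylogeny$samples + fit$posteriors$residual$samples
  pm <- apply(tot, c(1, 2), mean)
  pr <- flat_prior(k, 0.02)
  Sc <- crossprod(scale(Y, scale = FALSE))
  # the sum gets both terms' prior mass; each term is IW with scale nu*V
  oracle <- (2 * pr$nu * pr$V + Sc) / (2 * pr$nu + n - 1 - k - 1)
  for (i in 1:k) for (j in i:k) {
    se <- entry_se(tot[i, j, ])
    expect_lt(abs(pm[i, j] - oracle[i, j]), 3 * se + 0.03 * abs(oracle[i, j]))
  }
})

test_that("raising the prior belief shrinks the posterior mean toward the prior scale", {
  set.seed(130)
  n <- 50; k <- 2
  Y <- matrix(rnorm(n * k, sd = 2), n, k)     # data variance 4, prior scale I
  V <- diag(k)
  dists <- vapply(c(0.1, 20, 200), function(nu) {
    fit <- pglmm_rates(Y, tree = NULL, priors = prior_spec(V, nu),
                       n_iter = 3000, burnin = 500, seed = 131)
    norm(posterior_mean(fit$posteriors$residual) - V, "F")
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("the burn-in rule follows 1.1 x the latest first median crossing", {
  expect_equal(macroaxes:::first_median_crossing(rep(5, 100)), 1L)
  expect_equal(macroaxes:::burnin_from_crossings(1), 2L)   # constant trace
  rising <- c(seq(-100, 0, length.out = 50), rep(0, 50))
  expect_equal(macroaxes:::first_median_crossing(rising),
               which(rising >= median(rising))[1])
  expect_equal(macroaxes:::burnin_from_crossings(c(100, 200, 150)), 220L)
})

test_that("parameterization chains return usable burn-in and informed priors", {
  tr <- unit_height(simulate_yule_tree(24, seed = 140))
  gt <- ground_truth(class_R = make_rate_matrix(c(2, 1)),
                     residual_E = 0.1 * diag(2))
  y <- simulate_traits(tr, truth = gt, seed = 141)
  cfg <- minichain_config(n_param_chains = 3, param_generations = 150,
                          samples_per_tree = 5, n_trees = 3,
                          minichain_thin = 2)
  pc <- run_parameterization_chains(y, tr, config = cfg, seed = 142)
  expect_length(pc$first_crossings, 3)
  expect_gte(pc$burnin, ceiling(1.1 * max(pc$first_crossings)) - 1)
  for (tm in c("phylogeny", "residual")) {
    expect_s3_class(pc$priors[[tm]], "prior_spec")
    expect_true(macroaxes:::is_symmetric_psd(pc$priors[[tm]]$V))
    expect_equal(pc$priors[[tm]]$nu, cfg$minichain_belief * 2)
  }
})

test_that("mini chains keep exactly n_trees x samples_per_tree aligned samples", {
  tr <- unit_height(simulate_yule_tree(20, seed = 150))
  gt <- ground_truth(class_R = diag(2), residual_E = 0.1 * diag(2))
  y <- simulate_traits(tr, truth = gt, seed = 151)
  trees <- simulate_tree_set(tr, 5, seed = 152)
  cfg <- minichain_config(samples_per_tree = 10, n_trees = 5,
                          minichain_thin = 2, param_generations = 100)
  mc <- run_mini_chains(y, trees, config = cfg, priors = flat_prior(2, 0.05),
                        burnin = 30, seed = 153)
  for (tm in names(mc$posteriors)) {
    post <- mc$posteriors[[tm]]
    expect_equal(dim(post$samples)[3], 50L)
    expect_false(any(duplicated(post$provenance[c("tree", "iteration")])))
    expect_setequal(unique(post$provenance$tree), 1:5)
  }
  expect_true(all(table(mc$posteriors$phylogeny$provenance$tree) == 10))
  t2 <- simulate_yule_tree(21, seed = 99)
  expect_error(run_mini_chains(y, list(tr, t2), config = cfg,
                               priors = flat_prior(2, 0.05), burnin = 10),
               "tip set")
})

test_that("effective sample size is calibrated on white noise and AR(1)", {
  set.seed(160)
  n <- 10000
  expect_equal(effective_sample_size(rnorm(n)), n, tolerance = 0.1)
  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(effective_sample_size(x), n * (1 - rho) / (1 + rho),
               tolerance = 0.25)
  expect_error(effective_sample_size(rep(1, 100)), "zero-variance")
  expect_error(effective_sample_size(rnorm(5)), "at least 10")
})
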