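# Folded angles, the orthogonality metric, and posterior angle comparisons.

test_that("folded angles collapse direction and scale", {
  v <- c(1, 2, 3)
  expect_equal(folded_angle(v, v), 0)
  expect_equal(folded_angle(v, -v), 0)
  expect_equal(folded_angle(c(1, 0), c(0, 1)), 90)
  expect_error(folded_angle(c(0, 0), v[1:2]), "zero vector")
  set.seed(301)
  for (r in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(folded_angle(a, b), folded_angle(b, a))
    expect_equal(folded_angle(3.7 * a, -0.2 * b), folded_angle(a, b),
                 tolerance = 1e-10)
  }
})

test_that("orthogonality is the calibrated rescaling of the folded angle", {
  expect_identical(orthogonality(45), 0.5)
  expect_identical(orthogonality(67.5), 0.75)
  expect_identical(orthogonality(0), 0)
  expect_identical(orthogonality(90), 1)
  expect_error(orthogonality(91), "90")
  expect_error(orthogonality(-1), "90")
  # monotone bijection on a grid
  g <- seq(0, 90, by = 1.5)
  expect_true(all(diff(orthogonality(g)) > 0))
})

constant_posterior <- function(R, n = 20, term = "t") {
  rate_posterior(array(R, c(nrow(R), nrow(R), n)), term = term)
}

test_that("between-clade angles recover planted offsets", {
  Ra <- diag(c(4, 1)); Rb <- diag(c(1, 4))
  same <- between_clade_angles(constant_posterior(Ra), constant_posterior(Ra))
  expect_true(all(same$angles == 0))
  orth <- between_clade_angles(constant_posterior(Ra), constant_posterior(Rb))
  expect_true(all(orth$angles == 90))
  expect_true(all(orth$orthogonality == 1))

  R0 <- make_rate_matrix(c(6, 1, 1), planar_angle = 0)
  R30 <- make_rate_matrix(c(6, 1, 1), planar_angle = 30)
  ad <- between_clade_angles(noisy_posterior(R0, 200, 600, "a", 311),
                             noisy_posterior(R30, 200, 600, "b", 312))
  expect_lt(abs(median(ad$angles) - 30), 5)
  expect_equal(ad$orthogonality, ad$angles / 90)

  short <- constant_posterior(Ra, n = 10)
  expect_error(between_clade_angles(constant_posterior(Ra, 20), short),
               "sample counts")
})

test_that("the within-clade null orders correctly against real offsets", {
  expect_true(all(within_clade_null(constant_posterior(diag(c(4, 1)), 30),
                                    n_pairs = 100, seed = 1)$angles == 0))
  R <- make_rate_matrix(c(100, 1, 1), planar_angle = 60)
  anis <- noisy_posterior(R, 100, 500, "c", 321)
  nul <- within_clade_null(anis, n_pairs = 400, seed = 322)
  betw <- between_clade_angles(anis,
                               noisy_posterior(make_rate_matrix(c(100, 1, 1),
                                                                planar_angle = 0),
                                               100, 500, "p", 323))
  expect_lt(median(nul$angles), median(betw$angles))
  expect_error(within_clade_null(constant_posterior(diag(2), 1)), "at least 2")
})

test_that("an isotropic posterior's null matches random directions", {
  # Wishart(I) is rotation-invariant: its leading eigenvector is uniform on
  # the sphere, so the null should match angles between random directions.
  k <- 8
  set.seed(331)
  iso <- rate_posterior(stats::rWishart(300, df = k + 2, Sigma = diag(k)),
                        term = "iso")
  nul <- within_clade_null(iso, n_pairs = 1500, seed = 332)
  rand_angles <- vapply(1:4000, function(i)
    folded_angle(rnorm(k), rnorm(k)), numeric(1))
  expect_lt(abs(median(nul$angles) - median(rand_angles)), 4)
})

test_that("posterior probabilities of orthogonality behave as probabilities", {
  pp1 <- orthogonality_pp(rep(90, 10), rep(0, 10))
  expect_equal(as.numeric(pp1), 1)
  expect_equal(attr(pp1, "signif"), "***")

  set.seed(341)
  x <- runif(8000, 0, 90)
  y <- runif(8000, 0, 90)
  pp <- orthogonality_pp(x, y, n_draws = 10000, seed = 342)
  expect_lt(abs(as.numeric(pp) - 0.5), 0.02)

  # exhaustive mode equals the brute-force double loop exactly
  b <- runif(40, 30, 90); w <- runif(35, 0, 60)
  pp_ex <- orthogonality_pp(b, w)
  expect_equal(attr(pp_ex, "method"), "exhaustive")
  acc <- 0
  for (i in seq_along(b)) for (j in seq_along(w)) acc <- acc + (b[i] > w[j])
  expect_identical(as.numeric(pp_ex), acc / (length(b) * length(w)))

  # complementarity under continuity
  expect_equal(as.numeric(orthogonality_pp(b, w)) +
               as.numeric(orthogonality_pp(w, b)), 1)
})

test_that("the orthogonality report covers every clade with its parent", {
  k <- 3
  X <- matrix(rnorm(30 * k), 30); rownames(X) <- paste0("t", 1:30)
  h <- clade_hierarchy(data.frame(tip = rownames(X),
                                  level1 = rep(c("A", "B"), each = 15)),
                       min_size = 5)
  posts <- list(
    phylogeny = noisy_posterior(make_rate_matrix(c(5, 1, 1), planar_angle = 0),
                                60, 500, "phylogeny", 351),
    A = noisy_posterior(make_rate_matrix(c(5, 1, 1), planar_angle = 80),
                        60, 500, "A", 352),
    B = noisy_posterior(make_rate_matrix(c(5, 1, 1), planar_angle = 5),
                        60, 500, "B", 353))
  rep <- orthogonality_report(posts, h, n_null = 200, seed = 354)
  expect_setequal(rep$clade, c("A", "B"))
  expect_true(all(rep$parent == "phylogeny"))
  expect_gt(rep$ortho_class_median[rep$clade == "A"],
            rep$ortho_class_median[rep$clade == "B"])
  expect_gt(rep$pp_class[rep$clade == "A"], 0.9)
  expect_equal(rep$n_species, c(15, 15))
})
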