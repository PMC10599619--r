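# Projection/rejection geometry: major axes, species and clade scores.

CHISQ95_DF2 <- 5.991464547108  # 95% chi-square quantile, 2 df (reference value)

test_that("major axis of a diagonal matrix has the tabulated extent", {
  ax <- major_axis(diag(c(4, 1)), centre = c(0, 0), level = 0.95)
  expect_equal(ax$direction, c(1, 0))
  expect_equal(ax$half_length, 2 * sqrt(CHISQ95_DF2), tolerance = 1e-9)
  expect_error(major_axis(matrix(0, 2, 2)), "zero")
})

test_that("tied leading eigenvalues fall back to the lowest axis with a warning", {
  expect_warning(ax <- major_axis(diag(3)), "tie")
  expect_equal(ax$direction, c(1, 0, 0))
})

test_that("the major axis rotates with the matrix", {
  set.seed(201)
  R <- make_rate_matrix(c(5, 2, 1, 0.5), orientation_seed = 7)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  v <- major_axis(R)$direction
  v_rot <- major_axis(Q %*% R %*% t(Q))$direction
  expect_lt(folded_angle(v_rot, Q %*% v), 1e-8)
})

test_that("projection scores satisfy the defining identities", {
  set.seed(202)
  ax <- major_axis(make_rate_matrix(c(4, 2, 1), orientation_seed = 3),
                   centre = rnorm(3))
  expect_equal(unname(project_point(ax$centre, ax)), c(0, 0))
  tip <- ax$centre + ax$half_length * ax$direction
  expect_equal(unname(project_point(tip, ax)), c(1, 0), tolerance = 1e-12)

  # Pythagoras in k = 8, random points and axes
  for (r in 1:200) {
    R <- make_rate_matrix(sort(rexp(8), decreasing = TRUE) + 0.1,
                          orientation_seed = 300 + r)
    ax <- major_axis(R, centre = rnorm(8))
    p <- rnorm(8, sd = 3)
    sc <- project_point(p, ax)
    d2 <- sum((p - ax$centre)^2) / ax$half_length^2
    expect_equal(unname(sc[1]^2 + sc[2]^2), d2, tolerance = 1e-10)
  }
  expect_error(project_point(rnorm(3), ax), "dimension")
})

test_that("scores are homogeneous in the half-length and sign-invariant", {
  ax <- major_axis(diag(c(9, 1)), centre = c(1, 1))
  p <- c(4, -2)
  s1 <- project_point(p, ax)
  ax2 <- ax; ax2$half_length <- 2 * ax$half_length
  expect_equal(unname(project_point(p, ax2)), unname(s1) / 2)
  ax3 <- ax; ax3$direction <- -ax$direction
  expect_equal(project_point(p, ax3), s1)
})

test_that("clade-axis projection reduces to planar trigonometry", {
  par <- major_axis(diag(c(4, 1, 1)), centre = c(0, 0, 0))
  child_same <- par
  expect_equal(unname(project_clade_axis(child_same, par)), c(1, 0),
               tolerance = 1e-12)
  child_orth <- major_axis(diag(c(1, 4, 1)), centre = c(9, 9, 9))
  child_orth$half_length <- par$half_length
  expect_equal(unname(project_clade_axis(child_orth, par)), c(0, 1),
               tolerance = 1e-12)
  for (theta in c(15, 30, 45, 60, 85)) {
    Rc <- make_rate_matrix(c(4, 1, 1), planar_angle = theta)
    child <- major_axis(Rc, centre = rnorm(3))
    child$half_length <- par$half_length
    sc <- project_clade_axis(child, par)
    expect_equal(unname(sc), c(cos(theta * pi / 180), sin(theta * pi / 180)),
                 tolerance = 1e-10)
  }
})

planted_fixture <- function(k = 4, n_sp = 12, seed = 210) {
  set.seed(seed)
  v <- c(1, rep(0, k - 1))
  w <- c(0, 1, rep(0, k - 2))
  centre <- rnorm(k)
  along <- sample(c(-1, 1), n_sp, TRUE) * runif(n_sp, 1.5, 3)
  orth <- rnorm(n_sp, sd = mean(abs(along)) / 2 / 2)  # displacement 2x the noise
  X <- matrix(rep(centre, each = n_sp), n_sp, k) +
    outer(along, v) + outer(orth, w)
  rownames(X) <- paste0("t", seq_len(n_sp))
  X
}

test_that("species displaced along the planted axis elaborate more than they innovate", {
  k <- 4
  X <- planted_fixture(k)
  R <- make_rate_matrix(c(4, 1, 0.5, 0.25), planar_angle = 0)
  posts <- list(phylogeny = noisy_posterior(R, n = 40, df = 400, term = "phylogeny",
                                            seed = 211))
  st <- score_all(X, posts, mode = "species", reference = "class")
  sm <- summary(st)
  expect_gte(mean(sm$elab_median > sm$innov_median), 0.9)
})

test_that("a clade displaced orthogonally to the parent axis innovates", {
  k <- 4
  n_sp <- 30
  set.seed(215)
  X <- matrix(rnorm(n_sp * k, sd = 0.3), n_sp, k)
  rownames(X) <- paste0("t", seq_len(n_sp))
  h <- clade_hierarchy(data.frame(tip = rownames(X),
                                  level1 = rep(c("A", "B"), c(15, 15))),
                       min_size = 5)
  R_par <- make_rate_matrix(c(4, 1, 1, 1), planar_angle = 0)
  R_child <- make_rate_matrix(c(4, 1, 1, 1), planar_angle = 90)
  posts <- list(phylogeny = noisy_posterior(R_par, 40, 800, "phylogeny", 216),
                A = noisy_posterior(R_child, 40, 800, "A", 217),
                B = noisy_posterior(R_par, 40, 800, "B", 218))
  st <- score_all(X, posts, h, mode = "clade", reference = "parent")
  sm <- summary(st)
  a <- sm[sm$entity == "A", ]
  b <- sm[sm$entity == "B", ]
  expect_gt(a$innov_median, a$elab_median)
  expect_gt(b$elab_median, b$innov_median)
})

test_that("scores are invariant under a joint rigid rotation", {
  set.seed(220)
  k <- 4
  X <- matrix(rnorm(10 * k), 10); rownames(X) <- paste0("t", 1:10)
  R <- make_rate_matrix(c(4, 2, 1, 0.5), orientation_seed = 5)
  posts <- list(phylogeny = noisy_posterior(R, 20, 500, "phylogeny", 221))
  st <- score_all(X, posts, mode = "species", reference = "class")

  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  Xr <- X %*% t(Q); rownames(Xr) <- rownames(X)
  posts_r <- posts
  for (s in seq_len(dim(posts_r$phylogeny$samples)[3]))
    posts_r$phylogeny$samples[, , s] <-
      Q %*% posts_r$phylogeny$samples[, , s] %*% t(Q)
  st_r <- score_all(Xr, posts_r, mode = "species", reference = "class")
  expect_equal(st_r$elaboration, st$elaboration, tolerance = 1e-8)
  expect_equal(st_r$innovation, st$innovation, tolerance = 1e-8)
})

test_that("score tables summarize consistently with their samples", {
  set.seed(230)
  X <- matrix(rnorm(8 * 3), 8); rownames(X) <- paste0("t", 1:8)
  posts <- list(phylogeny = noisy_posterior(diag(c(3, 2, 1)), 25, 300,
                                            "phylogeny", 231))
  st <- score_all(X, posts, mode = "species", reference = "class")
  sm <- summary(st)
  one <- st[st$entity == "t1", ]
  expect_equal(sm$elab_median[sm$entity == "t1"], median(one$elaboration))
  expect_equal(sm$innov_q975[sm$entity == "t1"],
               unname(quantile(one$innovation, 0.975)))
  expect_true(all(st$elaboration >= 0) && all(st$innovation >= 0))
})
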