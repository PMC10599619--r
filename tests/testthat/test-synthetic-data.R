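# Synthetic-data module: Yule trees, carved clades, rate-matrix construction
# and nested-Brownian trait simulation.

test_that("yule trees have the right shape and are deterministic", {
  cherry <- simulate_yule_tree(2, seed = 1)
  expect_length(cherry$tip.label, 2)
  el <- cherry$edge.length
  expect_equal(el[1], el[2])                      # ultrametric cherry
  expect_gt(el[1], 0)

  tr <- simulate_yule_tree(50, seed = 3)
  expect_equal(tr$Nnode, 49L)                     # bifurcating: n - 1 internals
  expect_equal(nrow(tr$edge), 98L)                # 2n - 2 edges
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.rooted(tr))

  expect_identical(simulate_yule_tree(20, seed = 7),
                   simulate_yule_tree(20, seed = 7))
  expect_false(identical(simulate_yule_tree(20, seed = 7),
                         simulate_yule_tree(20, seed = 8)))
  expect_error(simulate_yule_tree(1), "n_tips")
  expect_error(simulate_yule_tree(10, birth_rate = 0), "birth_rate")
})

test_that("lineage accumulation matches the pure-birth expectation", {
  # E[N(t)] = 2 e^{b t} for a pure-birth process started from the root split;
  # counted from branching depths, averaged over replicates, at times small
  # enough that stopping at n_tips does not truncate.
  b <- 1
  reps <- 400
  counts <- vapply(seq_len(reps), function(r) {
    tr <- simulate_yule_tree(60, birth_rate = b, seed = 1000 + r)
    h <- max(ape::node.depth.edgelength(tr))
    depths <- h - ape::branching.times(tr)         # internal node depths
    vapply(c(0.5, 1.0), function(t0) 2 + sum(depths > 1e-12 & depths <= t0),
           numeric(1))
  }, numeric(2))
  means <- rowMeans(counts)
  expect_equal(means[1], 2 * exp(b * 0.5), tolerance = 0.12)
  expect_equal(means[2], 2 * exp(b * 1.0), tolerance = 0.12)
})

test_that("carved clades are monophyletic, disjoint, nested and large enough", {
  for (s in 1:4) {
    tr <- simulate_yule_tree(80, seed = 20 + s)
    h <- carve_clades(tr, c(2, 4), min_size = 4, seed = 30 + s)
    for (lv in names(h$levels)) {
      members <- h$levels[[lv]]
      expect_equal(anyDuplicated(unlist(members)), 0L)
      for (cl in names(members)) {
        expect_gt(length(members[[cl]]), 4)
        expect_true(oracle_is_monophyletic(tr, members[[cl]]))
      }
    }
    # nesting: every level-2 clade inside some level-1 clade
    for (cl in names(h$levels$level2)) {
      inside <- vapply(h$levels$level1, function(p)
        all(h$levels$level2[[cl]] %in% p), logical(1))
      expect_true(any(inside))
    }
  }
})

test_that("carve_clades handles trivial and infeasible requests", {
  tr <- simulate_yule_tree(30, seed = 5)
  whole <- carve_clades(tr, 1, min_size = 5, seed = 1)
  expect_setequal(whole$levels$level1[[1]], tr$tip.label)
  expect_error(carve_clades(tr, 2, min_size = 30), "min_size")
  expect_error(carve_clades(tr, 40, min_size = 2, seed = 1), "infeasible")
})

test_that("make_rate_matrix reproduces its eigenstructure", {
  expect_equal(make_rate_matrix(c(4, 1), planar_angle = 0), diag(c(4, 1)))
  expect_equal(make_rate_matrix(c(3, 3, 3), orientation_seed = 2), 3 * diag(3))

  R <- make_rate_matrix(c(4, 1), planar_angle = 30)
  v <- eigen(R, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(abs(v[2]), abs(v[1])) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-8)
  expect_equal(sort(eigen(R)$values), c(1, 4), tolerance = 1e-10)

  R8 <- make_rate_matrix(c(5, 3, 2, 1), orientation_seed = 9)
  expect_equal(eigen(R8, symmetric = TRUE)$values, c(5, 3, 2, 1),
               tolerance = 1e-10)
  expect_error(make_rate_matrix(c(4, -1)), "nonnegative")
  expect_error(make_rate_matrix(c(1, 4)), "decreasing")
})

test_that("zero-variance ground truth returns the root state exactly", {
  tr <- simulate_yule_tree(12, seed = 2)
  gt <- ground_truth(class_R = matrix(0, 3, 3), residual_E = matrix(0, 3, 3),
                     root_state = c(1, -2, 0.5))
  y <- simulate_traits(tr, truth = gt, seed = 1)
  expect_equal(unname(y), matrix(rep(c(1, -2, 0.5), each = 12), 12, 3))
})

test_that("two-tip Brownian difference has the analytic covariance", {
  # tips separated by total path 2t: y1 - y2 ~ MVN(0, 2 t R)
  tree <- ape::read.tree(text = "(a:1,b:1);")
  R <- matrix(c(2, 1, 1, 2), 2)
  gt <- ground_truth(class_R = R, residual_E = matrix(0, 2, 2))
  set.seed(99)
  diffs <- t(vapply(seq_len(3000), function(r) {
    y <- simulate_traits(tree, truth = gt, seed = 5000 + r)
    y[1, ] - y[2, ]
  }, numeric(2)))
  emp <- stats::cov(diffs)
  expect_equal(unname(emp), 2 * R, tolerance = 0.12)
})

test_that("star-tree residual-only simulation recovers the residual covariance", {
  tr <- star_tree(2000)
  E <- matrix(c(1, 0.4, 0.4, 0.5), 2)
  gt <- ground_truth(class_R = matrix(0, 2, 2), residual_E = E)
  y <- simulate_traits(tr, truth = gt, seed = 11)
  expect_equal(unname(stats::cov(y)), E, tolerance = 0.1)
})

test_that("clade deviation terms are structurally zero outside the clade", {
  tr <- simulate_yule_tree(40, seed = 13)
  h <- carve_clades(tr, 2, min_size = 6, seed = 14)
  cl <- names(h$levels$level1)[1]
  cladeR <- stats::setNames(list(diag(2), matrix(0, 2, 2)),
                            names(h$levels$level1))
  gt <- ground_truth(class_R = matrix(0, 2, 2), clade_R = cladeR,
                     residual_E = matrix(0, 2, 2), hierarchy = h)
  y <- simulate_traits(tr, h, gt, seed = 15)
  outside <- setdiff(rownames(y), h$levels$level1[[cl]])
  expect_true(all(y[outside, ] == 0))
  expect_true(any(y[h$levels$level1[[cl]], ] != 0))
})

test_that("trait simulation is seed-deterministic", {
  tr <- simulate_yule_tree(15, seed = 4)
  gt <- ground_truth(class_R = diag(2), residual_E = 0.1 * diag(2))
  expect_identical(simulate_traits(tr, truth = gt, seed = 8),
                   simulate_traits(tr, truth = gt, seed = 8))
  expect_false(identical(simulate_traits(tr, truth = gt, seed = 8),
                         simulate_traits(tr, truth = gt, seed = 9)))
})

test_that("recorded ground-truth angles equal recomputed ones", {
  tr <- simulate_yule_tree(60, seed = 21)
  h <- carve_clades(tr, 2, min_size = 8, seed = 22)
  cls <- names(h$levels$level1)
  cladeR <- stats::setNames(list(make_rate_matrix(c(4, 1, 0.5), planar_angle = 60),
                                 make_rate_matrix(c(4, 1, 0.5), planar_angle = 150)),
                            cls)
  gt <- ground_truth(class_R = make_rate_matrix(c(4, 1, 0.5), planar_angle = 0),
                     clade_R = cladeR, residual_E = 0.01 * diag(3),
                     hierarchy = h)
  expect_equal(unname(gt$major_axis_angles[cls[1]]), 60, tolerance = 1e-8)
  expect_equal(unname(gt$major_axis_angles[cls[2]]), 30, tolerance = 1e-8) # folded
})
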