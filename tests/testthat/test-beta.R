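test_that("PhyloSor worked examples are exact", {
  tr <- demo_tree()
  expect_equal(phylosor(tr, c("A", "B"), c("A", "B")), 1)
  expect_equal(phylo_beta(tr, c("A", "B"), c("A", "B")), 0)
  expect_equal(phylosor(tr, c("A", "B"), c("A", "C")), 4 / 7)
  # disjoint clades under a zero-length root edge: complete turnover
  expect_equal(phylo_beta(tr, c("A", "B"), c("C", "D")), 1)
})

test_that("PhyloSor is symmetric, bounded, and oracle-consistent", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      tr <- random_coalescent(10)
      tr$root.edge <- 0
      a <- sample(tr$tip.label, 4)
      b <- sample(tr$tip.label, 5)
      ps <- phylosor(tr, a, b)
      expect_equal(ps, phylosor(tr, b, a), tolerance = 1e-12)
      expect_gte(ps, 0)
      expect_lte(ps, 1)
      expect_equal(ps, oracle_phylosor(tr, a, b), tolerance = 1e-10)
      # shared length bounded by the smaller spanning subtree
      shared <- ps * (faith_pd(tr, a) + faith_pd(tr, b)) / 2
      expect_lte(shared, min(faith_pd(tr, a), faith_pd(tr, b)) + 1e-12)
    }
  })
})

test_that("nested assemblages attain the shared-length bound", {
  tr <- demo_tree()
  a <- c("A", "B")
  ab <- c("A", "B", "C")
  shared <- phylosor(tr, a, ab) * (faith_pd(tr, a) + faith_pd(tr, ab)) / 2
  expect_equal(shared, min(faith_pd(tr, a), faith_pd(tr, ab)), tolerance = 1e-12)
})

test_that("ses_phylosor flags degenerate nulls and detects clade turnover", {
  tr <- balanced_tree(5) # 32 tips
  # identical assemblages: dissimilarity 0 under every relabelling
  same <- ses_phylosor(tr, c("t01", "t02"), c("t01", "t02"), n_rand = 49, seed = 1)
  expect_true(same$degenerate)

  # one basal clade versus the other maximizes unshared branch length
  left <- tr$tip.label[1:16]
  right <- tr$tip.label[17:32]
  hits <- vapply(1:20, function(s) {
    ses_phylosor(tr, left, right, n_rand = 199, seed = s)$ses
  }, numeric(1))
  expect_gte(mean(hits > 1.96), 0.95)
})

test_that("random uniform assemblage pairs mostly look like chance", {
  tr <- random_coalescent(40)
  withr::with_seed(14, {
    vals <- vapply(1:60, function(i) {
      a <- sample(tr$tip.label, 10)
      b <- sample(tr$tip.label, 10)
      ses_phylosor(tr, a, b, n_rand = 99)$ses
    }, numeric(1))
  })
  expect_gte(mean(abs(vals) < 1.96), 0.90)
})

test_that("temporal beta is zero without change and grows with introductions", {
  cfg0 <- sim_config(
    n_islands = 3, native_pool = 30, exotic_pool = 10,
    occupancy = 0.4, extinction_fraction = 0, introductions = 0
  )
  sys0 <- simulate_system(cfg0, seed = 5)
  tb0 <- temporal_beta(sys0$tree, sys0$flora)
  expect_equal(tb0$beta, rep(0, nrow(tb0)), tolerance = 1e-12)

  cfg1 <- sim_config(
    n_islands = 3, native_pool = 30, exotic_pool = 60,
    occupancy = 0.4, extinction_fraction = 0.1, introductions = 30
  )
  sys1 <- simulate_system(cfg1, seed = 5)
  heavy <- temporal_beta(sys1$tree, sys1$flora)
  native_only <- temporal_beta(sys1$tree, sys1$flora, scope = "native_only")
  expect_gt(mean(heavy$beta), mean(native_only$beta))
  expect_true(all(heavy$beta >= 0 & heavy$beta <= 1))
})

test_that("spatial beta matrices are symmetric with zero diagonal", {
  sys <- simulate_system(sim_config(
    n_islands = 4, native_pool = 40, exotic_pool = 30,
    occupancy = 0.5, extinction_fraction = 0.1, introductions = 10
  ), seed = 7)
  bm <- spatial_beta(sys$tree, sys$flora, period = "current")
  m <- as.matrix(bm)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_true(all(m >= 0 & m <= 1))
  long <- tidy(bm)
  expect_equal(nrow(long), choose(length(bm$labels), 2))
})

test_that("great-circle distances match the haversine closed form", {
  expect_equal(great_circle_km(-27, -109, -27, -109), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  # neighbouring Desventuradas islands are ~21 km apart
  expect_equal(
    great_circle_km(-26.2833, -80.0833, -26.3333, -79.8833),
    21, tolerance = 0.05
  )
  d <- island_distance_km(pacific_islands())
  expect_equal(d, t(d))
  expect_gt(d["Easter", "Robinson Crusoe"], 2000)
})

test_that("mantel test recovers perfect association and matches vegan's r", {
  set.seed(31)
  x <- as.matrix(dist(cbind(runif(6), runif(6))))
  expect_equal(mantel_test(x, x, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(x, max(x) - x, n_perm = 99, seed = 1)$r,
               -1, tolerance = 1e-12)

  skip_if_not_installed("vegan")
  y <- as.matrix(dist(cbind(runif(6), runif(6))))
  ours <- mantel_test(x, y, n_perm = 199, seed = 2)
  ref <- vegan::mantel(as.dist(x), as.dist(y), permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)

  flat <- matrix(1, 6, 6) - diag(6)
  expect_true(mantel_test(flat, y, n_perm = 99)$degenerate)
})
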