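test_that("parsing preserves counts, labels, and lengths", {
  tr <- demo_tree()
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)
  expect_equal(total_branch_length(tr), 6)

  single <- parse_newick("(A);")
  expect_equal(single$tip.label, "A")
  expect_null(single$edge.length) # absent, not zero
})

test_that("malformed input errors name a character offset", {
  expect_error(parse_newick("((A:1,B:1):1;"), "character 13")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("('Abc:1,B:1);"), "quote opened at character 2")
  expect_error(parse_newick("(A:1,A:1);"), "duplicate tip labels: A")
})

test_that("write/parse round-trip is the identity on topology and lengths", {
  withr::with_seed(7, {
    for (n in c(2, 5, 16)) {
      tr <- ape::rtree(n)
      back <- parse_newick(write_newick(tr, digits = 10))
      expect_equal(sort(back$tip.label), sort(tr$tip.label))
      expect_true(ape::all.equal.phylo(tr, back, use.edge.length = FALSE))
      d1 <- stats::cophenetic(tr)
      d2 <- stats::cophenetic(back)[rownames(d1), colnames(d1)]
      expect_equal(d2, d1, tolerance = 1e-8)
    }
  })
  # unset lengths are omitted on write
  nolen <- parse_newick("((A,B),C);")
  expect_false(grepl("0", write_newick(nolen), fixed = TRUE))
})

test_that("graft attaches under the named node and inverts by pruning", {
  back <- parse_newick("((A:1,B:1)Poaceae:1,(C:1,D:1)Fabaceae:1)root:0;")

  g1 <- graft(back, "Poaceae", parse_newick("(X:1);"))
  expect_equal(ape::Ntip(g1), 5)
  poa <- ape::Ntip(g1) + which(g1$node.label == "Poaceae")
  expect_length(g1$edge[g1$edge[, 1] == poa, 2], 3) # child count +1

  clade <- parse_newick("((p:1,q:1):1,r:2);")
  g2 <- graft(back, "Fabaceae", clade)
  expect_equal(ape::Ntip(g2), 7)

  # graft then prune the grafted labels recovers the original
  pruned <- prune_to(g2, back$tip.label)
  expect_true(ape::all.equal.phylo(
    ape::unroot(pruned), ape::unroot(back),
    use.edge.length = FALSE
  ))
  expect_equal(
    stats::cophenetic(pruned)[back$tip.label, back$tip.label],
    stats::cophenetic(back),
    tolerance = 1e-10
  )

  expect_error(graft(back, "Asteraceae", clade), "not found")
  expect_error(graft(back, "Poaceae", parse_newick("(A:1);")), "already present")
})

test_that("pruning preserves pairwise distances and root-inclusive PD", {
  tr <- demo_tree()
  expect_true(ape::all.equal.phylo(prune_to(tr, c("A", "B", "C", "D")), tr))

  pr <- prune_to(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(pairwise_distance(pr, "A", "C"), 4)

  # property: distances and PD survive pruning on random trees
  withr::with_seed(11, {
    for (rep in 1:5) {
      big <- random_coalescent(16)
      keep <- sample(big$tip.label, 6)
      small <- prune_to(big, keep)
      expect_lte(total_branch_length(small), total_branch_length(big))
      expect_equal(total_branch_length(small), oracle_pd(big, keep), tolerance = 1e-10)
      for (pair in list(keep[1:2], keep[3:4], keep[c(1, 6)])) {
        expect_equal(
          pairwise_distance(small, pair[1], pair[2]),
          oracle_dist(big, pair[1], pair[2]),
          tolerance = 1e-10
        )
      }
    }
  })

  # single-taxon pruning keeps the full root path
  one <- prune_to(tr, "A")
  expect_equal(one$tip.label, "A")
  expect_equal(total_branch_length(one), 2)

  expect_error(prune_to(tr, c("A", "Z")), "Z")
})
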