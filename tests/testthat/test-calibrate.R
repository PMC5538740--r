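test_that("undated chain nodes are spaced evenly between root and tip", {
  # root(100) -> n1 -> n2 -> tip: two undated nodes split 100 My in thirds
  cal <- bladj(chain_tree(3), c(root = 100))
  ages <- attr(cal, "node_ages")
  expect_equal(unname(ages[c("n1", "n2")]), c(100 * 2 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(cal$edge.length, rep(100 / 3, 3), tolerance = 1e-9)
})

test_that("fully dated trees get exact age-difference branch lengths", {
  tr <- parse_newick("((a:9,b:9)gen:9,c:9)root;")
  cal <- bladj(tr, c(root = 10, gen = 4))
  ages <- attr(cal, "node_ages")
  expect_equal(unname(ages[c("root", "gen", "a", "b", "c")]), c(10, 4, 0, 0, 0))
  depths <- ape::node.depth.edgelength(cal)
  expect_equal(max(abs(depths[1:3] - 10)), 0, tolerance = 1e-12)
})

test_that("sister clades of different depths are interpolated per path", {
  # dated root at 90; left chain has 1 undated node, right chain has 2:
  # root -> x1 -> a  and  root -> y1 -> y2 -> b
  edge <- matrix(c(3L, 4L, 4L, 1L, 3L, 5L, 5L, 6L, 6L, 2L), ncol = 2, byrow = TRUE)
  tree <- structure(
    list(edge = edge, Nnode = 4L, tip.label = c("a", "b"),
         node.label = c("root", "x1", "y1", "y2")),
    class = "phylo"
  )
  cal <- bladj(tree, c(root = 90))
  ages <- attr(cal, "node_ages")
  expect_equal(unname(ages["x1"]), 45, tolerance = 1e-9)
  expect_equal(unname(ages[c("y1", "y2")]), c(60, 30), tolerance = 1e-9)
  depths <- ape::node.depth.edgelength(cal)
  expect_equal(unname(depths[1:2]), c(90, 90), tolerance = 1e-9)
})

test_that("calibration is ultrametric, idempotent, and monotone", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      tr <- ape::rtree(24)
      tr$node.label <- paste0("nd", seq_len(tr$Nnode))
      depths <- ape::node.depth.edgelength(tr)
      # date the root and a random consistent subset of internal nodes using
      # ages proportional to (max depth - depth), which can never invert
      root_age <- 200
      cand <- (ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode)
      pick <- c(cand[1], sample(cand[-1], 8))
      ages <- tibble::tibble(
        node_name = tr$node.label[pick - ape::Ntip(tr)],
        age = root_age * (max(depths) - depths[pick]) / max(depths)
      )
      ages$age[1] <- root_age
      cal <- bladj(tr, ages)

      tip_depths <- ape::node.depth.edgelength(cal)[seq_len(ape::Ntip(tr))]
      expect_lt(max(abs(tip_depths - root_age)), 1e-9)

      cal2 <- bladj(cal, ages)
      expect_equal(cal2$edge.length, cal$edge.length, tolerance = 1e-12)

      node_ages <- attr(cal, "node_ages")
      parent_ages <- node_ages[cal$edge[, 1]]
      child_ages <- node_ages[cal$edge[, 2]]
      expect_true(all(parent_ages > child_ages))
    }
  })
})

test_that("calibration errors are informative", {
  tr <- parse_newick("((a:1,b:1)gen:1,c:1)root;")
  expect_error(bladj(tr, c(gen = 4)), "root must be dated")
  expect_error(bladj(tr, c(root = 10, gen = 40)), "inversion")
  expect_error(bladj(tr, c(root = 10, nosuch = 5)), "absent from the tree")
  expect_error(bladj(tr, c(root = 10, a = 3)), "nonzero age")
  expect_error(
    bladj(tr, tibble::tibble(node_name = c("root", "root"), age = c(10, 9))),
    "duplicate"
  )
})
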