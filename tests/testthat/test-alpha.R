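test_that("worked examples on the four-tip tree are exact", {
  tr <- demo_tree()
  expect_equal(pairwise_distance(tr, "A", "B"), 2)
  expect_equal(pairwise_distance(tr, "A", "C"), 4)
  expect_equal(pairwise_distance(tr, "A", "A"), 0)

  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, "A"), 2) # root-inclusive single species
  expect_equal(faith_pd(tr, c("A", "B", "C", "D")), 6)

  expect_equal(mpd(tr, c("A", "B")), 2)
  expect_equal(mpd(tr, c("A", "B", "C")), 10 / 3)
  expect_equal(mpd(tr, c("A", "B", "C", "D")), 10 / 3)

  expect_equal(mntd(tr, c("A", "B")), 2)
  expect_equal(mntd(tr, c("A", "B", "C")), 8 / 3)

  expect_error(mpd(tr, "A"), "at least 2")
  expect_error(faith_pd(tr, character()), "empty")
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
})

test_that("metrics agree with path-enumeration oracles on random subsets", {
  withr::with_seed(42, {
    for (rep in 1:6) {
      tr <- random_coalescent(10)
      tr$root.edge <- 0
      for (k in c(2, 4, 7)) {
        taxa <- sample(tr$tip.label, k)
        expect_equal(faith_pd(tr, taxa), oracle_pd(tr, taxa), tolerance = 1e-10)
        expect_equal(mpd(tr, taxa), oracle_mpd(tr, taxa), tolerance = 1e-10)
        expect_equal(mntd(tr, taxa), oracle_mntd(tr, taxa), tolerance = 1e-10)
        expect_lte(mntd(tr, taxa), mpd(tr, taxa) + 1e-12)
      }
    }
  })
})

test_that("PD is monotone under adding taxa and equals tree length on all tips", {
  withr::with_seed(5, {
    tr <- random_coalescent(12)
    taxa <- sample(tr$tip.label)
    pds <- vapply(seq_along(taxa), function(k) faith_pd(tr, taxa[1:k]), numeric(1))
    expect_true(all(diff(pds) >= -1e-12))
    expect_equal(pds[length(pds)], total_branch_length(tr), tolerance = 1e-10)
  })
})

test_that("metrics match picante on a shared assemblage", {
  skip_if_not_installed("picante")
  withr::with_seed(9, {
    tr <- random_coalescent(24)
    taxa <- sample(tr$tip.label, 10)
    samp <- matrix(as.integer(tr$tip.label %in% taxa), nrow = 1,
                   dimnames = list("isl", tr$tip.label))
    expect_equal(
      faith_pd(tr, taxa),
      picante::pd(samp, tr, include.root = TRUE)$PD,
      tolerance = 1e-8
    )
    dis <- stats::cophenetic(tr)
    expect_equal(mpd(tr, taxa), picante::mpd(samp, dis), tolerance = 1e-8)
    expect_equal(mntd(tr, taxa), picante::mntd(samp, dis), tolerance = 1e-8)
  })
})

test_that("alpha_diversity scores every island/period/scope against the tree", {
  tr <- parse_newick("((a:1,b:1):1,(c:1,x:1):1):0;")
  fl <- demo_flora()
  tbl <- alpha_diversity(tr, fl)
  expect_setequal(unique(tbl$period), c("pre_european", "current"))
  # isla current complete = {a, c, x}
  row <- tbl[tbl$island == "isla" & tbl$period == "current" & tbl$scope == "complete", ]
  expect_equal(row$n_matched, 3)
  expect_equal(row$pd, oracle_pd(tr, c("a", "c", "x")), tolerance = 1e-10)
  expect_equal(row$mpd, oracle_mpd(tr, c("a", "c", "x")), tolerance = 1e-10)
  # islb current native_only = {c}: distance metrics undefined
  row1 <- tbl[tbl$island == "islb" & tbl$period == "current" & tbl$scope == "native_only", ]
  expect_equal(row1$n_matched, 1)
  expect_true(is.na(row1$mpd) && is.na(row1$mntd))
  expect_equal(row1$pd, oracle_pd(tr, "c"), tolerance = 1e-10)
})

test_that("species absent from the tree error unless skipped explicitly", {
  tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1):0;") # no tip 'x'
  fl <- demo_flora()
  expect_error(alpha_diversity(tr, fl), "absent from the tree")
  expect_message(
    tbl <- alpha_diversity(tr, fl, skip_missing = TRUE),
    "dropping"
  )
  row <- tbl[tbl$island == "isla" & tbl$period == "current" & tbl$scope == "complete", ]
  expect_equal(row$n_species, 3)
  expect_equal(row$n_matched, 2)
})
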