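test_that("assembly applies the two-period rules", {
  fl <- demo_flora()
  expect_setequal(assemble(fl, "isla", "pre_european", "complete"), c("a", "b", "c"))
  expect_setequal(assemble(fl, "isla", "current", "complete"), c("a", "c", "x"))
  expect_setequal(assemble(fl, "isla", "current", "native_only"), c("a", "c"))
  expect_setequal(assemble(fl, "isla", "current", "exotic_only"), "x")
  # richness partition: complete - native_only = exotics present
  expect_equal(
    length(assemble(fl, "isla", "current", "complete")) -
      length(assemble(fl, "isla", "current", "native_only")),
    length(assemble(fl, "isla", "current", "exotic_only"))
  )
  expect_error(assemble(fl, "isla", "pre_european", "exotic_only"), "rejected")
  expect_error(assemble(fl, "nowhere", "current", "complete"), "unknown island")
})

test_that("flora validation catches inconsistent input", {
  occ <- tibble::tibble(
    species = c("a", "a"), status = c("native", "native"),
    extinct = c(FALSE, FALSE), i1 = c(1, 1)
  )
  expect_error(island_flora(occ), "duplicate species")
  occ2 <- tibble::tibble(
    species = "x", status = "exotic", extinct = TRUE, i1 = 1
  )
  expect_error(island_flora(occ2), "cannot be flagged extinct")
  occ3 <- tibble::tibble(
    species = "a", status = "native", extinct = FALSE, i1 = 0
  )
  expect_error(island_flora(occ3), "present on no island")
  occ4 <- tibble::tibble(
    species = "a", status = "native", extinct = FALSE, i1 = 1
  )
  expect_error(
    island_flora(occ4, tibble::tibble(island = "i1", lat = -95, lon = 0)),
    "out of range"
  )
})

test_that("occurrence spectrum fractions sum to one and match construction", {
  fl <- demo_flora()
  sp <- occurrence_spectrum(fl, "pre_european", "complete")
  expect_equal(sum(sp$fraction), 1)
  # natives a (1 island), b (2), c (2)
  expect_equal(sp$fraction[sp$n_islands == 1], 1 / 3)
  expect_equal(sp$fraction[sp$n_islands == 2], 2 / 3)

  # pool with the published pre-European occupancy profile: 205 natives,
  # 166 on one island, 35 on two, 4 on three
  counts <- c(rep(1, 166), rep(2, 35), rep(3, 4))
  occ <- tibble::tibble(
    species = sprintf("n%03d", seq_along(counts)),
    status = "native", extinct = FALSE
  )
  pres <- t(vapply(counts, function(k) {
    v <- integer(6)
    v[seq_len(k)] <- 1L
    v
  }, integer(6)))
  colnames(pres) <- paste0("isl", 1:6)
  fl2 <- island_flora(dplyr::bind_cols(occ, tibble::as_tibble(pres)))
  sp2 <- occurrence_spectrum(fl2, "pre_european", "complete")
  expect_equal(round(sp2$fraction[1:3], 2), c(0.81, 0.17, 0.02))
})

test_that("the Easter Island richness fixture reproduces published counts", {
  rich <- pacific_richness()
  easter <- rich[rich$island == "Easter", ]
  expect_equal(easter$pre_european, 40)
  expect_equal(easter$current_total, 366)
  expect_equal(easter$current_native, 26)
  expect_equal(easter$exotic, 340)
})

test_that("flora CSV round-trips", {
  fl <- demo_flora()
  occ_path <- withr::local_tempfile(fileext = ".csv")
  isl_path <- withr::local_tempfile(fileext = ".csv")
  write_flora_csv(fl, occ_path, isl_path)
  back <- read_flora_csv(occ_path, isl_path)
  expect_equal(back$occurrences, fl$occurrences)
  expect_equal(back$islands, fl$islands)
  expect_equal(
    richness_table(back)$change_complete_pct,
    richness_table(fl)$change_complete_pct
  )
})
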