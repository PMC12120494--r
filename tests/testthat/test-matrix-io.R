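test_that("community matrices round-trip through delimited text", {
  m <- toy_matrix(c(0, 5, 2, 1, 3, 0), nr = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  cm <- community_matrix(m)
  write_community_matrix(cm, path)
  back <- suppressMessages(read_community_matrix(path))
  expect_identical(unclass(back), unclass(cm))
  expect_identical(rowSums(back), rowSums(m))
  expect_identical(colSums(back), colSums(m))

  # tab-delimited is auto-detected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_community_matrix(cm, path2, delim = "\t")
  expect_identical(
    unclass(suppressMessages(read_community_matrix(path2))), unclass(cm)
  )
})

test_that("orientation flag transposes to the same internal matrix", {
  m <- toy_matrix(c(0, 5, 2, 1, 3, 0), nr = 3)
  a <- community_matrix(m, orientation = "species_rows")
  b <- community_matrix(t(m), orientation = "species_cols")
  expect_identical(unclass(a), unclass(b))
})

test_that("validation names the offending label or cell", {
  m <- toy_matrix(1:6, nr = 3, species = c("dup", "dup", "x"))
  expect_error(community_matrix(m), "dup")
  m2 <- toy_matrix(c(1, -2, 3, 4, 5, 6), nr = 3)
  expect_error(community_matrix(m2), "sp1.*s2|non-negative")
  m3 <- matrix(c(1, 2.5, 3, 4, 5, 6), nrow = 3,
    dimnames = list(paste0("sp", 1:3), paste0("s", 1:2))
  )
  expect_error(community_matrix(m3), "integer")
})

test_that("all-zero species are dropped with a warning, zero sites kept", {
  m <- toy_matrix(c(1, 0, 0, 0, 2, 0), nr = 3)
  expect_warning(cm <- community_matrix(m), "sp2")
  expect_equal(nrow(cm), 2)
  expect_equal(ncol(cm), 2) # site s2 is all-zero after the drop but retained
})

test_that("group subsetting removes waterbirds first and filters guilds", {
  m <- toy_matrix(rep(1L, 10), nr = 5)
  g <- toy_groups(rownames(m),
    passerine = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    guild = c("insectivorous", "insectivorous", "omnivorous", "carnivorous", "omnivorous"),
    waterbird = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  ins <- subset_by_group(m, g, "insectivorous")
  expect_identical(rownames(ins), c("sp1", "sp2"))
  all_birds <- subset_by_group(m, g, "all")
  expect_identical(rownames(all_birds), c("sp1", "sp2", "sp3", "sp4"))
  expect_equal(nrow(all_birds), nrow(m) - sum(g$is_waterbird))
  # groups outside the analyzable set are refused outright
  expect_error(subset_by_group(m, g, "nectarivorous"), "not analysable")
  # too few species left
  expect_error(
    subset_by_group(m, toy_groups(rownames(m), guild = rep("carnivorous", 5)),
      "insectivorous"
    ),
    "fewer than 2"
  )
  # unclassified species are an error
  expect_error(subset_by_group(m, g[-1, ], "all"), "sp1")
})

test_that("ordering specs permute as documented with stable ties", {
  m <- toy_matrix(c(
    1, 0, 0,
    1, 1, 1,
    1, 1, 0
  ), nr = 3) # row totals 1, 3, 2
  out <- order_matrix(m, rows = "marginal_totals_desc", cols = "given")
  expect_identical(rownames(out), c("sp2", "sp3", "sp1"))

  areas <- c(s1 = 10, s2 = 300, s3 = 25)
  out2 <- order_matrix(m,
    rows = "given", cols = "external_attribute_desc", col_attr = areas
  )
  expect_identical(colnames(out2), c("s2", "s3", "s1"))

  # equal totals keep input order
  m3 <- toy_matrix(c(1, 1, 0, 0, 1, 1, 1, 1, 0), nr = 3) # totals 2, 2, 2
  out3 <- order_matrix(m3, rows = "marginal_totals_desc", cols = "given")
  expect_identical(rownames(out3), rownames(m3))

  expect_error(
    order_matrix(m, cols = "external_attribute_desc", col_attr = areas[-1]),
    "s1"
  )
  expect_error(order_matrix(m, rows = "bogus"), "ordering spec")
})

test_that("ordering is a pure permutation of cells and marginals", {
  set.seed(11)
  for (rep in 1:20) {
    x <- random_community(sample(3:7, 1), sample(3:7, 1))
    areas <- stats::setNames(runif(ncol(x), 1, 100), colnames(x))
    out <- order_matrix(x,
      rows = "marginal_totals_desc",
      cols = "external_attribute_desc", col_attr = areas
    )
    expect_equal(sort(as.vector(out)), sort(as.vector(x)))
    expect_equal(sort(unname(rowSums(out))), sort(unname(rowSums(x))))
    expect_equal(sort(unname(colSums(out))), sort(unname(colSums(x))))
    expect_equal(sum(out), sum(x))
  }
})

test_that("attribute and group tables are validated on read", {
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(site_id = c("a", "b"), area = c(5, 12.5)), p)
  tab <- suppressMessages(read_site_attributes(p))
  expect_equal(tab$area, c(5, 12.5))
  readr::write_csv(tibble::tibble(site_id = c("a", "b"), area = c(5, -1)), p)
  expect_error(suppressMessages(read_site_attributes(p)), "positive")

  g <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(
      species_id = c("x", "y"), is_passerine = c(TRUE, FALSE),
      is_resident = TRUE, diet_guild = c("omnivorous", "granivorous"),
      is_waterbird = FALSE
    ), g
  )
  expect_equal(nrow(suppressMessages(read_group_table(g))), 2)
  readr::write_csv(
    tibble::tibble(
      species_id = "x", is_passerine = TRUE, is_resident = TRUE,
      diet_guild = "frugivorous", is_waterbird = FALSE
    ), g
  )
  expect_error(suppressMessages(read_group_table(g)), "frugivorous")
})
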