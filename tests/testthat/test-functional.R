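test_that("Gower distance is range-normalised mean absolute difference", {
  tr <- tibble::tibble(
    species_id = c("A", "B", "C"),
    t1 = c(10, 20, 30),
    t2 = c(50, 100, 150)
  )
  d <- as.matrix(gower_distance(tr))
  expect_equal(d["A", "B"], 0.5) # (0.5 + 0.5) / 2
  expect_equal(d["A", "C"], 1) # both traits at observed min and max
  expect_equal(d["A", "A"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))

  # identical trait vectors are at distance zero
  tr2 <- tibble::tibble(
    species_id = c("A", "B", "C"), t1 = c(3, 3, 9), t2 = c(1, 1, 7)
  )
  expect_equal(as.matrix(gower_distance(tr2))["A", "B"], 0)

  # zero-range traits are dropped with a warning; all flat is an error
  tr3 <- tibble::tibble(species_id = c("A", "B"), flat = c(1, 1), t = c(0, 2))
  expect_warning(d3 <- gower_distance(tr3), "flat")
  expect_equal(as.matrix(d3)["A", "B"], 1)
  expect_error(
    gower_distance(tibble::tibble(species_id = c("A", "B"), flat = c(1, 1))),
    "zero range"
  )
})

test_that("UPGMA places nodes at half the merge height", {
  d <- stats::as.dist(matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))
  tree <- upgma(d)
  expect_equal(sort(tree$edge.length), c(1, 1)) # two tips at distance 2

  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tree3 <- upgma(stats::as.dist(dm))
  # (A,B) merge at height 1, then join C at height 2: cophenetic distances
  # reproduce the merge heights exactly
  coph <- ape::cophenetic.phylo(tree3)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  expect_equal(coph["B", "C"], 4)

  # defining property on a random distance matrix: tree cophenetic equals
  # hclust's cophenetic
  set.seed(10)
  p <- matrix(runif(24), 8)
  rownames(p) <- paste0("x", 1:8)
  dd <- dist(p)
  hc <- hclust(dd, method = "average")
  expect_equal(
    as.matrix(ape::cophenetic.phylo(ape::as.phylo(hc)))[hc$labels, hc$labels],
    as.matrix(stats::cophenetic(hc)),
    tolerance = 1e-12
  )
})

star_tree <- function(tips, len = 1) {
  n <- length(tips)
  structure(
    list(
      edge = cbind(rep(n + 1L, n), seq_len(n)),
      edge.length = rep(len, n),
      tip.label = tips,
      Nnode = 1L
    ),
    class = "phylo", order = "cladewise"
  )
}

test_that("a strict species subset scores a full pair term", {
  m <- toy_matrix(c(
    1, 1,
    1, 0,
    1, 0
  ), nr = 3) # site s2's species are a strict subset of s1's
  tr <- generate_traits(3, seed = 2, species_ids = rownames(m))
  tree <- upgma(gower_distance(tr))
  res <- tree_nodf(m, tree, areas = c(s1 = 10, s2 = 1))
  expect_equal(res$tree_nodf, 100) # single pair, full containment
  expect_equal(res$site_order, c("s1", "s2"))
  expect_equal(res$n_pairs, 1)
})

test_that("on a star dendrogram treeNODF reduces to site-wise NODF, topo 0", {
  set.seed(55)
  for (rep in 1:25) {
    nsp <- sample(4:9, 1); nsi <- sample(3:6, 1)
    x <- (random_community(nsp, nsi) > 0) * 1L
    x[, colSums(x) == 0] <- 0L # keep as-is; empty sites allowed
    if (all(rowSums(x) == 0)) next
    tree <- star_tree(rownames(x))
    res <- tree_nodf(x, tree, site_order = "given")
    # oracle: literal NODF pair terms over sites in the same fixed order
    b <- t(x)
    n <- nrow(b)
    s <- 0
    for (u in seq_len(n - 1)) {
      for (v in seq(u + 1, n)) {
        ru <- sum(b[u, ]); rv <- sum(b[v, ])
        if (ru > rv && rv > 0) s <- s + 100 * sum(b[u, ] & b[v, ]) / rv
      }
    }
    expect_equal(res$tree_nodf, s / choose(n, 2), tolerance = 1e-9)
    expect_equal(res$topo_nodf, 0, tolerance = 1e-9)
  }
})

test_that("treeNODF decomposes additively with non-negative parts", {
  set.seed(66)
  for (rep in 1:30) {
    nsp <- sample(5:12, 1); nsi <- sample(3:8, 1)
    x <- random_community(nsp, nsi)
    tr <- generate_traits(nsp, seed = rep, species_ids = rownames(x))
    tree <- upgma(gower_distance(tr))
    res <- tree_nodf(x, tree, site_order = "marginal_totals_desc")
    expect_lt(abs(res$tree_nodf - (res$s_fraction + res$topo_nodf)), 1e-9)
    expect_gte(res$s_fraction, 0)
    expect_gte(res$topo_nodf, 0)
    expect_lte(res$tree_nodf, 100 + 1e-9)
  }
})

test_that("sites with equal branch totals contribute nothing", {
  m <- toy_matrix(c(
    1, 1,
    1, 1
  ), nr = 2) # identical composition, equal BL
  tr <- generate_traits(2, seed = 3, species_ids = rownames(m))
  tree <- upgma(gower_distance(tr))
  res <- tree_nodf(m, tree, areas = c(s1 = 5, s2 = 2))
  expect_equal(res$tree_nodf, 0)
})

test_that("adding species to the richer site never lowers the pair term", {
  set.seed(88)
  for (rep in 1:20) {
    nsp <- 8
    x <- matrix(0L, nsp, 2, dimnames = list(sprintf("sp%d", 1:nsp), c("s1", "s2")))
    x[sample(nsp, 5), 1] <- 1L
    x[sample(nsp, 2), 2] <- 1L
    tr <- generate_traits(nsp, seed = rep, species_ids = rownames(x))
    tree <- upgma(gower_distance(tr))
    base <- tree_nodf(x, tree, site_order = "given")
    absent <- which(x[, 1] == 0)
    if (length(absent) == 0) next
    x2 <- x
    x2[sample(absent, 1), 1] <- 1L
    grown <- tree_nodf(x2, tree, site_order = "given")
    expect_gte(grown$tree_nodf + 1e-9, base$tree_nodf)
  }
})

test_that("species missing from the dendrogram are named in the error", {
  m <- toy_matrix(c(1, 1, 1, 0), nr = 2)
  tr <- generate_traits(2, seed = 1, species_ids = c("sp1", "other"))
  tree <- upgma(gower_distance(tr))
  expect_error(tree_nodf(m, tree, areas = c(s1 = 2, s2 = 1)), "sp2")
})

test_that("permRows reaches the exact p floor and reproduces under a seed", {
  sim <- generate_community(n_species = 20, n_sites = 10, theta = 1, seed = 14)
  tr <- generate_traits(20, seed = 14)
  tree <- upgma(gower_distance(tr))
  pt <- perm_rows_test(sim$community, tree, sim$areas, n_perm = 99, seed = 5)
  res <- tidy(pt)
  # decreasing-area order is optimal for a theta = 1 community: nothing beats
  # the observed value, so p sits at the floor 1/(n_perm + 1) = 0.01
  expect_equal(res$p[res$component == "treeNODF"], 0.01)
  expect_gt(res$z[res$component == "treeNODF"], 2)

  pt2 <- perm_rows_test(sim$community, tree, sim$areas, n_perm = 99, seed = 5)
  expect_identical(tidy(pt), tidy(pt2))
})

test_that("permutation p is uniform when composition is area-independent", {
  # with the nestedness dial at zero, site order carries no signal, so the
  # permRows p-value must be uniform on its achievable grid
  ps <- vapply(1:200, function(s) {
    sim <- generate_community(n_species = 14, n_sites = 8, theta = 0, seed = 8000 + s)
    tree <- upgma(gower_distance(generate_traits(14, seed = 8000 + s)))
    res <- tidy(perm_rows_test(sim$community, tree, sim$areas,
      n_perm = 99, seed = 9000 + s
    ))
    res$p[res$component == "treeNODF"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("with a single permutation that ties the observation, p is 1", {
  m <- toy_matrix(c(1, 1, 1, 0), nr = 2)
  tr <- generate_traits(2, seed = 9, species_ids = rownames(m))
  tree <- upgma(gower_distance(tr))
  # find a seed whose first derived permutation of the two sites is the
  # identity, so the permuted value ties the observed one
  seed <- NULL
  for (s in 1:50) {
    set.seed(s + 1)
    if (identical(sample.int(2), 1:2)) { seed <- s; break }
  }
  pt <- perm_rows_test(m, tree, c(s1 = 9, s2 = 3), n_perm = 1, seed = seed)
  expect_equal(tidy(pt)$p, rep(1, 3))
})
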