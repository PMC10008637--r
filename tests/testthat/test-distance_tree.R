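test_that("chord distance hits its closed-form boundary cases", {
  # identical multilocus genotypes
  expect_equal(chord_distance(c(155, 155, 200, 202), c(155, 155, 200, 202)), 0)
  # fully disjoint fixed alleles: the theoretical maximum 2*sqrt(2)/pi
  expect_equal(chord_distance(c(155, 155), c(161, 161)), 2 * sqrt(2) / pi)
  # one locus, AA vs AB
  expect_equal(chord_distance(c(155, 155), c(155, 161)),
               (2 / pi) * sqrt(2 * (1 - sqrt(0.5))))
  # scaling toggle drops the 2/pi prefactor
  expect_equal(chord_distance(c(155, 155), c(161, 161), variant = "angular"),
               sqrt(2))
  expect_error(chord_distance(c(NA, NA), c(155, 155)), "incomparable")
})

test_that("the distance matrix equals brute-force per-pair recomputation", {
  gm <- random_gm(n = 12, L = 6, seed = 44, missing_rate = 0.15)
  dm <- distance_matrix(gm)
  expect_equal(diag(dm$d), rep(0, 12), ignore_attr = TRUE)
  expect_equal(dm$d, t(dm$d))
  for (i in 1:11) for (j in (i + 1):12)
    expect_equal(dm$d[i, j], oracle_chord(gm, i, j))
  dma <- distance_matrix(gm, variant = "angular")
  expect_equal(dma$d[1, 2], oracle_chord(gm, 1, 2, variant = "angular"))
})

test_that("identical accessions give a zero matrix and diverged populations are farther apart", {
  gm <- make_gm(list(a = rep("155/155", 3), b = rep("200/202", 3)))
  expect_true(all(distance_matrix(gm)$d == 0))

  sim <- simulate_paperlike(seed = 10, n_per_pop = c(20, 20), n_admixed = 0,
                            n_loci = 12, fst = 0.3, missing_rate = 0.02)
  d <- distance_matrix(sim$gm)$d
  same <- outer(sim$labels, sim$labels, "==")
  ut <- upper.tri(d)
  expect_gt(mean(d[ut & !same]), mean(d[ut & same]))
})

test_that("single-locus chord distance satisfies the triangle inequality", {
  set.seed(50)
  codes <- c(155L, 157L, 159L, 161L)
  for (rep in 1:40) {
    g <- matrix(sample(codes, 6, replace = TRUE), 3, 2)
    d12 <- chord_distance(g[1, ], g[2, ])
    d13 <- chord_distance(g[1, ], g[3, ])
    d23 <- chord_distance(g[2, ], g[3, ])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("NJ recovers additive trees exactly (topology and branch lengths)", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    dm <- cophenetic(true)
    fit <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(fit))[1], 0)
    expect_lt(max(abs(cophenetic(fit)[rownames(dm), colnames(dm)] - dm)), 1e-9)
  }
})

test_that("a 3-taxon star has the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 2, 3))  # (dAB+dAC-dBC)/2 etc.
  expect_true(all(nj_tree(distance_matrix(random_gm(6, 4, 3))$d)$edge.length >= 0))
})

test_that("UPGMA returns the generating ultrametric dendrogram", {
  set.seed(62)
  true <- ape::rcoal(8)                      # coalescent trees are ultrametric
  dm <- cophenetic(true)
  fit <- upgma_tree(dm)
  expect_lt(max(abs(cophenetic(fit)[rownames(dm), colnames(dm)] - dm)), 1e-9)
  # ultrametricity: equal root-to-leaf depths
  depths <- ape::node.depth.edgelength(fit)[seq_along(fit$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)

  two <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  fit2 <- upgma_tree(two)
  expect_equal(fit2$edge.length, c(0.4, 0.4))  # root at height d/2

  # label permutation changes nothing but the labels
  gm <- random_gm(10, 5, seed = 77)
  d0 <- distance_matrix(gm)$d
  perm <- sample(10)
  c0 <- cophenetic(upgma_tree(d0))
  c1 <- cophenetic(upgma_tree(d0[perm, perm]))
  expect_equal(c1[rownames(c0), colnames(c0)], c0)
})

test_that("UPGMA merge heights never decrease", {
  gm <- random_gm(15, 6, seed = 78)
  hc <- hclust(as.dist(distance_matrix(gm)$d), method = "average")
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("Newick and PHYLIP round trips preserve the objects", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*\\);$")
  for (tip in c("A:", "B:", "C:")) expect_match(txt, tip, fixed = TRUE)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(cophenetic(back)[rownames(d), colnames(d)],
               cophenetic(tr)[rownames(d), colnames(d)], tolerance = 1e-5)

  gm <- random_gm(6, 4, seed = 9)
  dm <- distance_matrix(gm)
  pp <- withr::local_tempfile(fileext = ".phy")
  write_phylip(dm, pp)
  back <- read_phylip(pp)
  expect_equal(back, dm$d, tolerance = 1e-6)
})
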