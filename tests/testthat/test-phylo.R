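test_that("p-distance endpoints and naive-oracle agreement", {
  g <- rbind(rep(0L, 20), rep(0L, 20), rep(2L, 20))
  D <- p_distance(make_gm(g))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  set.seed(131)
  g2 <- random_geno(10, 100, miss = 0.1)
  D2 <- p_distance(make_gm(g2))
  expect_lt(max(abs(D2 - naive_pdist(g2))), 1e-12)
  g3 <- rbind(c(1L, NA), c(NA, 1L))
  expect_error(p_distance(make_gm(g3)), "shared")
})

test_that("NJ recovers a known additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) with internal edge 1
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tree <- neighbor_joining(D)
  expect_identical(sort(splits_of(tree)), "C|D")
  co <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_lt(max(abs(co - D)), 1e-12)
})

test_that("3 taxa resolve to the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  expect_equal(length(tree$tip.label), 3)
  len <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(len[["A"]], 1)   # (3 + 4 - 5) / 2
  expect_equal(len[["B"]], 2)
  expect_equal(len[["C"]], 3)
})

test_that("NJ recovers random additive 5-8 taxon trees", {
  set.seed(137)
  for (rep in 1:40) {
    n <- sample(5:8, 1)
    ra <- random_additive(n)
    tree <- neighbor_joining(ra$D)
    expect_identical(sort(splits_of(tree)), sort(splits_of(ra$tree)))
    co <- ape::cophenetic.phylo(tree)[rownames(ra$D), colnames(ra$D)]
    expect_lt(max(abs(co - ra$D)), 1e-9)
  }
})

test_that("taxon permutation yields an isomorphic tree", {
  set.seed(141)
  ra <- random_additive(7)
  perm <- sample(7)
  Dp <- ra$D[perm, perm]
  t1 <- neighbor_joining(ra$D)
  t2 <- neighbor_joining(Dp)
  expect_identical(sort(splits_of(t1)), sort(splits_of(t2)))
})

test_that("bootstrap supports are frequencies over replicate splits", {
  set.seed(145)
  g <- random_geno(6, 400)
  gm <- make_gm(g)
  tr <- bootstrap_support(gm, reps = 1, seed = 9)
  ss <- attr(tr, "split_support")
  expect_true(all(ss %in% c(0, 1)))
  tr2 <- bootstrap_support(gm, reps = 25, seed = 9)
  expect_true(all(attr(tr2, "split_support") >= 0 &
                    attr(tr2, "split_support") <= 1))
  # determinism under identical seed and sample reordering
  perm <- sample(6)
  gm_perm <- geno_matrix(g[perm, ], gm$loci,
                         samples = gm$samples[perm])
  tr3 <- bootstrap_support(gm_perm, reps = 25, seed = 9)
  k <- intersect(names(attr(tr2, "split_support")),
                 names(attr(tr3, "split_support")))
  expect_gt(length(k), 0)
  expect_equal(attr(tr2, "split_support")[k],
               attr(tr3, "split_support")[k])
})

test_that("samples from one simulated population form a clade", {
  spec <- population_spec(n_pops = 2, n_per_pop = 10, fst = 0.25,
                          n_loci = 500, seq_lengths = rep(50000L, 2),
                          seed = 149)
  sim <- simulate_population(spec, simulate_reference(spec))
  tr <- bootstrap_support(sim$matrix, reps = 50, seed = 5)
  pop1 <- names(sim$truth$groups)[sim$truth$groups == "pop1"]
  key <- split_key(pop1, sim$matrix$samples)
  expect_true(key %in% splits_of(tr))
  expect_gte(attr(tr, "split_support")[[key]], 0.9)
})

test_that("newick output is standard, quoted and round-trippable", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  txt <- readLines(path)
  expect_match(txt, "^\\([A-C]:[0-9.]+,[A-C]:[0-9.]+,[A-C]:[0-9.]+\\);$")
  set.seed(153)
  ra <- random_additive(8)
  t1 <- neighbor_joining(ra$D)
  write_newick(t1, path)
  t2 <- ape::read.tree(path)
  expect_identical(sort(splits_of(t1)), sort(splits_of(t2)))
  expect_equal(sort(t2$edge.length), sort(t1$edge.length),
               tolerance = 1e-4)
  # labels with spaces are quoted
  t1$tip.label[1] <- "sample one"
  write_newick(t1, path)
  expect_match(readLines(path), "'sample one'")
  t3 <- ape::read.tree(path)   # ape keeps the quotes in the label
  expect_true(any(t3$tip.label %in% c("sample one", "'sample one'")))
})

test_that("group-frequency distances separate differentiated breeds", {
  spec <- population_spec(n_pops = 3, n_per_pop = 8, fst = 0.2,
                          n_loci = 400, seq_lengths = rep(50000L, 2),
                          seed = 157)
  sim <- simulate_population(spec, simulate_reference(spec))
  D <- group_distance(sim$matrix)
  expect_true(isSymmetric(D))
  expect_true(all(D[upper.tri(D)] > 0))
  expect_identical(rownames(D), c("pop1", "pop2", "pop3"))
})
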