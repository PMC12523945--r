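test_that("crafted cascade fixture: one removal per rule, chained report", {
  gm <- cascade_fixture()
  res <- filter_candidates(gm, filter_params())
  rules <- res$report$rules
  expect_identical(rules$rule, c("qual", "biallelic_snp", "depth", "maf",
                                 "missing", "het", "spacing"))
  expect_identical(rules$n_removed, rep(1L, 7))
  expect_identical(rules$n_out[-7], rules$n_in[-1])      # chained
  expect_identical(rules$n_in - rules$n_removed, rules$n_out)
  expect_equal(n_loci(res$matrix), 2)
  expect_identical(res$matrix$loci$pos, c(700L, 900L))
  ff <- unname(res$report$first_fail)
  expect_identical(ff, c("qual", "biallelic_snp", "depth", "maf",
                         "missing", "het", NA, "spacing", NA))
})

test_that("MAF exactly at the threshold is retained (rule is >=)", {
  g <- rbind(matrix(0L, 9, 1), 1L)        # 1 alt in 20 alleles = 0.05
  gm <- make_gm(cbind(g, c(rep(0L, 5), rep(1L, 3), 2L, 2L)))
  res <- filter_candidates(gm, filter_params())
  expect_equal(n_loci(res$matrix), 2)
  expect_equal(min(locus_diversity(res$matrix)$maf), 0.05)
})

test_that("disabling thresholds leaves only structural rules active", {
  gm <- cascade_fixture()
  params <- filter_params(min_qual = 0, min_maf = 0, max_missing = 1,
                          max_het_rate = 1, min_site_depth = 0,
                          depth_window = c(0, Inf))
  res <- filter_candidates(gm, params)
  rules <- res$report$rules
  removed <- setNames(rules$n_removed, rules$rule)
  expect_identical(unname(removed[c("qual", "depth", "maf", "missing",
                                    "het")]), rep(0L, 5))
  expect_identical(unname(removed["biallelic_snp"]), 1L)
  expect_identical(unname(removed["spacing"]), 1L)
})

test_that("het rule direction is configurable", {
  gm <- cascade_fixture()
  res <- filter_candidates(gm, filter_params(het_rule = "remove_low"))
  ff <- res$report$first_fail
  # the het-0.9 locus now survives; the clean 0.3-het locus is removed
  expect_identical(unname(ff["seq1:600"]), NA_character_)
  expect_identical(unname(ff["seq1:900"]), "het")
})

test_that("ranking prefers high MAF, low missing, low het, then position", {
  g1 <- c(rep(0L, 6), rep(1L, 2), 2L, 2L)       # maf 0.3
  g2 <- c(rep(0L, 4), rep(1L, 4), 2L, 2L)       # maf 0.4
  gm <- make_gm(cbind(g1, g2), pos = c(1000L, 2000L))
  panel <- rank_and_select(gm, filter_params(target_size = 1))
  expect_equal(panel$pos, 2000L)
  expect_equal(panel$maf, 0.4)
  # full tie on the statistics: lower (seq_id, pos) wins
  gm2 <- make_gm(cbind(g2, g2), pos = c(5000L, 3000L))
  panel2 <- rank_and_select(gm2, filter_params(target_size = 1))
  expect_equal(panel2$pos, 3000L)
})

test_that("spacing conflicts resolve in favour of the higher-ranked locus", {
  hi <- c(rep(0L, 4), rep(1L, 4), 2L, 2L)       # maf 0.4
  lo <- c(rep(0L, 6), rep(1L, 2), 2L, 2L)       # maf 0.3
  gm <- make_gm(cbind(lo, hi, lo), pos = c(100L, 103L, 200L))
  panel <- rank_and_select(gm, filter_params(target_size = 10))
  expect_identical(sort(panel$pos), c(103L, 200L))
})

test_that("panel membership is invariant to sample and locus order", {
  set.seed(8)
  g <- random_geno(20, 120, miss = 0.05)
  pos <- sort(sample(1000:50000, 120))
  gm <- make_gm(g, pos = pos, qual = round(runif(120, 25, 60), 2))
  panel <- rank_and_select(gm, filter_params(target_size = 40))
  perm_s <- sample(20)
  perm_l <- sample(120)
  gm2 <- geno_matrix(g[perm_s, perm_l], gm$loci[perm_l, ],
                     samples = gm$samples[perm_s])
  panel2 <- rank_and_select(gm2, filter_params(target_size = 40))
  expect_identical(panel$pos, panel2$pos)
  expect_identical(panel$maf, panel2$maf)
})

test_that("weakening any single threshold never shrinks the survivors", {
  set.seed(15)
  spec <- population_spec(n_pops = 2, n_per_pop = 10, fst = 0.15,
                          n_loci = 400, seq_lengths = rep(30000L, 2),
                          missing_rate = 0.1, qual_low_fraction = 0.15,
                          seed = 15)
  gm <- simulate_population(spec, simulate_reference(spec))$matrix
  base <- filter_params(min_qual = 30, min_maf = 0.1, max_missing = 0.15,
                        max_het_rate = 0.4, min_site_depth = 10)
  surv <- function(p) {
    m <- filter_candidates(gm, p)$matrix
    paste(m$loci$seq_id, m$loci$pos)
  }
  s0 <- surv(base)
  weaker <- list(
    filter_params(min_qual = 0, min_maf = 0.1, max_missing = 0.15,
                  max_het_rate = 0.4, min_site_depth = 10),
    filter_params(min_qual = 30, min_maf = 0, max_missing = 0.15,
                  max_het_rate = 0.4, min_site_depth = 10),
    filter_params(min_qual = 30, min_maf = 0.1, max_missing = 1,
                  max_het_rate = 0.4, min_site_depth = 10),
    filter_params(min_qual = 30, min_maf = 0.1, max_missing = 0.15,
                  max_het_rate = 1, min_site_depth = 10),
    filter_params(min_qual = 30, min_maf = 0.1, max_missing = 0.15,
                  max_het_rate = 0.4, min_site_depth = 0))
  for (p in weaker) expect_true(all(s0 %in% surv(p)))
})

test_that("all-removed input warns and returns an empty matrix", {
  g <- matrix(0L, 5, 3)                    # monomorphic everywhere
  gm <- make_gm(g)
  expect_warning(res <- filter_candidates(gm, filter_params()),
                 "all loci removed")
  expect_equal(n_loci(res$matrix), 0)
  expect_equal(res$report$rules$n_out[nrow(res$report$rules)], 0L)
})
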