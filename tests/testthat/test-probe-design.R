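# A deterministic random reference for probe tests.
probe_ref <- function(lengths = 100000L, seed = 33) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

toy_panel <- function(seq_id, pos) {
  structure(data.frame(rank = seq_along(pos), seq_id = seq_id, pos = pos,
                       ref = "A", alt = "G", qual = 50, maf = 0.3,
                       missing = 0, het = 0.3),
            params = filter_params(), class = c("snp_panel", "data.frame"))
}

test_that("gc_content follows the stated N-exclusion convention", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_true(is.na(gc_content("NNN")))
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("ACGX"), "only A, C, G, T or N")
})

test_that("probe pair placement matches the arithmetic rule", {
  ref <- probe_ref()
  pp <- extract_probe_pair(ref, "seq1", 10000L)
  expect_true(pp$ok)
  expect_equal(nchar(pp$probe_a), 110)
  expect_equal(nchar(pp$probe_b), 110)
  expect_equal(pp$start_b - pp$start_a, 38)          # round(110 * 0.35)
  expect_equal(pp$overlap, 72 / 110)                 # 110 - 38 shared
  # SNP inside both probes
  expect_true(pp$start_a <= 10000 && 10000 <= pp$start_a + 109)
  expect_true(pp$start_b <= 10000 && 10000 <= pp$start_b + 109)
  # probes match the reference at their stated coordinates
  expect_identical(pp$probe_a,
                   as.character(Biostrings::subseq(ref[[1]], pp$start_a,
                                                   pp$start_a + 109)))
  expect_identical(pp$probe_b,
                   as.character(Biostrings::subseq(ref[[1]], pp$start_b,
                                                   pp$start_b + 109)))
})

test_that("overlap targets at both band edges stay inside the band", {
  ref <- probe_ref()
  for (ov in c(0.60, 0.65, 0.70)) {
    pp <- extract_probe_pair(ref, "seq1", 50000L,
                             probe_params(overlap_target = ov))
    expect_true(pp$ok)
    expect_gte(pp$overlap, 0.60)
    expect_lte(pp$overlap, 0.70)
  }
})

test_that("insufficient flank fails with reason edge", {
  ref <- probe_ref()
  pp <- extract_probe_pair(ref, "seq1", 20L)
  expect_false(pp$ok)
  expect_identical(pp$reason, "edge")
  near_end <- extract_probe_pair(ref, "seq1", 99990L)
  expect_false(near_end$ok)
})

test_that("homology count is 1 on unique sequence, 2 with a planted copy", {
  ref <- probe_ref(20000L)
  pp <- extract_probe_pair(ref, "seq1", 5000L)
  idx <- homology_index(ref)
  expect_equal(count_homologous_regions(pp$probe_a, idx), 1L)
  # plant an exact copy of probe A elsewhere
  s <- as.character(ref[[1]])
  dup <- paste0(substr(s, 1, 14000), pp$probe_a,
                substr(s, 14111, 20000))
  ref2 <- Biostrings::DNAStringSet(c(seq1 = dup))
  expect_equal(count_homologous_regions(pp$probe_a,
                                        homology_index(ref2)), 2L)
  # brute-force oracle: exact string occurrences on both strands
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pp$probe_a)))
  hits <- length(gregexpr(pp$probe_a, dup, fixed = TRUE)[[1]]) +
    sum(gregexpr(rc, dup, fixed = TRUE)[[1]] > 0)
  expect_equal(count_homologous_regions(pp$probe_a,
                                        homology_index(ref2)), hits)
})

test_that("a repetitive probe exceeds the homology cap", {
  set.seed(44)
  chunks <- replicate(10, paste(
    sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = ""))
  polyA <- strrep("A", 150)
  ref <- Biostrings::DNAStringSet(c(seq1 = paste0(
    paste(chunks, polyA, sep = "", collapse = ""),
    paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
          collapse = ""))))
  probe <- strrep("A", 110)
  count <- count_homologous_regions(probe, homology_index(ref))
  expect_gt(count, 5)
})

test_that("evaluate_panel_probes flags GC and homology violations", {
  set.seed(55)
  bg <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
              collapse = "")
  gc_block <- paste(sample(c("G", "C", "A"), 400, replace = TRUE,
                           prob = c(0.48, 0.48, 0.04)), collapse = "")
  s <- paste0(substr(bg, 1, 10000), gc_block, substr(bg, 10401, 30000))
  ref <- Biostrings::DNAStringSet(c(seq1 = s))
  panel <- toy_panel("seq1", c(5000L, 10200L))
  ev <- evaluate_panel_probes(panel, ref)
  expect_true(ev$pass[1])
  expect_false(ev$pass[2])
  expect_identical(ev$fail_reason[2], "gc")
  expect_equal(ev$homology_a[1], 1L)
})

test_that("replacement loop refills the panel after planted failures", {
  set.seed(66)
  L <- 120000L
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cand_pos <- seq(5000L, 115000L, by = 300L)          # 367 candidates
  bad <- seq(10, length(cand_pos), by = 10)           # 10% GC-extreme
  for (b in cand_pos[bad]) {
    bases[(b - 150):(b + 150)] <- sample(c("G", "C"), 301, replace = TRUE)
  }
  ref <- Biostrings::DNAStringSet(c(seq1 = paste(bases, collapse = "")))
  n_cand <- length(cand_pos)
  g <- random_geno(20, n_cand, p = runif(n_cand, 0.2, 0.8))
  gm <- make_gm(g, pos = cand_pos)
  target <- 300L
  panel <- design_probe_panel(gm, ref,
                              filter_params(target_size = target))
  expect_equal(nrow(panel), target)
  expect_true(all(panel$pass))
  expect_gte(attr(panel, "n_rejected"), 20)
  expect_false(any(panel$pos %in% cand_pos[bad]))
})
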