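#' Specification of a simulated structured population
#'
#' Collects the knobs of the cohort simulator: a set of reference
#' sequences, `n_loci` biallelic SNPs placed on them, and
#' `n_pops * n_per_pop` diploid samples whose population allele
#' frequencies follow the Balding-Nichols model: for ancestral frequency
#' `p` and differentiation `F`, population frequencies are
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `F` plays the role of FST.
#' Genotypes are binomial draws from the population frequency; an
#' optional fraction of samples is admixed, drawing each of its two
#' allele copies from population `k` with probability `q_k` where `q`
#' is Dirichlet(1) distributed. Per-call depths are Poisson around
#' `mean_depth`; a fraction of sites receives a QUAL below 20;
#' genotype calls go missing independently with `missing_rate`.
#'
#' @param n_pops number of source populations (>= 1)
#' @param n_per_pop diploid samples per population
#' @param fst differentiation parameter in (0, 1); recycled to `n_pops`
#' @param n_loci number of SNP loci to place
#' @param seq_lengths integer vector of reference sequence lengths (bp)
#' @param admixed_fraction fraction of samples given mixed ancestry
#' @param missing_rate per-call missingness probability
#' @param mean_depth expected per-call sequencing depth
#' @param qual_low_fraction fraction of sites with QUAL drawn below 20
#' @param seed integer seed; all randomness derives from it
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_pops = 3, n_per_pop = 15, fst = 0.1,
                            n_loci = 2000, seq_lengths = rep(100000L, 6),
                            admixed_fraction = 0, missing_rate = 0.02,
                            mean_depth = 20, qual_low_fraction = 0.05,
                            seed = 1L) {
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_loci >= 1,
            all(fst > 0), all(fst < 1),
            admixed_fraction >= 0, admixed_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            qual_low_fraction >= 0, qual_low_fraction <= 1,
            mean_depth > 0, length(seq_lengths) >= 1)
  seq_lengths <- as.integer(seq_lengths)
  if (any(seq_lengths <= 0)) stop("sequence lengths must be positive")
  if (sum(seq_lengths) < n_loci * 10) {
    stop("reference too short: need total length >= 10 bp per locus")
  }
  fst <- rep_len(fst, n_pops)
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop), fst = fst,
                 n_loci = as.integer(n_loci), seq_lengths = seq_lengths,
                 admixed_fraction = admixed_fraction,
                 missing_rate = missing_rate, mean_depth = mean_depth,
                 qual_low_fraction = qual_low_fraction,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate reference sequences
#'
#' Uniform-base ACGT sequences of the lengths in `spec$seq_lengths`,
#' deterministic for a given seed. Sequence ids are `seq1..seqN`.
#'
#' @param spec a [population_spec()]
#' @return a [Biostrings::DNAStringSet] named `seq1..seqN`
#' @export
simulate_reference <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  seqs <- vapply(spec$seq_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

# Place n_loci positions on the reference: allocated to sequences by
# largest-remainder proportional split of usable length, then uniform
# within each sequence at >= min_gap bp apart and >= margin bp from ends.
place_loci <- function(spec, min_gap = 10L, margin = 200L) {
  L <- spec$seq_lengths
  usable <- pmax(L - 2L * margin, 0L)
  cap <- ifelse(usable >= 1L, (usable - 1L) %/% min_gap + 1L, 0L)
  quota <- floor(spec$n_loci * usable / sum(usable))
  rem <- spec$n_loci - sum(quota)
  if (rem > 0) {
    frac <- spec$n_loci * usable / sum(usable) - quota
    quota[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      quota[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  over <- which(quota > cap)
  for (s in over) {
    stop(sprintf("cannot place %d loci on seq%d (%d bp): spacing infeasible",
                 quota[s], s, L[s]))
  }
  do.call(rbind, lapply(seq_along(L), function(s) {
    n_s <- quota[s]
    if (n_s == 0L) return(NULL)
    span <- usable[s] - (n_s - 1L) * min_gap
    u <- sort(runif(n_s, 0, span))
    data.frame(seq_id = paste0("seq", s),
               pos = margin + floor(u) + (seq_len(n_s) - 1L) * min_gap + 1L)
  }))
}

#' Simulate a structured diploid population at placed SNP loci
#'
#' Draws ancestral frequencies Uniform(0.05, 0.95), Balding-Nichols
#' population frequencies, binomial genotypes (allele copies drawn
#' population-wise through each sample's ancestry vector `q`), Poisson
#' depths, site QUALs, and missingness, and returns the genotype matrix
#' together with the generating truth.
#'
#' @param spec a [population_spec()]
#' @param ref reference sequences from [simulate_reference()]
#' @return list with elements `matrix` (a [geno_matrix()], REF/ALT alleles
#'   taken from/complementary to the reference base at each site) and
#'   `truth` (class `truth_set`: `ancestral_freqs` (length n_loci),
#'   `pop_freqs` (n_pops x n_loci), `q_true` (n_samples x n_pops, rows
#'   sum to 1), `groups` (named by sample)).
#' @export
simulate_population <- function(spec, ref) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed + 1L)
  K <- spec$n_pops
  n <- K * spec$n_per_pop
  L <- spec$n_loci
  sites <- place_loci(spec)
  p_anc <- runif(L, 0.05, 0.95)
  pop_freqs <- t(vapply(seq_len(K), function(k) {
    f <- spec$fst[k]
    rbeta(L, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }, numeric(L)))
  pop_freqs <- pmin(pmax(pop_freqs, 1e-9), 1 - 1e-9)

  samples <- sprintf("S%03d", seq_len(n))
  block <- rep(seq_len(K), each = spec$n_per_pop)
  groups <- paste0("pop", block)
  names(groups) <- samples
  q_true <- diag(K)[block, , drop = FALSE]
  n_adm <- round(spec$admixed_fraction * n)
  if (n_adm > 0) {
    adm <- sample(n, n_adm)
    g <- matrix(rgamma(n_adm * K, 1), n_adm, K)
    q_true[adm, ] <- g / rowSums(g)
  }
  rownames(q_true) <- samples
  colnames(q_true) <- paste0("pop", seq_len(K))

  geno <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    q <- q_true[i, ]
    if (max(q) >= 1) {
      geno[i, ] <- rbinom(L, 2L, pop_freqs[which.max(q), ])
    } else {
      k1 <- sample.int(K, L, replace = TRUE, prob = q)
      k2 <- sample.int(K, L, replace = TRUE, prob = q)
      geno[i, ] <- rbinom(L, 1L, pop_freqs[cbind(k1, seq_len(L))]) +
        rbinom(L, 1L, pop_freqs[cbind(k2, seq_len(L))])
    }
  }
  depth <- matrix(rpois(n * L, spec$mean_depth), n, L)
  if (spec$missing_rate > 0) {
    geno[matrix(runif(n * L) < spec$missing_rate, n, L)] <- NA_integer_
  }
  qual <- round(runif(L, 20, 60), 2)
  n_low <- round(spec$qual_low_fraction * L)
  if (n_low > 0) {
    low <- sample(L, n_low)
    qual[low] <- round(runif(n_low, 2, 19.9), 2)
  }

  ref_chars <- mapply(function(s, p) {
    as.character(Biostrings::subseq(ref[[s]], p, p))
  }, sites$seq_id, sites$pos)
  alt_chars <- vapply(ref_chars, function(b) {
    switch(b, A = "G", C = "T", G = "A", T = "C", "A")
  }, character(1), USE.NAMES = FALSE)

  loci <- data.frame(seq_id = sites$seq_id, pos = sites$pos,
                     ref = unname(ref_chars), alt = alt_chars, qual = qual,
                     stringsAsFactors = FALSE)
  gm <- geno_matrix(geno, loci, samples = samples, depth = depth,
                    groups = groups)
  truth <- structure(list(ancestral_freqs = p_anc, pop_freqs = pop_freqs,
                          q_true = q_true, groups = groups),
                     class = "truth_set")
  list(matrix = gm, truth = truth)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_reference()] and [simulate_population()] and writes
#' `<prefix>.fasta`, `<prefix>.vcf`, `<prefix>.groups.tsv` (sample, group)
#' and `<prefix>.truth.tsv` (sample, group, q per population). Same seed,
#' same bytes.
#'
#' @param spec a [population_spec()]
#' @param out_prefix path prefix for the output files
#' @return (invisibly) list with `ref`, `matrix`, `truth` and the output
#'   `paths`
#' @export
simulate_cohort <- function(spec, out_prefix) {
  ref <- simulate_reference(spec)
  sim <- simulate_population(spec, ref)
  paths <- paste0(out_prefix, c(".fasta", ".vcf", ".groups.tsv",
                                ".truth.tsv"))
  names(paths) <- c("fasta", "vcf", "groups", "truth")
  Biostrings::writeXStringSet(ref, paths["fasta"])
  write_vcf(sim$matrix, paths["vcf"])
  write_groups(sim$matrix$groups, paths["groups"])
  q <- sim$truth$q_true
  tr <- data.frame(sample = rownames(q),
                   group = unname(sim$truth$groups[rownames(q)]),
                   round(q, 6), check.names = FALSE)
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(ref = ref, matrix = sim$matrix, truth = sim$truth,
                 paths = paths))
}
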