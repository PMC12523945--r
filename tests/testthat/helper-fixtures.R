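# In-code fixtures and independent oracles shared across the suite.

# Quick geno_matrix from a dosage matrix (samples x loci).
make_gm <- function(geno, pos = NULL, seq_id = "seq1", qual = 50,
                    depth = NULL, groups = NULL, ref = "A", alt = "G") {
  n_l <- ncol(geno)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = n_l)
  loci <- data.frame(seq_id = rep_len(seq_id, n_l), pos = pos,
                     ref = rep_len(ref, n_l), alt = rep_len(alt, n_l),
                     qual = rep_len(qual, n_l))
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%03d", seq_len(nrow(geno)))
  }
  geno_matrix(geno, loci, depth = depth, groups = groups)
}

# Random dosage matrix with optional missingness.
random_geno <- function(n, L, p = NULL, miss = 0) {
  if (is.null(p)) p <- runif(L, 0.05, 0.95)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (miss > 0) g[matrix(runif(n * L) < miss, n, L)] <- NA
  matrix(as.integer(g), n, L)
}

# Hand-crafted screening-cascade fixture: one locus failing each rule
# (QUAL, indel, depth, MAF, missing, het), a 3-bp spacing pair, and one
# clean locus. Mean depth over the 9 loci is 10x so the depth-fail locus
# (2x) sits below both the window (> 10/3) and the 5x site minimum.
cascade_fixture <- function() {
  n <- 10L
  good <- c(rep(0L, 4), rep(1L, 3), rep(2L, 3))       # maf .45, ho .3
  loci <- data.frame(
    seq_id = "seq1",
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 703L, 900L),
    ref = "A",
    alt = c("G", "GT", "G", "G", "G", "G", "G", "G", "G"),
    qual = c(10, rep(50, 8)))
  geno <- cbind(
    good,                                  # fails qual (10 < 20)
    good,                                  # indel ALT "GT"
    good,                                  # depth 2x (see below)
    rep(0L, 10),                           # monomorphic: maf 0 < 0.05
    c(good[1:6], rep(NA, 4)),              # missing 0.4
    c(rep(1L, 9), 0L),                     # het 0.9
    good,                                  # spacing pair @700 (kept: rank)
    c(rep(0L, 5), rep(1L, 3), 2L, 2L),     # spacing pair @703, lower MAF
    good)                                  # clean survivor
  depth <- matrix(11L, n, 9)
  depth[, 3] <- 2L                         # grand mean = 10x exactly
  storage.mode(geno) <- "integer"
  rownames(geno) <- sprintf("S%03d", 1:10)
  geno_matrix(geno, loci, depth = depth)
}

# --- independent oracles -------------------------------------------------

# Per-genotype enumeration oracle for locus diversity statistics.
naive_locus_stats <- function(dos) {
  dos <- dos[!is.na(dos)]
  n0 <- sum(dos == 0); n1 <- sum(dos == 1); n2 <- sum(dos == 2)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  list(n_called = n, maf = min(p, q), he = 1 - p^2 - q^2,
       pic = 1 - p^2 - q^2 - 2 * p^2 * q^2,
       ao = if (p > 0 && p < 1) 2 else 1, ae = 1 / (p^2 + q^2),
       ho = n1 / n)
}

# Naive double-loop Pearson r^2 between two dosage vectors.
naive_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 4) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  num <- sum((a - mean(a)) * (b - mean(b)))
  (num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
}

# Naive per-pair p-distance.
naive_pdist <- function(g) {
  n <- nrow(g)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    D[i, j] <- mean(abs(g[i, ok] - g[j, ok]) / 2)
  }
  D
}

# Naive per-pair GRM (same formula, double loop).
naive_grm <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  n <- nrow(g)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    G[i, j] <- mean((g[i, ok] - 2 * p[ok]) * (g[j, ok] - 2 * p[ok]) /
                      (2 * p[ok] * (1 - p[ok])))
  }
  G
}

# Hudson FST (ratio of averages) from two frequency vectors.
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# Random unrooted binary tree with additive distances.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  ord <- order(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Canonical split set of a tree (via the package helper on a copy).
splits_of <- function(tree) snpanel:::tree_splits(tree)
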