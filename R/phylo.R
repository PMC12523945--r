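#' Genotype p-distance matrix
#'
#' Allele-sharing distance for unphased diploid dosages:
#' `d(i, j)` is the mean over loci called in both samples of
#' `|g_i - g_j| / 2`, i.e. 0 for identical genotypes, 1/2 for a
#' one-allele mismatch, 1 for opposite homozygotes. Computed with
#' matrix cross-products, so bootstrap replicates stay cheap.
#'
#' @param x a [geno_matrix()] (>= 2 samples)
#' @return symmetric distance matrix with sample dimnames
#' @export
p_distance <- function(x) {
  stopifnot(inherits(x, "geno_matrix"), n_samples(x) >= 2)
  D <- p_distance_geno(x$geno)
  dimnames(D) <- list(x$samples, x$samples)
  D
}

# core on a raw dosage matrix (rows = samples); tolerates duplicated
# locus columns (bootstrap resampling)
p_distance_geno <- function(g) {
  called <- !is.na(g)
  a <- ifelse(called, g, 0)
  sq <- a^2
  cross <- tcrossprod(a)
  sqsum <- tcrossprod(sq, called)          # sum_i g_i^2 over j-called loci
  h0 <- (a == 0) & called
  h2 <- a == 2
  opp <- tcrossprod(h0, h2)
  opp <- opp + t(opp)
  nshared <- tcrossprod(called)
  if (any(nshared[upper.tri(nshared)] == 0)) {
    stop("sample pair with no shared called loci")
  }
  absdiff <- sqsum + t(sqsum) - 2 * cross - 2 * opp
  D <- absdiff / (2 * nshared)
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric
#' distance matrix, returning an unrooted tree. Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' adjacent (sibling) edge, preserving the distance between the joined
#' pair.
#'
#' @param D symmetric distance matrix (>= 3 taxa, finite entries)
#' @return an [ape] `phylo` tree
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(D))) stop("non-finite distances")
  tree <- ape::nj(D)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

# Canonical label-based bipartition keys of a tree's internal edges.
# Each split is represented by the side not containing the
# alphabetically first taxon, as a "|"-joined sorted label string;
# trivial splits are dropped.
tree_splits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  ref <- sort(labs)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Canonical key of a bipartition
#'
#' Helper to query bootstrap supports: the key of the split separating
#' `taxa` from the rest, in the same canonical form used by
#' [bootstrap_support()].
#'
#' @param taxa character vector of tip labels on one side of the split
#' @param all_taxa all tip labels
#' @return character key
#' @export
split_key <- function(taxa, all_taxa) {
  ref <- sort(all_taxa)[1]
  side <- if (ref %in% taxa) setdiff(all_taxa, taxa) else taxa
  paste(sort(side), collapse = "|")
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree on the full p-distance matrix, then resamples
#' loci with replacement `reps` times, rebuilds the tree, and scores
#' each internal edge of the base tree by the fraction of replicate
#' trees containing the same bipartition. Supports are written to
#' `tree$node.label` and returned keyed by bipartition in attribute
#' `split_support`.
#'
#' @param x a [geno_matrix()] (>= 4 samples)
#' @param reps bootstrap replicates (>= 1)
#' @param seed integer seed
#' @return an [ape] `phylo` tree with `node.label` supports in [0, 1]
#'   and attribute `split_support` (named numeric vector)
#' @export
bootstrap_support <- function(x, reps = 1000L, seed = 1L) {
  stopifnot(inherits(x, "geno_matrix"), n_samples(x) >= 4)
  if (reps < 1) stop("reps must be >= 1")
  base <- neighbor_joining(p_distance(x))
  set.seed(seed)
  L <- n_loci(x)
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    g <- x$geno[, cols, drop = FALSE]
    D <- p_distance_geno(g)
    dimnames(D) <- list(x$samples, x$samples)
    for (key in tree_splits(neighbor_joining(D))) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else
        counts[[key]]) + 1L
    }
  }
  labs <- base$tip.label
  ref <- sort(labs)[1]
  n <- length(labs)
  parts <- ape::prop.part(base)
  support <- rep(NA_real_, base$Nnode)
  keys <- rep(NA_character_, base$Nnode)
  for (i in seq_along(parts)) {
    side <- labs[parts[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) next
    key <- paste(sort(side), collapse = "|")
    keys[i] <- key
    support[i] <- (if (is.null(counts[[key]])) 0L else
      counts[[key]]) / reps
  }
  base$node.label <- ifelse(is.na(support), "",
                            sprintf("%.6g", support))
  ss <- support[!is.na(keys)]
  names(ss) <- keys[!is.na(keys)]
  attr(base, "split_support") <- ss
  base
}

#' Group-level distance matrix on mean allele frequencies
#'
#' Alternative to individual-level trees: per-group alt-allele
#' frequencies are computed and the distance between groups is the mean
#' absolute frequency difference over loci polymorphic somewhere.
#'
#' @param x a [geno_matrix()] with group labels
#' @return symmetric matrix over groups
#' @export
group_distance <- function(x) {
  if (is.null(x$groups)) stop("geno_matrix has no group labels")
  groups <- sort(unique(x$groups))
  freqs <- vapply(groups, function(gname) {
    g <- x$geno[x$groups == gname, , drop = FALSE]
    colMeans(g, na.rm = TRUE) / 2
  }, numeric(n_loci(x)))
  D <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    ok <- !is.na(freqs[, i]) & !is.na(freqs[, j])
    D[i, j] <- D[j, i] <- mean(abs(freqs[ok, i] - freqs[ok, j]))
  }
  D
}

#' Write a tree as newick
#'
#' Standard newick with branch lengths to 6 significant digits and any
#' node labels (e.g. bootstrap supports) as internal-node labels. Tip
#' labels containing whitespace or newick metacharacters are
#' single-quoted.
#'
#' @param tree an [ape] `phylo` tree
#' @param path output file
#' @return (invisibly) the path
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

newick_string <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(s) {
    if (grepl("[][ \t(),:;']", s)) {
      paste0("'", gsub("'", "''", s), "'")
    } else s
  }
  node_str <- function(node) {
    if (node <= ntip) return(quote_label(tree$tip.label[node]))
    edges <- kids[[as.character(node)]]
    inner <- vapply(edges, function(e) {
      child <- tree$edge[e, 2]
      paste0(node_str(child), ":",
             sprintf("%.6g", tree$edge.length[e]))
    }, character(1))
    lab <- if (!is.null(tree$node.label)) {
      quote_label(as.character(tree$node.label[node - ntip]))
    } else ""
    paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  root <- ntip + 1L
  paste0(node_str(root), ";")
}

#' Write a square distance matrix as TSV
#'
#' @param D symmetric matrix with dimnames
#' @param path output file
#' @return (invisibly) the path
#' @export
write_dist_tsv <- function(D, path) {
  tab <- data.frame(sample = rownames(D),
                    matrix(sprintf("%.8g", D), nrow(D),
                           dimnames = list(NULL, colnames(D))),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
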