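#' Genotype matrix container
#'
#' A `geno_matrix` bundles a samples x loci minor/alternate-allele dosage
#' matrix (integer 0/1/2, `NA` for missing calls) with per-locus metadata
#' (sequence id, 1-based position, alleles, site QUAL, biallelic-SNP flags)
#' and an optional per-sample, per-locus sequencing depth matrix and group
#' labels. Loci are kept sorted by `(seq_id, pos)` and must be unique.
#'
#' @param geno integer matrix, samples in rows, loci in columns; entries in
#'   \{0, 1, 2, NA\}. Dosage counts copies of the first ALT allele.
#' @param loci data.frame with columns `seq_id`, `pos`, `ref`, `alt`,
#'   `qual`, and optionally `is_snp`, `is_biallelic` (recomputed from the
#'   allele strings when absent). `alt` may hold comma-separated
#'   alternates for multi-allelic records.
#' @param samples character vector of sample ids (defaults to rownames).
#' @param depth optional integer matrix of per-call read depths, same
#'   dimensions as `geno`.
#' @param groups optional named character vector mapping every sample to a
#'   group label.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, loci, samples = rownames(geno),
                        depth = NULL, groups = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  stopifnot(length(samples) == nrow(geno))
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("seq_id", "pos", "ref", "alt", "qual")
  if (!all(req %in% names(loci))) {
    stop("loci must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loci) != ncol(geno)) {
    stop("loci rows (", nrow(loci), ") != genotype columns (", ncol(geno), ")")
  }
  if (nrow(loci) && any(loci$pos < 1)) stop("positions must be >= 1")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  alt1 <- vapply(strsplit(as.character(loci$alt), ","), `[`, "", 1L)
  n_alt <- lengths(strsplit(as.character(loci$alt), ","))
  loci$is_biallelic <- n_alt == 1L
  loci$is_snp <- loci$is_biallelic &
    nchar(as.character(loci$ref)) == 1L & nchar(alt1) == 1L
  ord <- order(loci$seq_id, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  if (!is.null(depth)) {
    depth <- as.matrix(depth)[, ord, drop = FALSE]
    storage.mode(depth) <- "integer"
    stopifnot(all(dim(depth) == dim(geno)))
  }
  if (anyDuplicated(paste(loci$seq_id, loci$pos))) {
    stop("duplicate (seq_id, pos) among loci")
  }
  rownames(loci) <- NULL
  dimnames(geno) <- list(samples, locus_ids(loci))
  if (!is.null(depth)) dimnames(depth) <- dimnames(geno)
  if (!is.null(groups)) {
    groups <- groups[samples]
    if (anyNA(groups)) stop("every sample needs a group label")
    names(groups) <- samples
  }
  structure(list(geno = geno, loci = loci, samples = samples,
                 depth = depth, groups = groups),
            class = "geno_matrix")
}

locus_ids <- function(loci) paste(loci$seq_id, loci$pos, sep = ":")

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of samples / loci
#' @param x a `geno_matrix`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_loci <- function(x) ncol(x$geno)

#' Subset a geno_matrix by loci and/or samples
#'
#' @param x a `geno_matrix`
#' @param loci_idx logical or integer index over loci
#' @param sample_idx logical, integer or character index over samples
#' @return a `geno_matrix`
#' @export
subset_geno <- function(x, loci_idx = NULL, sample_idx = NULL) {
  if (is.null(loci_idx)) loci_idx <- seq_len(n_loci(x))
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(x))
  if (is.character(sample_idx)) sample_idx <- match(sample_idx, x$samples)
  geno_matrix(x$geno[sample_idx, loci_idx, drop = FALSE],
              x$loci[loci_idx, , drop = FALSE],
              samples = x$samples[sample_idx],
              depth = if (!is.null(x$depth))
                x$depth[sample_idx, loci_idx, drop = FALSE],
              groups = x$groups)
}

#' Per-locus mean sequencing depth
#'
#' Mean of the per-sample DP values at each locus (all samples, including
#' ones with missing genotype calls). `NA` when no depth matrix is present.
#' @param x a `geno_matrix`
#' @return numeric vector, one value per locus
#' @export
locus_mean_depth <- function(x) {
  if (is.null(x$depth)) return(rep(NA_real_, n_loci(x)))
  colMeans(x$depth, na.rm = TRUE)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci (%d sequence%s)\n",
              n_samples(x), n_loci(x), length(unique(x$loci$seq_id)),
              if (length(unique(x$loci$seq_id)) == 1) "" else "s"))
  miss <- if (n_loci(x)) mean(is.na(x$geno)) else 0
  cat(sprintf("  missing calls: %.2f%%; depth: %s; groups: %s\n",
              100 * miss,
              if (is.null(x$depth)) "absent" else "present",
              if (is.null(x$groups)) "absent" else
                paste0(length(unique(x$groups)), " group(s)")))
  invisible(x)
}
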