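#' Per-locus diversity statistics
#'
#' For each locus, from the non-missing calls of the chosen samples:
#' alt-allele frequency `p`, minor allele frequency `maf = min(p, 1-p)`,
#' expected heterozygosity (gene diversity) `he = 1 - p^2 - q^2`
#' (plug-in estimator; the unbiased `2n/(2n-1)` variant is available via
#' `unbiased`), polymorphism information content
#' `pic = 1 - p^2 - q^2 - 2 p^2 q^2` (Botstein's form for two alleles),
#' observed allele number `ao` (2 when both alleles are seen), effective
#' allele number `ae = 1 / (p^2 + q^2)`, and observed heterozygosity
#' `ho` (fraction of non-missing calls that are heterozygous).
#'
#' @param x a [geno_matrix()]
#' @param samples optional subset of sample ids/indices to compute from
#' @param unbiased apply the small-sample `2n/(2n-1)` correction to `he`
#'   (and recompute `pic`, `ae` coherently from the corrected homozygosity)
#' @return data.frame with one row per locus: `seq_id`, `pos`,
#'   `n_called`, `maf`, `pic`, `ao`, `ae`, `ho`, `he`. Loci with no
#'   non-missing call get `NA` statistics.
#' @export
locus_diversity <- function(x, samples = NULL, unbiased = FALSE) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- if (is.null(samples)) x$geno else {
    if (is.character(samples)) samples <- match(samples, x$samples)
    x$geno[samples, , drop = FALSE]
  }
  n_called <- colSums(!is.na(g))
  p <- ifelse(n_called > 0, colSums(g, na.rm = TRUE) / (2 * n_called), NA)
  q <- 1 - p
  hom <- p^2 + q^2
  if (unbiased) {
    nn <- 2 * n_called
    hom <- ifelse(nn > 1, (hom * nn - 1) / (nn - 1), hom)
    hom <- pmin(pmax(hom, 0), 1)
  }
  he <- 1 - hom
  pic <- he - 2 * p^2 * q^2
  ao <- ifelse(p > 0 & p < 1, 2L, 1L)
  ae <- 1 / hom
  ho <- ifelse(n_called > 0, colMeans(g == 1L, na.rm = TRUE), NA)
  data.frame(seq_id = x$loci$seq_id, pos = x$loci$pos,
             n_called = n_called, maf = pmin(p, q), pic = pic, ao = ao,
             ae = ae, ho = ho, he = he, stringsAsFactors = FALSE)
}

#' Per-group diversity summary table
#'
#' Mean per-locus diversity statistics within each group (allele
#' frequencies recomputed from that group's samples only) plus an `All`
#' row computed from the pooled cohort. Means are unweighted over loci
#' with at least one called genotype in the group. Groups are listed
#' alphabetically after the `All` row.
#'
#' @param x a [geno_matrix()] with group labels attached
#' @param unbiased passed to [locus_diversity()]
#' @return data.frame with columns `group`, `n_samples`, `maf`, `pic`,
#'   `ao`, `ae`, `ho`, `he`
#' @export
group_diversity <- function(x, unbiased = FALSE) {
  stopifnot(inherits(x, "geno_matrix"))
  if (is.null(x$groups)) stop("geno_matrix has no group labels")
  groups <- sort(unique(x$groups))
  rows <- lapply(c("All", groups), function(gname) {
    ids <- if (gname == "All") x$samples else
      x$samples[x$groups == gname]
    if (!length(ids)) stop("empty group: ", gname)
    st <- locus_diversity(x, samples = ids, unbiased = unbiased)
    st <- st[st$n_called > 0, , drop = FALSE]
    data.frame(group = gname, n_samples = length(ids),
               maf = mean(st$maf), pic = mean(st$pic), ao = mean(st$ao),
               ae = mean(st$ae), ho = mean(st$ho), he = mean(st$he),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
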