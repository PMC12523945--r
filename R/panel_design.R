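#' Screening-cascade and panel-selection parameters
#'
#' Thresholds of the marker screening cascade and the ranked selection.
#' Defaults follow the usual targeted-genotyping screen: site QUAL >= 20,
#' biallelic SNPs only, per-locus mean depth within `[1/3, 5]` times the
#' cohort average and >= 5x, MAF >= 0.05, missing rate < 0.25,
#' heterozygosity rate <= 0.5, loci >= 5 bp apart, and a 5000-locus
#' target panel.
#'
#' @param min_qual minimum site QUAL retained
#' @param min_spacing_bp minimum distance (bp) between retained loci on
#'   the same sequence
#' @param depth_window multipliers `(low, high)` on the cohort mean depth
#' @param min_site_depth minimum per-locus mean depth
#' @param min_maf minimum minor allele frequency (inclusive)
#' @param max_missing loci with missing rate `>= max_missing` are removed
#'   (the retain rule is strict `<`)
#' @param max_het_rate heterozygosity-rate threshold
#' @param het_rule `"remove_high"` (default) removes loci with het rate
#'   above `max_het_rate`; `"remove_low"` removes those below it
#' @param target_size panel size for [rank_and_select()]
#' @return an object of class `filter_params`
#' @export
filter_params <- function(min_qual = 20, min_spacing_bp = 5L,
                          depth_window = c(1 / 3, 5), min_site_depth = 5,
                          min_maf = 0.05, max_missing = 0.25,
                          max_het_rate = 0.5,
                          het_rule = c("remove_high", "remove_low"),
                          target_size = 5000L) {
  het_rule <- match.arg(het_rule)
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0,
            max_missing <= 1, length(depth_window) == 2,
            depth_window[1] < depth_window[2], min_spacing_bp >= 0)
  structure(list(min_qual = min_qual,
                 min_spacing_bp = as.integer(min_spacing_bp),
                 depth_window = depth_window,
                 min_site_depth = min_site_depth, min_maf = min_maf,
                 max_missing = max_missing, max_het_rate = max_het_rate,
                 het_rule = het_rule, target_size = as.integer(target_size)),
            class = "filter_params")
}

# Per-locus screening covariates. Mean depth is the grand mean of
# per-locus mean depths over the *input* loci (computed once, before any
# rule fires). Missing rate counts all samples; MAF and het rate count
# non-missing calls only.
locus_screen_stats <- function(x) {
  st <- locus_diversity(x)
  data.frame(seq_id = x$loci$seq_id, pos = x$loci$pos,
             qual = x$loci$qual, is_snp = x$loci$is_snp,
             depth = locus_mean_depth(x),
             maf = st$maf, ho = st$ho,
             missing = 1 - st$n_called / n_samples(x),
             stringsAsFactors = FALSE)
}

# Rank-score ordering: high MAF, then low missing rate, then low het
# rate, then (seq_id, pos) as the deterministic tiebreak.
rank_order <- function(stats) {
  order(-stats$maf, stats$missing, stats$ho, stats$seq_id, stats$pos)
}

# Greedy spacing enforcement in rank order. Conflicts only arise inside
# maximal runs of same-sequence loci whose consecutive gaps are all
# < min_spacing, so each run is resolved independently: accept members in
# rank order, dropping any within min_spacing of an accepted one.
spacing_keep <- function(stats, min_spacing, rank_idx) {
  n <- nrow(stats)
  keep <- rep(TRUE, n)
  if (n < 2 || min_spacing <= 1) return(keep)
  rnk <- integer(n)
  rnk[rank_idx] <- seq_len(n)
  ord <- order(stats$seq_id, stats$pos)
  gap_ok <- c(TRUE, stats$seq_id[ord[-n]] != stats$seq_id[ord[-1]] |
                stats$pos[ord[-1]] - stats$pos[ord[-n]] >= min_spacing)
  comp <- cumsum(gap_ok)
  for (cc in unique(comp[duplicated(comp)])) {
    members <- ord[comp == cc]
    members <- members[order(rnk[members])]
    acc <- integer(0)
    for (m in members) {
      if (length(acc) && any(abs(stats$pos[acc] - stats$pos[m]) <
                               min_spacing)) {
        keep[m] <- FALSE
      } else {
        acc <- c(acc, m)
      }
    }
  }
  keep
}

#' Apply the marker screening cascade
#'
#' Runs the ordered filter cascade on a genotype matrix: (1) site QUAL,
#' (2) biallelic SNP (indels and multi-allelic sites removed), (3) depth
#' (per-locus mean depth inside the window around the cohort average and
#' above the site minimum), (4) MAF, (5) missing rate, (6) heterozygosity
#' rate, (7) minimum spacing, resolved in favour of the higher-ranked
#' locus (see [rank_and_select()] for the ranking). Returns the
#' survivors and a per-rule attrition report.
#'
#' When the matrix carries no depth information the depth rule passes
#' every locus.
#'
#' @param x a [geno_matrix()]
#' @param params a [filter_params()]
#' @return list with `matrix` (surviving [geno_matrix()]) and `report`
#'   (class `filter_report`: `$rules` data.frame of per-rule
#'   `n_in`/`n_removed`/`n_out`, `$first_fail` named character vector of
#'   the first failing rule per input locus, `NA` for survivors)
#' @export
filter_candidates <- function(x, params = filter_params()) {
  stopifnot(inherits(x, "geno_matrix"), n_loci(x) > 0)
  stats <- locus_screen_stats(x)
  grand_depth <- mean(stats$depth)
  pass_depth <- if (all(is.na(stats$depth))) rep(TRUE, nrow(stats)) else
    stats$depth >= params$depth_window[1] * grand_depth &
    stats$depth <= params$depth_window[2] * grand_depth &
    stats$depth >= params$min_site_depth
  het_pass <- if (params$het_rule == "remove_high")
    stats$ho <= params$max_het_rate else stats$ho >= params$max_het_rate
  checks <- list(
    qual = !is.na(stats$qual) & stats$qual >= params$min_qual,
    biallelic_snp = stats$is_snp,
    depth = pass_depth,
    maf = !is.na(stats$maf) & stats$maf >= params$min_maf,
    missing = stats$missing < params$max_missing,
    het = !is.na(stats$ho) & het_pass)

  n <- n_loci(x)
  alive <- rep(TRUE, n)
  first_fail <- rep(NA_character_, n)
  rules <- data.frame(rule = character(0), n_in = integer(0),
                      n_removed = integer(0), n_out = integer(0))
  for (rule in names(checks)) {
    n_in <- sum(alive)
    fail <- alive & !checks[[rule]]
    first_fail[fail] <- rule
    alive <- alive & checks[[rule]]
    rules <- rbind(rules, data.frame(rule = rule, n_in = n_in,
                                     n_removed = sum(fail),
                                     n_out = sum(alive)))
  }
  # spacing last, greedy by rank among the still-alive loci
  n_in <- sum(alive)
  idx <- which(alive)
  sub <- stats[idx, , drop = FALSE]
  keep <- spacing_keep(sub, params$min_spacing_bp, rank_order(sub))
  first_fail[idx[!keep]] <- "spacing"
  alive[idx[!keep]] <- FALSE
  rules <- rbind(rules, data.frame(rule = "spacing", n_in = n_in,
                                   n_removed = sum(!keep),
                                   n_out = sum(alive)))
  names(first_fail) <- locus_ids(x$loci)
  if (!any(alive)) warning("all loci removed by the screening cascade")
  out <- subset_geno(x, loci_idx = alive)
  report <- structure(list(rules = rules, first_fail = first_fail),
                      class = "filter_report")
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("marker screening cascade:\n")
  print(x$rules, row.names = FALSE)
  invisible(x)
}

#' Ranked selection of a fixed-size panel
#'
#' Scores each candidate locus lexicographically — MAF descending, then
#' missing rate ascending, then heterozygosity rate ascending, with
#' `(seq_id, pos)` as the deterministic tiebreak — and selects greedily
#' in score order under the minimum-spacing constraint until
#' `target_size` loci are chosen or candidates run out.
#'
#' @param x candidate [geno_matrix()] (normally the survivors of
#'   [filter_candidates()])
#' @param params a [filter_params()]
#' @return an object of class `snp_panel`: a data.frame of the selected
#'   loci (rank order) with columns `rank`, `seq_id`, `pos`, `ref`,
#'   `alt`, `qual`, `maf`, `missing`, `het` plus the `filter_params` as
#'   attribute `params`
#' @export
rank_and_select <- function(x, params = filter_params()) {
  stopifnot(inherits(x, "geno_matrix"))
  if (params$target_size <= 0) stop("target_size must be positive")
  stats <- locus_screen_stats(x)
  ord <- rank_order(stats)
  keep <- spacing_keep(stats, params$min_spacing_bp, ord)
  sel <- ord[keep[ord]]
  sel <- sel[seq_len(min(length(sel), params$target_size))]
  panel <- data.frame(rank = seq_along(sel),
                      seq_id = x$loci$seq_id[sel], pos = x$loci$pos[sel],
                      ref = x$loci$ref[sel], alt = x$loci$alt[sel],
                      qual = x$loci$qual[sel], maf = stats$maf[sel],
                      missing = stats$missing[sel], het = stats$ho[sel],
                      stringsAsFactors = FALSE)
  structure(panel, params = params, class = c("snp_panel", "data.frame"))
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d loci on %d sequence(s); mean MAF %.3f\n",
              nrow(x), length(unique(x$seq_id)), mean(x$maf)))
  if ("pass" %in% names(x)) {
    cat(sprintf("  probe pairs: %d pass, %d fail\n", sum(x$pass),
                sum(!x$pass)))
  }
  invisible(x)
}

#' Write panel files
#'
#' Writes `<prefix>.panel.tsv` (the score table), `<prefix>.panel.bed`
#' (0-based half-open single-base intervals) and, when the source
#' genotype matrix is given, `<prefix>.panel.vcf` restricted to the
#' panel loci.
#'
#' @param panel a [rank_and_select()] panel
#' @param prefix output path prefix
#' @param x optional source [geno_matrix()] for the VCF subset
#' @return (invisibly) the paths written
#' @export
write_panel <- function(panel, prefix, x = NULL) {
  paths <- paste0(prefix, c(".panel.tsv", ".panel.bed"))
  tab <- as.data.frame(panel)
  num <- vapply(tab, is.numeric, logical(1)) &
    !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.6g", v))
  utils::write.table(tab, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(panel$seq_id, panel$pos - 1L, panel$pos,
                    paste0(panel$seq_id, ":", panel$pos))
  bed <- bed[order(bed[[1]], bed[[2]]), ]
  utils::write.table(bed, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(x)) {
    keep <- locus_ids(x$loci) %in% paste(panel$seq_id, panel$pos,
                                         sep = ":")
    vpath <- paste0(prefix, ".panel.vcf")
    write_vcf(subset_geno(x, loci_idx = keep), vpath)
    paths <- c(paths, vpath)
  }
  invisible(paths)
}
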