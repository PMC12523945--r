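#' Probe-design parameters
#'
#' Constraints for in-solution capture probes: two 110 bp probes per
#' locus sharing 60-70% of their length (target 65%), each probe with
#' GC in [0.30, 0.70] and at most 5 homologous regions genome-wide.
#' Homologous regions are counted as merged k-mer seed-hit windows
#' (`k = 15`, at least `min_seed_hits = 5` shared k-mers per window,
#' both strands). The locus is evaluated inside a 120 bp window and the
#' SNP is kept at least `min_snp_edge_bp = 10` bp from each probe end.
#'
#' @param probe_length probe length in bp
#' @param overlap_target target overlap fraction of the two probes
#' @param overlap_range admissible `[low, high]` overlap fractions
#' @param gc_range admissible `[low, high]` per-probe GC fraction
#' @param max_homology maximum homologous-region count per probe
#' @param k seed k-mer length for homology search
#' @param min_seed_hits k-mer hits required to call a homologous window
#' @param eval_window_bp locus evaluation window (bp), centred on the SNP
#' @param min_snp_edge_bp minimum distance (bp) of the SNP from either
#'   probe end
#' @return an object of class `probe_params`
#' @export
probe_params <- function(probe_length = 110L, overlap_target = 0.65,
                         overlap_range = c(0.60, 0.70),
                         gc_range = c(0.30, 0.70), max_homology = 5L,
                         k = 15L, min_seed_hits = 5L,
                         eval_window_bp = 120L, min_snp_edge_bp = 10L) {
  stopifnot(probe_length > 0, k >= 11, k <= probe_length,
            overlap_target > 0, overlap_target < 1, min_seed_hits >= 1)
  structure(list(probe_length = as.integer(probe_length),
                 overlap_target = overlap_target,
                 overlap_range = overlap_range, gc_range = gc_range,
                 max_homology = as.integer(max_homology),
                 k = as.integer(k),
                 min_seed_hits = as.integer(min_seed_hits),
                 eval_window_bp = as.integer(eval_window_bp),
                 min_snp_edge_bp = as.integer(min_snp_edge_bp)),
            class = "probe_params")
}

#' GC fraction of a nucleotide string
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both
#' numerator and denominator. All-`N` input yields `NA`.
#'
#' @param seq non-empty character string over ACGTN (case-insensitive)
#' @return GC fraction in [0, 1], or `NA` for all-N input
#' @export
gc_content <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("seq must be one non-empty string")
  }
  b <- strsplit(toupper(seq), "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T", "N"))) {
    stop("seq must contain only A, C, G, T or N")
  }
  acgt <- sum(b != "N")
  if (acgt == 0L) return(NA_real_)
  sum(b %in% c("G", "C")) / acgt
}

#' Extract the overlapping probe pair covering a SNP
#'
#' Probe B starts `shift = round(probe_length * (1 - overlap_target))`
#' bp after probe A, so the pair shares `probe_length - shift` bases;
#' the shared window is centred on the SNP. Near sequence ends the pair
#' slides (keeping the shift) as far as needed to fit; when no placement
#' keeps the SNP inside both probes at least `min_snp_edge_bp` from the
#' probe ends, the pair fails with reason `"edge"`.
#'
#' @param ref reference [Biostrings::DNAStringSet]
#' @param seq_id sequence id of the locus
#' @param pos 1-based SNP position
#' @param params a [probe_params()]
#' @return list: `seq_id`, `pos`, `start_a`, `start_b` (1-based probe
#'   starts), `probe_a`, `probe_b` (sequences), `overlap` (shared
#'   fraction), `ok` (placement succeeded), `reason` (`NA` or `"edge"`)
#' @export
extract_probe_pair <- function(ref, seq_id, pos, params = probe_params()) {
  pl <- params$probe_length
  shift <- as.integer(round(pl * (1 - params$overlap_target)))
  ov_len <- pl - shift
  pos <- as.integer(pos)
  L <- Biostrings::width(ref)[match(seq_id, names(ref))]
  if (is.na(L)) stop("unknown sequence: ", seq_id)
  edge <- params$min_snp_edge_bp
  # probe A covers [sa, sa+pl-1], probe B [sa+shift, sa+shift+pl-1];
  # SNP must sit in both, >= edge bp from every probe end
  lo <- max(1L, pos - pl + 1L + edge)          # SNP far enough from A end
  hi <- min(L - pl - shift + 1L, pos - shift - edge)  # ... and from B start
  target <- pos - (ov_len - 1L) %/% 2L - shift  # centre SNP in the overlap
  sa <- min(max(target, lo), hi)
  if (lo > hi || sa < 1L) {
    return(list(seq_id = seq_id, pos = pos, start_a = NA_integer_,
                start_b = NA_integer_, probe_a = NA_character_,
                probe_b = NA_character_, overlap = NA_real_, ok = FALSE,
                reason = "edge"))
  }
  sb <- sa + shift
  sq <- ref[[match(seq_id, names(ref))]]
  list(seq_id = seq_id, pos = pos, start_a = sa, start_b = sb,
       probe_a = as.character(Biostrings::subseq(sq, sa, sa + pl - 1L)),
       probe_b = as.character(Biostrings::subseq(sq, sb, sb + pl - 1L)),
       overlap = ov_len / pl, ok = TRUE, reason = NA_character_)
}

#' Build a k-mer homology index over a reference
#'
#' Stores the reference and seed parameters; queries match a probe's
#' k-mers against both strands (via [Biostrings::matchPDict()]) and
#' merge hit positions within one probe length into candidate
#' homologous windows.
#'
#' @param ref reference [Biostrings::DNAStringSet]
#' @param params a [probe_params()]
#' @return an object of class `homology_index`
#' @export
homology_index <- function(ref, params = probe_params()) {
  structure(list(ref = ref, rc = Biostrings::reverseComplement(ref),
                 params = params),
            class = "homology_index")
}

#' Count homologous regions of a probe
#'
#' Number of distinct genomic windows (hits merged within one probe
#' length, both strands) sharing at least `min_seed_hits` k-mers with
#' the probe. The probe's own source window counts, so a unique probe
#' scores 1.
#'
#' @param probe probe sequence (character)
#' @param index a [homology_index()]
#' @return integer count
#' @export
count_homologous_regions <- function(probe, index) {
  if (nchar(probe) < index$params$k) {
    stop("k-mer length exceeds probe length")
  }
  batch_homology(probe, index$ref, index$params)[1]
}

#' Design and validate probe pairs for a panel
#'
#' Attaches a probe pair to every panel locus and checks the capture
#' constraints: placement feasible (`edge`), per-probe GC inside
#' `gc_range` (`gc`), overlap inside `overlap_range` (`overlap`), and
#' homologous-region count of both probes at most `max_homology`
#' (`homology`). Failures are recorded per locus, not raised.
#'
#' All probes' k-mers are matched against the reference in one batch,
#' so evaluating thousands of loci stays fast.
#'
#' @param panel a [rank_and_select()] panel
#' @param ref reference [Biostrings::DNAStringSet]
#' @param params a [probe_params()]
#' @return the panel with added columns `start_a`, `start_b`, `probe_a`,
#'   `probe_b`, `overlap`, `gc_a`, `gc_b`, `homology_a`, `homology_b`,
#'   `pass`, `fail_reason`
#' @export
evaluate_panel_probes <- function(panel, ref, params = probe_params()) {
  stopifnot(nrow(panel) > 0)
  pairs <- lapply(seq_len(nrow(panel)), function(i) {
    extract_probe_pair(ref, panel$seq_id[i], panel$pos[i], params)
  })
  out <- as.data.frame(panel)
  out$start_a <- vapply(pairs, `[[`, integer(1), "start_a")
  out$start_b <- vapply(pairs, `[[`, integer(1), "start_b")
  out$probe_a <- vapply(pairs, `[[`, character(1), "probe_a")
  out$probe_b <- vapply(pairs, `[[`, character(1), "probe_b")
  out$overlap <- vapply(pairs, `[[`, numeric(1), "overlap")
  ok <- vapply(pairs, `[[`, logical(1), "ok")
  out$gc_a <- out$gc_b <- NA_real_
  out$gc_a[ok] <- vapply(out$probe_a[ok], gc_content, numeric(1))
  out$gc_b[ok] <- vapply(out$probe_b[ok], gc_content, numeric(1))
  out$homology_a <- out$homology_b <- NA_integer_
  if (any(ok)) {
    hom <- batch_homology(c(out$probe_a[ok], out$probe_b[ok]), ref, params)
    out$homology_a[ok] <- hom[seq_len(sum(ok))]
    out$homology_b[ok] <- hom[sum(ok) + seq_len(sum(ok))]
  }
  reason <- rep(NA_character_, nrow(out))
  reason[!ok] <- "edge"
  bad_gc <- ok & (out$gc_a < params$gc_range[1] |
                    out$gc_a > params$gc_range[2] |
                    out$gc_b < params$gc_range[1] |
                    out$gc_b > params$gc_range[2])
  reason[bad_gc & is.na(reason)] <- "gc"
  bad_ov <- ok & (out$overlap < params$overlap_range[1] |
                    out$overlap > params$overlap_range[2])
  reason[bad_ov & is.na(reason)] <- "overlap"
  bad_hom <- ok & (out$homology_a > params$max_homology |
                     out$homology_b > params$max_homology)
  reason[bad_hom & is.na(reason)] <- "homology"
  out$pass <- is.na(reason)
  out$fail_reason <- reason
  structure(out, params = attr(panel, "params"), probe_params = params,
            class = c("snp_panel", "data.frame"))
}

# Homology counts for many probes at once: one PDict over the union of
# their k-mers, matched against every sequence and strand, then fully
# vectorized clustering of the (probe, genomic position) hit pairs.
# Positions are encoded as seq_index * 1e7 + pos so hits on different
# sequences can never merge (gap >> probe length).
batch_homology <- function(probes, ref, params) {
  if (!length(probes)) return(integer(0))
  k <- params$k
  probe_kmers <- lapply(probes, function(sq) {
    st <- seq_len(nchar(sq) - k + 1L)
    unique(substring(sq, st, st + k - 1L))
  })
  all_kmers <- unique(unlist(probe_kmers, use.names = FALSE))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_kmers))
  rc <- Biostrings::reverseComplement(ref)
  hit_kmer <- integer(0)
  hit_code <- numeric(0)
  for (s in seq_along(ref)) {
    L <- Biostrings::width(ref)[s]
    for (strand in 1:2) {
      si <- Biostrings::startIndex(Biostrings::matchPDict(
        pd, if (strand == 1) ref[[s]] else rc[[s]]))
      cnt <- lengths(si)
      pos <- unlist(si, use.names = FALSE)
      if (is.null(pos)) next
      if (strand == 2) pos <- L - (pos + k - 1L) + 1L
      hit_kmer <- c(hit_kmer, rep.int(seq_along(si), cnt))
      hit_code <- c(hit_code, s * 1e7 + pos)
    }
  }
  ord <- order(hit_kmer, hit_code)
  hit_kmer <- hit_kmer[ord]
  hit_code <- hit_code[ord]
  n_hits <- tabulate(hit_kmer, nbins = length(all_kmers))
  offset <- cumsum(c(0L, n_hits))[seq_along(all_kmers)]
  # expand every (probe, k-mer) membership to that k-mer's hits
  pair_kmer <- match(unlist(probe_kmers, use.names = FALSE), all_kmers)
  pair_probe <- rep.int(seq_along(probes), lengths(probe_kmers))
  reps <- n_hits[pair_kmer]
  pp <- rep.int(pair_probe, reps)
  codes <- hit_code[sequence(reps) + rep.int(offset[pair_kmer], reps)]
  o2 <- order(pp, codes)
  pp <- pp[o2]
  codes <- codes[o2]
  m <- length(pp)
  if (!m) return(integer(length(probes)))
  new_cluster <- c(TRUE, pp[-1] != pp[-m] |
                     codes[-1] - codes[-m] > params$probe_length)
  cl <- cumsum(new_cluster)
  big <- tabulate(cl) >= params$min_seed_hits
  tabulate(pp[new_cluster][big], nbins = length(probes))
}

#' Build a probe-validated panel with replacement
#'
#' Runs [rank_and_select()], designs probes, and replaces probe-failing
#' loci with the next-ranked candidates (respecting spacing against the
#' current panel) until the target size is reached with all probes
#' passing, or candidates are exhausted.
#'
#' @param x candidate [geno_matrix()] (already screened by
#'   [filter_candidates()])
#' @param ref reference [Biostrings::DNAStringSet]
#' @param params a [filter_params()]
#' @param pparams a [probe_params()]
#' @return a probe-annotated `snp_panel` of passing loci (see
#'   [evaluate_panel_probes()]); attribute `n_rejected` counts loci
#'   discarded for probe failures
#' @export
design_probe_panel <- function(x, ref, params = filter_params(),
                               pparams = probe_params()) {
  stats <- locus_screen_stats(x)
  ord <- rank_order(stats)
  keep <- spacing_keep(stats, params$min_spacing_bp, ord)
  queue <- ord[keep[ord]]
  accepted <- NULL
  rejected <- 0L
  while (length(queue) && (is.null(accepted) ||
                           nrow(accepted) < params$target_size)) {
    need <- params$target_size - if (is.null(accepted)) 0L else
      nrow(accepted)
    batch <- queue[seq_len(min(need, length(queue)))]
    queue <- queue[-seq_len(min(need, length(queue)))]
    cand <- data.frame(rank = NA_integer_,
                       seq_id = x$loci$seq_id[batch],
                       pos = x$loci$pos[batch], ref = x$loci$ref[batch],
                       alt = x$loci$alt[batch],
                       qual = x$loci$qual[batch], maf = stats$maf[batch],
                       missing = stats$missing[batch],
                       het = stats$ho[batch], stringsAsFactors = FALSE)
    cand <- structure(cand, params = params,
                      class = c("snp_panel", "data.frame"))
    ev <- evaluate_panel_probes(cand, ref, pparams)
    rejected <- rejected + sum(!ev$pass)
    accepted <- if (is.null(accepted)) ev[ev$pass, , drop = FALSE] else
      rbind(accepted, ev[ev$pass, , drop = FALSE])
  }
  if (!is.null(accepted) && nrow(accepted)) accepted$rank <-
    seq_len(nrow(accepted))
  structure(accepted, params = params, probe_params = pparams,
            n_rejected = rejected, class = c("snp_panel", "data.frame"))
}

#' Write probe FASTA and TSV
#'
#' `<prefix>.probes.fasta` holds two records per passing locus, ids
#' `<seq>_<pos>_A` and `<seq>_<pos>_B`; `<prefix>.probes.tsv` reports
#' 1-based probe coordinates, GC, overlap, homology counts and pass
#' status for every locus.
#'
#' @param panel a probe-annotated `snp_panel`
#' @param prefix output path prefix
#' @return (invisibly) the paths written
#' @export
write_probes <- function(panel, prefix) {
  paths <- paste0(prefix, c(".probes.fasta", ".probes.tsv"))
  ok <- which(panel$pass)
  ids <- c(rbind(paste0(panel$seq_id[ok], "_", panel$pos[ok], "_A"),
                 paste0(panel$seq_id[ok], "_", panel$pos[ok], "_B")))
  seqs <- c(rbind(panel$probe_a[ok], panel$probe_b[ok]))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)), paths[1])
  tab <- as.data.frame(panel)[, c("seq_id", "pos", "start_a", "start_b",
                                  "overlap", "gc_a", "gc_b",
                                  "homology_a", "homology_b", "pass",
                                  "fail_reason")]
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.6g", v))
  utils::write.table(tab, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
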