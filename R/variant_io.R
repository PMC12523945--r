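#' Read a multi-sample VCF into a geno_matrix
#'
#' Parses a VCF v4.x (via vcfR), encoding each sample's genotype as the
#' dosage of the first ALT allele (0/1/2) with `./.` treated as missing.
#' Multi-allelic records are retained but flagged (`is_biallelic` FALSE)
#' so the screening cascade can drop them. Per-sample `DP` is kept when
#' the FORMAT carries it. Phase separators (`|`) are accepted and phase
#' is ignored: none of the downstream statistics use it.
#'
#' @param path VCF file
#' @param groups_path optional two-column TSV (`sample`, `group`); must
#'   cover exactly the VCF's samples, otherwise an error is raised
#' @param unsorted how to treat records out of (CHROM, POS) order:
#'   `"sort"` canonically, or `"fail"`
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path, groups_path = NULL,
                     unsorted = c("sort", "fail")) {
  unsorted <- match.arg(unsorted)
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_rec <- nrow(fix)
  if (is.null(n_rec)) n_rec <- 0L
  has_gt <- ncol(vcf@gt) > 1L
  samples <- if (has_gt) colnames(vcf@gt)[-1L] else character(0)

  if (n_rec == 0L) {
    gm <- geno_matrix(matrix(integer(0), length(samples), 0),
                      data.frame(seq_id = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0),
                                 qual = numeric(0)),
                      samples = samples)
  } else {
    pos <- as.integer(fix[, "POS"])
    if (unsorted == "fail" &&
        is.unsorted(order(fix[, "CHROM"], pos), strictly = FALSE) &&
        any(order(fix[, "CHROM"], pos) != seq_len(n_rec))) {
      stop("VCF records are not sorted by (CHROM, POS)")
    }
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    geno <- matrix(gt_to_dosage(gt), nrow = n_rec)
    depth <- NULL
    fmt <- strsplit(vcf@gt[1, 1], ":")[[1]]
    if ("DP" %in% fmt) {
      dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
      depth <- t(matrix(as.integer(dp), nrow = n_rec))
    }
    loci <- data.frame(seq_id = fix[, "CHROM"], pos = pos,
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       qual = qual, stringsAsFactors = FALSE)
    gm <- geno_matrix(t(geno), loci, samples = samples, depth = depth)
  }
  if (!is.null(groups_path)) {
    groups <- read_groups(groups_path)
    extra <- setdiff(names(groups), gm$samples)
    if (length(extra)) {
      stop("group mapping names unknown samples: ",
           paste(extra, collapse = ", "))
    }
    missing <- setdiff(gm$samples, names(groups))
    if (length(missing)) {
      stop("samples without group label: ", paste(missing, collapse = ", "))
    }
    gm$groups <- groups[gm$samples]
  }
  gm
}

# GT strings -> dosage of the first ALT allele; any "." allele => NA.
gt_to_dosage <- function(gt) {
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  out <- unname(known[gt])
  todo <- which(is.na(out) & !is.na(gt) & gt != "./." & gt != ".|." &
                  gt != ".")
  if (length(todo)) {
    parts <- strsplit(gt[todo], "[/|]")
    out[todo] <- vapply(parts, function(a) {
      if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, integer(1))
  }
  out
}

#' Write a geno_matrix as VCF v4.2
#'
#' Emits a deterministic, plain-text VCF with GT:DP per sample (GT only
#' when no depth matrix is present), QUAL to two decimals, and loci in
#' canonical (seq_id, pos) order. A 0-locus matrix yields a header-only
#' file.
#'
#' @param x a [geno_matrix()]
#' @param path output file
#' @return (invisibly) the path
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  has_dp <- !is.null(x$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snpanel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp)
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  lines <- header
  if (n_loci(x) > 0) {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", n_samples(x), n_loci(x))
    ok <- !is.na(x$geno)
    gt[ok] <- gt_code[x$geno[ok] + 1L]
    if (has_dp) {
      dp <- ifelse(is.na(x$depth), ".", as.character(x$depth))
      gt <- matrix(paste0(gt, ":", dp), nrow(gt), ncol(gt))
    }
    per_sample <- lapply(seq_len(n_samples(x)), function(i) gt[i, ])
    body <- do.call(paste, c(
      list(x$loci$seq_id, x$loci$pos, ".", x$loci$ref, x$loci$alt,
           ifelse(is.na(x$loci$qual), ".", sprintf("%.2f", x$loci$qual)),
           ".", ".", if (has_dp) "GT:DP" else "GT"),
      per_sample, sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a sample-to-group mapping TSV
#'
#' Two tab-separated columns with header `sample` and `group`.
#'
#' @param path TSV file
#' @return named character vector (names = samples)
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample", "group") %in% names(tab))) {
    stop("groups file needs columns 'sample' and 'group'")
  }
  if (anyDuplicated(tab$sample)) stop("duplicated sample in groups file")
  stats::setNames(tab$group, tab$sample)
}

#' @rdname read_groups
#' @param groups named character vector mapping samples to groups
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]
#' @export
read_reference <- function(path) Biostrings::readDNAStringSet(path)
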