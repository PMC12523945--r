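#' Pairwise linkage disequilibrium r-squared
#'
#' Composite (genotype-dosage) LD: for each pair of loci on the same
#' sequence within `max_dist_bp`, the squared Pearson correlation of the
#' two dosage vectors over the samples called at both loci. Pairs with
#' fewer than `min_obs` complete observations, a member monomorphic in
#' the shared samples, or a member below `min_maf` are skipped (and
#' counted).
#'
#' @param x a [geno_matrix()]
#' @param max_dist_bp maximum inter-locus distance (bp)
#' @param min_maf minimum per-locus MAF for a locus to enter any pair
#' @param min_obs minimum number of complete observations per pair
#' @param samples optional subset of samples (e.g. one group)
#' @return data.frame `seq_id`, `pos1`, `pos2`, `dist`, `r2`, `n`;
#'   attribute `n_skipped` counts the skipped pairs
#' @export
pairwise_r2 <- function(x, max_dist_bp = 300000, min_maf = 0,
                        min_obs = 4L, samples = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- if (is.null(samples)) x$geno else {
    if (is.character(samples)) samples <- match(samples, x$samples)
    x$geno[samples, , drop = FALSE]
  }
  if (min_maf > 0) {
    st <- colMeans(g, na.rm = TRUE) / 2
    ok <- !is.na(st) & pmin(st, 1 - st) >= min_maf
    g <- g[, ok, drop = FALSE]
    loci <- x$loci[ok, , drop = FALSE]
  } else loci <- x$loci
  out <- list()
  n_skipped <- 0L
  for (sid in unique(loci$seq_id)) {
    li <- which(loci$seq_id == sid)
    if (length(li) < 2) next
    sub <- g[, li, drop = FALSE]
    pos <- loci$pos[li]
    cc <- suppressWarnings(stats::cor(sub,
                                      use = "pairwise.complete.obs"))
    nn <- crossprod(!is.na(sub))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    inrange <- d <= max_dist_bp
    valid <- inrange & nn[pr] >= min_obs & !is.na(cc[pr])
    n_skipped <- n_skipped + sum(inrange & !valid)
    pr <- pr[valid, , drop = FALSE]
    if (!nrow(pr)) next
    out[[sid]] <- data.frame(seq_id = sid, pos1 = pos[pr[, 1]],
                             pos2 = pos[pr[, 2]],
                             dist = pos[pr[, 2]] - pos[pr[, 1]],
                             r2 = cc[pr]^2, n = nn[pr],
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), pos1 = integer(0),
               pos2 = integer(0), dist = integer(0), r2 = numeric(0),
               n = integer(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Distance-binned LD decay curve
#'
#' Mean r-squared per distance bin, plus a half-decay distance: the
#' midpoint of the first bin at which the 3-bin moving-average-smoothed
#' curve falls to half its maximum (`NA` when it never does). Empty
#' bins carry no value.
#'
#' @param pairs data.frame from [pairwise_r2()]
#' @param bin_width_bp bin width in bp
#' @param group optional label stored on the curve
#' @return an object of class `ld_decay_curve`: data.frame `bin_mid`
#'   (bp), `mean_r2`, `n_pairs`, with attributes `half_decay_bp`,
#'   `group`, `bin_width_bp`
#' @export
decay_curve <- function(pairs, bin_width_bp = 1000, group = NA_character_) {
  if (bin_width_bp <= 0) stop("bin width must be positive")
  if (!nrow(pairs)) stop("empty pair list")
  bin <- floor(pairs$dist / bin_width_bp)
  mean_r2 <- tapply(pairs$r2, bin, mean)
  n_pairs <- tapply(pairs$r2, bin, length)
  b <- as.integer(names(mean_r2))
  curve <- data.frame(bin_mid = (b + 0.5) * bin_width_bp,
                      mean_r2 = as.numeric(mean_r2),
                      n_pairs = as.integer(n_pairs))
  curve <- curve[order(curve$bin_mid), ]
  rownames(curve) <- NULL
  sm <- smooth_ma3(curve$mean_r2)
  half <- which(sm <= max(sm) / 2)
  half_bp <- if (length(half)) curve$bin_mid[min(half)] else NA_real_
  structure(curve, half_decay_bp = half_bp, group = group,
            bin_width_bp = bin_width_bp,
            class = c("ld_decay_curve", "data.frame"))
}

# 3-point moving average with shortened windows at the ends.
smooth_ma3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
}

#' Per-group LD decay curves
#'
#' @param x a [geno_matrix()] with groups
#' @param max_dist_bp,min_maf,min_obs passed to [pairwise_r2()]
#' @param bin_width_bp passed to [decay_curve()]
#' @return named list of `ld_decay_curve`, one per group
#' @export
ld_decay_by_group <- function(x, max_dist_bp = 300000, bin_width_bp = 1000,
                              min_maf = 0, min_obs = 4L) {
  if (is.null(x$groups)) stop("geno_matrix has no group labels")
  groups <- sort(unique(x$groups))
  stats::setNames(lapply(groups, function(gname) {
    ids <- x$samples[x$groups == gname]
    pr <- pairwise_r2(x, max_dist_bp, min_maf, min_obs, samples = ids)
    decay_curve(pr, bin_width_bp, group = gname)
  }), groups)
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  cat(sprintf("ld_decay_curve%s: %d bins (%g bp), half-decay %s bp\n",
              if (is.na(attr(x, "group"))) "" else
                paste0(" [", attr(x, "group"), "]"),
              nrow(x), attr(x, "bin_width_bp"),
              format(attr(x, "half_decay_bp"))))
  invisible(x)
}

#' @export
plot.ld_decay_curve <- function(x, ...) {
  plot(x$bin_mid, x$mean_r2, type = "b", pch = 16,
       xlab = "distance (bp)", ylab = expression(mean ~ r^2), ...)
  hd <- attr(x, "half_decay_bp")
  if (!is.na(hd)) graphics::abline(v = hd, lty = 2)
  invisible(x)
}

#' Inject block-copy LD into a simulated matrix
#'
#' Testing device for the LD module: within consecutive blocks of
#' `block_size` loci, every locus's dosages are replaced by a copy of
#' the block's first locus with per-call flip probability that grows
#' with the locus's distance from the block head
#' (`eps_per_bp * distance`, capped at 0.5). Produces tunable,
#' distance-decaying LD without a recombination model.
#'
#' @param x a [geno_matrix()]
#' @param block_size loci per block
#' @param eps_per_bp per-bp flip probability
#' @param seed integer seed
#' @return a [geno_matrix()] with correlated dosage columns
#' @export
inject_block_ld <- function(x, block_size = 10L, eps_per_bp = 2e-4,
                            seed = 1L) {
  set.seed(seed)
  g <- x$geno
  blocks <- split(seq_len(n_loci(x)),
                  (seq_len(n_loci(x)) - 1L) %/% block_size)
  for (b in blocks) {
    head_pos <- x$loci$pos[b[1]]
    same <- x$loci$seq_id[b] == x$loci$seq_id[b[1]]
    for (j in b[-1][same[-1]]) {
      eps <- min(0.5, eps_per_bp * (x$loci$pos[j] - head_pos))
      col <- g[, b[1]]
      flip <- stats::runif(length(col)) < eps
      resample <- stats::rbinom(sum(flip), 2L,
                                mean(col, na.rm = TRUE) / 2)
      col[flip] <- as.integer(resample)
      g[, j] <- col
    }
  }
  geno_matrix(g, x$loci, samples = x$samples, depth = x$depth,
              groups = x$groups)
}
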