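#' Run the full panel-design and evaluation pipeline
#'
#' Simulates (or loads) a cohort, runs the marker screening cascade,
#' selects a probe-validated panel, and computes the downstream battery
#' on the panel loci: per-group diversity, LD decay per group, GRM +
#' PCA, admixture with CV choice of K, and the NJ tree with bootstrap
#' supports. All outputs are plain-text files under `out_dir`; the run
#' is fully determined by the spec's seed.
#'
#' @param spec a [population_spec()] describing the cohort to simulate
#' @param out_dir output directory (created if needed)
#' @param params a [filter_params()]
#' @param pparams a [probe_params()]
#' @param ld_bin_bp LD decay bin width (bp)
#' @param k_min,k_max,cv_folds admixture CV settings
#' @param boot_reps tree bootstrap replicates
#' @param n_pc principal components to keep
#' @return (invisibly) list with every intermediate result
#' @export
run_pipeline <- function(spec, out_dir, params = filter_params(),
                         pparams = probe_params(), ld_bin_bp = 1000,
                         k_min = 1L, k_max = 4L, cv_folds = 3L,
                         boot_reps = 100L, n_pc = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  sim <- simulate_cohort(spec, path("cohort"))
  gm <- sim$matrix

  filt <- filter_candidates(gm, params)
  utils::write.table(filt$report$rules, path("filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- design_probe_panel(filt$matrix, sim$ref, params, pparams)
  write_panel(panel, path("cohort"), x = gm)
  write_probes(panel, path("cohort"))

  keep <- locus_ids(gm$loci) %in% paste(panel$seq_id, panel$pos,
                                        sep = ":")
  pm <- subset_geno(gm, loci_idx = keep)

  div <- group_diversity(pm)
  write_num_tsv(div, path("diversity.tsv"))
  write_num_tsv(locus_diversity(pm), path("locus_stats.tsv"))

  curves <- ld_decay_by_group(pm, bin_width_bp = ld_bin_bp)
  ld_tab <- do.call(rbind, lapply(names(curves), function(gname) {
    cbind(group = gname, as.data.frame(curves[[gname]]))
  }))
  write_num_tsv(ld_tab, path("ld_curves.tsv"))

  G <- grm(pm)
  pca <- grm_pca(G, n_pc = n_pc)
  write_num_tsv(data.frame(sample = rownames(pca$scores), pca$scores,
                           check.names = FALSE),
                path("pca_scores.tsv"))
  write_num_tsv(data.frame(component = seq_along(pca$var_explained),
                           var_explained = pca$var_explained),
                path("pca_varexp.tsv"))

  cv <- cv_choose_k(pm, k_min = k_min, k_max = k_max, folds = cv_folds,
                    seed = spec$seed)
  write_num_tsv(as.data.frame(cv), path("admixture_cv.tsv"))
  fit <- admixture_em(pm, attr(cv, "best_k"), seed = spec$seed)
  write_num_tsv(data.frame(sample = rownames(fit$Q), fit$Q,
                           check.names = FALSE),
                path("admixture_Q.tsv"))

  D <- p_distance(pm)
  write_dist_tsv(D, path("p_distance.tsv"))
  tree <- bootstrap_support(pm, reps = boot_reps, seed = spec$seed)
  write_newick(tree, path("tree.nwk"))

  invisible(list(sim = sim, filter = filt, panel = panel,
                 panel_matrix = pm, diversity = div, ld = curves,
                 grm = G, pca = pca, cv = cv, admixture = fit,
                 dist = D, tree = tree))
}

# TSV writer with stable numeric formatting (doubles to 8 significant
# digits) so identical runs are byte-identical.
write_num_tsv <- function(tab, path) {
  tab <- as.data.frame(tab)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.8g", v))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
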