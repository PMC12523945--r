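#' Genomic relationship matrix
#'
#' VanRaden-style standardized relationship matrix: with `p` the pooled
#' alt-allele frequency of each locus, entry `(i, j)` is the mean over
#' loci called in both samples of
#' `(g_i - 2p)(g_j - 2p) / (2 p (1 - p))`. Monomorphic loci are
#' excluded; missing calls are handled pairwise.
#'
#' @param x a [geno_matrix()] with at least 2 samples
#' @return symmetric n x n matrix with sample dimnames
#' @export
grm <- function(x) {
  stopifnot(inherits(x, "geno_matrix"), n_samples(x) >= 2)
  g <- x$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci for the GRM")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  called <- !is.na(g)
  z[!called] <- 0
  num <- tcrossprod(z)
  den <- tcrossprod(called)
  if (any(den == 0)) stop("sample pair with no shared called loci")
  G <- num / den
  dimnames(G) <- list(x$samples, x$samples)
  G
}

#' PCA of a relationship matrix
#'
#' Eigendecomposition of a symmetric kinship/GRM matrix. Scores are
#' eigenvectors scaled by the square root of their eigenvalue;
#' variance explained is each eigenvalue over the sum of positive
#' eigenvalues. Component signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param G symmetric matrix (e.g. from [grm()])
#' @param n_pc number of components to keep
#' @return an object of class `pca_result`: `scores` (samples x
#'   components), `var_explained`, `values` (all eigenvalues)
#' @export
grm_pca <- function(G, n_pc = 10L) {
  if (!isSymmetric(unname(G), tol = 1e-8)) {
    stop("input matrix is not symmetric")
  }
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos_sum <- sum(e$values[e$values > 0])
  m <- max(1L, min(n_pc, ncol(G)))
  vecs <- e$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- vecs %*% diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(m)))
  structure(list(scores = scores,
                 var_explained = pmax(e$values[seq_len(m)], 0) / pos_sum,
                 values = e$values),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("pca_result: %d components; variance explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(ve, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.pca_result <- function(x, pcs = c(1, 2), groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.factor(groups[rownames(x$scores)])
  plot(x$scores[, pcs[1]], x$scores[, pcs[2]], col = col, pch = 16,
       xlab = sprintf("PC%d (%.1f%%)", pcs[1],
                      100 * x$var_explained[pcs[1]]),
       ylab = sprintf("PC%d (%.1f%%)", pcs[2],
                      100 * x$var_explained[pcs[2]]), ...)
  invisible(x)
}

#' Fit the admixture model by EM
#'
#' Binomial admixture model: sample `i` carries ancestry proportions
#' `q_i` over `K` clusters with cluster allele frequencies `f_kj`; each
#' genotype is Binomial(2, sum_k q_ik f_kj). The complete-data EM
#' update is closed-form; the log-likelihood is monotone non-decreasing
#' and is asserted at every iteration. Multiple seeded restarts guard
#' against local optima; the best-likelihood fit is returned.
#'
#' @param x a [geno_matrix()]
#' @param K number of ancestral clusters (>= 1, <= n_samples)
#' @param seed integer seed for the random starts
#' @param max_iter maximum EM iterations per start
#' @param tol stop when the log-likelihood gain drops below `tol`
#' @param n_starts number of seeded restarts
#' @return an object of class `admixture_fit`: `K`, `Q` (samples x K,
#'   rows sum to 1), `F` (K x loci, clamped to [1e-6, 1 - 1e-6]),
#'   `log_likelihood`, `loglik_trace`, `n_iterations`, `converged`
#' @export
admixture_em <- function(x, K, seed = 1L, max_iter = 300L, tol = 1e-4,
                         n_starts = 5L) {
  stopifnot(inherits(x, "geno_matrix"), K >= 1)
  if (K > n_samples(x)) stop("K exceeds the number of samples")
  g <- x$geno
  called <- !is.na(g)
  G0 <- ifelse(called, g, 0)            # alt-allele counts
  G2 <- ifelse(called, 2 - g, 0)        # ref-allele counts
  denom_i <- 2 * rowSums(called)
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    fit <- admixture_em_once(G0, G2, denom_i, K, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
      best <- fit
    }
  }
  dimnames(best$Q) <- list(x$samples, paste0("anc", seq_len(K)))
  dimnames(best$F) <- list(paste0("anc", seq_len(K)),
                           locus_ids(x$loci))
  best$K <- K
  structure(best, class = "admixture_fit")
}

admixture_em_once <- function(G0, G2, denom_i, K, max_iter, tol) {
  n <- nrow(G0); L <- ncol(G0)
  gm <- rgamma(n * K, 1)
  Q <- matrix(gm, n, K)
  Q <- Q / rowSums(Q)
  F <- matrix(runif(K * L, 0.05, 0.95), K, L)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- Q %*% F
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    ll <- sum(G0 * log(P) + G2 * log1p(-P))
    if (ll < ll_prev - 1e-6 * max(1, abs(ll))) {
      stop(sprintf("EM log-likelihood decreased at iteration %d", it))
    }
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_prev < tol) { converged <- TRUE; break }
    ll_prev <- ll
    Ra <- G0 / P
    Rb <- G2 / (1 - P)
    A <- Q * crossprod(t(Ra), t(F))          # n x K: q_ik (Ra F^T)_ik
    B <- Q * crossprod(t(Rb), t(1 - F))
    Fnum <- F * t(crossprod(Ra, Q))          # K x L
    Fden <- (1 - F) * t(crossprod(Rb, Q))
    Q <- (A + B) / denom_i
    # exact in real arithmetic; renormalize so float drift cannot
    # accumulate across iterations when F saturates at the clamp bounds
    Q <- Q / rowSums(Q)
    F <- Fnum / (Fnum + Fden)
    F[is.nan(F)] <- 0.5          # locus with no called genotype
    F <- pmin(pmax(F, 1e-6), 1 - 1e-6)
  }
  list(Q = Q, F = F, log_likelihood = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, n_iterations = length(ll_trace),
       converged = converged)
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "admixture_fit: K = %d, %d samples, logLik %.2f, %d iterations%s\n",
    x$K, nrow(x$Q), x$log_likelihood, x$n_iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Align ancestry columns to a reference
#'
#' Resolves label switching: greedily matches columns of `Q` to columns
#' of `Q_ref` by correlation and returns `Q` with columns permuted
#' accordingly.
#'
#' @param Q fitted ancestry matrix (samples x K)
#' @param Q_ref reference ancestry matrix (samples x K)
#' @return `Q` with permuted columns
#' @export
align_ancestries <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q) == nrow(Q_ref))
  cc <- suppressWarnings(stats::cor(Q_ref, Q))
  cc[is.na(cc)] <- 0
  perm <- integer(K)
  for (step in seq_len(K)) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    cc[best[1], ] <- -Inf
    cc[, best[2]] <- -Inf
  }
  Q[, perm, drop = FALSE]
}

#' Choose K by masked-genotype cross-validation
#'
#' Non-missing genotype entries are partitioned into `folds` folds;
#' each fold is masked in turn, the admixture model refit, and the
#' masked dosages predicted as `2 * sum_k q_ik f_kj`. The CV error per
#' K is the root-mean-squared prediction error over masked entries,
#' averaged over folds (`error = "deviance"` uses the mean binomial
#' deviance instead). The best K is the argmin, smallest K on ties.
#'
#' @param x a [geno_matrix()]
#' @param k_min,k_max K range to test
#' @param folds number of folds (>= 2)
#' @param seed integer seed (fold assignment and EM starts)
#' @param max_iter,tol,n_starts passed to [admixture_em()]
#' @param error `"rmse"` or `"deviance"`
#' @return an object of class `cv_report`: data.frame `K`, `cv_error`,
#'   attributes `best_k` and `folds`
#' @export
cv_choose_k <- function(x, k_min = 1L, k_max = 15L, folds = 5L,
                        seed = 1L, max_iter = 200L, tol = 1e-3,
                        n_starts = 1L, error = c("rmse", "deviance")) {
  error <- match.arg(error)
  if (folds < 2) stop("folds must be >= 2")
  g <- x$geno
  obs <- which(!is.na(g))
  if (length(obs) < folds) stop("not enough non-missing entries")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs)))
  ks <- seq.int(k_min, k_max)
  errs <- vapply(ks, function(K) {
    fe <- vapply(seq_len(folds), function(fd) {
      masked <- obs[fold_of == fd]
      xm <- x
      xm$geno[masked] <- NA_integer_
      fit <- admixture_em(xm, K, seed = seed + 1000L * K + fd,
                          max_iter = max_iter, tol = tol,
                          n_starts = n_starts)
      P <- pmin(pmax(fit$Q %*% fit$F, 1e-9), 1 - 1e-9)
      if (error == "rmse") {
        sqrt(mean((g[masked] - 2 * P[masked])^2))
      } else {
        -mean(g[masked] * log(P[masked]) +
                (2 - g[masked]) * log1p(-P[masked]))
      }
    }, numeric(1))
    mean(fe)
  }, numeric(1))
  rep <- data.frame(K = ks, cv_error = errs)
  structure(rep, best_k = ks[which.min(errs)], folds = folds,
            class = c("cv_report", "data.frame"))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%d folds): best K = %d\n", attr(x, "folds"),
              attr(x, "best_k")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.cv_report <- function(x, ...) {
  plot(x$K, x$cv_error, type = "b", pch = 16, xlab = "K",
       ylab = "CV error", ...)
  graphics::abline(v = attr(x, "best_k"), lty = 2)
  invisible(x)
}
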