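# Bayesian admixture clustering with inbreeding ------------------------------
#
# A deliberately simplified version of the InStruct model family: each
# individual i has admixture proportions q_i over K clusters and an
# inbreeding coefficient f_i.  At a SNP, with probability f_i the two allele
# copies are a single draw from one cluster of origin (autozygous); otherwise
# the two copies have independent cluster origins drawn from q_i and
# independent allele draws.  Conjugate Gibbs updates are used for allele
# frequencies (Beta), admixture (Dirichlet) and, because autozygosity
# indicators are sampled explicitly, for f_i (Beta) as well.  Model choice
# over K uses DIC with the posterior-mean plug-in deviance.

# greedy label alignment: permutation of rows of p_new best matching p_ref
.align_labels <- function(p_new, p_ref) {
  k <- nrow(p_ref)
  cost <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    cost[a, b] <- sum(abs(p_new[a, ] - p_ref[b, ]))
  perm <- integer(k)
  free_a <- seq_len(k); free_b <- seq_len(k)
  while (length(free_a)) {
    idx <- which(cost[free_a, free_b, drop = FALSE] ==
                   min(cost[free_a, free_b]), arr.ind = TRUE)[1L, ]
    perm[free_a[idx[1L]]] <- free_b[idx[2L]]
    free_a <- free_a[-idx[1L]]; free_b <- free_b[-idx[2L]]
  }
  perm  # new cluster a plays the role of reference cluster perm[a]
}

# log-likelihood of genotypes given (q, p, f); marginal over latents
.cluster_loglik <- function(G, q, p, f) {
  P1 <- q %*% p
  P0 <- 1 - P1
  lik <- matrix(NA_real_, nrow(G), ncol(G))
  i0 <- which(G == 0L); i1 <- which(G == 1L); i2 <- which(G == 2L)
  Fm <- matrix(f, nrow(G), ncol(G))
  lik[i0] <- Fm[i0] * P0[i0] + (1 - Fm[i0]) * P0[i0]^2
  lik[i1] <- (1 - Fm[i1]) * 2 * P1[i1] * P0[i1]
  lik[i2] <- Fm[i2] * P1[i2] + (1 - Fm[i2]) * P1[i2]^2
  sum(log(pmax(lik, 1e-300)), na.rm = TRUE)
}

# one vectorized categorical draw over K clusters; W = list of K NxM weight
# matrices; need = logical NxM mask of cells requiring a draw.
# returns integer matrix (NA where !need)
.draw_origins <- function(W, need) {
  K <- length(W)
  tot <- Reduce(`+`, W)
  z <- matrix(NA_integer_, nrow(tot), ncol(tot))
  if (!any(need)) return(z)
  u <- matrix(stats::runif(length(tot)), nrow(tot)) * tot
  acc <- W[[1L]]
  zz <- matrix(1L, nrow(tot), ncol(tot))
  if (K > 1L) for (k in 2:K) {
    zz <- zz + (u > acc)
    acc <- acc + W[[k]]
  }
  z[need] <- zz[need]
  z
}

#' Fit the admixture-with-inbreeding model by MCMC
#'
#' @param snps A `snp_matrix`.
#' @param k Number of clusters (>= 1; must not exceed the individual count).
#' @param iterations Total MCMC iterations per chain.
#' @param burn_in Iterations discarded before averaging.
#' @param seed Optional RNG seed.
#' @param chains Number of independent chains; with > 1 chain a split-chain
#'   Gelman-Rubin diagnostic on the deviance flags non-convergence
#'   (PSRF > 1.2) and the chain with the lowest mean deviance is reported.
#' @param lambda Beta/Dirichlet prior mass for allele frequencies (default 1).
#' @param alpha Dirichlet prior mass for admixture proportions (fixed at 1;
#'   no hyperprior updating).
#' @return A `cluster_model`: posterior mean `admixture` (N x k, rows sum to
#'   1), `allele_freqs` (k x SNPs), `inbreeding` (per individual),
#'   `log_likelihood_trace`, `dic`, `converged`, `psrf`.
#' @export
fit_clusters <- function(snps, k, iterations = 20000L, burn_in = 2000L,
                         seed = NULL, chains = 1L, lambda = 1, alpha = 1) {
  G <- snps$genotypes
  N <- nrow(G); M <- ncol(G)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > N) stop("k exceeds the number of individuals")
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(chains), function(ch)
    .fit_chain(G, k, iterations, burn_in, lambda, alpha))
  psrf <- NA_real_
  converged <- TRUE
  if (chains > 1L) {
    psrf <- .gelman_rubin(lapply(runs, function(r)
      r$loglik[(burn_in + 1L):iterations]))
    converged <- is.finite(psrf) && psrf <= 1.2
    if (!converged)
      warning(sprintf("chains may not have converged (PSRF = %.3f)", psrf))
  }
  best <- runs[[which.min(vapply(runs, function(r) r$mean_dev, numeric(1)))]]
  structure(list(k = k, admixture = best$q_mean, allele_freqs = best$p_mean,
                 inbreeding = best$f_mean,
                 log_likelihood_trace = best$loglik, dic = best$dic,
                 converged = converged, psrf = psrf,
                 iterations = iterations, burn_in = burn_in),
            class = "cluster_model")
}

.fit_chain <- function(G, K, iterations, burn_in, lambda, alpha) {
  N <- nrow(G); M <- ncol(G)
  obs <- !is.na(G)
  n_obs_i <- rowSums(obs)
  g0 <- !is.na(G) & G == 0L
  g1 <- !is.na(G) & G == 1L
  g2 <- !is.na(G) & G == 2L

  p <- matrix(stats::runif(K * M, 0.2, 0.8), K, M)
  q <- matrix(stats::rgamma(N * K, 1), N, K)
  q <- q / rowSums(q)
  f <- stats::runif(N, 0.2, 0.8)

  loglik <- numeric(iterations)
  q_sum <- matrix(0, N, K); p_sum <- matrix(0, K, M); f_sum <- numeric(N)
  dev_sum <- 0; n_keep <- 0L
  p_ref <- NULL

  for (it in seq_len(iterations)) {
    P1 <- q %*% p
    P0 <- 1 - P1
    Fm <- matrix(f, N, M)

    # autozygosity indicators (possible only for homozygous genotypes)
    A <- matrix(FALSE, N, M)
    pa2 <- Fm / (Fm + (1 - Fm) * P1)   # given g = 2
    pa0 <- Fm / (Fm + (1 - Fm) * P0)   # given g = 0
    U <- matrix(stats::runif(N * M), N, M)
    A[g2] <- U[g2] < pa2[g2]
    A[g0] <- U[g0] < pa0[g0]

    # copy counts per cell: c1 = copies carrying allele 1, c0 = allele 0
    c1 <- g1 * 1L + g2 * (2L - A)
    c0 <- g1 * 1L + g0 * (2L - A)

    if (K == 1L) {
      n1 <- colSums(c1); n0 <- colSums(c0)
      p <- matrix(stats::rbeta(M, lambda + n1, lambda + n0), 1L, M)
      q <- matrix(1, N, 1L)
    } else {
      W1 <- lapply(seq_len(K), function(kk) outer(q[, kk], p[kk, ]))
      W0 <- lapply(seq_len(K), function(kk) outer(q[, kk], 1 - p[kk, ]))
      z1a <- .draw_origins(W1, c1 >= 1L)
      z1b <- .draw_origins(W1, c1 == 2L)
      z0a <- .draw_origins(W0, c0 >= 1L)
      z0b <- .draw_origins(W0, c0 == 2L)
      n1 <- matrix(0, K, M); n0 <- matrix(0, K, M)
      qcnt <- matrix(0, N, K)
      for (kk in seq_len(K)) {
        m1 <- (!is.na(z1a) & z1a == kk) + (!is.na(z1b) & z1b == kk)
        m0 <- (!is.na(z0a) & z0a == kk) + (!is.na(z0b) & z0b == kk)
        n1[kk, ] <- colSums(m1)
        n0[kk, ] <- colSums(m0)
        qcnt[, kk] <- rowSums(m1) + rowSums(m0)
      }
      p <- matrix(stats::rbeta(K * M, lambda + n1, lambda + n0), K, M)
      qg <- matrix(stats::rgamma(N * K, alpha + qcnt), N, K)
      q <- qg / rowSums(qg)
    }
    a_cnt <- rowSums(A)
    f <- stats::rbeta(N, 1 + a_cnt, 1 + n_obs_i - a_cnt)

    ll <- .cluster_loglik(G, q, p, f)
    loglik[it] <- ll

    if (it > burn_in) {
      if (is.null(p_ref)) p_ref <- p
      perm <- if (K > 1L) .align_labels(p, p_ref) else 1L
      q_sum <- q_sum + q[, order(perm), drop = FALSE]
      p_sum <- p_sum + p[order(perm), , drop = FALSE]
      f_sum <- f_sum + f
      dev_sum <- dev_sum - 2 * ll
      n_keep <- n_keep + 1L
    }
  }
  q_mean <- q_sum / n_keep
  p_mean <- p_sum / n_keep
  f_mean <- f_sum / n_keep
  mean_dev <- dev_sum / n_keep
  dev_at_mean <- -2 * .cluster_loglik(G, q_mean, p_mean, f_mean)
  dic <- 2 * mean_dev - dev_at_mean
  rownames(q_mean) <- rownames(G)
  list(q_mean = q_mean, p_mean = p_mean, f_mean = f_mean,
       loglik = loglik, mean_dev = mean_dev, dic = dic)
}

# split-chain potential scale reduction factor on scalar traces
.gelman_rubin <- function(traces) {
  m <- length(traces)
  n <- min(lengths(traces))
  X <- vapply(traces, function(x) x[seq_len(n)], numeric(n))
  means <- colMeans(X)
  W <- mean(apply(X, 2L, stats::var))
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K=%d, DIC=%.1f (%d iterations, %d burn-in)\n",
              x$k, x$dic, x$iterations, x$burn_in))
  if (!is.na(x$psrf)) cat(sprintf("  PSRF=%.3f converged=%s\n",
                                  x$psrf, x$converged))
  invisible(x)
}

#' Choose the number of clusters by DIC
#'
#' Returns both the DIC argmin and a parsimony choice: the smallest K whose
#' DIC lies within 2 units of the minimum.  Reporting both reflects the
#' common situation where the DIC optimum is large while only a couple of
#' clusters carry interpretable structure.
#'
#' @param models List of `cluster_model` fits over a K range; non-converged
#'   models are excluded with a warning.
#' @return List: `k_opt` (argmin DIC), `k_parsimony`, `dic_curve`
#'   (data.frame k, dic).
#' @export
choose_k <- function(models) {
  if (length(models) < 2L) stop("need >= 2 models to choose K")
  conv <- vapply(models, function(m) isTRUE(m$converged), logical(1))
  if (any(!conv)) {
    warning("excluding non-converged model(s) at K = ",
            paste(vapply(models[!conv], `[[`, integer(1), "k"),
                  collapse = ", "))
    models <- models[conv]
  }
  ks <- vapply(models, `[[`, integer(1), "k")
  dics <- vapply(models, `[[`, numeric(1), "dic")
  ord <- order(ks)
  ks <- ks[ord]; dics <- dics[ord]
  k_opt <- ks[which.min(dics)]
  k_par <- min(ks[dics <= min(dics) + 2])
  list(k_opt = k_opt, k_parsimony = k_par,
       dic_curve = data.frame(k = ks, dic = dics))
}

#' Refit using one random SNP per locus
#'
#' Draws a single SNP uniformly from each locus, refits the model at the same
#' K, and scores assignment concordance with the full-SNP model (after greedy
#' cluster matching, the fraction of individuals whose modal cluster agrees).
#'
#' @param snps Full `snp_matrix`.
#' @param full_model A fitted `cluster_model` on all SNPs.
#' @param seed Optional RNG seed.
#' @param ... Passed to [fit_clusters()] (iterations, burn_in, ...).
#' @return List: `model` (the rerun fit), `concordance`, `snp_ids` used.
#' @export
single_snp_per_locus_rerun <- function(snps, full_model, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pick <- vapply(split(seq_len(nrow(snps$snp_info)), snps$snp_info$locus_id),
                 function(ix) if (length(ix) == 1L) ix else
                   ix[sample.int(length(ix), 1L)], integer(1))
  sub <- subset_snps(snps, sort(unname(pick)))
  refit <- fit_clusters(sub, k = full_model$k, ...)
  conc <- .assignment_concordance(full_model$admixture, refit$admixture)
  list(model = refit, concordance = conc, snp_ids = sub$snp_info$snp_id)
}

.assignment_concordance <- function(q_a, q_b) {
  k <- ncol(q_a)
  mod_a <- max.col(q_a); mod_b <- max.col(q_b)
  conf <- as.matrix(table(factor(mod_a, levels = seq_len(k)),
                          factor(mod_b, levels = seq_len(k))))
  # greedy matching of cluster labels by shared individuals
  map <- integer(k)
  free_a <- seq_len(k); free_b <- seq_len(k)
  for (s in seq_len(k)) {
    sub <- conf[free_a, free_b, drop = FALSE]
    ix <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    a <- free_a[ix[1L]]; b <- free_b[ix[2L]]
    map[b] <- a
    free_a <- setdiff(free_a, a); free_b <- setdiff(free_b, b)
  }
  mean(mod_a == map[mod_b])
}

#' Principal coordinates analysis of a genetic distance matrix
#'
#' Gower double-centering and eigendecomposition via [stats::cmdscale()];
#' axes are ordered by eigenvalue with percent variance explained over the
#' positive eigenvalues.
#'
#' @param dist Symmetric zero-diagonal distance matrix (or `dist`).
#' @param k Number of axes to return (default 2).
#' @return List: `coordinates`, `eigenvalues`, `pct_variance`.
#' @export
pcoa <- function(dist, k = 2L) {
  d <- as.matrix(dist)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  if (all(d == 0))
    return(list(coordinates = matrix(0, n, k), eigenvalues = rep(0, n - 1L),
                pct_variance = rep(0, n - 1L)))
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1L), eig = TRUE)
  pos <- pmax(fit$eig, 0)
  list(coordinates = fit$points, eigenvalues = fit$eig,
       pct_variance = 100 * fit$eig / sum(pos))
}

#' Allele-sharing distance between individuals
#'
#' Mean absolute dosage difference over SNPs, scaled to `[0,1]`.
#'
#' @param snps A `snp_matrix`.
#' @return A `dist` object over individuals.
#' @export
genotype_distance <- function(snps) {
  stats::dist(snps$genotypes, method = "manhattan") / (2 * ncol(snps$genotypes))
}
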