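#' MCMC configuration for the admixture sampler
#'
#' Desk-scale defaults (burn-in 2,000, 8,000 post-burn-in sweeps, thinning
#' 10, 5 replicate runs per K) trade the long chains typical of production
#' STRUCTURE analyses (1e5 burn-in / 5e5 sweeps / 12 runs) for test-bench
#' turnaround; production-scale values are one config edit away.
#'
#' @param K number of clusters (>= 1).
#' @param burn_in burn-in sweeps (>= 0).
#' @param reps post-burn-in sweeps (>= 1).
#' @param lambda symmetric Dirichlet prior on cluster allele frequencies.
#' @param alpha initial admixture Dirichlet parameter.
#' @param infer_alpha update alpha by Metropolis? (STRUCTURE default).
#' @param alpha_max upper bound of alpha's uniform prior.
#' @param alpha_sd s.d. of the symmetric normal alpha proposal.
#' @param thin thinning interval for the recorded trace.
#' @param seed integer seed making the run exactly reproducible.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(K = 2L, burn_in = 2000L, reps = 8000L, lambda = 1.0,
                        alpha = 1.0, infer_alpha = TRUE, alpha_max = 10.0,
                        alpha_sd = 0.05, thin = 10L, seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  if (burn_in < 0L) stop("burn_in must be >= 0")
  if (reps < 1L) stop("reps must be >= 1")
  if (lambda <= 0) stop("lambda must be > 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(K = as.integer(K), burn_in = as.integer(burn_in),
                 reps = as.integer(reps), lambda = lambda, alpha = alpha,
                 infer_alpha = infer_alpha, alpha_max = alpha_max,
                 alpha_sd = alpha_sd, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Run the admixture Gibbs sampler
#'
#' Executes burn-in plus `reps` full sweeps (each sweep: reassign latent
#' origins Z from their full conditionals, conjugate Dirichlet updates of
#' the cluster allele frequencies P and the admixture proportions Q,
#' optional Metropolis update of alpha). Q and P are posterior means over
#' the thinned post-burn-in samples; `lnPD` estimates Ln Pr(X|K) from the
#' log-likelihood trace via [estimate_lnPD()]. Gene copies with missing
#' calls are skipped (no imputation). Alleles absent from `g` are dropped
#' from the model's per-locus code space.
#'
#' @param g a [genotype_matrix()].
#' @param cfg an [mcmc_config()].
#' @return An object of class `structure_run`: list with `config`, `Q`
#'   (n x K posterior-mean admixture proportions, rows sum to 1), `P`
#'   (per-locus K x J_l posterior-mean allele frequencies, named by the
#'   original allele codes), `lnl_trace`, `alpha_trace`, `lnPD`.
#' @export
run_mcmc <- function(g, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "mcmc_config"))
  if (n_individuals(g) == 0L) stop("empty genotype matrix")
  rec <- dense_recode(g)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  res <- gibbs_admixture_cpp(rec$geno, rec$nalleles, cfg$K, cfg$lambda,
                             cfg$alpha, cfg$infer_alpha && cfg$K > 1L,
                             cfg$alpha_max, cfg$alpha_sd,
                             cfg$burn_in, cfg$reps, cfg$thin)
  rownames(res$Q) <- g$individual_ids
  for (l in seq_along(res$P)) colnames(res$P[[l]]) <- as.character(rec$codes[[l]])
  names(res$P) <- g$locus_names
  structure(list(config = cfg, Q = res$Q, P = res$P,
                 lnl_trace = as.numeric(res$lnl_trace),
                 alpha_trace = as.numeric(res$alpha_trace),
                 lnPD = estimate_lnPD(as.numeric(res$lnl_trace)),
                 individual_ids = g$individual_ids,
                 pop_labels = g$pop_labels),
            class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("structure_run: K = %d, %d individuals, lnPD = %.1f\n",
              x$config$K, nrow(x$Q), x$lnPD))
  invisible(x)
}

#' Estimate Ln Pr(X|K) from a log-likelihood trace
#'
#' The harmonic-style estimator used by STRUCTURE:
#' `mean(lnL) - var(lnL) / 2` over the post-burn-in trace (sample variance,
#' n - 1 denominator). Noisier chains are penalized.
#'
#' @param lnl_trace numeric trace, length >= 2.
#' @return scalar estimate, never above the trace mean.
#' @export
estimate_lnPD <- function(lnl_trace) {
  if (length(lnl_trace) < 2L) stop("trace must have length >= 2")
  mean(lnl_trace) - stats::var(lnl_trace) / 2
}

#' Model log-likelihood ln Pr(X | P, Q)
#'
#' Sum over non-missing gene copies of `ln(sum_k q_ik p_kla)`; missing
#' copies contribute 0.
#'
#' @param g a [genotype_matrix()].
#' @param P per-locus K x J_l frequency matrices with allele-code column
#'   names (as in a `structure_run`).
#' @param Q n x K admixture proportion matrix.
#' @return finite scalar; an exactly zero mixture probability at an observed
#'   copy raises an error.
#' @export
log_likelihood <- function(g, P, Q) {
  n <- n_individuals(g); L <- n_loci(g)
  stopifnot(nrow(Q) == n, length(P) == L)
  ll <- 0
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      for (c in 1:2) {
        a <- g$alleles[i, l, c]
        if (is.na(a)) next
        j <- match(as.character(a), colnames(P[[l]]))
        if (is.na(j)) stop("allele ", a, " at locus ", l, " not in P")
        m <- sum(Q[i, ] * P[[l]][, j])
        if (m <= 0) stop("zero mixture probability for an observed copy")
        ll <- ll + log(m)
      }
    }
  }
  ll
}

#' Align replicate runs across the label-switching symmetry
#'
#' Cluster labels are arbitrary per run. Each run after the first gets a
#' greedy column permutation maximizing the summed correlation between its
#' Q columns and the first run's (columns with zero variance fall back to a
#' negative-distance score).
#'
#' @param runs list of `structure_run`s sharing K and individuals.
#' @return the list with `Q` (and `P`) columns permuted; each run gains a
#'   `permutation` field.
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1L)
  K <- runs[[1]]$config$K
  n <- nrow(runs[[1]]$Q)
  for (r in runs) {
    if (r$config$K != K || nrow(r$Q) != n)
      stop("all runs must share K and the individual set")
  }
  if (K == 1L) {
    for (i in seq_along(runs)) runs[[i]]$permutation <- 1L
    return(runs)
  }
  ref <- runs[[1]]$Q
  score <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-mean((x - y)^2))
    stats::cor(x, y)
  }
  for (ri in seq_along(runs)) {
    Q <- runs[[ri]]$Q
    S <- outer(seq_len(K), seq_len(K),
               Vectorize(function(a, b) score(ref[, a], Q[, b])))
    perm <- integer(K)  # perm[target col] = source col in Q
    free_t <- seq_len(K); free_s <- seq_len(K)
    while (length(free_t)) {
      sub <- S[free_t, free_s, drop = FALSE]
      ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      t <- free_t[ij[1]]; s <- free_s[ij[2]]
      perm[t] <- s
      free_t <- setdiff(free_t, t); free_s <- setdiff(free_s, s)
    }
    runs[[ri]]$Q <- Q[, perm, drop = FALSE]
    runs[[ri]]$P <- lapply(runs[[ri]]$P, function(pm) pm[perm, , drop = FALSE])
    runs[[ri]]$permutation <- perm
  }
  runs
}
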