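# Pure-R reference implementation of the sampler's single sweeps. The
# production chain runs in compiled code (run_mcmc); these functions expose
# the same full conditionals one update at a time, for inspection and for
# cross-checking the compiled path against an independent route.

#' Initialize sampler state
#'
#' Z drawn uniformly over clusters, P from the Dirichlet(lambda) prior,
#' Q uniform at 1/K.
#'
#' @param g a [genotype_matrix()].
#' @param cfg an [mcmc_config()].
#' @return a `mcmc_state` list: dense genotype codes, `z` (n x 2L cluster of
#'   each gene copy, NA where the copy is missing), `P`, `Q`, `alpha`.
#' @export
mcmc_init_state <- function(g, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "mcmc_config"))
  if (n_individuals(g) == 0L) stop("empty genotype matrix")
  rec <- dense_recode(g)
  n <- n_individuals(g); L <- n_loci(g); K <- cfg$K
  z <- matrix(NA_integer_, n, 2L * L)
  obs <- !is.na(rec$geno)
  z[obs] <- sample.int(K, sum(obs), replace = TRUE)
  P <- lapply(rec$nalleles, function(J) {
    pm <- t(vapply(seq_len(K), function(k) rdirichlet1(rep(cfg$lambda, J)),
                   numeric(J)))
    matrix(pm, nrow = K, ncol = J)
  })
  Q <- matrix(1 / K, n, K)
  structure(list(geno = rec$geno, nalleles = rec$nalleles, codes = rec$codes,
                 n = n, L = L, K = K, cfg = cfg,
                 z = z, P = P, Q = Q, alpha = cfg$alpha),
            class = "mcmc_state")
}

#' Full-conditional probabilities of a gene copy's cluster origin
#'
#' `P(z = k)` is proportional to `q_ik * p_{k,l,a}`; exposed for oracle
#' tests of the Z update.
#'
#' @param state an `mcmc_state`.
#' @param i individual index; @param l locus index; @param copy 1 or 2.
#' @return normalized K-vector.
#' @export
z_full_conditional <- function(state, i, l, copy) {
  a <- state$geno[i, 2L * (l - 1L) + copy]
  if (is.na(a)) stop("gene copy is missing; it carries no Z")
  w <- state$Q[i, ] * state$P[[l]][, a + 1L]
  if (sum(w) == 0) rep(1 / state$K, state$K) else w / sum(w)
}

#' One Gibbs update of all latent origins Z
#' @param state an `mcmc_state`.
#' @return the state with `z` resampled (missing copies stay NA).
#' @export
mcmc_update_z <- function(state) {
  for (i in seq_len(state$n)) for (l in seq_len(state$L)) for (cp in 1:2) {
    col <- 2L * (l - 1L) + cp
    if (is.na(state$geno[i, col])) next
    pr <- z_full_conditional(state, i, l, cp)
    state$z[i, col] <- sample.int(state$K, 1L, prob = pr)
  }
  state
}

#' One conjugate update of the cluster allele frequencies P
#'
#' `p_{k,l,.} ~ Dirichlet(lambda + counts of copies assigned to k)`.
#' @param state an `mcmc_state`.
#' @return the state with every (k, l) simplex resampled.
#' @export
mcmc_update_p <- function(state) {
  lam <- state$cfg$lambda
  for (l in seq_len(state$L)) {
    J <- state$nalleles[l]
    cols <- c(2L * (l - 1L) + 1L, 2L * (l - 1L) + 2L)
    a <- c(state$geno[, cols[1]], state$geno[, cols[2]])
    zk <- c(state$z[, cols[1]], state$z[, cols[2]])
    keep <- !is.na(a)
    for (k in seq_len(state$K)) {
      cnt <- tabulate(a[keep & zk == k] + 1L, nbins = J)
      state$P[[l]][k, ] <- rdirichlet1(lam + cnt)
    }
  }
  state
}

#' One conjugate update of the admixture proportions Q
#'
#' `q_i ~ Dirichlet(alpha + per-cluster copy counts of individual i)`.
#' @param state an `mcmc_state`.
#' @return the state with every Q row resampled.
#' @export
mcmc_update_q <- function(state) {
  for (i in seq_len(state$n)) {
    cnt <- tabulate(state$z[i, !is.na(state$z[i, ])], nbins = state$K)
    state$Q[i, ] <- rdirichlet1(state$alpha + cnt)
  }
  state
}

#' One Metropolis update of the admixture parameter alpha
#'
#' Symmetric normal proposal, uniform prior on `(0, alpha_max]`; the
#' acceptance ratio compares the Dirichlet(alpha) likelihood of the current
#' Q rows.
#'
#' @param state an `mcmc_state`.
#' @return the state with `alpha` possibly replaced.
#' @export
mcmc_update_alpha <- function(state) {
  if (!state$cfg$infer_alpha || state$K == 1L) return(state)
  a0 <- state$alpha
  a1 <- a0 + stats::rnorm(1L, 0, state$cfg$alpha_sd)
  if (a1 <= 0 || a1 > state$cfg$alpha_max) return(state)
  lr <- alpha_log_ratio(state$Q, a0, a1)
  if (lr >= 0 || stats::runif(1) < exp(lr)) state$alpha <- a1
  state
}

alpha_log_ratio <- function(Q, a0, a1) {
  n <- nrow(Q); K <- ncol(Q)
  slog <- sum(log(pmax(Q, 1e-300)))
  n * (lgamma(K * a1) - K * lgamma(a1) - lgamma(K * a0) + K * lgamma(a0)) +
    (a1 - a0) * slog
}

#' One full reference sweep (Z, P, Q, alpha)
#' @param state an `mcmc_state`.
#' @return the updated state.
#' @export
mcmc_sweep <- function(state) {
  state <- mcmc_update_z(state)
  state <- mcmc_update_p(state)
  state <- mcmc_update_q(state)
  mcmc_update_alpha(state)
}

# log-likelihood of the current reference state (dense-coded route)
state_log_likelihood <- function(state) {
  ll <- 0
  for (l in seq_len(state$L)) {
    for (cp in 1:2) {
      col <- 2L * (l - 1L) + cp
      a <- state$geno[, col]
      keep <- which(!is.na(a))
      if (!length(keep)) next
      m <- rowSums(state$Q[keep, , drop = FALSE] *
                     t(state$P[[l]][, a[keep] + 1L, drop = FALSE]))
      ll <- ll + sum(log(m))
    }
  }
  ll
}

#' Reference (pure-R) MCMC run
#'
#' Same chain as [run_mcmc()] but executed by the single-step reference
#' functions. Slow; intended for cross-validation on small instances.
#'
#' @param g a [genotype_matrix()].
#' @param cfg an [mcmc_config()].
#' @return a `structure_run` (without per-allele P column names' guarantees
#'   beyond [run_mcmc()]'s).
#' @export
run_mcmc_reference <- function(g, cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  state <- mcmc_init_state(g, cfg)
  nsave <- cfg$reps %/% cfg$thin
  if (nsave < 1L) stop("no post-burn-in samples; increase reps or lower thin")
  lnl <- numeric(nsave); atr <- numeric(nsave)
  Qsum <- matrix(0, state$n, state$K)
  Psum <- lapply(state$P, function(m) m * 0)
  saved <- 0L
  for (it in seq_len(cfg$burn_in + cfg$reps)) {
    state <- mcmc_sweep(state)
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L &&
        saved < nsave) {
      saved <- saved + 1L
      lnl[saved] <- state_log_likelihood(state)
      atr[saved] <- state$alpha
      Qsum <- Qsum + state$Q
      for (l in seq_len(state$L)) Psum[[l]] <- Psum[[l]] + state$P[[l]]
    }
  }
  Q <- Qsum / saved
  Q <- Q / rowSums(Q)
  P <- lapply(seq_len(state$L), function(l) {
    pm <- Psum[[l]] / saved
    pm <- pm / rowSums(pm)
    colnames(pm) <- as.character(state$codes[[l]])
    pm
  })
  names(P) <- g$locus_names
  rownames(Q) <- g$individual_ids
  structure(list(config = cfg, Q = Q, P = P, lnl_trace = lnl,
                 alpha_trace = atr, lnPD = estimate_lnPD(lnl),
                 individual_ids = g$individual_ids,
                 pop_labels = g$pop_labels),
            class = "structure_run")
}
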