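# Gibbs sampler: single-step full conditionals against hand computations
# and conjugate moments, the compiled chain against the pure-R reference,
# and the run-level contracts

test_that("init_state respects the degenerate and shape contracts", {
  g <- toy_matrix()
  cfg1 <- mcmc_config(K = 1L, seed = 1L)
  set.seed(1); st1 <- mcmc_init_state(g, cfg1)
  expect_true(all(st1$z[!is.na(st1$z)] == 1L))
  expect_equal(unname(st1$Q[, 1]), rep(1, 6))

  cfg <- mcmc_config(K = 3L, seed = 1L)
  set.seed(5); a <- mcmc_init_state(g, cfg)
  set.seed(5); b <- mcmc_init_state(g, cfg)
  expect_identical(a, b)
  expect_equal(dim(a$Q), c(6L, 3L))
  expect_equal(dim(a$z), c(6L, 4L))
  expect_length(a$P, 2L)
  expect_equal(nrow(a$P[[1]]), 3L)
})

test_that("Z full conditional matches the hand computation and normalizes", {
  g <- genotype_matrix(array(c(1L, 1L), c(1, 1, 2)), "p")
  st <- mcmc_init_state(g, mcmc_config(K = 2L))
  st$Q[1, ] <- c(1, 0)
  pr <- z_full_conditional(st, 1L, 1L, 1L)
  expect_equal(pr, c(1, 0))
  st$Q[1, ] <- c(0.5, 0.5)
  st$P[[1]][, 1] <- c(0.9, 0.1)
  expect_equal(z_full_conditional(st, 1L, 1L, 1L), c(0.9, 0.1))
  for (s in 1:20) {
    set.seed(s)
    st$Q[1, ] <- rgamma(2, 1); st$Q[1, ] <- st$Q[1, ] / sum(st$Q[1, ])
    st$P[[1]][, 1] <- runif(2)
    expect_equal(sum(z_full_conditional(st, 1L, 1L, 1L)), 1.0)
  }
})

test_that("P update has the conjugate posterior mean", {
  # one locus, 2 alleles, counts (3, 1) in cluster 1, lambda = 1 -> (4/6, 2/6)
  a <- array(c(1L, 1L, 1L, 2L), c(2, 1, 2))  # copies: 1,1,1,2
  g <- genotype_matrix(a, c("p", "p"))
  st <- mcmc_init_state(g, mcmc_config(K = 1L, lambda = 1))
  set.seed(3)
  draws <- replicate(4000, mcmc_update_p(st)$P[[1]][1, ])
  expect_equal(rowMeans(draws), c(4 / 6, 2 / 6), tolerance = 0.02)
  # empty cluster falls back to the prior Dirichlet(lambda): mean 1/J
  st2 <- mcmc_init_state(g, mcmc_config(K = 2L, lambda = 1))
  st2$z[] <- 1L
  set.seed(4)
  d2 <- replicate(4000, mcmc_update_p(st2)$P[[1]][2, ])
  expect_equal(rowMeans(d2), c(0.5, 0.5), tolerance = 0.02)
})

test_that("Q update: degeneracy at K=1 and count domination as alpha -> 0", {
  g <- toy_matrix()
  st <- mcmc_init_state(g, mcmc_config(K = 1L))
  expect_equal(unname(mcmc_update_q(st)$Q[, 1]), rep(1, 6))
  st2 <- mcmc_init_state(g, mcmc_config(K = 2L, alpha = 1e-9,
                                        infer_alpha = FALSE))
  st2$z[] <- 1L
  set.seed(2)
  expect_gt(min(mcmc_update_q(st2)$Q[, 1]), 0.999)
  # conjugate moment: alpha = 1, counts (4, 0) over 2L = 4 copies
  st3 <- mcmc_init_state(toy_matrix(n_per = 1L), mcmc_config(K = 2L, alpha = 1))
  st3$z[] <- 1L
  set.seed(6)
  qd <- replicate(4000, mcmc_update_q(st3)$Q[1, ])
  expect_equal(rowMeans(qd), c(5 / 6, 1 / 6), tolerance = 0.02)
})

test_that("alpha Metropolis respects its support and self-consistency", {
  g <- toy_matrix()
  st <- mcmc_init_state(g, mcmc_config(K = 2L, alpha = 9.99, alpha_sd = 10))
  # force proposals out of support: with sd huge most proposals leave (0,10]
  set.seed(8)
  rejected <- replicate(50, {
    s2 <- mcmc_update_alpha(st)
    s2$alpha == st$alpha || (s2$alpha > 0 && s2$alpha <= 10)
  })
  expect_true(all(rejected))
  # identity proposal accepts: log-ratio is exactly 0
  expect_equal(hierstruct:::alpha_log_ratio(st$Q, 0.7, 0.7), 0)
  # chain on fixed Q drawn from Dirichlet(0.5) concentrates near 0.5
  set.seed(9)
  n <- 200L
  q <- t(replicate(n, { x <- rgamma(2, 0.5); x / sum(x) }))
  st$Q <- q
  st$alpha <- 5
  trace <- numeric(5000)
  set.seed(10)
  for (i in seq_along(trace)) { st <- mcmc_update_alpha(st); trace[i] <- st$alpha }
  est <- median(trace[1000:5000])
  expect_gt(est, 0.2); expect_lt(est, 1.0)
})

test_that("log-likelihood matches hand values and brute force", {
  g <- genotype_matrix(array(c(1L, 1L), c(1, 1, 2)), "p")
  P <- list(matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("1", "2"))))
  Q <- matrix(1, 1, 1)
  expect_equal(log_likelihood(g, P, Q), 2 * log(0.5))
  # all-missing individual contributes 0
  g2 <- genotype_matrix(array(c(1L, NA, 1L, NA), c(2, 1, 2)), c("p", "p"))
  Q2 <- matrix(1, 2, 1)
  expect_equal(log_likelihood(g2, P, Q2), 2 * log(0.5))
  # brute force on random instances
  for (s in 1:5) {
    set.seed(s)
    g3 <- random_matrix(n = 5L, n_loci = 3L, n_pops = 1L, seed = s,
                        missing_rate = 0.2)
    K <- 2L
    rec <- hierstruct:::dense_recode(g3)
    P3 <- lapply(seq_len(3), function(l) {
      m <- matrix(rgamma(K * rec$nalleles[l], 1), K)
      m <- m / rowSums(m)
      colnames(m) <- as.character(rec$codes[[l]])
      m
    })
    Q3 <- matrix(rgamma(5 * K, 1), 5); Q3 <- Q3 / rowSums(Q3)
    brute <- 0
    for (i in 1:5) for (l in 1:3) for (cp in 1:2) {
      a <- g3$alleles[i, l, cp]
      if (is.na(a)) next
      j <- match(as.character(a), colnames(P3[[l]]))
      brute <- brute + log(sum(Q3[i, ] * P3[[l]][, j]))
    }
    expect_equal(log_likelihood(g3, P3, Q3), brute)
  }
})

test_that("lnPD estimator: hand values and monotone noise penalty", {
  expect_equal(estimate_lnPD(c(-5, -5, -5)), -5)
  expect_equal(estimate_lnPD(c(-100, -102)), -102)  # mean -101, var 2
  expect_error(estimate_lnPD(-3), "length")
  set.seed(1)
  base <- rnorm(200, -1000, 1)
  expect_gt(estimate_lnPD(base), estimate_lnPD(base + rnorm(200, 0, 10)))
})

test_that("run_mcmc: K=1 degeneracy, determinism, simplex conservation", {
  g <- random_matrix(n = 8L, n_loci = 4L, seed = 2L, missing_rate = 0.1)
  r1 <- run_mcmc(g, mcmc_config(K = 1L, burn_in = 50L, reps = 200L,
                                thin = 2L, seed = 3L))
  expect_equal(unname(r1$Q[, 1]), rep(1, 8))
  expect_true(is.finite(r1$lnPD))
  cfg <- mcmc_config(K = 3L, burn_in = 100L, reps = 400L, thin = 4L, seed = 4L)
  ra <- run_mcmc(g, cfg); rb <- run_mcmc(g, cfg)
  expect_identical(ra, rb)
  expect_equal(unname(rowSums(ra$Q)), rep(1, 8), tolerance = 1e-9)
  for (pm in ra$P) expect_equal(unname(rowSums(pm)), rep(1, 3), tolerance = 1e-9)
  expect_lte(ra$lnPD, max(ra$lnl_trace))
})

test_that("compiled chain agrees with the pure-R reference sampler", {
  sim <- two_deme_sim(gst = 0.3, size = 12L, n_loci = 6L, seed = 21L)
  g <- sim$genotypes
  cfg <- mcmc_config(K = 2L, burn_in = 300L, reps = 1200L, thin = 5L,
                     seed = 5L)
  rc <- run_mcmc(g, cfg)
  rr <- run_mcmc_reference(g, cfg)
  rc_al <- align_runs(list(rc, rr))
  # posterior means agree within Monte-Carlo tolerance
  expect_lt(max(abs(rc_al[[1]]$Q - rc_al[[2]]$Q)), 0.15)
  expect_lt(abs(rc$lnPD - rr$lnPD) / abs(rr$lnPD), 0.05)
})

test_that("permuting individuals permutes the posterior Q rows", {
  sim <- two_deme_sim(gst = 0.4, size = 10L, n_loci = 8L, seed = 22L)
  g <- sim$genotypes
  set.seed(1); perm <- sample.int(n_individuals(g))
  gp <- genotype_matrix(g$alleles[perm, , , drop = FALSE],
                        g$pop_labels[perm], g$individual_ids[perm],
                        g$locus_names)
  cfg <- mcmc_config(K = 2L, burn_in = 400L, reps = 1600L, thin = 4L, seed = 6L)
  r1 <- run_mcmc(g, cfg); r2 <- run_mcmc(gp, cfg)
  al <- align_runs(list(r1, r2))
  expect_lt(max(abs(al[[1]]$Q[perm, ] - al[[2]]$Q)), 0.15)
})

test_that("align_runs detects column swaps and never lowers agreement", {
  sim <- two_deme_sim(gst = 0.4, size = 10L, n_loci = 8L, seed = 23L)
  cfg <- mcmc_config(K = 2L, burn_in = 200L, reps = 800L, thin = 4L, seed = 7L)
  r <- run_mcmc(sim$genotypes, cfg)
  r_sw <- r
  r_sw$Q <- r$Q[, 2:1]
  r_sw$P <- lapply(r$P, function(pm) pm[2:1, , drop = FALSE])
  al <- align_runs(list(r, r_sw))
  expect_equal(al[[2]]$Q, r$Q)
  expect_equal(al[[2]]$permutation, c(2L, 1L))
  # K = 1 is a no-op
  r1 <- run_mcmc(sim$genotypes, mcmc_config(K = 1L, burn_in = 50L,
                                            reps = 200L, thin = 2L, seed = 8L))
  expect_identical(align_runs(list(r1, r1))[[2]]$Q, r1$Q)
  # objective monotonicity over random "runs"
  agree <- function(a, b) sum(a * b)
  for (s in 1:10) {
    set.seed(s)
    K <- 3L; n <- 15L
    qa <- matrix(rgamma(n * K, 1), n); qa <- qa / rowSums(qa)
    prm <- sample.int(K)
    rb <- r
    ra <- r
    ra$config$K <- rb$config$K <- K
    ra$Q <- qa; rb$Q <- qa[, prm] + matrix(rnorm(n * K, 0, 0.01), n)
    rb$Q <- abs(rb$Q) / rowSums(abs(rb$Q))
    ra$P <- rb$P <- list(matrix(1 / K, K, 1))
    al <- align_runs(list(ra, rb))
    expect_gte(agree(qa, al[[2]]$Q), agree(qa, rb$Q) - 1e-12)
  }
})
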