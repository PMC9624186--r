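# fixture builders shared across the suite; everything is generated in code

# small deterministic genotype matrix: 2 pops x n_per pop, n_loci loci
toy_matrix <- function(n_per = 3L, n_loci = 2L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per
  a <- array(sample(1:4, n * n_loci * 2L, replace = TRUE), c(n, n_loci, 2L))
  genotype_matrix(a, rep(c("popA", "popB"), each = n_per))
}

random_matrix <- function(n = 20L, n_loci = 12L, n_pops = 4L, seed = 1L,
                          missing_rate = 0) {
  set.seed(seed)
  a <- array(sample(1:8, n * n_loci * 2L, replace = TRUE), c(n, n_loci, 2L))
  if (missing_rate > 0) {
    drop <- array(runif(n * n_loci * 2L) < missing_rate, dim(a))
    # genotype-level missingness: both copies
    for (l in seq_len(n_loci)) {
      miss <- drop[, l, 1]
      a[miss, l, ] <- NA_integer_
    }
  }
  genotype_matrix(a, sample(paste0("P", seq_len(n_pops)), n, replace = TRUE))
}

# star tree: n_demes leaves all at drift F from the root
star_tree <- function(n_demes, F, size) {
  labs <- paste0("D", seq_len(n_demes))
  deme_tree(paste0("(", paste0(labs, ":", F, collapse = ","), ");"),
            stats::setNames(rep(size, n_demes), labs))
}

# two clades x demes_per_clade; branch drift chosen via the two-deme
# pairwise-Gst relation gst = F/(2-F)
two_clade_tree <- function(demes_per_clade = 3L, f_deep = 0.4444,
                           f_shallow = 0.4, size = 15L) {
  mk <- function(pref) paste0("(", paste0(pref, seq_len(demes_per_clade),
                                          ":", f_shallow, collapse = ","),
                              "):", f_deep)
  labs <- c(paste0("A", seq_len(demes_per_clade)),
            paste0("B", seq_len(demes_per_clade)))
  deme_tree(paste0("(", mk("A"), ",", mk("B"), ");"),
            stats::setNames(rep(size, length(labs)), labs))
}

two_deme_sim <- function(gst = 0.3, size = 50L, n_loci = 20L, seed = 1L) {
  F <- 2 * gst / (1 + gst)  # invert gst = F / (2 - F)
  tr <- star_tree(2L, F, size)
  simulate_genotypes(simulation_spec(tr, n_loci = n_loci,
                                     alleles_per_locus = 8L, seed = seed))
}

# assignment accuracy of a K=2 run against true deme labels, maximised
# over the label permutation
assignment_accuracy <- function(run, truth) {
  cl <- apply(run$Q, 1L, which.max)
  lv <- unique(truth)
  max(mean((cl == 1L) == (truth == lv[1])),
      mean((cl == 2L) == (truth == lv[1])))
}

light_mcmc <- function(...) mcmc_config(burn_in = 500L, reps = 2000L,
                                        thin = 5L, ...)
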