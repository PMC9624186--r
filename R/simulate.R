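# F-model genotype simulator: ancestral frequencies drift down a deme tree
# (child ~ Dirichlet(parent * (1-F)/F), so E[child] = parent and
# Var[child_j] = F p_j (1 - p_j)), then two gene copies per individual per
# locus are drawn from each leaf's realized frequencies.

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = pmax(shape, 1e-12), rate = 1)
  s <- sum(g)
  if (s == 0) { # numerical underflow at extreme drift: mass on largest shape
    g[which.max(shape)] <- 1
    s <- 1
  }
  g / s
}

#' Sample ancestral (root) allele frequencies
#'
#' One symmetric-Dirichlet(`lambda_anc`) draw per locus.
#'
#' @param spec a [simulation_spec()].
#' @return list of per-locus frequency vectors (each sums to 1).
#' @export
sample_ancestral_frequencies <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, 101L))
  lapply(spec$alleles_per_locus, function(J)
    rdirichlet1(rep(spec$lambda_anc, J)))
}

#' Dirichlet drift of allele frequencies along one branch
#'
#' The F-model transition: `child ~ Dirichlet(parent * (1 - F) / F)`, whose
#' mean is the parent vector and whose per-allele variance is
#' `F * p_j * (1 - p_j)` — `F` is the expected fixation index accrued on the
#' branch.
#'
#' @param parent_freqs numeric frequency vector summing to 1.
#' @param F drift parameter, strictly inside (0, 1).
#' @return a frequency vector of the same length, summing to 1.
#' @export
drift_frequencies <- function(parent_freqs, F) {
  if (F <= 0 || F >= 1) stop("F must lie strictly inside (0, 1)")
  if (abs(sum(parent_freqs) - 1) > 1e-6) stop("parent_freqs must sum to 1")
  rdirichlet1(parent_freqs * (1 - F) / F)
}

#' Simulate a genotype dataset from an F-model deme tree
#'
#' Draws ancestral frequencies at the root, applies [drift_frequencies()]
#' along every branch (composing multiplicatively root to leaf), then
#' samples two gene copies per individual per locus from each leaf deme's
#' realized frequencies. Whole genotypes (both copies) are knocked out at
#' `missing_rate` to emulate PCR dropout. Allele codes are `1..J_l`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genotypes` (a [genotype_matrix()], one population per
#'   leaf deme) and `freqs` (list `freqs[[deme]][[locus]]` of realized
#'   frequency vectors — the ground truth for estimator recovery tests).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  phy <- spec$tree$phylo
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  anc <- sample_ancestral_frequencies(spec)
  set.seed(derive_seed(spec$seed, 202L))

  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nnode <- ntip + phy$Nnode
  # preorder traversal: parents before children
  phy_pre <- ape::reorder.phylo(phy, "cladewise")
  edges <- phy_pre$edge
  elen <- phy_pre$edge.length
  node_freqs <- vector("list", nnode)
  node_freqs[[root]] <- anc
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    F <- elen[e]
    node_freqs[[child]] <- lapply(node_freqs[[par]],
                                  function(p) drift_frequencies(p, F))
  }
  demes <- phy$tip.label
  freqs <- stats::setNames(node_freqs[seq_len(ntip)], demes)

  sizes <- spec$tree$sizes[demes]
  n <- sum(sizes); L <- spec$n_loci
  alleles <- array(NA_integer_, c(n, L, 2L))
  pop_labels <- rep(demes, sizes)
  row0 <- 0L
  for (d in demes) {
    nd <- sizes[[d]]
    for (l in seq_len(L)) {
      p <- freqs[[d]][[l]]
      draws <- sample.int(length(p), size = 2L * nd, replace = TRUE, prob = p)
      alleles[row0 + seq_len(nd), l, 1L] <- draws[seq_len(nd)]
      alleles[row0 + seq_len(nd), l, 2L] <- draws[nd + seq_len(nd)]
    }
    row0 <- row0 + nd
  }
  if (spec$missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    for (l in seq_len(L)) {
      alleles[drop[, l], l, 1L] <- NA_integer_
      alleles[drop[, l], l, 2L] <- NA_integer_
    }
  }
  ids <- paste0(pop_labels, "_", unlist(lapply(sizes, seq_len)))
  g <- genotype_matrix(alleles, pop_labels, ids)
  list(genotypes = g, freqs = freqs)
}

#' Parametric G_ST of a set of deme frequency tables
#'
#' Nei's fixation index computed directly from (realized) deme allele
#' frequencies: per locus `Hs` = mean within-deme expected heterozygosity,
#' `Ht` = expected heterozygosity of the pooled (mean) frequencies;
#' `G_ST = (mean(Ht) - mean(Hs)) / mean(Ht)` over loci. This is the ground
#' truth differentiation of a simulation, the recovery target for the
#' sample-based estimators.
#'
#' @param freqs list `freqs[[deme]][[locus]]` of frequency vectors, as
#'   returned by [simulate_genotypes()].
#' @param demes optional subset of deme names.
#' @return scalar in `[0, 1]`.
#' @export
parametric_gst <- function(freqs, demes = NULL) {
  if (!is.null(demes)) freqs <- freqs[demes]
  if (length(freqs) < 2L) stop("need >= 2 demes")
  L <- length(freqs[[1]])
  Hs <- Ht <- numeric(L)
  for (l in seq_len(L)) {
    pl <- lapply(freqs, `[[`, l)
    Hs[l] <- mean(vapply(pl, function(p) 1 - sum(p^2), 0))
    pbar <- Reduce(`+`, pl) / length(pl)
    Ht[l] <- 1 - sum(pbar^2)
  }
  if (mean(Ht) <= 0)
    stop("all loci monomorphic across all demes: G_ST undefined")
  (mean(Ht) - mean(Hs)) / mean(Ht)
}
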