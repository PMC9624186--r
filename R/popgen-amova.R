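# Three-level AMOVA (Excoffier-style) on inter-individual allele-mismatch
# distances, with permutation tests for the three Phi statistics.

# squared distance between individuals: number of differing allele copies
# per locus (0, 1, 2), summed over loci; loci missing in either individual
# are skipped
amova_distance_matrix <- function(g) {
  n <- n_individuals(g); L <- n_loci(g)
  D <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1) & !is.na(a2)
    idx <- which(ok)
    if (length(idx) < 2L) next
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      js <- idx[seq_len(ii - 1L)]
      if (!length(js)) next
      # shared copies between {a1[i],a2[i]} and {a1[j],a2[j]}, with multiplicity
      shared <- (a1[i] == a1[js]) + (a2[i] == a2[js])
      shared_x <- (a1[i] == a2[js]) + (a2[i] == a1[js])
      mism <- 2L - pmax(shared, shared_x)
      D[i, js] <- D[i, js] + mism
      D[js, i] <- D[i, js]
    }
  }
  D
}

ss_from_distances <- function(D, idx) {
  if (length(idx) < 2L) return(0)
  sum(D[idx, idx][upper.tri(D[idx, idx])]) / length(idx)
}

amova_phi <- function(D, pop, group) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  groups <- unique(group)
  G <- length(groups)
  pop_group <- vapply(pops, function(p) group[match(p, pop)], "")

  SS_total <- ss_from_distances(D, seq_len(N))
  SS_wp <- sum(vapply(pops, function(p) ss_from_distances(D, which(pop == p)), 0))
  SS_group <- vapply(groups, function(gr)
    ss_from_distances(D, which(group == gr)), 0)
  SS_ap_wg <- sum(SS_group) - SS_wp
  SS_ag <- SS_total - sum(SS_group)

  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P

  np <- vapply(pops, function(p) sum(pop == p), 0)
  Ng <- vapply(groups, function(gr) sum(group == gr), 0)
  sum_np2_by_g <- vapply(groups, function(gr)
    sum(np[pop_group == gr]^2) / Ng[match(gr, groups)], 0)
  n1 <- (N - sum(sum_np2_by_g)) / max(df_ap, 1L)
  n2 <- if (df_ag > 0) (sum(sum_np2_by_g) - sum(np^2) / N) / df_ag else NA_real_
  n3 <- if (df_ag > 0) (N - sum(Ng^2) / N) / df_ag else NA_real_

  MS_wp <- if (df_wp > 0) SS_wp / df_wp else 0
  MS_ap <- if (df_ap > 0) SS_ap_wg / df_ap else 0
  MS_ag <- if (df_ag > 0) SS_ag / df_ag else 0

  sig_c <- MS_wp
  sig_b <- if (df_ap > 0) (MS_ap - sig_c) / n1 else 0
  sig_a <- if (df_ag > 0) (MS_ag - sig_c - n2 * sig_b) / n3 else 0

  tot <- sig_a + sig_b + sig_c
  list(df = c(among_groups = df_ag, among_pops_within_groups = df_ap,
              within_pops = df_wp),
       SS = c(among_groups = SS_ag, among_pops_within_groups = SS_ap_wg,
              within_pops = SS_wp),
       MS = c(among_groups = MS_ag, among_pops_within_groups = MS_ap,
              within_pops = MS_wp),
       sigma = c(among_groups = sig_a, among_pops_within_groups = sig_b,
                 within_pops = sig_c),
       phi_CT = if (tot != 0) sig_a / tot else NA_real_,
       phi_SC = if ((sig_b + sig_c) != 0) sig_b / (sig_b + sig_c) else NA_real_,
       phi_ST = if (tot != 0) (sig_a + sig_b) / tot else NA_real_)
}

#' Three-level AMOVA with permutation tests
#'
#' Partitions molecular variance among groups, among populations within
#' groups, and within populations, from inter-individual allele-mismatch
#' distances (the number of differing allele copies per locus, 0/1/2,
#' summed over loci). Variance components use the Excoffier unequal-size
#' coefficients; negative components are reported raw and floored at 0 only
#' for the percentage computation (flagged by `floored`). Permutation
#' p-values: Phi_ST permutes individuals among populations, Phi_SC permutes
#' individuals among populations within their group, Phi_CT permutes whole
#' populations among groups.
#'
#' @param g a [genotype_matrix()].
#' @param grouping named character vector: group label per population label
#'   (must cover all populations). With a single group the analysis
#'   degenerates to a two-level AMOVA (among/within populations) and the
#'   group-level entries are NA.
#' @param n_permutations permutations per test (default 999).
#' @param seed integer seed for the permutations.
#' @return an object of class `amova_result`: `df`, `SS`, `MS`, `sigma`
#'   (variance components), `percent` (summing to 100), `floored`, `phi`
#'   (Phi_CT, Phi_SC, Phi_ST) and `p_values`.
#' @export
amova_three_level <- function(g, grouping, n_permutations = 999L, seed = 1L) {
  pops <- populations(g)
  if (!all(pops %in% names(grouping)))
    stop("grouping must cover every population")
  pop <- g$pop_labels
  group <- unname(grouping[pop])
  two_level <- length(unique(group)) < 2L

  D <- amova_distance_matrix(g)
  obs <- amova_phi(D, pop, group)

  sig <- obs$sigma
  floored <- sig < 0
  sigf <- pmax(sig, 0)
  if (two_level) { sigf <- sigf[-1]; floored <- floored[-1] }
  percent <- 100 * sigf / sum(sigf)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 777L))
  n <- length(pop)
  cnt_st <- cnt_sc <- cnt_ct <- 0L
  for (b in seq_len(n_permutations)) {
    # Phi_ST: individuals shuffled among all populations
    perm <- sample.int(n)
    r <- amova_phi(D, pop[perm], group[perm])
    if (!is.na(r$phi_ST) && !is.na(obs$phi_ST) && r$phi_ST >= obs$phi_ST)
      cnt_st <- cnt_st + 1L
    if (!two_level) {
      # Phi_SC: individuals shuffled among populations within their group
      pop_sc <- pop
      for (gr in unique(group)) {
        rows <- which(group == gr)
        pop_sc[rows] <- pop[rows][sample.int(length(rows))]
      }
      r <- amova_phi(D, pop_sc, group)
      if (!is.na(r$phi_SC) && !is.na(obs$phi_SC) && r$phi_SC >= obs$phi_SC)
        cnt_sc <- cnt_sc + 1L
      # Phi_CT: whole populations shuffled among groups
      gperm <- sample(unname(grouping[pops]))
      names(gperm) <- pops
      r <- amova_phi(D, pop, unname(gperm[pop]))
      if (!is.na(r$phi_CT) && !is.na(obs$phi_CT) && r$phi_CT >= obs$phi_CT)
        cnt_ct <- cnt_ct + 1L
    }
  }
  pval <- function(cnt) (cnt + 1) / (n_permutations + 1)
  structure(list(
    df = obs$df, SS = obs$SS, MS = obs$MS, sigma = obs$sigma,
    percent = percent, floored = floored,
    phi = c(phi_CT = obs$phi_CT, phi_SC = obs$phi_SC, phi_ST = obs$phi_ST),
    p_values = c(phi_CT = if (two_level) NA_real_ else pval(cnt_ct),
                 phi_SC = if (two_level) NA_real_ else pval(cnt_sc),
                 phi_ST = pval(cnt_st)),
    n_permutations = n_permutations, two_level = two_level),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (allele-mismatch distances)\n")
  lev <- names(x$sigma)
  for (i in seq_along(x$sigma)) {
    pc <- if (x$two_level && i == 1L) NA_real_
          else x$percent[names(x$percent) == lev[i]]
    cat(sprintf("  %-28s df %4d  SS %10.2f  sigma %8.4f  %6s\n",
                lev[i], x$df[i], x$SS[i], x$sigma[i],
                if (length(pc) && !is.na(pc)) sprintf("%.2f%%", pc) else "-"))
  }
  cat(sprintf("  Phi_CT %.4f (p=%s)  Phi_SC %.4f (p=%s)  Phi_ST %.4f (p=%.4g)\n",
              x$phi["phi_CT"], format(x$p_values["phi_CT"]),
              x$phi["phi_SC"], format(x$p_values["phi_SC"]),
              x$phi["phi_ST"], x$p_values["phi_ST"]))
  invisible(x)
}
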