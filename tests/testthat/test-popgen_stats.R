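# supporting statistics: theta, Nm, Nei distance, AMOVA, UPGMA, PCoA

# ---- independent oracle: Weir-Cockerham theta via indicator-variable ANOVA
wc_theta_anova <- function(g, pops) {
  keep <- g$pop_labels %in% pops
  a1 <- g$alleles[keep, , 1, drop = FALSE]
  a2 <- g$alleles[keep, , 2, drop = FALSE]
  labs <- g$pop_labels[keep]
  A <- B <- C <- 0
  for (l in seq_len(n_loci(g))) {
    x1 <- a1[, l, 1]; x2 <- a2[, l, 1]
    ok <- !is.na(x1) & !is.na(x2)
    if (sum(ok) < 2) next
    ni <- table(labs[ok])
    if (any(ni == 0) || length(ni) < 2) next
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    if (length(alleles) < 2) next
    r <- length(ni)
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (u in alleles) {
      # per-copy indicators, ANOVA across pops / individuals / copies
      y <- cbind(as.numeric(x1[ok] == u), as.numeric(x2[ok] == u))
      pop <- labs[ok]
      ybar <- mean(y)
      ybar_pop <- tapply(rowMeans(y), pop, mean)
      ybar_ind <- rowMeans(y)
      npop <- as.numeric(table(pop)[names(ybar_pop)])
      MSP <- sum(2 * npop * (ybar_pop - ybar)^2) / (r - 1)
      MSI <- sum(2 * (ybar_ind - ybar_pop[pop])^2) / (sum(npop) - r)
      MSG <- sum((y - ybar_ind)^2) / sum(npop)
      a <- (MSP - MSI) / (2 * nc)
      b <- (MSI - MSG) / 2
      cc <- MSG
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  A / (A + B + C)
}

test_that("theta: fixed demes give 1, null demes give ~0", {
  a <- array(NA_integer_, c(20, 5, 2))
  a[1:10, , ] <- 1L; a[11:20, , ] <- 2L
  g <- genotype_matrix(a, rep(c("x", "y"), each = 10))
  expect_equal(pairwise_fst(g, "x", "y"), 1.0)

  set.seed(3)
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  a2 <- array(sample(1:4, 400 * 50 * 2, TRUE, prob = freqs), c(400, 50, 2))
  g2 <- genotype_matrix(a2, rep(c("x", "y"), each = 200))
  expect_lt(abs(pairwise_fst(g2, "x", "y")), 0.05)
})

test_that("theta matches the indicator-ANOVA oracle on random instances", {
  for (s in 1:8) {
    g <- random_matrix(n = 20L, n_loci = 2L, n_pops = 2L, seed = 100 + s,
                       missing_rate = if (s > 4) 0.15 else 0)
    pops <- populations(g)
    if (length(pops) < 2L) next
    expect_equal(pairwise_fst(g, pops[1], pops[2]),
                 wc_theta_anova(g, pops[1:2]), tolerance = 1e-10)
  }
  # multi-population overall theta against the same oracle
  g <- random_matrix(n = 40L, n_loci = 3L, n_pops = 4L, seed = 200L)
  expect_equal(wc_theta(g), wc_theta_anova(g, populations(g)),
               tolerance = 1e-10)
})

test_that("theta recovers the simulation's drift on star trees", {
  # 20 demes: parametric Gst and theta both approximate the branch F
  for (F in c(0.1, 0.3)) {
    sim <- simulate_genotypes(simulation_spec(star_tree(20L, F, 20L),
                                              n_loci = 30L, seed = round(100 * F)))
    gst <- parametric_gst(sim$freqs)
    th <- wc_theta(sim$genotypes)
    expect_lt(abs(th - gst), 0.05)
  }
})

test_that("Nm conversion implements the island-model formula", {
  expect_equal(nm_from_fst(0.25), 0.75)
  expect_equal(nm_from_fst(0.5), 0.25)
  expect_equal(nm_from_fst(1), 0)
  expect_error(nm_from_fst(0), "unbounded")
  expect_error(nm_from_fst(-0.02), "unbounded")
})

test_that("Nei distance: identity, hand value, symmetry, infinity", {
  fa <- list(c(a = 0.5, b = 0.5))
  expect_equal(nei_distance(fa, fa), 0)
  fb <- list(c(a = 1.0))
  # I = 0.5 / sqrt(0.5 * 1) -> D = -ln(0.7071) = 0.34657
  expect_equal(nei_distance(fa, fb), -log(0.5 / sqrt(0.5)), tolerance = 1e-9)
  expect_equal(nei_distance(fa, fb), 0.3465736, tolerance = 1e-6)
  disjoint <- list(c(a = 1.0)); other <- list(c(b = 1.0))
  expect_equal(nei_distance(disjoint, other), Inf)
  for (s in 1:10) {
    set.seed(s)
    f1 <- list(prop.table(setNames(rgamma(3, 1), c("a", "b", "c"))))
    f2 <- list(prop.table(setNames(rgamma(3, 1), c("a", "b", "c"))))
    expect_equal(nei_distance(f1, f2), nei_distance(f2, f1))
  }
  # unbiased variant needs sample sizes and can undercut the standard one
  expect_error(nei_distance(fa, fb, variant = "unbiased"), "sample sizes")
  d_std <- nei_distance(fa, fb)
  d_unb <- nei_distance(fa, fb, variant = "unbiased", n_a = 40, n_b = 40)
  expect_lt(d_unb, d_std)
})

# ---- independent oracle: AMOVA sums of squares by direct triple loop
amova_ss_brute <- function(g, grouping) {
  D <- hierstruct:::amova_distance_matrix(g)
  pop <- g$pop_labels
  grp <- unname(grouping[pop])
  N <- length(pop)
  ss <- function(idx) {
    if (length(idx) < 2) return(0)
    tot <- 0
    for (i in idx) for (j in idx) if (i < j) tot <- tot + D[i, j]
    tot / length(idx)
  }
  SS_total <- ss(seq_len(N))
  SS_wp <- sum(vapply(unique(pop), function(p) ss(which(pop == p)), 0))
  SS_wg <- sum(vapply(unique(grp), function(x) ss(which(grp == x)), 0))
  c(among_groups = SS_total - SS_wg, among_pops = SS_wg - SS_wp,
    within = SS_wp)
}

test_that("AMOVA matches brute-force sums of squares on a 3-group toy", {
  set.seed(5)
  # 3 groups x 2 pops x 5 individuals
  labs <- rep(paste0("p", 1:6), each = 5)
  a <- array(sample(1:6, 30 * 4 * 2, TRUE), c(30, 4, 2))
  g <- genotype_matrix(a, labs)
  grouping <- setNames(rep(c("g1", "g2", "g3"), each = 2), paste0("p", 1:6))
  res <- amova_three_level(g, grouping, n_permutations = 49L, seed = 1L)
  brute <- amova_ss_brute(g, grouping)
  expect_equal(unname(res$SS), unname(brute), tolerance = 1e-10)
  expect_equal(sum(res$percent), 100, tolerance = 1e-6)
  expect_equal(unname(res$df), c(2L, 3L, 24L))
})

test_that("AMOVA under panmixia puts the variance within populations", {
  set.seed(6)
  a <- array(sample(1:8, 200 * 20 * 2, TRUE), c(200, 20, 2))
  g <- genotype_matrix(a, rep(paste0("p", 1:8), each = 25))
  grouping <- setNames(rep(c("g1", "g2"), each = 4), paste0("p", 1:8))
  res <- amova_three_level(g, grouping, n_permutations = 99L, seed = 2L)
  pc <- res$percent
  expect_lt(pc[["among_groups"]], 5)
  expect_lt(pc[["among_pops_within_groups"]], 5)
  expect_gt(res$p_values[["phi_ST"]], 0.05)
})

test_that("AMOVA within-population share falls as drift rises", {
  within_pc <- vapply(c(0.05, 0.2, 0.5), function(F) {
    sim <- simulate_genotypes(simulate_spec <- simulation_spec(
      two_clade_tree(2L, f_deep = F, f_shallow = F, size = 12L),
      n_loci = 10L, seed = 31L))
    grouping <- setNames(c("gA", "gA", "gB", "gB"), c("A1", "A2", "B1", "B2"))
    amova_three_level(sim$genotypes, grouping, n_permutations = 19L,
                      seed = 3L)$percent[["within_pops"]]
  }, 0)
  expect_true(all(diff(within_pc) < 0))
})

test_that("single-group AMOVA degenerates to two levels", {
  g <- random_matrix(n = 24L, n_loci = 4L, n_pops = 3L, seed = 7L)
  grouping <- setNames(rep("g1", 3), populations(g))
  res <- amova_three_level(g, grouping, n_permutations = 19L, seed = 4L)
  expect_true(res$two_level)
  expect_length(res$percent, 2L)
  expect_equal(sum(res$percent), 100, tolerance = 1e-6)
})

test_that("UPGMA: hand example, 2-taxon case, hclust oracle", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ut <- upgma(distance_matrix(m))
  expect_equal(ut$newick, "((A:1,B:1):1,C:2);")

  m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  u2 <- upgma(m2)
  expect_equal(sort(u2$phylo$edge.length), c(1.5, 1.5))

  # random <=6-taxon matrices against stats::hclust average linkage
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:6, 1)
    x <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    ut <- upgma(d)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(ut$height, hc$height, tolerance = 1e-12)
    # identical topologies: same leaf partitions at every merge
    part <- function(merge, i) sort(hierstruct:::merge_leaves(
      list(merge = merge), i))
    for (i in seq_len(n - 1))
      expect_identical(part(ut$merge, i), part(hc$merge, i))
  }
})

test_that("UPGMA on an ultrametric input returns that tree", {
  # build an ultrametric matrix from a known tree and re-estimate it
  m <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ut <- upgma(m)
  expect_equal(sort(ut$height), c(1, 2, 4))
  d2 <- ape::cophenetic.phylo(ut$phylo)  # path lengths = original distances
  expect_equal(d2[LETTERS[1:4], LETTERS[1:4]], m, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("PCoA: two-point hand example, Euclidean recovery, equivariance", {
  m <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- pcoa(m)
  expect_equal(unname(sort(res$coordinates[, 1])), c(-2, 2))
  expect_equal(res$eigenvalues[1], 8)
  expect_equal(res$percent_variance[1], 100)

  set.seed(8)
  x <- matrix(rnorm(10), 5)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("t", 1:5), paste0("t", 1:5))
  res <- pcoa(d)
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # eigenvalue sum equals trace of the centered matrix
  A <- -0.5 * d^2; J <- diag(5) - 1 / 5
  expect_equal(sum(res$eigenvalues), sum(diag(J %*% A %*% J)),
               tolerance = 1e-9)
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  res_p <- pcoa(d[perm, perm])
  expect_equal(abs(res_p$coordinates), abs(res$coordinates[perm, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("fst summary matches brute force and handles one pair", {
  m <- matrix(c(0, .2, .4, .2, 0, .3, .4, .3, 0), 3,
              dimnames = list(1:3, 1:3))
  s <- fst_distribution_summary(m)
  v <- c(.2, .4, .3)
  expect_equal(s$min, min(v)); expect_equal(s$max, max(v))
  expect_equal(s$mean, mean(v)); expect_equal(s$sd, sd(v))
  one <- matrix(c(0, .2, .2, 0), 2, dimnames = list(1:2, 1:2))
  s1 <- fst_distribution_summary(one)
  expect_equal(s1$min, s1$max)
  expect_equal(s1$mean, 0.2)
})

test_that("distance matrices from genotypes are well-formed", {
  sim <- two_deme_sim(gst = 0.3, size = 15L, n_loci = 10L, seed = 41L)
  g <- sim$genotypes
  fm <- fst_matrix(g)
  expect_s3_class(fm, "distance_matrix")
  expect_equal(fm$m, t(fm$m))
  nm <- nei_matrix(g, variant = "unbiased")
  expect_true(all(diag(nm$m) == 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(fm, f)
  back <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(back[[2]][1], 0)
})
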