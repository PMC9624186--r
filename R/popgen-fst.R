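# Pairwise differentiation estimators, the island-model Nm conversion, and
# distance-matrix plumbing shared by UPGMA / PCoA.

#' Symmetric population distance matrix
#'
#' @param m square numeric matrix (symmetric, zero diagonal) with population
#'   labels as dimnames.
#' @param statistic name of the statistic the entries hold.
#' @return an object of class `distance_matrix`.
#' @export
distance_matrix <- function(m, statistic = "distance") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (is.null(rownames(m))) stop("population labels (dimnames) required")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) stop("matrix must be symmetric")
  diag(m) <- 0
  if (any(m < 0, na.rm = TRUE) && statistic != "theta")
    stop("negative entries in a ", statistic, " matrix")
  structure(list(labels = rownames(m), m = m, statistic = statistic),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d populations\n", x$statistic,
              length(x$labels)))
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param d a [distance_matrix()]; @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(cbind(population = d$labels, as.data.frame(d$m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Weir-Cockerham (1984) per-locus, per-allele variance components for a set
# of populations; returns the a, b, c sums over alleles and loci.
wc_components <- function(g, pops) {
  suba <- g$alleles[g$pop_labels %in% pops, , , drop = FALSE]
  labs <- g$pop_labels[g$pop_labels %in% pops]
  A <- B <- C <- 0
  any_locus <- FALSE
  for (l in seq_len(dim(suba)[2])) {
    a1 <- suba[, l, 1]; a2 <- suba[, l, 2]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    ni <- vapply(pops, function(p) sum(ok & labs == p), 0)
    if (any(ni == 0)) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2L) next
    any_locus <- TRUE
    r <- length(pops)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (u in alleles) {
      pi_ <- vapply(pops, function(p) {
        rows <- ok & labs == p
        (sum(a1[rows] == u) + sum(a2[rows] == u)) / (2 * sum(rows))
      }, 0)
      hi <- vapply(pops, function(p) {
        rows <- ok & labs == p
        mean((a1[rows] == u) != (a2[rows] == u))
      }, 0)
      pbar <- sum(ni * pi_) / (r * nbar)
      s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      if (nbar <= 1) next
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  if (!any_locus) stop("no shared polymorphic locus: F_ST undefined")
  list(a = A, b = B, c = C)
}

#' Pairwise F_ST between two populations
#'
#' Default estimator is the Weir-Cockerham theta (ratio of summed variance
#' components over alleles and loci; may be slightly negative and is
#' reported raw). `"gst"` gives Nei's G_ST from the two populations' sample
#' frequencies, bounded in `[0, 1]`.
#'
#' @param g a [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @param estimator `"wc"` (theta, default) or `"gst"`.
#' @return scalar.
#' @export
pairwise_fst <- function(g, pop_a, pop_b, estimator = c("wc", "gst")) {
  estimator <- match.arg(estimator)
  if (!all(c(pop_a, pop_b) %in% g$pop_labels)) stop("unknown population label")
  if (pop_a == pop_b) stop("pop_a and pop_b must differ")
  if (estimator == "wc") {
    comp <- wc_components(g, c(pop_a, pop_b))
    tot <- comp$a + comp$b + comp$c
    if (tot == 0) stop("zero total variance: F_ST undefined")
    return(comp$a / tot)
  }
  af <- allele_frequencies(subset_genotypes(g, pops = c(pop_a, pop_b)))
  fl <- lapply(c(pop_a, pop_b), function(p) af$freq[[p]])
  L <- n_loci(g)
  Hs <- Ht <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    pa <- fl[[1]][[l]]; pb <- fl[[2]][[l]]
    if (is.null(pa) || is.null(pb)) next
    all_alleles <- union(names(pa), names(pb))
    va <- stats::setNames(rep(0, length(all_alleles)), all_alleles)
    vb <- va
    va[names(pa)] <- pa; vb[names(pb)] <- pb
    Hs[l] <- mean(c(1 - sum(va^2), 1 - sum(vb^2)))
    pm <- (va + vb) / 2
    Ht[l] <- 1 - sum(pm^2)
  }
  ok <- !is.na(Ht)
  if (!any(ok) || mean(Ht[ok]) <= 0) stop("no polymorphism: G_ST undefined")
  (mean(Ht[ok]) - mean(Hs[ok])) / mean(Ht[ok])
}

#' Overall (multi-population) Weir-Cockerham theta
#'
#' Theta over an arbitrary set of populations: the ratio of the summed
#' among-population variance components to the total, over alleles and
#' loci. With many demes drifted independently at intensity `F` from a
#' common ancestor, theta estimates `F`.
#'
#' @param g a [genotype_matrix()].
#' @param pops population labels (default all).
#' @return scalar theta (may be slightly negative; reported raw).
#' @export
wc_theta <- function(g, pops = populations(g)) {
  if (length(pops) < 2L) stop("need >= 2 populations")
  comp <- wc_components(g, pops)
  tot <- comp$a + comp$b + comp$c
  if (tot == 0) stop("zero total variance: theta undefined")
  comp$a / tot
}

#' All pairwise F_ST values as a distance matrix
#'
#' @param g a [genotype_matrix()].
#' @param estimator as in [pairwise_fst()].
#' @return a [distance_matrix()] (statistic `"theta"` or `"gst"`). Negative
#'   theta estimates are floored at 0 for the distance-matrix use; raw
#'   values are kept in the `raw` attribute.
#' @export
fst_matrix <- function(g, estimator = c("wc", "gst")) {
  estimator <- match.arg(estimator)
  pops <- populations(g)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    v <- pairwise_fst(g, pops[i], pops[j], estimator)
    m[i, j] <- m[j, i] <- v
  }
  raw <- m
  m[m < 0] <- 0
  d <- distance_matrix(m, statistic = if (estimator == "wc") "theta" else "gst")
  attr(d, "raw") <- raw
  d
}

#' Island-model gene flow from F_ST
#'
#' `Nm = (1 - F_ST) / (4 F_ST)`: the effective number of migrants per
#' generation under the infinite-island equilibrium.
#'
#' @param fst scalar in `(0, 1]`.
#' @return non-negative scalar.
#' @export
nm_from_fst <- function(fst) {
  if (is.na(fst) || fst <= 0)
    stop("F_ST <= 0: gene flow is unbounded (Nm undefined)")
  if (fst > 1) stop("F_ST > 1 is not a fixation index")
  (1 - fst) / (4 * fst)
}

#' Summary of the pairwise F_ST distribution
#'
#' @param d a [distance_matrix()] of F_ST values (or a square matrix).
#' @return list `(min, max, mean, sd, n_pairs)` over the upper triangle.
#' @export
fst_distribution_summary <- function(d) {
  m <- if (inherits(d, "distance_matrix")) {
    if (!is.null(attr(d, "raw"))) attr(d, "raw") else d$m
  } else as.matrix(d)
  v <- m[upper.tri(m)]
  if (!length(v)) stop("need >= 1 population pair")
  list(min = min(v), max = max(v), mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n_pairs = length(v))
}
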