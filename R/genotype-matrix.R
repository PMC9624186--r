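#' Diploid multi-allelic genotype matrix
#'
#' The universal input container: allele calls for `n` diploid individuals at
#' `L` co-dominant loci, with a population label per individual. Allele codes
#' are arbitrary non-negative integers (raw fragment lengths and recoded
#' indices are both legal); missing gene copies are stored as `NA` internally
#' and serialized as `-9` in STRUCTURE files (`000` in GenePop).
#'
#' @param alleles integer array of dim `c(n, L, 2)`; `NA` = missing copy.
#' @param pop_labels character vector of length `n`.
#' @param individual_ids unique character vector of length `n`; autogenerated
#'   (`ind1..indn`) when `NULL`.
#' @param locus_names character vector of length `L`; autogenerated when
#'   `NULL`.
#' @return An object of class `genotype_matrix` with fields
#'   `individual_ids`, `pop_labels`, `alleles`, `locus_names`.
#' @export
genotype_matrix <- function(alleles, pop_labels, individual_ids = NULL,
                            locus_names = NULL) {
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("alleles must be an n x L x 2 array (ploidy is fixed at 2)")
  n <- dim(alleles)[1]; L <- dim(alleles)[2]
  if (is.null(individual_ids)) individual_ids <- sprintf("ind%d", seq_len(n))
  if (is.null(locus_names)) locus_names <- sprintf("locus%d", seq_len(L))
  storage.mode(alleles) <- "integer"
  g <- structure(list(individual_ids = as.character(individual_ids),
                      pop_labels = as.character(pop_labels),
                      alleles = alleles,
                      locus_names = as.character(locus_names)),
                 class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  n <- dim(g$alleles)[1]; L <- dim(g$alleles)[2]
  if (length(g$individual_ids) != n) stop("individual_ids length mismatch")
  if (anyDuplicated(g$individual_ids)) stop("individual_ids must be unique")
  if (length(g$pop_labels) != n) stop("pop_labels length mismatch")
  if (length(g$locus_names) != L) stop("locus_names length mismatch")
  if (any(g$alleles < 0L, na.rm = TRUE))
    stop("allele codes must be non-negative integers")
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals, %d loci, %d populations\n",
              n_individuals(x), n_loci(x), length(unique(x$pop_labels))))
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing gene copies: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_individuals <- function(g) dim(g$alleles)[1]

#' @rdname genotype_matrix
#' @export
n_loci <- function(g) dim(g$alleles)[2]

#' @rdname genotype_matrix
#' @export
populations <- function(g) unique(g$pop_labels)

#' Subset a genotype matrix by individuals or populations
#'
#' Retains individuals in their original order; loci are unchanged. This is
#' the primitive both the hierarchical recursion and the subsampling
#' experiments rely on.
#'
#' @param g a [genotype_matrix()].
#' @param individuals integer indices of individuals to keep (optional).
#' @param pops population labels to keep (optional). Exactly one of
#'   `individuals` / `pops` must be given.
#' @return a `genotype_matrix` with the retained individuals.
#' @export
subset_genotypes <- function(g, individuals = NULL, pops = NULL) {
  if (is.null(individuals) == is.null(pops))
    stop("give exactly one of `individuals` or `pops`")
  if (!is.null(pops)) {
    pops <- unique(as.character(pops))
    unknown <- setdiff(pops, g$pop_labels)
    if (length(unknown))
      stop("unknown population label(s): ", paste(unknown, collapse = ", "))
    keep <- which(g$pop_labels %in% pops)
  } else {
    individuals <- unique(as.integer(individuals))
    if (length(individuals) == 0L) stop("empty individual set")
    if (any(individuals < 1L | individuals > n_individuals(g)))
      stop("individual index out of range")
    keep <- sort(individuals)
  }
  genotype_matrix(g$alleles[keep, , , drop = FALSE],
                  g$pop_labels[keep], g$individual_ids[keep], g$locus_names)
}

#' Per-population allele frequencies
#'
#' Relative allele frequencies per (population, locus), computed over
#' observed (non-missing) gene copies only. These are the inputs to F_ST,
#' Nei distances and the AMOVA.
#'
#' @param g a [genotype_matrix()].
#' @return An object of class `allele_freq_table`: a list with `freq` (a list
#'   `freq[[pop]][[locus]]` of named frequency vectors, absent when a
#'   population has no calls at a locus) and `sample_size` (pop x locus
#'   matrix of observed gene copies).
#' @export
allele_frequencies <- function(g) {
  if (all(is.na(g$alleles))) stop("no non-missing calls anywhere")
  pops <- populations(g)
  L <- n_loci(g)
  sizes <- matrix(0L, length(pops), L, dimnames = list(pops, g$locus_names))
  freq <- vector("list", length(pops)); names(freq) <- pops
  for (p in pops) {
    rows <- g$pop_labels == p
    fl <- vector("list", L); names(fl) <- g$locus_names
    for (l in seq_len(L)) {
      a <- c(g$alleles[rows, l, 1], g$alleles[rows, l, 2])
      a <- a[!is.na(a)]
      sizes[p, l] <- length(a)
      if (length(a)) {
        tab <- table(a)
        fl[[l]] <- stats::setNames(as.numeric(tab) / length(a), names(tab))
      }
    }
    freq[[p]] <- fl
  }
  structure(list(freq = freq, sample_size = sizes,
                 pops = pops, locus_names = g$locus_names),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d loci\n",
              length(x$pops), length(x$locus_names)))
  invisible(x)
}

# dense per-locus recoding to 0..J_l-1 (used by the MCMC); alleles absent
# from the given matrix are dropped from the code space
dense_recode <- function(g) {
  n <- n_individuals(g); L <- n_loci(g)
  geno <- matrix(NA_integer_, n, 2L * L)
  nalleles <- integer(L)
  codes <- vector("list", L)
  for (l in seq_len(L)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    lev <- sort(unique(c(a1, a2)))
    lev <- lev[!is.na(lev)]
    if (length(lev) == 0L) lev <- 0L  # all-missing locus: 1 dummy allele
    codes[[l]] <- lev
    nalleles[l] <- max(length(lev), 1L)
    geno[, 2L * l - 1L] <- match(a1, lev) - 1L
    geno[, 2L * l] <- match(a2, lev) - 1L
  }
  list(geno = geno, nalleles = nalleles, codes = codes)
}
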