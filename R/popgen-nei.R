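#' Nei's genetic distance between two populations
#'
#' Standard variant (Nei 1972): `D = -ln I` with
#' `I = sum_l J_ab / sqrt(sum_l J_a * sum_l J_b)`, where `J_a = sum_j p_aj^2`
#' etc. are per-locus gene identities. The unbiased variant (Nei 1978)
#' replaces the within-population identities by
#' `(2 n sum p^2 - 1) / (2 n - 1)` and may dip below 0 (reported raw).
#'
#' @param freqs_a,freqs_b per-locus lists of named frequency vectors (as in
#'   `allele_frequencies(g)$freq[[pop]]`); loci with a missing entry in
#'   either population are skipped.
#' @param variant `"standard"` (default) or `"unbiased"`.
#' @param n_a,n_b per-locus gene-copy sample sizes (vectors or scalars),
#'   required for the unbiased variant.
#' @return scalar `D`; `+Inf` when no alleles are shared anywhere.
#' @export
nei_distance <- function(freqs_a, freqs_b, variant = c("standard", "unbiased"),
                         n_a = NULL, n_b = NULL) {
  variant <- match.arg(variant)
  L <- length(freqs_a)
  if (length(freqs_b) != L) stop("populations must share the locus set")
  if (variant == "unbiased") {
    if (is.null(n_a) || is.null(n_b))
      stop("the unbiased variant needs gene-copy sample sizes n_a, n_b")
    n_a <- rep_len(n_a, L); n_b <- rep_len(n_b, L)
  }
  Jab <- Ja <- Jb <- 0
  used <- FALSE
  for (l in seq_len(L)) {
    pa <- freqs_a[[l]]; pb <- freqs_b[[l]]
    if (is.null(pa) || is.null(pb)) next
    used <- TRUE
    shared <- intersect(names(pa), names(pb))
    Jab <- Jab + sum(pa[shared] * pb[shared])
    ja <- sum(pa^2); jb <- sum(pb^2)
    if (variant == "unbiased") {
      ja <- (n_a[l] * ja - 1) / (n_a[l] - 1)
      jb <- (n_b[l] * jb - 1) / (n_b[l] - 1)
    }
    Ja <- Ja + ja; Jb <- Jb + jb
  }
  if (!used) stop("no locus with data in both populations")
  if (Jab <= 0) return(Inf)
  I <- Jab / sqrt(Ja * Jb)
  -log(I)
}

#' Nei distance matrix over all populations
#'
#' @param g a [genotype_matrix()].
#' @param variant as in [nei_distance()]; the unbiased variant draws its
#'   sample sizes from the observed gene-copy counts.
#' @return a [distance_matrix()]. Unbiased estimates below 0 are floored at
#'   0 for matrix use (raw values in the `raw` attribute).
#' @export
nei_matrix <- function(g, variant = c("standard", "unbiased")) {
  variant <- match.arg(variant)
  af <- allele_frequencies(g)
  pops <- af$pops
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    v <- nei_distance(af$freq[[pops[i]]], af$freq[[pops[j]]], variant,
                      n_a = af$sample_size[pops[i], ],
                      n_b = af$sample_size[pops[j], ])
    m[i, j] <- m[j, i] <- v
  }
  raw <- m
  m[m < 0] <- 0
  d <- distance_matrix(m, statistic = paste0("nei_", variant))
  attr(d, "raw") <- raw
  d
}
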