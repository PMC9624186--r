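#' Rooted deme tree with per-branch drift parameters
#'
#' The scaffold of the F-model simulator: a rooted tree whose tips are demes
#' (populations) and whose branch lengths are drift parameters `F` in (0,1)
#' — the intensity of Dirichlet drift applied along that branch. Leaves
#' carry diploid sample sizes and, optionally, clade/subclade tags used by
#' the clade-composition experiment.
#'
#' @param newick rooted tree in Newick notation with branch lengths holding
#'   the drift parameters `F` (all strictly inside (0,1)).
#' @param sizes named integer vector: diploid individuals per leaf label
#'   (all `>= 1`); a single unnamed value is recycled to all leaves.
#' @param clades optional named character vector tagging each leaf with a
#'   clade label.
#' @param subclades optional named character vector tagging each leaf with a
#'   subclade label.
#' @return an object of class `deme_tree` wrapping an [ape::read.tree()]
#'   phylo plus the per-leaf metadata.
#' @export
deme_tree <- function(newick, sizes, clades = NULL, subclades = NULL) {
  phy <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(phy)) stop("could not parse Newick tree")
  if (length(phy$tip.label) < 2L) stop("deme tree needs >= 2 leaves")
  if (anyDuplicated(phy$tip.label)) stop("leaf labels must be unique")
  if (is.null(phy$edge.length)) stop("branch lengths (drift F) are required")
  if (any(phy$edge.length <= 0 | phy$edge.length >= 1))
    stop("all drift parameters F must lie strictly inside (0, 1)")
  if (length(sizes) == 1L && is.null(names(sizes)))
    sizes <- stats::setNames(rep(as.integer(sizes), length(phy$tip.label)),
                             phy$tip.label)
  if (!all(phy$tip.label %in% names(sizes)))
    stop("every leaf needs a sample size")
  sizes <- as.integer(sizes[phy$tip.label])
  names(sizes) <- phy$tip.label
  if (any(sizes < 1L)) stop("sample sizes must be >= 1")
  check_tags <- function(tags, what) {
    if (is.null(tags)) return(NULL)
    if (!all(phy$tip.label %in% names(tags)))
      stop("every leaf needs a ", what, " tag (or none)")
    tags[phy$tip.label]
  }
  structure(list(phylo = phy, sizes = sizes,
                 clades = check_tags(clades, "clade"),
                 subclades = check_tags(subclades, "subclade")),
            class = "deme_tree")
}

#' @export
print.deme_tree <- function(x, ...) {
  cat(sprintf("deme_tree: %d demes, %d total diploid individuals\n",
              length(x$sizes), sum(x$sizes)))
  if (!is.null(x$clades))
    cat("  clades:", paste(sprintf("%s(%d)", names(table(x$clades)),
                                   table(x$clades)), collapse = " "), "\n")
  invisible(x)
}

#' Simulation specification for the F-model genotype simulator
#'
#' Bundles everything [simulate_genotypes()] needs. Defaults mirror a
#' microsatellite survey: 12 multi-allelic loci with 8 possible alleles
#' each, ancestral frequencies from a symmetric Dirichlet, and a small rate
#' of genotype-level dropout.
#'
#' @param tree a [deme_tree()].
#' @param n_loci number of loci (>= 1).
#' @param alleles_per_locus `J_l`, recycled to `n_loci`; every `J_l >= 2`.
#' @param lambda_anc symmetric Dirichlet concentration for the ancestral
#'   (root) allele frequencies; > 0.
#' @param missing_rate probability that a (individual, locus) genotype is
#'   missing (both copies dropped), in `[0, 1)`.
#' @param seed integer seed; all downstream draws are derived from it.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, n_loci = 12L, alleles_per_locus = 8L,
                            lambda_anc = 1.0, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(tree, "deme_tree"))
  if (n_loci < 1L) stop("n_loci must be >= 1")
  J <- rep_len(as.integer(alleles_per_locus), n_loci)
  if (any(J < 2L)) stop("every locus needs >= 2 possible alleles")
  if (lambda_anc <= 0) stop("lambda_anc must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  structure(list(tree = tree, n_loci = as.integer(n_loci),
                 alleles_per_locus = J, lambda_anc = lambda_anc,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Study-mimic deme tree: 38 demes in four deep clades
#'
#' A ready-made [deme_tree()] emulating a strongly subdivided shrub
#' metapopulation: four deep clades of 4, 9, 23 and 2 demes; the 9-deme
#' clade splits into subclades of 6 and 3, the 23-deme clade into subclades
#' of 11, 11 and 1. Deep branches carry `F = 0.35` so that between-clade
#' differentiation lands in the 0.37-0.74 G_ST band typical of highly
#' fragmented populations; subclade branches carry `F = 0.12` and terminal
#' branches `F = 0.10` (`F = 0.20` for leaves attached directly to a clade
#' root) so that within-clade differentiation sits near 0.1-0.3. Sample
#' sizes are drawn uniformly from 9..33 diploids per deme.
#'
#' Drift composes along a root-to-leaf path as `1 - prod(1 - F_edge)`,
#' giving each deme a total drift `F_tot`; the pairwise Weir-Cockerham
#' theta of two demes is roughly the mean of their `F_tot` since their
#' common ancestor, while the two-deme Nei G_ST is the smaller
#' `F_tot / (2 - F_tot)`. The defaults — terminal `F = 0.40`, subclade
#' `F = 0.15`, `F = 0.45` for leaves attached directly to a clade root,
#' deep `F = 0.25` — put every pairwise theta inside the 0.37-0.74 band
#' that characterises this kind of extremely fragmented metapopulation
#' (within-subclade about 0.40, between clades about 0.59-0.66) while
#' keeping within-clade pairwise G_ST near 0.25-0.32 and between-clade
#' G_ST near 0.45. The hierarchy is deliberately shallow-but-everywhere:
#' every deme is strongly differentiated from every other, with clade
#' membership adding a further increment on top.
#'
#' @param seed seed for the sample-size draw.
#' @return a [deme_tree()] with clade (`I`..`IV`) and subclade tags.
#' @export
study_mimic_tree <- function(seed = 1L) {
  f_deep <- 0.25; f_sub <- 0.15; f_leaf <- 0.40; f_direct <- 0.45
  leaf <- function(ids, F) paste0(ids, ":", F)
  clade_of_leaves <- function(ids, Fleaf, Fclade)
    paste0("(", paste(leaf(ids, Fleaf), collapse = ","), "):", Fclade)
  subclade <- function(ids)
    if (length(ids) == 1L) leaf(ids, 1 - (1 - f_sub) * (1 - f_leaf))
    else paste0("(", paste(leaf(ids, f_leaf), collapse = ","), "):", f_sub)

  p <- paste0("P", sprintf("%02d", 1:38))
  cI <- p[1:4]                       # 4 demes, no subclades
  cII_a <- p[5:10]; cII_b <- p[11:13]    # 9 demes: 6 + 3
  cIII_a <- p[14:24]; cIII_b <- p[25:35]; cIII_c <- p[36]  # 23: 11 + 11 + 1
  cIV <- p[37:38]                    # 2 demes

  nwk <- paste0("(",
    clade_of_leaves(cI, f_direct, f_deep), ",",
    "(", subclade(cII_a), ",", subclade(cII_b), "):", f_deep, ",",
    "(", subclade(cIII_a), ",", subclade(cIII_b), ",",
         subclade(cIII_c), "):", f_deep, ",",
    clade_of_leaves(cIV, f_direct, f_deep),
    ");")

  clades <- stats::setNames(rep(c("I", "II", "III", "IV"),
                                c(4L, 9L, 23L, 2L)), p)
  subclades <- stats::setNames(c(rep("I.a", 4), rep("II.a", 6), rep("II.b", 3),
                                 rep("III.a", 11), rep("III.b", 11), "III.c",
                                 rep("IV.a", 2)), p)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 38L))
  sizes <- stats::setNames(sample(9:33, 38, replace = TRUE), p)
  deme_tree(nwk, sizes, clades = clades, subclades = subclades)
}

# save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
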