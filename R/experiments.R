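# Meta-experiments on delta-K behaviour: how the selected K* responds to
# (1) the number of randomly sampled populations and (2) the clade
# composition of small (4-population) samples.

#' Design of the population-number subsampling experiment
#'
#' @param levels numbers of populations to draw (default
#'   `c(4, 6, 8, 10, 12, 16, 20, 30)`).
#' @param replicates random samples per level (default 10). Every sample
#'   draws populations without replacement.
#' @param seed integer seed.
#' @return an object of class `subsample_design`.
#' @export
subsample_design <- function(levels = c(4L, 6L, 8L, 10L, 12L, 16L, 20L, 30L),
                             replicates = 10L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(levels = as.integer(levels),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "subsample_design")
}

# one K* determination on a subset of populations (single-level scan)
scan_k_star <- function(g_subset, hcfg, node_id) {
  lev <- run_level(g_subset, hcfg, node_id = node_id)
  list(k_star = lev$k_star, table = lev$table)
}

#' Optimal K versus the number of sampled populations
#'
#' For each level, draws `replicates` random population subsets (each
#' population at most once per subset), scans K on each subset and selects
#' `K*` by delta K; summarises `K*` per level.
#'
#' @param g a [genotype_matrix()].
#' @param design a [subsample_design()].
#' @param hcfg a [hier_config()] supplying the per-subset K scan settings
#'   (MCMC config, runs per K, K bounds).
#' @return list with `results` (data.frame: level, replicate, pops, k_star)
#'   and `summary` (per level: min, max, mean, median of `K*`).
#' @export
run_subsample_experiment <- function(g, design, hcfg = hier_config()) {
  stopifnot(inherits(design, "subsample_design"))
  pops <- populations(g)
  if (any(design$levels > length(pops)))
    stop("a level exceeds the number of populations")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  rows <- list()
  for (li in seq_along(design$levels)) {
    lv <- design$levels[li]
    for (r in seq_len(design$replicates)) {
      set.seed(derive_seed(design$seed, li, r))
      chosen <- sample(pops, lv)
      sub <- subset_genotypes(g, pops = chosen)
      res <- scan_k_star(sub, hcfg, node_id = derive_seed(design$seed, li, r, 5L))
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, replicate = r,
        pops = paste(sort(chosen), collapse = ","),
        k_star = res$k_star)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$level), function(df)
    data.frame(level = df$level[1], n = nrow(df),
               min = min(df$k_star, na.rm = TRUE),
               max = max(df$k_star, na.rm = TRUE),
               mean = mean(df$k_star, na.rm = TRUE),
               median = stats::median(df$k_star, na.rm = TRUE),
               prop_k2 = mean(df$k_star == 2, na.rm = TRUE))))
  rownames(summary) <- NULL
  list(results = results, summary = summary[order(summary$level), ])
}

#' Classify a population sample by its clade composition
#'
#' Categories follow the distinct clade count of the sampled populations,
#' refined by the subclade count when exactly two clades are present:
#' `"3-4 clades"`, `"2 clades, 3+ subclades"`, `"2 clades"`, `"1 clade"`.
#'
#' @param sample_pops population labels in the sample.
#' @param annotation data.frame with columns `pop`, `clade`, `subclade`.
#' @return category string.
#' @export
classify_sample_by_clades <- function(sample_pops, annotation) {
  m <- match(sample_pops, annotation$pop)
  if (anyNA(m)) stop("unannotated population(s): ",
                     paste(sample_pops[is.na(m)], collapse = ", "))
  ncl <- length(unique(annotation$clade[m]))
  nsub <- length(unique(annotation$subclade[m]))
  if (ncl >= 3L) "3-4 clades"
  else if (ncl == 2L) {
    if (nsub >= 3L) "2 clades, 3+ subclades" else "2 clades"
  } else "1 clade"
}

#' Clade/subclade annotation from simulator truth
#'
#' @param tree a [deme_tree()] carrying clade and subclade tags.
#' @return data.frame `pop` / `clade` / `subclade`.
#' @export
clade_annotation_from_tree <- function(tree) {
  stopifnot(inherits(tree, "deme_tree"))
  if (is.null(tree$clades) || is.null(tree$subclades))
    stop("deme tree carries no clade/subclade tags")
  data.frame(pop = names(tree$sizes),
             clade = unname(tree$clades[names(tree$sizes)]),
             subclade = unname(tree$subclades[names(tree$sizes)]),
             row.names = NULL)
}

#' Design of the clade-composition experiment
#'
#' @param n_samples number of random 4-population samples (default 60).
#' @param seed integer seed.
#' @return an object of class `clade_design`.
#' @export
clade_design <- function(n_samples = 60L, seed = 1L) {
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "clade_design")
}

#' Optimal K versus clade composition of 4-population samples
#'
#' Draws random 4-population samples, determines each sample's `K*` and
#' mean pairwise F_ST, classifies the sample by clade composition and
#' tabulates per category: sample count, count with `K* = 2`, mean `K*`,
#' mean and s.d. of F_ST.
#'
#' @param g a [genotype_matrix()].
#' @param design a [clade_design()].
#' @param annotation clade annotation, e.g. [clade_annotation_from_tree()]
#'   or [cut_upgma_clades()].
#' @param hcfg a [hier_config()] for the K scans.
#' @param fst_estimator passed to [pairwise_fst()].
#' @return list with `results` (one row per sample) and `summary` (one row
#'   per category; empty categories reported with n = 0).
#' @export
run_clade_experiment <- function(g, design, annotation,
                                 hcfg = hier_config(),
                                 fst_estimator = "wc") {
  stopifnot(inherits(design, "clade_design"))
  pops <- populations(g)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  rows <- list()
  for (s in seq_len(design$n_samples)) {
    set.seed(derive_seed(design$seed, 31L, s))
    chosen <- sample(pops, 4L)
    sub <- subset_genotypes(g, pops = chosen)
    res <- scan_k_star(sub, hcfg, node_id = derive_seed(design$seed, 31L, s, 5L))
    prs <- utils::combn(chosen, 2L)
    fsts <- vapply(seq_len(ncol(prs)), function(j)
      pairwise_fst(sub, prs[1, j], prs[2, j], fst_estimator), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, pops = paste(sort(chosen), collapse = ","),
      category = classify_sample_by_clades(chosen, annotation),
      k_star = res$k_star, mean_fst = mean(fsts))
  }
  results <- do.call(rbind, rows)
  cats <- c("3-4 clades", "2 clades, 3+ subclades", "2 clades", "1 clade")
  summary <- do.call(rbind, lapply(cats, function(cat) {
    df <- results[results$category == cat, , drop = FALSE]
    data.frame(category = cat, n = nrow(df),
               n_k2 = sum(df$k_star == 2, na.rm = TRUE),
               mean_k = if (nrow(df)) mean(df$k_star, na.rm = TRUE) else NA_real_,
               mean_fst = if (nrow(df)) mean(df$mean_fst) else NA_real_,
               sd_fst = if (nrow(df) > 1L) stats::sd(df$mean_fst) else NA_real_)
  }))
  list(results = results, summary = summary)
}

#' Cut an UPGMA tree into clades and subclades
#'
#' The clade cut is the height that yields exactly `n_clades` subtrees
#' (i.e. between the `n_clades`-th and `(n_clades - 1)`-th highest merge).
#' When tied merge heights make that count unattainable the nearest
#' attainable count is used and flagged. Subclades come from one further
#' split: each clade with at least two leaves is divided into the two
#' subtrees below its root merge.
#'
#' @param ut an [upgma()] result.
#' @param n_clades requested number of clades (2..leaves).
#' @return data.frame `pop` / `clade` / `subclade` with attribute
#'   `attained` (the realized clade count).
#' @export
cut_upgma_clades <- function(ut, n_clades) {
  stopifnot(inherits(ut, "upgma_tree"))
  n <- length(ut$labels)
  if (n_clades < 2L || n_clades > n) stop("n_clades must lie in 2..leaves")
  hc <- ut$hclust
  cl <- stats::cutree(hc, k = n_clades)
  attained <- length(unique(cl))
  if (attained != n_clades)
    warning("tied merge heights: attained ", attained, " clades instead of ",
            n_clades)
  # subclades: split each clade at its root merge into two subtrees
  sub <- paste0(cl, ".a")
  for (k in unique(cl)) {
    leaves <- which(cl == k)
    if (length(leaves) < 2L) next
    # the clade's root merge is the last merge joining only its leaves
    members <- lapply(seq_len(nrow(hc$merge)), function(i) merge_leaves(hc, i))
    inside <- which(vapply(members, function(mm)
      all(mm %in% leaves), TRUE))
    root_merge <- inside[which.max(hc$height[inside])]
    left <- merge_members_side(hc, root_merge, 1L)
    sub[leaves] <- ifelse(leaves %in% left, paste0(k, ".a"), paste0(k, ".b"))
  }
  out <- data.frame(pop = ut$labels, clade = as.character(cl), subclade = sub,
                    row.names = NULL)
  attr(out, "attained") <- attained
  out
}

merge_leaves <- function(hc, i) {
  out <- integer()
  for (v in hc$merge[i, ]) {
    if (v < 0) out <- c(out, -v) else out <- c(out, merge_leaves(hc, v))
  }
  out
}

merge_members_side <- function(hc, i, side) {
  v <- hc$merge[i, side]
  if (v < 0) -v else merge_leaves(hc, v)
}
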