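#' Configuration of the hierarchical clustering pipeline
#'
#' @param mcmc an [mcmc_config()] template; K and seed are overridden per
#'   run.
#' @param runs_per_k replicate runs at each K (>= 2; delta K needs an s.d.).
#' @param k_max global upper bound of the K scan (top-level convention: 12).
#' @param k_slack each node scans K up to
#'   `min(k_max, n_pops_in_subset + k_slack)`.
#' @param min_individuals subsets smaller than this are terminal.
#' @param min_cluster_size clusters smaller than this dissolve; their
#'   members are reported unassigned and excluded from deeper levels.
#' @param q_threshold terminal when the mean over individuals of their
#'   maximum admixture proportion falls below this (the symmetric-Q
#'   signature of no real structure).
#' @param max_depth recursion depth cap (top level = 1).
#' @param assignment `"individual"` (argmax-q per individual, default) or
#'   `"population"` (each population follows the majority vote of its
#'   individuals).
#' @param seed master seed; all per-run seeds derive from it.
#' @return an object of class `hier_config`.
#' @export
hier_config <- function(mcmc = mcmc_config(), runs_per_k = 5L, k_max = 12L,
                        k_slack = 3L, min_individuals = 10L,
                        min_cluster_size = 5L, q_threshold = 0.6,
                        max_depth = 8L,
                        assignment = c("individual", "population"),
                        seed = 1L) {
  if (runs_per_k < 2L) stop("runs_per_k must be >= 2 (delta K needs an s.d.)")
  if (k_max < 3L) stop("k_max must be >= 3 to give delta K an interior K")
  structure(list(mcmc = mcmc, runs_per_k = as.integer(runs_per_k),
                 k_max = as.integer(k_max), k_slack = as.integer(k_slack),
                 min_individuals = as.integer(min_individuals),
                 min_cluster_size = as.integer(min_cluster_size),
                 q_threshold = q_threshold, max_depth = as.integer(max_depth),
                 assignment = match.arg(assignment),
                 seed = as.integer(seed)),
            class = "hier_config")
}

#' Scan K for one subset: replicate runs, delta-K table, best run
#'
#' Runs `runs_per_k` replicate chains at each K in
#' `1..min(k_max, n_pops + k_slack)`, builds the Evanno table, selects `K*`
#' and returns the highest-lnPD run at `K*`.
#'
#' @param g_subset a [genotype_matrix()] (the node's subset).
#' @param cfg a [hier_config()].
#' @param node_id integer distinguishing this node's seed stream.
#' @return list with `table` (a `k_selection_table`), `k_star` (NA on
#'   selection failure), `best_run` (the max-lnPD `structure_run` at `K*`,
#'   NULL on failure) and `runs` (all runs).
#' @export
run_level <- function(g_subset, cfg, node_id = 1L) {
  stopifnot(inherits(cfg, "hier_config"))
  npop <- length(populations(g_subset))
  k_hi <- max(3L, min(cfg$k_max, npop + cfg$k_slack))
  runs <- list()
  for (K in seq_len(k_hi)) {
    for (r in seq_len(cfg$runs_per_k)) {
      mc <- cfg$mcmc
      mc$K <- K
      mc$seed <- derive_seed(cfg$seed, node_id, K, r)
      runs[[length(runs) + 1L]] <- run_mcmc(g_subset, mc)
    }
  }
  tab <- build_k_table(runs)
  k_star <- tryCatch(select_optimal_k(tab), error = function(e) NA_integer_)
  best <- NULL
  if (!is.na(k_star)) {
    at_k <- Filter(function(r) r$config$K == k_star, runs)
    best <- at_k[[which.max(vapply(at_k, function(r) r$lnPD, 0))]]
  }
  list(table = tab, k_star = k_star, best_run = best, runs = runs)
}

#' Partition a subset by argmax admixture proportion
#'
#' Each individual goes to its maximum-q cluster (ties to the lowest
#' cluster index); in `"population"` mode each population follows the
#' majority vote of its individuals. Clusters smaller than
#' `min_cluster_size` dissolve: their members are returned unassigned and
#' do not recurse.
#'
#' @param Q aligned n x K matrix, rows summing to 1.
#' @param pop_labels population label per row (used by population mode).
#' @param cfg a [hier_config()].
#' @return list with `children` (list of integer row-index vectors, one per
#'   retained cluster) and `unassigned` (integer row indices).
#' @export
partition_by_assignment <- function(Q, pop_labels, cfg) {
  n <- nrow(Q); K <- ncol(Q)
  assign_k <- apply(Q, 1L, which.max)  # which.max: ties -> lowest index
  if (cfg$assignment == "population") {
    for (p in unique(pop_labels)) {
      rows <- which(pop_labels == p)
      votes <- tabulate(assign_k[rows], nbins = K)
      assign_k[rows] <- which.max(votes)
    }
  }
  children <- list(); unassigned <- integer()
  for (k in seq_len(K)) {
    rows <- which(assign_k == k)
    if (length(rows) == 0L) next
    if (length(rows) < cfg$min_cluster_size) unassigned <- c(unassigned, rows)
    else children[[length(children) + 1L]] <- rows
  }
  list(children = children, unassigned = sort(unassigned))
}

#' Decide whether a node terminates
#'
#' Terminal when any of: (a) the subset is smaller than `min_individuals`;
#' (b) the depth cap is reached; (c) the mean over individuals of their
#' maximum admixture proportion is below `q_threshold` (symmetric Q = no
#' real structure); (d) K selection failed; (e) every proposed child equals
#' the whole parent subset.
#'
#' @param n_subset subset size.
#' @param depth node depth (top = 1).
#' @param Q the selected run's Q matrix (NULL if unavailable).
#' @param children list of child index vectors from
#'   [partition_by_assignment()] (NULL if unavailable).
#' @param cfg a [hier_config()].
#' @return list `(terminal = flag, reason = string or NA)`.
#' @export
should_terminate <- function(n_subset, depth, Q, children, cfg) {
  if (n_subset < cfg$min_individuals)
    return(list(terminal = TRUE, reason = "too_few_individuals"))
  if (depth >= cfg$max_depth)
    return(list(terminal = TRUE, reason = "max_depth"))
  if (is.null(Q))
    return(list(terminal = TRUE, reason = "selection_failure"))
  if (mean(apply(Q, 1L, max)) < cfg$q_threshold)
    return(list(terminal = TRUE, reason = "no_structure"))
  if (is.null(children) || length(children) == 0L)
    return(list(terminal = TRUE, reason = "all_clusters_dissolved"))
  if (length(children) == 1L && length(children[[1]]) == n_subset)
    return(list(terminal = TRUE, reason = "single_cluster"))
  list(terminal = FALSE, reason = NA_character_)
}

#' Recursive hierarchical structure analysis
#'
#' The core procedure: scan K and pick `K*` by delta K, split the subset by
#' cluster assignment, and recurse into every retained cluster until no
#' subset can be divided further. Terminal nodes are the "genetic
#' components", labeled `C1, C2, ...` in depth-first order.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [hier_config()].
#' @return a `hierarchy_node` tree. Each node carries `individuals` (row
#'   indices into `g`), `pops`, `depth`, `k_table`, `k_star`, `mean_max_q`,
#'   `children`, `unassigned`, `terminal`, `termination_reason`,
#'   `component` (terminal nodes only).
#' @export
run_hierarchical <- function(g, cfg = hier_config()) {
  counter <- new.env()
  counter$node <- 0L
  counter$component <- 0L
  root <- hier_recurse(g, seq_len(n_individuals(g)), 1L, cfg, counter)
  class(root) <- "hierarchy_node"
  root
}

hier_recurse <- function(g, idx, depth, cfg, counter) {
  counter$node <- counter$node + 1L
  node_id <- counter$node
  node <- list(node_id = node_id, individuals = idx,
               pops = unique(g$pop_labels[idx]), depth = depth,
               k_table = NULL, k_star = NA_integer_, mean_max_q = NA_real_,
               children = list(), unassigned = integer(),
               terminal = FALSE, termination_reason = NA_character_,
               component = NA_character_)
  n_subset <- length(idx)

  # cheap rules first: size and depth need no MCMC
  early <- should_terminate(n_subset, depth, NULL, NULL, cfg)
  if (early$terminal && early$reason %in% c("too_few_individuals", "max_depth"))
    return(finish_terminal(node, early$reason, counter))

  sub <- subset_genotypes(g, individuals = idx)
  lev <- run_level(sub, cfg, node_id = node_id)
  node$k_table <- lev$table
  node$k_star <- lev$k_star
  Q <- if (!is.null(lev$best_run)) lev$best_run$Q else NULL
  part <- if (!is.null(Q))
    partition_by_assignment(Q, sub$pop_labels, cfg) else NULL
  if (!is.null(Q)) node$mean_max_q <- mean(apply(Q, 1L, max))

  dec <- should_terminate(n_subset, depth, Q,
                          if (is.null(part)) NULL else part$children, cfg)
  if (dec$terminal) return(finish_terminal(node, dec$reason, counter))

  node$unassigned <- idx[part$unassigned]
  node$children <- lapply(part$children, function(rows)
    hier_recurse(g, idx[rows], depth + 1L, cfg, counter))
  class(node) <- "hierarchy_node"
  node
}

finish_terminal <- function(node, reason, counter) {
  counter$component <- counter$component + 1L
  node$terminal <- TRUE
  node$termination_reason <- reason
  node$component <- paste0("C", counter$component)
  class(node) <- "hierarchy_node"
  node
}

#' @export
print.hierarchy_node <- function(x, ...) {
  cat(sprintf("hierarchical analysis: %d individuals, %d components\n",
              length(x$individuals), count_terminal_components(x)))
  invisible(x)
}

#' Count the terminal "genetic components" of a hierarchy
#' @param tree a [run_hierarchical()] result.
#' @return integer number of terminal nodes.
#' @export
count_terminal_components <- function(tree) {
  if (tree$terminal) return(1L)
  sum(vapply(tree$children, count_terminal_components, 0L))
}

collect_terminals <- function(tree) {
  if (tree$terminal) return(list(tree))
  do.call(c, lapply(tree$children, collect_terminals))
}

#' Per-population component profile and uniqueness fraction
#'
#' For each population, the components its individuals fall in. A
#' population is "unique" iff some component contains individuals of that
#' population only AND a majority of the population's individuals sit in
#' it.
#'
#' @param tree a [run_hierarchical()] result.
#' @param g the [genotype_matrix()] the tree was built from.
#' @return list with `profile` (data.frame population / component /
#'   n_individuals), `unique_populations`, `fraction_unique`.
#' @export
population_component_summary <- function(tree, g) {
  terms <- collect_terminals(tree)
  prof <- do.call(rbind, lapply(terms, function(nd) {
    tab <- table(g$pop_labels[nd$individuals])
    data.frame(population = names(tab), component = nd$component,
               n_individuals = as.integer(tab), row.names = NULL)
  }))
  pops <- populations(g)
  uniq <- logical(length(pops)); names(uniq) <- pops
  for (p in pops) {
    np <- sum(g$pop_labels == p)
    rows <- prof[prof$population == p, , drop = FALSE]
    for (comp in rows$component) {
      comp_rows <- prof[prof$component == comp, , drop = FALSE]
      only_this_pop <- nrow(comp_rows) == 1L && comp_rows$population[1] == p
      majority <- rows$n_individuals[rows$component == comp] > np / 2
      if (only_this_pop && majority) { uniq[p] <- TRUE; break }
    }
  }
  list(profile = prof, unique_populations = names(uniq)[uniq],
       fraction_unique = mean(uniq))
}

#' Flatten a hierarchy to one row per individual
#'
#' @param tree a [run_hierarchical()] result.
#' @param g the source [genotype_matrix()].
#' @return data.frame: individual, population, component (NA when the
#'   individual was left unassigned by a dissolved cluster), path (slash
#'   separated node ids), depth.
#' @export
hierarchy_assignments <- function(tree, g) {
  rows <- list()
  walk <- function(node, path) {
    path <- c(path, node$node_id)
    if (length(node$unassigned))
      rows[[length(rows) + 1L]] <<- data.frame(
        individual = g$individual_ids[node$unassigned],
        population = g$pop_labels[node$unassigned],
        component = NA_character_,
        path = paste(path, collapse = "/"), depth = node$depth)
    if (node$terminal) {
      rows[[length(rows) + 1L]] <<- data.frame(
        individual = g$individual_ids[node$individuals],
        population = g$pop_labels[node$individuals],
        component = node$component,
        path = paste(path, collapse = "/"), depth = node$depth)
    } else for (ch in node$children) walk(ch, path)
  }
  walk(tree, integer())
  out <- do.call(rbind, rows)
  out[order(match(out$individual, g$individual_ids)), , drop = FALSE]
}

#' Serialize a hierarchy as nested JSON
#'
#' @param tree a [run_hierarchical()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hierarchy_json <- function(tree, path) {
  strip <- function(node) {
    list(node_id = node$node_id, pops = node$pops, depth = node$depth,
         n_individuals = length(node$individuals),
         k_star = node$k_star, terminal = node$terminal,
         termination_reason = node$termination_reason,
         component = node$component,
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(tree), path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
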