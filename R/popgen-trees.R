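#' UPGMA clustering of a distance matrix
#'
#' Size-weighted average-linkage agglomeration producing a rooted
#' ultrametric tree: each merge sits at half the between-cluster mean
#' distance, so leaf-to-root heights are equal and merge heights never
#' decrease. Ties merge the lexicographically first pair (by current
#' cluster order).
#'
#' @param d a [distance_matrix()] (or square symmetric matrix with
#'   dimnames), >= 2 taxa, finite non-negative entries.
#' @return An object of class `upgma_tree`: `phylo` ([ape] tree), `newick`
#'   string, `merge`/`height`/`labels` in [stats::hclust()] layout (heights
#'   are the full merge distances, as hclust reports them).
#' @export
upgma <- function(d) {
  m <- if (inherits(d, "distance_matrix")) d$m else as.matrix(d)
  labels <- rownames(m)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 taxa")
  if (any(!is.finite(m)) || any(m < 0)) stop("distances must be finite and >= 0")

  # active clusters: negative = singleton leaf, positive = merge row
  active <- as.list(-seq_len(n))
  sizes <- rep(1L, n)
  cur <- m
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node_of <- seq_len(n)      # column in `cur` per active cluster
  for (step in seq_len(n - 1L)) {
    na <- nrow(cur)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(na - 1L)) for (j in seq((i + 1L), na)) {
      if (cur[i, j] < best[1]) best <- c(cur[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    merge[step, ] <- c(active[[i]], active[[j]])
    height[step] <- best[1]
    # weighted average linkage
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(na), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], step)
  }
  hc <- structure(list(merge = merge, height = height, order = seq_len(n),
                       labels = labels, method = "average"),
                  class = "hclust")
  hc$order <- stats::order.dendrogram(stats::as.dendrogram(hc))
  phy <- hclust_to_ultrametric_phylo(merge, height, labels)
  structure(list(phylo = phy, newick = ape::write.tree(phy),
                 merge = merge, height = height, labels = labels, hclust = hc),
            class = "upgma_tree")
}

# build an ape phylo with leaf depth = merge height / 2 (ultrametric);
# children are ordered by their smallest leaf index for a stable layout
hclust_to_ultrametric_phylo <- function(merge, height, labels) {
  minleaf <- function(node)
    if (node < 0) -node else min(minleaf(merge[node, 1]),
                                 minleaf(merge[node, 2]))
  nwk_of <- function(node) {
    if (node < 0) return(list(str = labels[-node], h = 0))
    kids <- merge[node, ]
    if (minleaf(kids[1]) > minleaf(kids[2])) kids <- rev(kids)
    l <- nwk_of(kids[1]); r <- nwk_of(kids[2])
    h <- height[node] / 2
    list(str = sprintf("(%s:%g,%s:%g)", l$str, h - l$h, r$str, h - r$h),
         h = h)
  }
  top <- nwk_of(nrow(merge))
  ape::read.tree(text = paste0(top$str, ";"))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", x$newick, "\n")
  invisible(x)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates reproduce the input distances exactly when they are
#' Euclidean. Percent variance per axis = eigenvalue over the sum of
#' positive eigenvalues; negative eigenvalues are reported but excluded
#' from the percentages and carry no coordinates.
#'
#' @param d a [distance_matrix()] (or square symmetric matrix with
#'   dimnames).
#' @return list with `coordinates` (taxa x positive axes), `eigenvalues`
#'   (all, descending), `percent_variance` (per positive axis), `labels`.
#' @export
pcoa <- function(d) {
  m <- if (inherits(d, "distance_matrix")) d$m else as.matrix(d)
  labels <- rownames(m)
  n <- nrow(m)
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values
  pos <- which(vals > max(vals[1], 0) * 1e-12 & vals > 0)
  if (!length(pos)) {
    return(list(coordinates = matrix(0, n, 1, dimnames = list(labels, "axis1")),
                eigenvalues = vals, percent_variance = 100, labels = labels))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), nrow = length(pos))
  dimnames(coords) <- list(labels, paste0("axis", seq_along(pos)))
  list(coordinates = coords, eigenvalues = vals,
       percent_variance = 100 * vals[pos] / sum(vals[pos]),
       labels = labels)
}
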