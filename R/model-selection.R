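#' Evanno delta-K table over replicate runs
#'
#' For each K in a consecutive scanned range, summarises the replicate runs'
#' Ln Pr(X|K) estimates: mean `L(K)`, sample s.d. `s(K)` (n - 1
#' denominator, the harvester convention), first difference
#' `L'(K) = L(K) - L(K-1)`, absolute second difference
#' `|L''(K)| = |L(K+1) - 2 L(K) + L(K-1)|`, and
#' `deltaK = |L''(K)| / s(K)`. `L'` is undefined at the smallest K;
#' `|L''|` and `deltaK` are undefined at both ends of the range.
#' `s(K) = 0` with `|L''| > 0` yields `+Inf` with a warning (degenerate
#' replication).
#'
#' @param runs either a list of `structure_run`s (grouped by their config's
#'   K) or a named list of numeric vectors of lnPD values, names = K.
#' @return a `data.frame` of class `k_selection_table` with columns `K`,
#'   `reps`, `mean_lnPD`, `sd_lnPD`, `d1`, `d2_abs`, `delta_K`.
#' @export
build_k_table <- function(runs) {
  if (length(runs) && inherits(runs[[1]], "structure_run")) {
    ks <- vapply(runs, function(r) r$config$K, 0L)
    by_k <- split(vapply(runs, function(r) r$lnPD, 0), ks)
  } else {
    by_k <- runs
    if (is.null(names(by_k))) stop("lnPD lists must be named by K")
  }
  K <- sort(as.integer(names(by_k)))
  if (length(K) < 3L) stop("need >= 3 consecutive K values")
  if (!all(diff(K) == 1L)) stop("scanned K range has gaps: ",
                                paste(K, collapse = ", "))
  by_k <- by_k[as.character(K)]
  reps <- lengths(by_k)
  if (any(reps < 2L))
    stop("need >= 2 runs at every K (s.d. undefined at K = ",
         paste(K[reps < 2L], collapse = ", "), ")")
  m <- vapply(by_k, mean, 0)
  s <- vapply(by_k, stats::sd, 0)
  nk <- length(K)
  d1 <- c(NA, diff(m))
  d2 <- rep(NA_real_, nk)
  dK <- rep(NA_real_, nk)
  for (i in seq(2L, nk - 1L)) {
    d2[i] <- abs(m[i + 1L] - 2 * m[i] + m[i - 1L])
    if (s[i] == 0) {
      dK[i] <- if (d2[i] > 0) Inf else 0
      if (d2[i] > 0)
        warning("s(K) = 0 with |L''| > 0 at K = ", K[i],
                ": delta K is +Inf (degenerate replication)")
    } else dK[i] <- d2[i] / s[i]
  }
  structure(data.frame(K = K, reps = as.integer(reps), mean_lnPD = m,
                       sd_lnPD = s, d1 = d1, d2_abs = d2, delta_K = dK,
                       row.names = NULL),
            class = c("k_selection_table", "data.frame"))
}

#' Select the optimal K by the delta-K argmax
#'
#' `K*` is the interior K maximizing delta K; ties break toward smaller K.
#' Delta K cannot evaluate the boundary Ks (in particular K = 1), so "no
#' further structure" is decided by the hierarchy's termination rules, not
#' here.
#'
#' @param table a [build_k_table()] result.
#' @return integer `K*`.
#' @export
select_optimal_k <- function(table) {
  stopifnot(inherits(table, "k_selection_table"))
  ok <- !is.na(table$delta_K)
  if (!any(ok)) stop("no interior K with a defined delta K")
  if (all(table$sd_lnPD[ok] == 0) && all(table$d2_abs[ok] == 0))
    stop("selection failure: all s(K) = 0 and flat likelihood")
  cand <- table[ok, ]
  cand$K[which.max(cand$delta_K)]  # which.max takes the first (smallest K)
}

#' Serialize a delta-K table in harvester column layout
#'
#' @param table a [build_k_table()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_k_table <- function(table, path) {
  out <- data.frame(K = table$K, Reps = table$reps,
                    `Mean LnP(K)` = table$mean_lnPD,
                    `Stdev LnP(K)` = table$sd_lnPD,
                    `Ln'(K)` = table$d1, `|Ln''(K)|` = table$d2_abs,
                    `Delta K` = table$delta_K, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
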