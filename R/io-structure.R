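#' Read a STRUCTURE-format genotype file
#'
#' Parses the plain-text genotype format used by the STRUCTURE program, in
#' either of its two dialects: one row per individual with two adjacent
#' columns per locus, or two rows per individual with one column per locus.
#' Columns are whitespace-separated: individual id, population column, then
#' allele columns. The missing sentinel `-9` becomes `NA` internally.
#'
#' If a sidecar population-label map written by [write_structure_file()]
#' (`<path>.popmap.tsv`) is present, integer population codes are translated
#' back to their original labels.
#'
#' @param path file to read.
#' @param one_row_per_individual `TRUE` for the one-row dialect (default
#'   `FALSE` = two-row dialect).
#' @param locus_names optional locus names; autogenerated otherwise.
#' @return a [genotype_matrix()].
#' @export
read_structure_file <- function(path, one_row_per_individual = FALSE,
                                locus_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty STRUCTURE file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows in %s: line %d has %d columns, expected %d",
                 path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]))
  nc <- ncols[1]
  if (nc < 3L) stop("need at least id, population and one allele column")
  if (one_row_per_individual) {
    if ((nc - 2L) %% 2L != 0L)
      stop("one-row dialect needs an even number of allele columns")
    L <- (nc - 2L) %/% 2L
    n <- length(toks)
    ids <- vapply(toks, `[[`, "", 1L)
    popcodes <- vapply(toks, `[[`, "", 2L)
    alleles <- array(NA_integer_, c(n, L, 2L))
    for (i in seq_len(n)) {
      v <- suppressWarnings(as.integer(toks[[i]][-(1:2)]))
      if (anyNA(v)) stop(sprintf("non-integer allele on line %d of %s", i, path))
      alleles[i, , 1L] <- v[seq(1L, 2L * L, by = 2L)]
      alleles[i, , 2L] <- v[seq(2L, 2L * L, by = 2L)]
    }
  } else {
    if (length(toks) %% 2L != 0L)
      stop("two-row dialect requires an even number of data rows, got ",
           length(toks))
    L <- nc - 2L
    n <- length(toks) %/% 2L
    ids <- character(n); popcodes <- character(n)
    alleles <- array(NA_integer_, c(n, L, 2L))
    for (i in seq_len(n)) {
      r1 <- toks[[2L * i - 1L]]; r2 <- toks[[2L * i]]
      if (r1[1] != r2[1])
        stop(sprintf("row pair for individual %d has mismatched ids ('%s' vs '%s')",
                     i, r1[1], r2[1]))
      ids[i] <- r1[1]; popcodes[i] <- r1[2]
      v1 <- suppressWarnings(as.integer(r1[-(1:2)]))
      v2 <- suppressWarnings(as.integer(r2[-(1:2)]))
      if (anyNA(v1) || anyNA(v2))
        stop(sprintf("non-integer allele near line %d of %s", 2L * i - 1L, path))
      alleles[i, , 1L] <- v1
      alleles[i, , 2L] <- v2
    }
  }
  alleles[alleles == -9L] <- NA_integer_
  if (any(alleles < 0L, na.rm = TRUE))
    stop("negative allele code other than the -9 missing sentinel")
  pops <- popcodes
  mapfile <- paste0(path, ".popmap.tsv")
  if (file.exists(mapfile)) {
    map <- utils::read.table(mapfile, header = TRUE, sep = "\t",
                             colClasses = c("character", "character"))
    m <- match(popcodes, map[[1]])
    pops <- ifelse(is.na(m), popcodes, map[[2]][m])
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_matrix(alleles, pops, ids, locus_names)
}

#' Write a genotype matrix in STRUCTURE format
#'
#' Serializes in either STRUCTURE dialect with `-9` for missing copies.
#' Population labels are written as consecutive integer codes (STRUCTURE
#' convention), with the code-to-label map in a TSV sidecar
#' `<path>.popmap.tsv` so that [read_structure_file()] round-trips labels.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param one_row_per_individual dialect flag, as in [read_structure_file()].
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(g, path, one_row_per_individual = FALSE) {
  validate_genotype_matrix(g)
  if (n_loci(g) == 0L) stop("refusing to write a matrix with zero loci")
  pops <- populations(g)
  code <- match(g$pop_labels, pops)
  a <- g$alleles
  a[is.na(a)] <- -9L
  n <- n_individuals(g); L <- n_loci(g)
  if (one_row_per_individual) {
    out <- character(n)
    for (i in seq_len(n)) {
      inter <- as.vector(rbind(a[i, , 1], a[i, , 2]))
      out[i] <- paste(c(g$individual_ids[i], code[i], inter), collapse = " ")
    }
  } else {
    out <- character(2L * n)
    for (i in seq_len(n)) {
      out[2L * i - 1L] <- paste(c(g$individual_ids[i], code[i], a[i, , 1]),
                                collapse = " ")
      out[2L * i] <- paste(c(g$individual_ids[i], code[i], a[i, , 2]),
                           collapse = " ")
    }
  }
  writeLines(out, path)
  utils::write.table(data.frame(integer_code = seq_along(pops), label = pops),
                     paste0(path, ".popmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
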