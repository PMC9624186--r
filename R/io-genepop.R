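#' Read a GenePop-format genotype file
#'
#' Parses the GenePop format: a title line, locus names (one per line or
#' comma-separated on one line), then `Pop` blocks of samples
#' `id , 0102 0304 ...`. Both 2-digit (`0102`) and 3-digit (`001002`) allele
#' encodings are supported; the width is inferred from the first genotype
#' token and must be consistent. `00`/`000` allele fields are missing.
#' Each `Pop` block becomes one population, labeled by the id of its first
#' sample (the common GenePop convention) unless ids repeat, in which case
#' `pop1..popk` labels are used.
#'
#' @param path file to read.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truncated GenePop file: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' keyword found in ", path)
  if (first_pop < 3L) stop("GenePop file has no locus-name section")
  header <- lines[2:(first_pop - 1L)]
  locus_names <- trimws(unlist(strsplit(header, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)

  ids <- character(); pops <- character(); rows <- list()
  popblock <- 0L; block_first_id <- character()
  digits <- NA_integer_
  for (i in seq(first_pop, length(lines))) {
    ln <- trimws(lines[i])
    if (toupper(ln) == "POP") { popblock <- popblock + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("line %d of %s: expected 'id , genotypes'", i, path))
    id <- trimws(parts[1])
    gt <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    if (length(gt) != L)
      stop(sprintf("line %d of %s: %d genotype fields, expected %d loci",
                   i, path, length(gt), L))
    w <- unique(nchar(gt))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop(sprintf("line %d of %s: inconsistent or unsupported allele digit width",
                   i, path))
    d <- w %/% 2L
    if (is.na(digits)) digits <- d
    if (d != digits)
      stop(sprintf("line %d of %s: digit width %d conflicts with earlier %d",
                   i, path, d, digits))
    a1 <- as.integer(substr(gt, 1L, digits))
    a2 <- as.integer(substr(gt, digits + 1L, 2L * digits))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, as.character(popblock))
    if (length(block_first_id) < popblock) block_first_id[popblock] <- id
    rows[[length(rows) + 1L]] <- rbind(a1, a2)
  }
  if (!length(rows)) stop("no samples found in ", path)
  n <- length(rows)
  alleles <- array(NA_integer_, c(n, L, 2L))
  for (i in seq_len(n)) {
    alleles[i, , 1L] <- rows[[i]][1, ]
    alleles[i, , 2L] <- rows[[i]][2, ]
  }
  labels <- block_first_id
  if (anyDuplicated(labels)) labels <- paste0("pop", seq_along(labels))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_matrix(alleles, labels[as.integer(pops)], ids, locus_names)
}

#' Write a genotype matrix in GenePop format
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param digits allele field width, 2 or 3. Allele codes must fit
#'   (`< 100` or `< 1000`); code 0 is reserved for missing, so all codes
#'   must be `>= 1`.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, digits = 3L, title = "hierstruct export") {
  validate_genotype_matrix(g)
  if (n_loci(g) == 0L) stop("refusing to write a matrix with zero loci")
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  maxcode <- max(g$alleles, na.rm = TRUE)
  if (maxcode >= 10^digits || any(g$alleles == 0L, na.rm = TRUE))
    stop("allele codes must lie in 1..", 10^digits - 1L,
         " for the ", digits, "-digit encoding")
  fmt <- paste0("%0", digits, "d")
  enc <- function(a1, a2) {
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    paste0(sprintf(fmt, a1), sprintf(fmt, a2))
  }
  out <- c(title, g$locus_names)
  for (p in populations(g)) {
    out <- c(out, "Pop")
    for (i in which(g$pop_labels == p)) {
      out <- c(out, paste(g$individual_ids[i], ",",
                          paste(enc(g$alleles[i, , 1], g$alleles[i, , 2]),
                                collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
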