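#' Read genotypes from plink text PED/MAP files
#'
#' Parses the 6-column PED dialect (FID IID PAT MAT SEX PHENO followed by two
#' allele columns per locus). Missing genotypes are "0 0" pairs; heterozygotes
#' are counted as one A2 copy regardless of allele order. The A2 (counted)
#' allele at each locus is the minor allele among non-missing calls, ties
#' broken towards the alphabetically later label; pass `a2` to fix the coding
#' explicitly (e.g. for round-trips).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (4 columns: chrom, id, cM, bp).
#' @param a2 optional character vector (one per locus) naming the allele whose
#'   copies are counted.
#' @return A [genotype_matrix()]; the PED family id column becomes the
#'   population assignment.
#' @export
read_ped_map <- function(ped_path, map_path, a2 = NULL) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stopf("MAP file %s: expected 4 columns", map_path)
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  n_loci <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  want <- 6L + 2L * n_loci
  len <- lengths(toks)
  if (any(len != want))
    stopf("PED file %s: line %d has %d fields, expected %d (PED/MAP mismatch or ragged row)",
          ped_path, which(len != want)[1], len[len != want][1], want)

  n_ind <- length(toks)
  al1 <- matrix("", n_ind, n_loci)
  al2 <- matrix("", n_ind, n_loci)
  fid <- iid <- character(n_ind)
  for (k in seq_len(n_ind)) {
    tk <- toks[[k]]
    fid[k] <- tk[1]; iid[k] <- tk[2]
    g <- tk[-(1:6)]
    al1[k, ] <- g[seq(1L, by = 2L, length.out = n_loci)]
    al2[k, ] <- g[seq(2L, by = 2L, length.out = n_loci)]
  }
  ok <- c("A", "C", "G", "T", "0")
  bad <- matrix(!(al1 %in% ok) | !(al2 %in% ok), n_ind, n_loci)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stopf("PED file %s: line %d locus %d has unknown allele symbol '%s'",
          ped_path, w[1], w[2], al1[w[1], w[2]])
  }
  half <- xor(al1 == "0", al2 == "0")
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stopf("PED file %s: line %d locus %d is half-missing", ped_path, w[1], w[2])
  }

  geno <- matrix(NA_integer_, n_ind, n_loci)
  a1lab <- a2lab <- character(n_loci)
  for (j in seq_len(n_loci)) {
    x1 <- al1[, j]; x2 <- al2[, j]
    miss <- x1 == "0"
    alleles <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(alleles) > 2L)
      stopf("locus %s has >2 alleles: %s", map$id[j], paste(alleles, collapse = ","))
    if (length(alleles) == 0L) alleles <- c("A", "A")  # all-missing column
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    if (is.null(a2)) {
      cnt <- c(sum(x1[!miss] == alleles[1]) + sum(x2[!miss] == alleles[1]),
               sum(x1[!miss] == alleles[2]) + sum(x2[!miss] == alleles[2]))
      # minor allele counted; tie -> alphabetically later (alleles is sorted)
      counted <- if (cnt[2] <= cnt[1]) alleles[2] else alleles[1]
    } else {
      counted <- a2[j]
    }
    a2lab[j] <- counted
    a1lab[j] <- if (alleles[1] == counted) alleles[2] else alleles[1]
    geno[!miss, j] <- (x1[!miss] == counted) + (x2[!miss] == counted)
  }
  loci <- data.frame(id = map$id, a1 = a1lab, a2 = a2lab,
                     chrom = map$chrom, pos = map$pos,
                     stringsAsFactors = FALSE)
  genotype_matrix(geno, iid, fid, loci)
}

#' Write a genotype matrix as plink text PED/MAP files
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- gm$loci
  chrom <- if ("chrom" %in% names(loci)) loci$chrom else 1
  pos <- if ("pos" %in% names(loci)) loci$pos else seq_len(nrow(loci))
  write.table(data.frame(chrom, loci$id, 0, pos), map_path,
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n_loci <- nrow(loci)
  rows <- vapply(seq_len(nrow(gm$geno)), function(k) {
    g <- gm$geno[k, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, loci$a2, loci$a1))
    x2 <- ifelse(is.na(g), "0", ifelse(g == 2L, loci$a2, loci$a1))
    paste(c(gm$pop[k], gm$sample_id[k], 0, 0, 0, -9,
            as.vector(rbind(x1, x2))), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}
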