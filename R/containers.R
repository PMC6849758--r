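#' Genotype matrix container
#'
#' Holds diploid biallelic genotype calls for a set of individuals, coded as
#' the number of copies (0/1/2) of the locus's A2 allele, with `NA` marking
#' missing calls, together with sample and locus metadata.
#'
#' @param geno integer matrix, individuals in rows, loci in columns; entries
#'   0, 1, 2 or `NA`.
#' @param sample_id character vector of unique individual identifiers.
#' @param pop character vector assigning each individual to a population.
#' @param loci data.frame with one row per locus: columns `id` (unique),
#'   `a1`, `a2` (allele labels, e.g. "A"/"G"); optional `chrom`, `pos`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sample_id, pop, loci) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(sample_id))
    stopf("geno has %d rows but %d sample ids", nrow(geno), length(sample_id))
  if (length(pop) != length(sample_id))
    stopf("pop has length %d, expected %d", length(pop), length(sample_id))
  if (ncol(geno) != nrow(loci))
    stopf("geno has %d columns but %d locus records", ncol(geno), nrow(loci))
  if (anyDuplicated(sample_id)) stopf("duplicated sample ids")
  if (anyDuplicated(loci$id)) stopf("duplicated locus ids")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stopf("genotype codes must be 0, 1, 2 or NA")
  dimnames(geno) <- list(sample_id, loci$id)
  structure(list(geno = geno, sample_id = as.character(sample_id),
                 pop = as.character(pop), loci = as.data.frame(loci)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$pop))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%; genotyping rate %.3f\n",
              100 * miss, 1 - miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# internal: subset by individual and/or locus index
gm_subset <- function(gm, ind = NULL, loc = NULL) {
  ind <- ind %||% seq_len(nrow(gm$geno))
  loc <- loc %||% seq_len(ncol(gm$geno))
  genotype_matrix(gm$geno[ind, loc, drop = FALSE], gm$sample_id[ind],
                  gm$pop[ind], gm$loci[loc, , drop = FALSE])
}

#' Labelled symmetric distance matrix
#'
#' @param m square numeric matrix (symmetric, zero diagonal).
#' @param labels row/column labels (population ids).
#' @param check if `TRUE`, validate symmetry and the zero diagonal.
#' @return A `dist_matrix`: a plain matrix with dimnames and a class tag.
#' @export
dist_matrix <- function(m, labels = rownames(m), check = TRUE) {
  m <- as.matrix(m)
  if (is.null(labels)) stopf("distance matrix needs labels")
  dimnames(m) <- list(labels, labels)
  if (check) {
    if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
    fin <- is.finite(m) & is.finite(t(m))
    if (any(abs(m[fin] - t(m)[fin]) > 1e-8)) stopf("distance matrix not symmetric")
    if (any(abs(diag(m)) > 1e-12)) stopf("distance matrix diagonal must be 0")
  }
  class(m) <- c("dist_matrix", "matrix")
  m
}

# strict lower triangle as vector, pair order fixed by label order
lower_vec <- function(m) m[lower.tri(m)]

#' ESRI ASCII grid raster
#'
#' Minimal in-memory raster: a numeric matrix (row 1 = northernmost row, as
#' in the ESRI ASCII format) plus georeferencing header fields.
#'
#' @param m numeric matrix of cell values (`NA` = nodata).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell edge length.
#' @param nodata_value value written for `NA` cells.
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(m, xllcorner = 0, yllcorner = 0, cellsize = 1,
                       nodata_value = -9999) {
  if (!is.matrix(m) || any(dim(m) < 1L))
    stopf("raster values must form a non-empty matrix")
  structure(list(m = m, xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("ascii_grid: %d rows x %d cols, cellsize %g, origin (%g, %g)\n",
              nrow(x$m), ncol(x$m), x$cellsize, x$xllcorner, x$yllcorner))
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid file
#'
#' @param g an [ascii_grid()].
#' @param path output file path.
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(inherits(g, "ascii_grid"))
  hdr <- c(sprintf("ncols %d", ncol(g$m)),
           sprintf("nrows %d", nrow(g$m)),
           sprintf("xllcorner %.10g", g$xllcorner),
           sprintf("yllcorner %.10g", g$yllcorner),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", g$nodata_value))
  m <- g$m
  m[is.na(m)] <- g$nodata_value
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file path.
#' @return An [ascii_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stopf("malformed ESRI ASCII header in %s", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- hdr[["nodata_value"]] %||% -9999
  m[m == nd] <- NA
  ascii_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nd)
}
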