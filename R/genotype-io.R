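PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1 binary fileset
#'
#' Reads a SNP-major `.bed`/`.bim`/`.fam` triple into a
#' [GenotypeData-class] object. Dosage counts copies of the bim A2 allele
#' (`allele_b`): the 2-bit bed codes map as 00 -> 0 (A1/A1), 10 -> 1 (het),
#' 11 -> 2 (A2/A2), 01 -> missing. Markers on chromosome codes outside
#' `1:maxAutosome` are dropped with a warning (sex chromosomes and
#' unplaced contigs are out of scope).
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param maxAutosome largest autosome code retained (29 for cattle).
#' @param strict disallow missing genotypes (default `TRUE`).
#' @return A [GenotypeData-class] object with markers sorted by
#'   (chrom, pos_bp).
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix, maxAutosome = 29L, strict = TRUE) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("missing PLINK file(s): ", paste(miss, collapse = ", "))
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paths[2], header = FALSE,
    col.names = c("chrom", "marker_id", "cm", "pos_bp", "allele_a",
                  "allele_b"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character"))
  n <- nrow(fam); s <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = 3 + ceiling(n / 4) * s)
  if (length(raw) < 3 || !identical(raw[1:3], PLINK_MAGIC))
    stop("not a PLINK 1 SNP-major bed file (bad magic bytes): ", paths[1])
  body <- raw[-(1:3)]
  bpl <- ceiling(n / 4)
  if (length(body) != bpl * s)
    stop("bed file size inconsistent with fam/bim dimensions")
  # 2-bit unpack: one column of codes per sample slot, SNP-major
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8 * bpl)
  idx <- seq_len(n)
  lo <- bits[2 * idx - 1, , drop = FALSE]
  hi <- bits[2 * idx, , drop = FALSE]
  # 00->0, 10(lo=0,hi=1)->1, 11->2, 01(lo=1,hi=0)->NA
  dose <- lo + hi
  dose[lo == 1 & hi == 0] <- NA_integer_
  dimnames(dose) <- list(fam[[2]], bim$marker_id)

  suppressWarnings(chromInt <- as.integer(bim$chrom))
  keep <- !is.na(chromInt) & chromInt >= 1L & chromInt <= maxAutosome
  if (any(!keep))
    warning(sum(!keep), " marker(s) on non-autosome codes removed")
  map <- data.frame(marker_id = bim$marker_id[keep],
                    chrom = chromInt[keep], pos_bp = bim$pos_bp[keep],
                    allele_a = bim$allele_a[keep],
                    allele_b = bim$allele_b[keep],
                    stringsAsFactors = FALSE)
  dose <- dose[, keep, drop = FALSE]
  o <- order(map$chrom, map$pos_bp)
  GenotypeData(dose[, o, drop = FALSE], map[o, , drop = FALSE],
               strict = strict)
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [readPlink()]; writes a v1.00 SNP-major bed plus bim/fam.
#' `readPlink(writePlink(g, prefix))` reproduces `g` exactly.
#'
#' @param g a [GenotypeData-class] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(g, prefix) {
  stopifnot(is(g, "GenotypeData"))
  d <- dosage(g); map <- markerMap(g)
  n <- nrow(d)
  fam <- data.frame(fid = rownames(d), iid = rownames(d), pat = 0L,
                    mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(chrom = map$chrom, id = map$marker_id, cm = 0,
                    pos = map$pos_bp, a1 = map$allele_a, a2 = map$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bpl <- ceiling(n / 4)
  pad <- bpl * 4 - n
  codes <- matrix(0L, nrow = 2 * (n + pad), ncol = ncol(d))
  idx <- seq_len(n)
  dv <- d
  lo <- (dv == 2) | is.na(dv)
  hi <- (dv >= 1) & !is.na(dv)
  codes[2 * idx - 1, ] <- lo * 1L
  codes[2 * idx, ] <- hi * 1L
  body <- packBits(as.integer(codes) > 0, type = "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(body, con)
  invisible(prefix)
}

#' Read/write genotypes as plain TSV
#'
#' Text alternative to the binary PLINK format: a dosage table
#' (samples x markers, first column `sample_id`, header row of marker ids)
#' plus a marker-map TSV with columns `marker_id`, `chrom`, `pos_bp`,
#' `allele_a`, `allele_b`.
#'
#' @param dosageFile,mapFile TSV paths.
#' @param strict disallow missing genotypes.
#' @return A [GenotypeData-class] object.
#' @export
readGenotypesTsv <- function(dosageFile, mapFile, strict = TRUE) {
  d <- utils::read.delim(dosageFile, check.names = FALSE)
  map <- utils::read.delim(mapFile, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  m <- m[, map$marker_id, drop = FALSE]
  GenotypeData(m, map, strict = strict)
}

#' @rdname readGenotypesTsv
#' @param g a [GenotypeData-class] object.
#' @export
writeGenotypesTsv <- function(g, dosageFile, mapFile) {
  d <- data.frame(sample_id = sampleIds(g), dosage(g), check.names = FALSE)
  utils::write.table(d, dosageFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(markerMap(g), mapFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dosageFile)
}

PHENO_COLS <- c("bull_id", "trait", "value", "year_season", "center",
                "interval", "n_sample", "age_months")

#' Read or write a phenotype record table
#'
#' Repeated semen-collection records, one row per record, with columns
#' `bull_id`, `trait` (EV/SC/SM), `value`, `year_season`, `center`,
#' `interval`, `n_sample` (categoricals) and `age_months`.
#'
#' @param file TSV path.
#' @return `data.frame` of records.
#' @export
readPhenotypes <- function(file) {
  p <- utils::read.delim(file, stringsAsFactors = FALSE)
  miss <- setdiff(PHENO_COLS, names(p))
  if (length(miss))
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "))
  p
}

#' @rdname readPhenotypes
#' @param p phenotype `data.frame`.
#' @export
writePhenotypes <- function(p, file) {
  utils::write.table(p, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene annotation from a BED file
#'
#' Imports a browser BED file (0-based half-open) and returns 1-based closed
#' coordinates consistent with the marker map, as a `GRanges` with gene
#' names in `mcols()$name`.
#'
#' @param file BED path; chromosome names must be bare autosome numbers or
#'   `chrN`.
#' @return A `GRanges` object.
#' @export
readGeneBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- sub("^chr", "", GenomeInfoDb::seqlevels(gr))
  gr
}
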