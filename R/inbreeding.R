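#' Excess-of-homozygosity inbreeding coefficient (F_SNP)
#'
#' Per sample, `F_SNP = (OH - EH) / (s - EH)` where `OH` is the observed
#' count of homozygous genotypes, `s` the number of SNPs, and
#' `EH = sum_j (1 - 2 m_j (1 - m_j))` the expected homozygosity at the
#' sample minor allele frequencies `m_j`. Equals 1 for a fully homozygous
#' sample and can be negative when observed homozygosity falls below
#' expectation. Computed on the full marker set, including low-MAF markers.
#'
#' @param g a [GenotypeData-class] object.
#' @return named numeric vector, one value per sample.
#' @export
fSnp <- function(g) {
  stopifnot(is(g, "GenotypeData"))
  d <- dosage(g)
  if (anyNA(d)) stop("missing genotypes are not supported by fSnp")
  m <- minorAlleleFreq(g)
  s <- ncol(d)
  if (s < 1) stop("no markers")
  eh <- sum(1 - 2 * m * (1 - m))
  if (isTRUE(all.equal(s, eh)))
    stop("all markers monomorphic: F_SNP undefined (s == EH)")
  oh <- rowSums(d != 1L)
  (oh - eh) / (s - eh)
}

#' ROH-based inbreeding coefficient (F_ROH)
#'
#' Proportion of the SNP-covered autosomal genome lying in called ROH:
#' `F_ROH = sum_k L_ROH_k / L_g`.
#'
#' @param segs `GRanges` of segments from [detectRoh()].
#' @param lg genome length in bp ([genomeLength()]), or a marker map
#'   `data.frame`, in which case `L_g` is computed and each segment is
#'   validated against its chromosome's mapped span.
#' @param samples sample ids to report; samples without segments get 0.
#' @return named numeric vector of per-sample F_ROH.
#' @export
fRoh <- function(segs, lg, samples = NULL) {
  if (is.data.frame(lg)) {
    map <- lg
    spans <- tapply(map$pos_bp, map$chrom, function(p) diff(range(p)) + 1)
    segChrom <- as.character(GenomicRanges::seqnames(segs))
    bad <- GenomicRanges::width(segs) > spans[segChrom]
    if (any(bad, na.rm = TRUE) || anyNA(bad))
      stop("segment longer than its chromosome's mapped span")
    lg <- genomeLength(map)
  }
  stopifnot(is.numeric(lg), lg > 0)
  sid <- S4Vectors::mcols(segs)$sample_id
  if (is.null(samples)) samples <- sort(unique(sid))
  tot <- tapply(as.numeric(GenomicRanges::width(segs)),
                factor(sid, levels = samples), sum)
  tot[is.na(tot)] <- 0
  setNames(as.numeric(tot) / lg, samples)
}

#' Autosomal genome length covered by SNPs
#'
#' Sum over chromosomes of (last SNP position - first SNP position + 1).
#' Chromosomes with fewer than two SNPs are excluded with a warning.
#'
#' @param map marker map `data.frame` with `chrom` and `pos_bp`.
#' @return length in bp.
#' @export
genomeLength <- function(map) {
  if (nrow(map) == 0) stop("empty marker map")
  cnt <- table(map$chrom)
  thin <- names(cnt)[cnt < 2]
  if (length(thin)) {
    warning("chromosome(s) with < 2 SNPs excluded: ",
            paste(thin, collapse = ", "))
    map <- map[!(map$chrom %in% as.integer(thin)), , drop = FALSE]
    if (nrow(map) == 0) stop("no chromosome has >= 2 SNPs")
  }
  sum(tapply(map$pos_bp, map$chrom, function(p) diff(range(p)) + 1))
}

#' Expected IBD segment length for a given age of inbreeding
#'
#' `E(L | gcA) = 100 / (2 gcA)` Mb, where `gcA` is the number of
#' generations back to the common ancestor; long ROH indicate recent
#' inbreeding, short ROH ancient inbreeding. `generationsForLength()` is
#' the inverse.
#'
#' @param gcA generations to the common ancestor (> 0).
#' @return expected haplotype length in Mb.
#' @export
expectedIbdLength <- function(gcA) {
  if (any(gcA <= 0)) stop("gcA must be positive")
  100 / (2 * gcA)
}

#' @rdname expectedIbdLength
#' @param lengthMb IBD segment length in Mb (> 0).
#' @export
generationsForLength <- function(lengthMb) {
  if (any(lengthMb <= 0)) stop("length must be positive")
  100 / (2 * lengthMb)
}

#' Per-sample inbreeding coefficient table
#'
#' Combines [fSnp()] (full marker set), [detectRoh()]/[fRoh()] and the ROH
#' length-class decomposition into one table. The five class coefficients
#' sum exactly to `f_roh`.
#'
#' @param g a [GenotypeData-class] object (pre-QC marker set).
#' @param segs `GRanges` of ROH segments; called with default parameters
#'   when omitted.
#' @return `data.frame` with columns `sample_id`, `f_snp`, `f_roh`,
#'   `f_roh_1_2`, `f_roh_2_4`, `f_roh_4_8`, `f_roh_8_16`, `f_roh_gt16`;
#'   attribute `l_g` holds the genome length used.
#' @export
inbreedingTable <- function(g, segs = detectRoh(g)) {
  lg <- genomeLength(markerMap(g))
  cls <- classifyRoh(segs, samples = sampleIds(g)) / lg
  fr <- rowSums(cls)
  out <- data.frame(sample_id = sampleIds(g), f_snp = unname(fSnp(g)),
                    f_roh = unname(fr))
  colnames(cls) <- paste0("f_", ROH_CLASSES)
  out <- cbind(out, as.data.frame(cls, row.names = NULL))
  attr(out, "l_g") <- lg
  out
}

#' @rdname inbreedingTable
#' @param tab table from `inbreedingTable()`.
#' @param file output TSV path.
#' @export
writeInbreedingTsv <- function(tab, file) {
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Correlogram of inbreeding measures
#'
#' Pearson correlations among `f_snp`, `f_roh` and the five length-class
#' coefficients, pairwise-complete. Measures with zero variance give `NA`
#' entries.
#'
#' @param tab table from [inbreedingTable()] (or any data.frame of numeric
#'   measure columns plus `sample_id`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
fCorrelogram <- function(tab) {
  num <- tab[, setdiff(names(tab), "sample_id"), drop = FALSE]
  if (nrow(num) < 3) stop("need at least 3 samples")
  suppressWarnings(r <- cor(num, use = "pairwise.complete.obs"))
  sdv <- apply(num, 2, sd, na.rm = TRUE)
  r[sdv == 0, ] <- NA
  r[, sdv == 0] <- NA
  diag(r) <- ifelse(sdv == 0, NA, 1)
  r
}
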