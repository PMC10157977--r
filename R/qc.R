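#' Allele frequencies and MAF
#'
#' Frequency of `allele_b` per marker, computed from the analysed sample
#' itself.
#'
#' @param g a [GenotypeData-class] object.
#' @return numeric vector, one entry per marker.
#' @export
alleleFreqB <- function(g) {
  colMeans(dosage(g), na.rm = TRUE) / 2
}

#' @rdname alleleFreqB
#' @export
minorAlleleFreq <- function(g) {
  p <- alleleFreqB(g)
  pmin(p, 1 - p)
}

#' Hardy-Weinberg chi-square test per marker
#'
#' Pearson chi-square with 1 df, no continuity correction: observed genotype
#' counts against expectations at the sample allele frequency. Monomorphic
#' markers give chi-square 0 (no deviation is possible).
#'
#' @param nAA,nAB,nBB genotype counts (vectors recycle).
#' @return `data.frame` with `chisq` and `p`.
#' @export
hweChisq <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  p <- (2 * nAA + nAB) / (2 * n)   # frequency of the A allele
  q <- 1 - p
  eAA <- n * p^2; eAB <- 2 * n * p * q; eBB <- n * q^2
  chisq <- ifelse(eAB == 0, 0,
                  (nAA - eAA)^2 / pmax(eAA, .Machine$double.xmin) +
                  (nAB - eAB)^2 / eAB +
                  (nBB - eBB)^2 / pmax(eBB, .Machine$double.xmin))
  data.frame(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Marker quality control
#'
#' Retains markers with MAF >= `mafMin` and Hardy-Weinberg chi-square
#' p-value >= `hwePMin` (both computed on the analysed sample). The input
#' object is not modified. Intended for the marker set feeding the genomic
#' relationship matrix; inbreeding coefficients use the full set.
#'
#' @param g a [GenotypeData-class] object without missing genotypes.
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param hwePMin minimum HWE p-value (default 1e-6).
#' @return A filtered [GenotypeData-class] object (possibly with zero
#'   markers).
#' @export
filterMarkersQC <- function(g, mafMin = 0.01, hwePMin = 1e-6) {
  stopifnot(is(g, "GenotypeData"))
  d <- dosage(g)
  if (anyNA(d)) stop("missing genotypes present; QC requires complete data")
  nBB <- colSums(d == 2L)
  nAB <- colSums(d == 1L)
  nAA <- nrow(d) - nBB - nAB
  maf <- minorAlleleFreq(g)
  hwe <- hweChisq(nAA, nAB, nBB)
  keep <- maf >= mafMin & hwe$p >= hwePMin
  GenotypeData(d[, keep, drop = FALSE],
               markerMap(g)[keep, , drop = FALSE], strict = g@strict)
}

TRAIT_RANGES <- list(EV = c(1, 25), SC = c(1, 30), SM = c(0.1, 0.98))

#' Phenotype range filter
#'
#' Drops out-of-range records: ejaculate volume (EV) outside \[1, 25\] mL,
#' sperm concentration (SC) outside \[1, 30\] (1e8/mL), sperm motility (SM)
#' outside \[0.1, 0.98\]. Boundaries are kept (closed intervals).
#'
#' @param p phenotype `data.frame` (see [readPhenotypes()]).
#' @return filtered `data.frame`.
#' @export
filterPhenotypes <- function(p) {
  if (nrow(p) == 0) return(p)
  bad <- setdiff(unique(p$trait), names(TRAIT_RANGES))
  if (length(bad))
    stop("unknown trait label(s): ", paste(bad, collapse = ", "))
  lim <- do.call(rbind, TRAIT_RANGES[p$trait])
  p[p$value >= lim[, 1] & p$value <= lim[, 2], , drop = FALSE]
}
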