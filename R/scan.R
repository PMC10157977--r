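#' Per-sample, per-SNP ROH-state indicator matrix
#'
#' Indicator coded 1 when the SNP position lies inside any called ROH
#' segment of that sample (closed interval, endpoints included), else 0.
#'
#' @param segs `GRanges` from [detectRoh()].
#' @param map marker map `data.frame`.
#' @param samples sample ids for the rows.
#' @return integer matrix, samples x markers (0/1), dimnames set.
#' @export
rohStateMatrix <- function(segs, map, samples) {
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(map$chrom),
    ranges = IRanges::IRanges(start = map$pos_bp, width = 1))
  out <- matrix(0L, nrow = length(samples), ncol = nrow(map),
                dimnames = list(samples, map$marker_id))
  if (length(segs)) {
    hits <- GenomicRanges::findOverlaps(snps, segs)
    si <- match(S4Vectors::mcols(segs)$sample_id[S4Vectors::subjectHits(hits)],
                samples)
    ok <- !is.na(si)
    out[cbind(si[ok], S4Vectors::queryHits(hits)[ok])] <- 1L
  }
  out
}

#' Genome scan for inbreeding-depression loci
#'
#' For each SNP, fits the per-SNP mapping model: all base fixed effects
#' plus an additive dosage covariate (0/1/2) and the 0/1 ROH-state
#' covariate of that SNP, by GLS with variance components held fixed at
#' the base-model (no-inbreeding-covariate) REML estimates. The reported
#' test is on the ROH-state coefficient: after adjusting for the additive
#' allele effect, does homozygosity at this position depress the trait?
#' Two-sided p-values from a Student t with `n_bulls - rank - 2` df.
#'
#' SNPs whose ROH-state column is constant across bulls -- or collinear
#' with the SNP's own dosage, leaving no free variation in ROH state --
#' get `status = "NA_no_variation"`. A monomorphic SNP inside variable ROH
#' is fitted with the ROH-state covariate only (`b_add` is `NA`).
#'
#' @param ph phenotype `data.frame` (single trait).
#' @param grm GRM from [buildGrm()].
#' @param g [GenotypeData-class] with the scan marker set (pre-QC set).
#' @param rohStates matrix from [rohStateMatrix()] (samples x markers).
#' @param vc base-model variance components: a converged
#'   [FitResult-class] from [fitAnimalModel()] without inbreeding
#'   covariates, or a named numeric vector.
#' @return `data.frame` (one row per SNP, ordered by chrom, pos):
#'   `marker_id`, `chrom`, `pos_bp`, `b_add`, `b_roh`, `se_roh`, `p_roh`,
#'   `status`.
#' @export
runScan <- function(ph, grm, g, rohStates, vc) {
  stopifnot(is(g, "GenotypeData"))
  if (is(vc, "FitResult")) {
    if (!isConverged(vc)) stop("base-model variance components not converged")
    vc <- varComp(vc)
  }
  th <- as.numeric(vc[.vcNames])
  if (anyNA(th) || any(th < 0)) stop("invalid variance components")
  if (length(unique(ph$trait)) > 1)
    stop("phenotype table contains multiple traits; subset to one")
  bulls <- sort(unique(as.character(ph$bull_id)))
  if (length(setdiff(bulls, rownames(grm))))
    stop("bull(s) absent from the GRM")
  if (length(setdiff(bulls, sampleIds(g))))
    stop("bull(s) absent from the genotype data")
  map <- markerMap(g)
  X <- .reduceRank(.buildDesign(ph, NULL, includeAge = TRUE))
  y <- as.numeric(ph$value)
  bi <- match(as.character(ph$bull_id), bulls)
  q <- length(bulls)
  G <- grm[bulls, bulls]

  # one GLS evaluation at the fixed variance components
  sa <- th[1]; sp <- max(th[2], 1e-12 * var(y)); se <- th[3]
  eg <- eigen(G, symmetric = TRUE)
  hinv <- eg$vectors %*% (t(eg$vectors) / pmax(sa * eg$values + sp, 1e-12))
  D <- tabulate(bi, nbins = q)
  C <- se * hinv; diag(C) <- diag(C) + D
  Cinv <- chol2inv(chol(C))
  vinv <- function(M)
    (M - (Cinv %*% rowsum(M, bi))[bi, , drop = FALSE]) / se
  W <- vinv(X$X)
  XtW <- crossprod(X$X, W)
  Fm <- chol2inv(chol((XtW + t(XtW)) / 2))
  beta <- Fm %*% crossprod(W, y)
  r <- drop(vinv(matrix(y)) - W %*% beta)        # P y
  ty <- drop(rowsum(matrix(r), bi))              # Z' P y
  ZtW <- rowsum(W, bi)
  ZtVZ <- -Cinv * tcrossprod(D); diag(ZtVZ) <- diag(ZtVZ) + D
  Tm <- ZtVZ / se - ZtW %*% Fm %*% t(ZtW)        # Z' P Z

  U1 <- dosage(g)[bulls, , drop = FALSE]
  storage.mode(U1) <- "double"
  U2 <- rohStates[bulls, map$marker_id, drop = FALSE]
  storage.mode(U2) <- "double"
  TU1 <- Tm %*% U1; TU2 <- Tm %*% U2
  a11 <- colSums(U1 * TU1); a12 <- colSums(U1 * TU2)
  a22 <- colSums(U2 * TU2)
  b1 <- colSums(U1 * ty); b2 <- colSums(U2 * ty)

  detv <- a11 * a22 - a12^2
  rohVar <- .colVars(U2)
  addVar <- .colVars(U1)
  collinear <- addVar > 0 & rohVar > 0 &
    detv <= 1e-10 * pmax(a11 * a22, .Machine$double.xmin)
  status <- ifelse(rohVar == 0 | collinear, "NA_no_variation", "ok")

  bAdd <- bRoh <- seRoh <- pRoh <- rep(NA_real_, nrow(map))
  full <- status == "ok" & addVar > 0
  rohOnly <- status == "ok" & addVar == 0
  bAdd[full] <- (a22[full] * b1[full] - a12[full] * b2[full]) / detv[full]
  bRoh[full] <- (a11[full] * b2[full] - a12[full] * b1[full]) / detv[full]
  seRoh[full] <- sqrt(a11[full] / detv[full])
  bRoh[rohOnly] <- b2[rohOnly] / a22[rohOnly]
  seRoh[rohOnly] <- sqrt(1 / a22[rohOnly])
  dfree <- pmax(q - X$rank - ifelse(rohOnly, 1, 2), 1)
  tv <- bRoh / seRoh
  pRoh[status == "ok"] <- (2 * pt(-abs(tv), df = dfree))[status == "ok"]

  out <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    pos_bp = map$pos_bp, b_add = bAdd, b_roh = bRoh,
                    se_roh = seRoh, p_roh = pRoh, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "df") <- q - X$rank - 2
  attr(out, "n_ok") <- sum(status == "ok")
  out
}

# colVars without a matrixStats dependency
.colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
}

#' Proportion-based false discovery rate
#'
#' `FDR = P (1 - N) / (N (1 - P))` where `P` is the p-value threshold and
#' `N` the proportion of SNPs significant at `P`.
#'
#' @param pThreshold p-value threshold, in (0, 1).
#' @param nProp proportion of significant SNPs, in (0, 1].
#' @return the FDR estimate.
#' @examples
#' fdrProportion(1e-5, 52 / 52655)  # ~0.0101
#' @export
fdrProportion <- function(pThreshold, nProp) {
  if (any(pThreshold <= 0 | pThreshold >= 1))
    stop("pThreshold must be in (0, 1)")
  if (any(nProp <= 0 | nProp > 1))
    stop("nProp must be in (0, 1]; no significant SNPs -> FDR undefined")
  pThreshold * (1 - nProp) / (nProp * (1 - pThreshold))
}

#' Minimum-FDR p-value threshold
#'
#' Evaluates [fdrProportion()] over candidate thresholds, with `N` taken as
#' the observed proportion of tested (status `ok`) SNPs below each
#' threshold, and returns the candidate with minimal FDR (ties broken by
#' the smaller threshold). Candidates with no significant SNP are skipped
#' with a warning.
#'
#' @param scan result of [runScan()].
#' @param candidates numeric vector of thresholds.
#' @return list with `p_threshold`, `fdr`, and the evaluation `table`.
#' @export
minFdrThreshold <- function(scan, candidates) {
  stopifnot(length(candidates) > 0)
  pok <- scan$p_roh[scan$status == "ok"]
  rows <- lapply(sort(candidates), function(P) {
    nsig <- sum(pok < P)
    if (nsig == 0) {
      warning("no significant SNPs at P = ", format(P), "; skipped")
      return(NULL)
    }
    N <- nsig / length(pok)
    data.frame(p_threshold = P, n_significant = nsig, n_prop = N,
               fdr = fdrProportion(P, N))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    stop("no candidate threshold yields a significant SNP")
  best <- which(tab$fdr == min(tab$fdr))[1]  # sorted: first = smallest P
  list(p_threshold = tab$p_threshold[best], fdr = tab$fdr[best],
       table = tab)
}

#' Call significant regions from a scan
#'
#' Significant SNPs (`status == "ok"`, `p_roh < pThreshold`) on the same
#' chromosome are merged into a region whenever consecutive significant
#' SNPs are at most `mergeGapBp` apart; region bounds are the min/max
#' significant SNP positions. When gene annotation is supplied, genes
#' overlapping the region extended by `windowBp` on each side are listed.
#'
#' @param scan result of [runScan()].
#' @param pThreshold significance threshold on `p_roh`.
#' @param mergeGapBp maximum distance between consecutive significant SNPs
#'   within one region (default 1 Mb).
#' @param genes optional `GRanges` of genes (see [readGeneBed()]).
#' @param windowBp half-width of the gene lookup window (default 500 kb).
#' @return `GRanges` of disjoint regions with metadata columns
#'   `n_significant_snps`, `min_p`, and `genes` (comma-separated, when
#'   annotation given); empty when nothing is significant.
#' @export
callRegions <- function(scan, pThreshold, mergeGapBp = 1e6, genes = NULL,
                        windowBp = 5e5) {
  sig <- scan$status == "ok" & scan$p_roh < pThreshold
  if (!any(sig)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$n_significant_snps <- integer()
    S4Vectors::mcols(gr)$min_p <- numeric()
    return(gr)
  }
  s <- scan[sig, , drop = FALSE]
  pts <- GenomicRanges::GRanges(
    seqnames = as.character(s$chrom),
    ranges = IRanges::IRanges(start = s$pos_bp, width = 1))
  reg <- GenomicRanges::reduce(pts, min.gapwidth = mergeGapBp)
  hits <- GenomicRanges::findOverlaps(pts, reg)
  S4Vectors::mcols(reg)$n_significant_snps <-
    as.integer(table(factor(S4Vectors::subjectHits(hits),
                            levels = seq_along(reg))))
  S4Vectors::mcols(reg)$min_p <- as.numeric(
    tapply(s$p_roh[S4Vectors::queryHits(hits)],
           factor(S4Vectors::subjectHits(hits), levels = seq_along(reg)),
           min))
  if (!is.null(genes)) {
    win <- reg
    GenomicRanges::start(win) <- pmax(GenomicRanges::start(win) - windowBp, 1)
    GenomicRanges::end(win) <- GenomicRanges::end(win) + windowBp
    gh <- GenomicRanges::findOverlaps(win, genes)
    nm <- S4Vectors::mcols(genes)$name
    if (is.null(nm)) nm <- paste0("gene", seq_along(genes))
    lst <- split(nm[S4Vectors::subjectHits(gh)],
                 factor(S4Vectors::queryHits(gh), levels = seq_along(reg)))
    S4Vectors::mcols(reg)$genes <-
      vapply(lst, function(v) paste(unique(v), collapse = ","), character(1))
  }
  reg
}
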