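#' @import methods
#' @importFrom stats pchisq pt var sd cor rnorm runif rpois rbinom setNames
#'   complete.cases ks.test lm coef quantile
NULL

#' GenotypeData: SNP dosage matrix with a marker map
#'
#' Container for biallelic autosomal SNP genotypes. Dosages count copies of
#' `allele_b` (0/1/2); 1 is the heterozygote. All downstream statistics
#' (homozygosity, ROH, GRM, scan) are symmetric under swapping which allele
#' is counted.
#'
#' @slot dosage integer matrix, samples x markers; entries 0/1/2 (NA only in
#'   permissive mode).
#' @slot map `data.frame` with columns `marker_id`, `chrom` (integer autosome
#'   code), `pos_bp` (1-based), `allele_a`, `allele_b`; sorted by
#'   (chrom, pos_bp), positions strictly increasing within chromosome.
#' @slot strict logical; when `TRUE` (default) missing genotypes are
#'   disallowed.
#'
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosage = "matrix", map = "data.frame", strict = "logical"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  m <- object@map
  need <- c("marker_id", "chrom", "pos_bp", "allele_a", "allele_b")
  if (!all(need %in% names(m)))
    return(paste("map must have columns", paste(need, collapse = ", ")))
  if (ncol(object@dosage) != nrow(m))
    msg <- c(msg, "ncol(dosage) must equal nrow(map)")
  if (is.null(rownames(object@dosage)))
    msg <- c(msg, "dosage must have sample ids as rownames")
  if (anyDuplicated(m$marker_id))
    msg <- c(msg, "marker_ids must be unique")
  if (nrow(m) > 1) {
    o <- order(m$chrom, m$pos_bp)
    if (!identical(o, seq_len(nrow(m))))
      msg <- c(msg, "map must be sorted by (chrom, pos_bp)")
    dup <- unlist(tapply(m$pos_bp, m$chrom, function(p) any(duplicated(p))))
    if (any(dup))
      msg <- c(msg, "pos_bp must be strictly increasing within chromosome")
  }
  bad <- !(object@dosage %in% c(0L, 1L, 2L) | is.na(object@dosage))
  if (any(bad))
    msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  if (isTRUE(object@strict) && anyNA(object@dosage))
    msg <- c(msg, "missing genotypes are not allowed in strict mode")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric/integer matrix (samples x markers) of 0/1/2 counts of
#'   `allele_b`; rownames are sample ids.
#' @param map marker map `data.frame` (see [GenotypeData-class]).
#' @param strict disallow missing genotypes (default `TRUE`).
#' @return A [GenotypeData-class] object.
#' @examples
#' g <- GenotypeData(matrix(c(0L, 1L, 2L, 2L), 2, 2,
#'                          dimnames = list(c("s1", "s2"), NULL)),
#'                   data.frame(marker_id = c("m1", "m2"), chrom = 1L,
#'                              pos_bp = c(100L, 200L),
#'                              allele_a = "A", allele_b = "B"))
#' nSamples(g)
#' @export
GenotypeData <- function(dosage, map, strict = TRUE) {
  storage.mode(dosage) <- "integer"
  map$chrom <- as.integer(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  map$marker_id <- as.character(map$marker_id)
  rownames(map) <- NULL
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker_id
  new("GenotypeData", dosage = dosage, map = map, strict = strict)
}

#' FitResult: a fitted repeated-records animal model
#'
#' Holds fixed-effect estimates and REML variance components from
#' [fitAnimalModel()]. Inestimable (collinear) terms are kept as `NA` rows,
#' never dropped.
#'
#' @slot coefficients `data.frame` with columns `term`, `estimate`, `se`,
#'   `t`, `p` (two-sided).
#' @slot varcomp named numeric: `sigma_a2`, `sigma_pe2`, `sigma_e2`.
#' @slot loglik restricted log-likelihood at convergence (constant dropped).
#' @slot converged logical.
#' @slot iterations iterations used.
#' @slot nRecords,nBulls problem dimensions.
#' @slot df residual degrees of freedom used for t tests
#'   (`nBulls - rank(X)`).
#' @slot trajectory per-iteration variance components and restricted
#'   log-likelihood (accepted steps only).
#' @exportClass FitResult
setClass("FitResult",
  representation(coefficients = "data.frame", varcomp = "numeric",
                 loglik = "numeric", converged = "logical",
                 iterations = "integer", nRecords = "integer",
                 nBulls = "integer", df = "numeric",
                 trajectory = "data.frame"))

setValidity("FitResult", function(object) {
  vc <- object@varcomp
  if (!all(c("sigma_a2", "sigma_pe2", "sigma_e2") %in% names(vc)))
    return("varcomp must contain sigma_a2, sigma_pe2, sigma_e2")
  if (any(vc < 0)) return("variance components must be nonnegative")
  ok <- is.na(object@coefficients$se) | object@coefficients$se > 0
  if (!all(ok)) return("SEs must be positive for estimable terms")
  TRUE
})
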