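#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z` the dosage matrix centred
#' at twice the observed allele frequencies. A small ridge is added to the
#' diagonal so downstream Cholesky factorisations are stable. Built from
#' the post-QC marker set (see [filterMarkersQC()]).
#'
#' @param g a [GenotypeData-class] object with no monomorphic markers.
#' @param ridge diagonal stabiliser (default 1e-6).
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
buildGrm <- function(g, ridge = 1e-6) {
  stopifnot(is(g, "GenotypeData"))
  d <- dosage(g)
  if (anyNA(d)) stop("missing genotypes are not supported")
  p <- colMeans(d) / 2
  if (any(p == 0 | p == 1))
    stop("monomorphic marker(s) present; run filterMarkersQC first")
  z <- sweep(d, 2, 2 * p)
  sc <- 2 * sum(p * (1 - p))
  grm <- tcrossprod(z) / sc
  diag(grm) <- diag(grm) + ridge
  dimnames(grm) <- list(rownames(d), rownames(d))
  grm
}
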