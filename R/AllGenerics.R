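#' Accessors for GenotypeData
#'
#' @param x a [GenotypeData-class] object.
#' @return `dosage()` the samples x markers integer matrix; `markerMap()` the
#'   marker map `data.frame`; `sampleIds()` character vector;
#'   `nSamples()`/`nMarkers()` dimensions.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname genotype-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname genotype-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname genotype-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname genotype-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname genotype-accessors
setMethod("dosage", "GenotypeData", function(x) x@dosage)
#' @rdname genotype-accessors
setMethod("markerMap", "GenotypeData", function(x) x@map)
#' @rdname genotype-accessors
setMethod("sampleIds", "GenotypeData", function(x) rownames(x@dosage))
#' @rdname genotype-accessors
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosage))
#' @rdname genotype-accessors
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosage))

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "markers on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  if (anyNA(object@dosage)) cat("  contains missing genotypes\n")
})

#' Accessors for FitResult
#'
#' @param x a [FitResult-class] object.
#' @return `coefTable()` the coefficient `data.frame`; `varComp()` the named
#'   variance-component vector; `logLik()`-style value via `restrictedLogLik()`.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
#' @rdname fit-accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname fit-accessors
#' @export
setGeneric("restrictedLogLik", function(x) standardGeneric("restrictedLogLik"))
#' @rdname fit-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname fit-accessors
#' @export
setGeneric("remlTrajectory", function(x) standardGeneric("remlTrajectory"))

#' @rdname fit-accessors
setMethod("coefTable", "FitResult", function(x) x@coefficients)
#' @rdname fit-accessors
setMethod("varComp", "FitResult", function(x) x@varcomp)
#' @rdname fit-accessors
setMethod("restrictedLogLik", "FitResult", function(x) x@loglik)
#' @rdname fit-accessors
setMethod("isConverged", "FitResult", function(x) x@converged)
#' @rdname fit-accessors
setMethod("remlTrajectory", "FitResult", function(x) x@trajectory)

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", object@nRecords, "records,", object@nBulls, "bulls;",
      if (object@converged) "converged" else "NOT converged",
      "in", object@iterations, "iterations\n")
  vc <- object@varcomp
  cat(sprintf("  sigma_a2 = %.4g  sigma_pe2 = %.4g  sigma_e2 = %.4g\n",
              vc["sigma_a2"], vc["sigma_pe2"], vc["sigma_e2"]))
  cat("  logLik =", format(object@loglik), "\n")
  print(utils::head(object@coefficients, 10), row.names = FALSE)
  if (nrow(object@coefficients) > 10)
    cat("  ...", nrow(object@coefficients) - 10, "more terms\n")
})
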