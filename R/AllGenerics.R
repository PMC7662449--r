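#' Accessors for pathGBC classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `dosage()` returns the animals-by-SNPs dosage matrix, `isMissing()` its
#' missingness mask, `animalIds()`/`snpIds()`/`breeds()` the identifier
#' vectors, `freq()`/`nObs()` the frequency and observation-count matrices,
#' `pathCoefficients()` the solved path coefficients, `composition()` the
#' breed simplex of an estimate and `reliability()` its explained-variance
#' reliability.
#'
#' @param x a pathGBC object.
#' @return The corresponding slot content (see above).
#' @name accessors
#' @aliases dosage isMissing animalIds snpIds breeds freq nObs
#'   pathCoefficients composition reliability
#' @examples
#' g <- GenotypeMatrix(matrix(c(2, 0, 1, NA), 2, 2,
#'        dimnames = list(c("a1", "a2"), c("s1", "s2"))))
#' dosage(g); animalIds(g); snpIds(g); isMissing(g)
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))
#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("breeds", function(x) standardGeneric("breeds"))
#' @rdname accessors
#' @export
setGeneric("freq", function(x) standardGeneric("freq"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("pathCoefficients", function(x) standardGeneric("pathCoefficients"))
#' @rdname accessors
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))
#' @rdname accessors
#' @export
setGeneric("reliability", function(x) standardGeneric("reliability"))

#' @rdname accessors
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
setMethod("isMissing", "GenotypeMatrix", function(x) is.na(x@dosage))
#' @rdname accessors
setMethod("animalIds", "GenotypeMatrix", function(x) rownames(x@dosage))
#' @rdname accessors
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @rdname accessors
setMethod("snpIds", "AlleleFreqTable", function(x) rownames(x@freq))
#' @rdname accessors
setMethod("breeds", "AlleleFreqTable", function(x) colnames(x@freq))
#' @rdname accessors
setMethod("freq", "AlleleFreqTable", function(x) x@freq)
#' @rdname accessors
setMethod("nObs", "AlleleFreqTable", function(x) x@nObs)

#' @rdname accessors
setMethod("breeds", "PathSolution", function(x) x@breeds)
#' @rdname accessors
setMethod("pathCoefficients", "PathSolution", function(x) x@pYX)
#' @rdname accessors
setMethod("reliability", "PathSolution", function(x) x@reliability)

#' @rdname accessors
setMethod("composition", "GBCEstimate", function(x) x@composition)
#' @rdname accessors
setMethod("breeds", "GBCEstimate", function(x) names(x@composition))
#' @rdname accessors
setMethod("reliability", "GBCEstimate", function(x) x@reliability)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat(sprintf("GenotypeMatrix: %d animals x %d SNPs (%.1f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
})

setMethod("show", "AlleleFreqTable", function(object) {
  f <- object@freq
  cat(sprintf("AlleleFreqTable: %d SNPs x %d breeds [%s]\n",
              nrow(f), ncol(f), paste(colnames(f), collapse = ", ")))
})

setMethod("show", "CorrelationStructure", function(object) {
  cat(sprintf("CorrelationStructure (%s, %d loci)\n",
              object@method, object@nLoci))
  print(round(object@rYX, 4))
})

setMethod("show", "PathSolution", function(object) {
  cat("PathSolution\n")
  m <- rbind(`path coefficient` = object@pYX,
             correlation = object@rYX,
             `direct determination` = object@directDet,
             `combined determination` = object@combinedDet)
  colnames(m) <- object@breeds
  print(round(m, 4))
  cat(sprintf("residual determination R = %.4f (reliability 1-R = %.4f)\n",
              object@residualDet, object@reliability))
})

setMethod("show", "GBCEstimate", function(object) {
  cat(sprintf("GBCEstimate [%s] %s\n", object@method, object@id))
  print(round(object@composition, 4))
  if (!is.na(object@reliability))
    cat(sprintf("reliability = %.4f\n", object@reliability))
})

setMethod("show", "PathDiagram", function(object) {
  cat(sprintf("PathDiagram: %d nodes, %d causal edges, %d correlation arcs\n",
              length(object@nodes), nrow(object@edges), nrow(object@arcs)))
})

setMethod("show", "AdmixtureFit", function(object) {
  cat(sprintf("AdmixtureFit (loglik %.3f, %sconverged, %d loci)\n",
              object@loglik, if (object@converged) "" else "NOT ",
              object@nLoci))
  print(round(object@W, 4))
})

setMethod("show", "LinRegFit", function(object) {
  cat(sprintf("LinRegFit (intercept %.4f, condition %.2f, %d loci)\n",
              object@intercept, object@condition, object@nLoci))
  print(round(object@coef, 4))
})
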