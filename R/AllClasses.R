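#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: animals-by-SNPs allele dosages
#'
#' Container for diploid SNP genotypes coded as the count (0, 1 or 2) of the
#' counted allele (allele A). Rows are animals, columns are SNPs; missing
#' genotypes are `NA`. This is the canonical genotype representation used by
#' every estimator in the package: the regression coding on the allele-A
#' frequency scale (AA = 1, AB = 0.5, BB = 0) is obtained as dosage/2 at the
#' point of use, while the admixture likelihood consumes the 0--2 dosage
#' directly.
#'
#' @slot dosage numeric matrix, animals x SNPs, entries in \{0, 1, 2\} or
#'   `NA`; rownames are animal identifiers, colnames SNP identifiers, both
#'   unique.
#'
#' @seealso [readGenotypes()], [alleleFrequencies()], [simulateCrossbreds()]
#' @export
setClass("GenotypeMatrix", representation(dosage = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msg <- character(0)
  if (!is.numeric(d))
    msg <- c(msg, "dosage must be a numeric matrix")
  if ((nrow(d) > 0 && is.null(rownames(d))) ||
      (ncol(d) > 0 && is.null(colnames(d))))
    msg <- c(msg, "dosage must have animal row names and SNP column names")
  else {
    if (anyDuplicated(rownames(d)))
      msg <- c(msg, "animal ids must be unique")
    if (anyDuplicated(colnames(d)))
      msg <- c(msg, "snp ids must be unique")
  }
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix (animals x SNPs) of allele-A dosages in
#'   \{0,1,2\} with `NA` for missing; must carry unique row (animal) and
#'   column (SNP) names.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c(2, 1, 0, NA), 2, 2,
#'             dimnames = list(c("A1", "A2"), c("rs1", "rs2")))
#' GenotypeMatrix(m)
#' @export
GenotypeMatrix <- function(dosage) {
  new("GenotypeMatrix", dosage = as.matrix(dosage))
}

#' AlleleFreqTable: SNPs-by-breeds allele-A frequencies
#'
#' Reference-panel allele frequencies: one row per SNP, one column per breed,
#' entries in \[0, 1\] (frequency of allele A) or `NA` where a breed has no
#' observed genotypes at a locus. `nObs` records the number of non-missing
#' allele observations (2 x genotyped animals) behind each cell; it is `NA`
#' for tables whose provenance does not carry counts (e.g. simulated
#' population frequencies or tables read from plain files).
#'
#' @slot freq numeric matrix, SNPs x breeds, in \[0,1\] or `NA`; rownames are
#'   SNP ids, colnames breed names, both unique.
#' @slot nObs numeric matrix of the same shape (allele observation counts),
#'   or `NULL` when unknown.
#'
#' @seealso [alleleFrequencies()], [readFrequencyTable()]
#' @export
setClass("AlleleFreqTable",
         representation(freq = "matrix", nObs = "matrixOrNULL"))

setValidity("AlleleFreqTable", function(object) {
  f <- object@freq
  msg <- character(0)
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msg <- c(msg, "freq must have SNP row names and breed column names")
  else {
    if (anyDuplicated(rownames(f))) msg <- c(msg, "snp ids must be unique")
    if (anyDuplicated(colnames(f))) msg <- c(msg, "breed names must be unique")
  }
  v <- f[!is.na(f)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (!is.null(object@nObs)) {
    if (!identical(dim(object@nObs), dim(f)))
      msg <- c(msg, "nObs must match the shape of freq")
    w <- object@nObs[!is.na(object@nObs)]
    if (length(w) && any(w < 0))
      msg <- c(msg, "nObs must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleFreqTable
#'
#' @param freq numeric matrix (SNPs x breeds) of allele-A frequencies in
#'   \[0,1\], with SNP rownames and breed colnames.
#' @param nObs optional matrix of allele observation counts, same shape.
#' @return An [AlleleFreqTable-class] object.
#' @export
AlleleFreqTable <- function(freq, nObs = NULL) {
  new("AlleleFreqTable", freq = as.matrix(freq),
      nObs = if (is.null(nObs)) NULL else as.matrix(nObs))
}

#' CorrelationStructure: target-breed and breed-breed correlations
#'
#' The correlation inputs of the path analysis: `rYX` holds the correlation
#' of the target (an animal's coded genotypes or a composite breed's allele
#' frequencies) with each reference breed's allele frequencies, and `RXX`
#' the breed-by-breed correlation matrix, both computed over the same loci
#' with pairwise-complete observations.
#'
#' @slot rYX named numeric vector, one correlation per breed, in \[-1,1\].
#' @slot RXX symmetric unit-diagonal breed correlation matrix.
#' @slot method "pearson" or "spearman".
#' @slot nLoci number of loci entering the target-breed correlations.
#'
#' @seealso [correlationStructure()], [solvePathCoefficients()]
#' @export
setClass("CorrelationStructure",
         representation(rYX = "numeric", RXX = "matrix",
                        method = "character", nLoci = "integer"))

setValidity("CorrelationStructure", function(object) {
  msg <- character(0)
  R <- object@RXX
  if (nrow(R) != ncol(R) || !isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    msg <- c(msg, "RXX must be a symmetric square matrix")
  else if (max(abs(diag(R) - 1)) > 1e-8)
    msg <- c(msg, "RXX must have unit diagonal")
  if (length(object@rYX) != nrow(R))
    msg <- c(msg, "rYX length must match RXX dimension")
  ok <- c(object@rYX, R)
  ok <- ok[!is.na(ok)]
  if (length(ok) && max(abs(ok)) > 1 + 1e-8)
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!object@method %in% c("pearson", "spearman"))
    msg <- c(msg, "method must be 'pearson' or 'spearman'")
  if (length(msg)) msg else TRUE
})

#' PathSolution: solved path coefficients and determination decomposition
#'
#' Result of solving the standardized (path) system for one target: the path
#' coefficients, the determination coefficients they imply, and the residual
#' determination. `combinedDet` holds the signed per-breed coefficients of
#' combined determination (direct square plus correlational cross terms);
#' their sum plus `residualDet` equals 1 exactly when the system is
#' consistent. `pYE` is the residual path coefficient (coefficient of
#' alienation), clamped to 0 with a warning when the correlational terms
#' push total determination above 1.
#'
#' @slot breeds breed names, in input column order.
#' @slot pYX per-breed path coefficients (standardized regression
#'   coefficients).
#' @slot rYX per-breed correlations of the target with each breed.
#' @slot RXX breed correlation matrix.
#' @slot directDet per-breed squared path coefficients.
#' @slot combinedDet per-breed coefficients of combined determination
#'   (signed; negative values are possible and retained here).
#' @slot residualDet unexplained variance R = 1 - sum(combinedDet)
#'   (unclamped, may be negative).
#' @slot pYE residual path coefficient sqrt(max(0, R)).
#' @slot reliability 1 - R.
#'
#' @seealso [solvePathCoefficients()], [dGBC()], [cGBC()]
#' @export
setClass("PathSolution",
         representation(breeds = "character", pYX = "numeric",
                        rYX = "numeric", RXX = "matrix",
                        directDet = "numeric", combinedDet = "numeric",
                        residualDet = "numeric", pYE = "numeric",
                        reliability = "numeric"))

setValidity("PathSolution", function(object) {
  k <- length(object@breeds)
  msg <- character(0)
  if (length(object@pYX) != k || length(object@directDet) != k ||
      length(object@combinedDet) != k)
    msg <- c(msg, "coefficient vectors must have one entry per breed")
  if (any(object@directDet < -1e-12))
    msg <- c(msg, "direct determinations must be non-negative")
  tot <- sum(object@combinedDet) + object@residualDet
  if (abs(tot - 1) > 1e-8)
    msg <- c(msg, "combined determinations and residual must sum to 1")
  if (length(msg)) msg else TRUE
})

#' GBCEstimate: a breed-composition estimate for one target
#'
#' A point on the breed simplex together with provenance: which estimator
#' produced it, over how many loci, and (for path-analysis estimates) the
#' explained-variance reliability. `clamped` records whether any negative
#' component was truncated to zero before renormalisation.
#'
#' @slot id target identifier (animal id or population label).
#' @slot method one of "linreg", "admixture", "path_direct",
#'   "path_combined", "diagram".
#' @slot composition named numeric simplex over breeds (entries >= 0,
#'   summing to 1).
#' @slot reliability 1 - R for path estimates; `NA` otherwise.
#' @slot nLoci number of loci used; `NA` for diagram arithmetic.
#' @slot clamped TRUE if negative components were truncated.
#'
#' @export
setClass("GBCEstimate",
         representation(id = "character", method = "character",
                        composition = "numeric", reliability = "numeric",
                        nLoci = "integer", clamped = "logical"))

setValidity("GBCEstimate", function(object) {
  msg <- character(0)
  comp <- object@composition
  if (is.null(names(comp)))
    msg <- c(msg, "composition must be named by breed")
  if (any(comp < -1e-10))
    msg <- c(msg, "composition entries must be non-negative")
  if (abs(sum(comp) - 1) > 1e-8)
    msg <- c(msg, "composition must sum to 1")
  if (!object@method %in%
      c("linreg", "admixture", "path_direct", "path_combined", "diagram"))
    msg <- c(msg, "unknown method label")
  if (length(msg)) msg else TRUE
})

#' PathDiagram: nodes, causal edges and correlation arcs
#'
#' A Wright path diagram: directed coefficient edges form a DAG from
#' exogenous breeds through intermediate composites down to the target, and
#' two-headed correlation arcs connect exogenous nodes only. Used to
#' propagate breed determination through multi-generation pedigrees (e.g.
#' composite-of-composite crosses) by the compound-path rule.
#'
#' @slot nodes node labels.
#' @slot edges data.frame with columns `from`, `to`, `coef` (path
#'   coefficients on directed edges).
#' @slot arcs data.frame with columns `from`, `to`, `r` (correlations
#'   between exogenous nodes); may have zero rows.
#'
#' @seealso [pathDiagram()], [traceWrightPaths()],
#'   [determinationFromDiagram()]
#' @export
setClass("PathDiagram",
         representation(nodes = "character", edges = "data.frame",
                        arcs = "data.frame"))

setValidity("PathDiagram", function(object) {
  msg <- character(0)
  e <- object@edges
  a <- object@arcs
  if (!all(c("from", "to", "coef") %in% names(e)))
    msg <- c(msg, "edges must have columns from, to, coef")
  if (!all(c("from", "to", "r") %in% names(a)))
    msg <- c(msg, "arcs must have columns from, to, r")
  if (length(msg)) return(msg)
  known <- c(e$from, e$to, a$from, a$to)
  if (!all(known %in% object@nodes))
    msg <- c(msg, "edges/arcs reference unknown nodes")
  if (nrow(e) && !all(is.finite(e$coef)))
    msg <- c(msg, "edge coefficients must be finite")
  if (nrow(a) && !all(is.finite(a$r)))
    msg <- c(msg, "arc correlations must be finite")
  ## DAG check by repeated removal of sink-free nodes
  if (nrow(e)) {
    nodes <- object@nodes
    ed <- e[, c("from", "to")]
    repeat {
      sinks <- setdiff(nodes, ed$from)
      if (!length(sinks)) break
      nodes <- setdiff(nodes, sinks)
      ed <- ed[ed$to %in% nodes, , drop = FALSE]
      if (!nrow(ed)) break
    }
    if (nrow(ed) && !length(setdiff(nodes, ed$from)))
      msg <- c(msg, "causal edges must form a DAG")
  }
  ## arcs only between exogenous nodes (no incoming causal edge)
  if (nrow(a)) {
    endo <- unique(e$to)
    if (any(a$from %in% endo) || any(a$to %in% endo))
      msg <- c(msg, "correlation arcs are only allowed between exogenous nodes")
  }
  if (length(msg)) msg else TRUE
})

#' LinRegFit: ordinary least squares fit of coded genotypes on breed
#' frequencies
#'
#' @slot intercept fitted intercept.
#' @slot coef named per-breed regression coefficients (unadjusted; any real
#'   values).
#' @slot sigma2 residual variance (RSS / df).
#' @slot condition ratio of the extreme singular values of the centered
#'   design (collinearity diagnostic).
#' @slot nLoci complete loci used.
#'
#' @seealso [fitLinReg()], [adjustCoefficients()]
#' @export
setClass("LinRegFit",
         representation(intercept = "numeric", coef = "numeric",
                        sigma2 = "numeric", condition = "numeric",
                        nLoci = "integer"))

#' AdmixtureFit: maximum-likelihood admixture proportions
#'
#' @slot W named admixture proportions on the simplex.
#' @slot loglik log-likelihood at W, omitting the W-independent
#'   binomial-constant term.
#' @slot nIter optimizer iteration count.
#' @slot converged TRUE if the optimizer reported convergence.
#' @slot nLoci complete loci used.
#'
#' @seealso [fitAdmixture()]
#' @export
setClass("AdmixtureFit",
         representation(W = "numeric", loglik = "numeric",
                        nIter = "integer", converged = "logical",
                        nLoci = "integer"))

setValidity("AdmixtureFit", function(object) {
  msg <- character(0)
  if (any(object@W < -1e-10)) msg <- c(msg, "W must be non-negative")
  if (abs(sum(object@W) - 1) > 1e-8) msg <- c(msg, "W must sum to 1")
  if (length(msg)) msg else TRUE
})
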