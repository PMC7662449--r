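## Path-analysis GBC: the package's core. Path coefficients are the
## standardized regression coefficients of the target on the reference
## breeds' allele frequencies; solving the normal equations of the
## standardized system R_xx p = r_yx decomposes the target's variance into
## per-breed direct determinations (p^2), correlational cross terms, and a
## residual. D-GBC normalises the direct determinations; C-GBC normalises
## the combined (direct + correlational) determinations.

.pathSolution <- function(breeds, p, rYX, RXX, warn = TRUE) {
  dd <- p^2
  cd <- as.vector(p * (RXX %*% p))  # p_j^2 + sum_{j' != j} p_j r_jj' p_j'
  R <- 1 - sum(cd)
  if (R < 0 && warn)
    warning(sprintf("residual determination R = %.4f < 0 (correlational terms exceed total variance); residual path coefficient clamped to 0", R))
  new("PathSolution", breeds = breeds,
      pYX = stats::setNames(p, breeds),
      rYX = stats::setNames(rYX, breeds), RXX = RXX,
      directDet = stats::setNames(dd, breeds),
      combinedDet = stats::setNames(cd, breeds),
      residualDet = R, pYE = sqrt(max(0, R)), reliability = 1 - R)
}

#' Solve path coefficients from a correlation structure
#'
#' Solves the standardized normal equations `R_xx p = r_yx` for the vector
#' of path coefficients (solving the linear system, not inverting), then
#' fills the full determination decomposition: direct determinations
#' `p^2`, combined determinations (direct plus correlational cross terms),
#' residual determination `R = 1 - sum(combined)`, the residual path
#' coefficient `sqrt(max(0, R))` and the reliability `1 - R`.
#'
#' @param cs a [CorrelationStructure-class] (from
#'   [correlationStructure()]), or any list with elements `rYX` and `RXX`.
#' @param conditionCap refuse to solve when the condition number of `RXX`
#'   (ratio of extreme absolute eigenvalues) exceeds this cap; default
#'   `1e8`.
#' @return A [PathSolution-class].
#' @export
solvePathCoefficients <- function(cs, conditionCap = 1e8) {
  if (is(cs, "CorrelationStructure")) {
    rYX <- cs@rYX; RXX <- cs@RXX
  } else {
    rYX <- cs$rYX; RXX <- cs$RXX
  }
  brds <- colnames(RXX)
  if (is.null(brds)) brds <- names(rYX)
  if (is.null(brds)) brds <- paste0("x", seq_along(rYX))
  ev <- abs(eigen(RXX, symmetric = TRUE, only.values = TRUE)$values)
  kappa <- if (min(ev) == 0) Inf else max(ev) / min(ev)
  if (!is.finite(kappa) || kappa > conditionCap) {
    off <- abs(RXX); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf("breed correlation matrix is singular or ill-conditioned (condition number %.3g > %.3g); most correlated pair: %s - %s (r = %.4f)",
                 kappa, conditionCap, brds[worst[1]], brds[worst[2]],
                 RXX[worst[1], worst[2]]))
  }
  p <- as.vector(solve(RXX, rYX))
  .pathSolution(brds, p, rYX, RXX)
}

#' Closed-form path coefficients for two reference breeds
#'
#' For two exogenous variables the system solves in closed form:
#' `p_y1 = (r_y1 - r_12 r_y2) / (1 - r_12^2)` and symmetrically for
#' `p_y2` -- each the semi-partial correlation of that breed with the
#' target.
#'
#' @param r_y1,r_y2 correlations of the target with breeds 1 and 2.
#' @param r_12 correlation between the two breeds; must satisfy
#'   `|r_12| < 1`.
#' @return numeric vector `c(p_y1, p_y2)`.
#' @examples
#' solveBivariate(0.6, 0.5, 0.4)  # 0.476190 0.309524
#' @export
solveBivariate <- function(r_y1, r_y2, r_12) {
  if (abs(r_12) >= 1)
    stop("singular system: |r_12| must be < 1")
  c((r_y1 - r_12 * r_y2) / (1 - r_12^2),
    (r_y2 - r_12 * r_y1) / (1 - r_12^2))
}

#' Path solution via standardized multiple regression
#'
#' The dual route to [solvePathCoefficients()]: fit the unstandardized
#' least-squares regression of the target on the breed columns and rescale
#' each coefficient by `sd(x_j) / sd(y)`. On the same data the two routes
#' agree to numerical precision, which is the package's internal
#' cross-check of the correlation-based solver.
#'
#' @param y numeric target vector (any location/scale; standardization is
#'   internal).
#' @param X numeric matrix of breed columns aligned to `y`.
#' @return A [PathSolution-class].
#' @export
pathFromRegression <- function(y, X) {
  X <- as.matrix(X)
  keep <- !is.na(y) & rowSums(is.na(X)) == 0
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (length(y) < ncol(X) + 2)
    stop("need at least K + 2 complete observations")
  brds <- colnames(X)
  if (is.null(brds)) brds <- paste0("x", seq_len(ncol(X)))
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < ncol(X) + 1)
    stop("rank-deficient design: breed columns are collinear")
  b <- fit$coefficients[-1]
  p <- as.vector(b * apply(X, 2, stats::sd) / stats::sd(y))
  RXX <- stats::cor(X)
  RXX <- (RXX + t(RXX)) / 2; diag(RXX) <- 1
  dimnames(RXX) <- list(brds, brds)
  rYX <- as.vector(stats::cor(y, X))
  .pathSolution(brds, p, rYX, RXX)
}

#' Coefficients of combined determination
#'
#' Per breed, the direct square plus the correlational cross terms:
#' `d_j = p_j^2 + sum_{j' != j} p_j r_jj' p_j'`. Summed over breeds this
#' equals the quadratic form `p' R_xx p`, the explained fraction of the
#' target's standardized variance.
#'
#' @param p_yx numeric vector of path coefficients.
#' @param R_xx breed correlation matrix (symmetric, unit diagonal).
#' @return numeric vector of signed combined determinations, one per
#'   breed.
#' @export
combinedDetermination <- function(p_yx, R_xx) {
  R_xx <- as.matrix(R_xx)
  if (length(p_yx) != nrow(R_xx) || nrow(R_xx) != ncol(R_xx))
    stop("p_yx and R_xx dimensions do not agree")
  out <- as.vector(p_yx * (R_xx %*% p_yx))
  names(out) <- names(p_yx)
  out
}

#' Residual determination, residual path coefficient and reliability
#'
#' `R = 1 - sum(combined determinations)` is the fraction of the target's
#' variance the reference breeds leave unexplained; the residual path
#' coefficient (coefficient of alienation) is `sqrt(max(0, R))`, clamped
#' with a warning when correlational terms push total determination above
#' one. `1 - R` is reported as the reliability of the composition
#' estimate. (The source literature is ambiguous about whether small
#' `1 - R` or small `R` marks the more reliable estimate; both quantities
#' are returned so users can apply either convention.)
#'
#' @inheritParams combinedDetermination
#' @return list with elements `R`, `pYE`, `reliability`.
#' @export
residualDetermination <- function(p_yx, R_xx) {
  R <- 1 - sum(combinedDetermination(p_yx, R_xx))
  if (R < 0)
    warning(sprintf("residual determination R = %.4f < 0; residual path coefficient clamped to 0", R))
  list(R = R, pYE = sqrt(max(0, R)), reliability = 1 - R)
}

.asGBC <- function(comp, id, method, reliability = NA_real_,
                   nLoci = NA_integer_, clamped = FALSE) {
  new("GBCEstimate", id = id, method = method, composition = comp,
      reliability = reliability, nLoci = as.integer(nLoci),
      clamped = clamped)
}

#' Direct genomic breed composition (D-GBC)
#'
#' The relative ratio of squared path coefficients,
#' `p_j^2 / sum_j p_j^2`: only the direct determination of each breed
#' counts, making the measure robust to correlations between reference
#' breeds.
#'
#' @param p_yx path coefficients (named by breed, or from a
#'   [PathSolution-class] via [pathCoefficients()]).
#' @param id target identifier for the returned estimate.
#' @param reliability optional reliability to attach.
#' @param nLoci optional locus count to attach.
#' @return A [GBCEstimate-class] with method `"path_direct"`.
#' @examples
#' composition(dGBC(c(Angus = 0.668, Brahman = 0.418)))  # 0.719 0.281
#' @export
dGBC <- function(p_yx, id = "target", reliability = NA_real_,
                 nLoci = NA_integer_) {
  if (is(p_yx, "PathSolution")) {
    if (is.na(reliability)) reliability <- p_yx@reliability
    p_yx <- p_yx@pYX
  }
  ss <- sum(p_yx^2)
  if (ss == 0) stop("all path coefficients are zero")
  comp <- p_yx^2 / ss
  if (is.null(names(comp))) names(comp) <- paste0("x", seq_along(comp))
  .asGBC(comp, id, "path_direct", reliability, nLoci)
}

#' Combined genomic breed composition (C-GBC)
#'
#' The relative ratio of combined determinations: each breed's direct
#' square plus its correlational cross terms, divided by the total. With
#' uncorrelated reference breeds C-GBC equals D-GBC. Negative combined
#' components (possible when cross terms are negative) are truncated to
#' zero and the remainder renormalised, with `clamped = TRUE` recorded on
#' the estimate; the signed values remain available via
#' [combinedDetermination()].
#'
#' @param p_yx path coefficients, or a [PathSolution-class].
#' @param R_xx breed correlation matrix (ignored when `p_yx` is a
#'   [PathSolution-class]).
#' @inheritParams dGBC
#' @return A [GBCEstimate-class] with method `"path_combined"`.
#' @export
cGBC <- function(p_yx, R_xx = NULL, id = "target", reliability = NA_real_,
                 nLoci = NA_integer_) {
  if (is(p_yx, "PathSolution")) {
    if (is.na(reliability)) reliability <- p_yx@reliability
    R_xx <- p_yx@RXX
    p_yx <- p_yx@pYX
  }
  d <- combinedDetermination(p_yx, R_xx)
  tot <- sum(d)
  if (tot <= 0) stop("total combined determination is not positive")
  comp <- d / tot
  clamped <- any(comp < 0)
  if (clamped) {
    comp <- pmax(comp, 0)
    comp <- comp / sum(comp)
  }
  if (is.null(names(comp))) names(comp) <- paste0("x", seq_along(comp))
  .asGBC(comp, id, "path_combined", reliability, nLoci, clamped)
}

#' Path-analysis GBC for one target
#'
#' The full pipeline: correlations of the target with the reference breeds
#' ([correlationStructure()]), path coefficients
#' ([solvePathCoefficients()]), then D-GBC or C-GBC with the reliability
#' `1 - R` attached.
#'
#' @param target dosage vector (`targetType = "dosage"`) or composite
#'   allele-frequency vector (`targetType = "frequency"`), aligned to `F`.
#' @param F an [AlleleFreqTable-class].
#' @param method correlation type, `"pearson"` or `"spearman"`.
#' @param mode `"direct"` for D-GBC or `"combined"` for C-GBC.
#' @param targetType see [correlationStructure()].
#' @param id identifier for the returned estimate.
#' @param conditionCap passed to [solvePathCoefficients()].
#' @return A [GBCEstimate-class].
#' @export
estimatePathGBC <- function(target, F, method = c("pearson", "spearman"),
                            mode = c("direct", "combined"),
                            targetType = c("frequency", "dosage"),
                            id = "target", conditionCap = 1e8) {
  mode <- match.arg(mode)
  cs <- correlationStructure(target, F, method = match.arg(method),
                             targetType = match.arg(targetType))
  sol <- solvePathCoefficients(cs, conditionCap = conditionCap)
  if (mode == "direct")
    dGBC(sol, id = id, nLoci = cs@nLoci)
  else
    cGBC(sol, id = id, nLoci = cs@nLoci)
}

#' Path-analysis GBC for every animal in a genotype matrix
#'
#' @param G a [GenotypeMatrix-class] aligned to `F`.
#' @param F an [AlleleFreqTable-class].
#' @param ... passed to [estimatePathGBC()] (per-animal `targetType` is
#'   forced to `"dosage"`).
#' @return data.frame with one row per animal: `id`, one column per breed,
#'   `reliability`, `n_loci`, `clamped`.
#' @export
pathGBCMatrix <- function(G, F, ...) {
  d <- dosage(G)
  rows <- lapply(rownames(d), function(a) {
    est <- estimatePathGBC(d[a, ], F, targetType = "dosage", id = a, ...)
    c(list(id = a), as.list(composition(est)),
      list(reliability = est@reliability, n_loci = est@nLoci,
           clamped = est@clamped))
  })
  do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE)))
}
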