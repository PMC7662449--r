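## Genotype coding, per-breed allele frequencies, standardization and the
## correlation structures every estimator consumes.

#' Per-breed allele-A frequencies from labelled genotypes
#'
#' For each SNP and breed, the allele-A frequency is the dosage sum over
#' non-missing genotypes divided by twice their count; the count of allele
#' observations (2 x genotyped animals) is recorded alongside. A cell with
#' no observed genotypes yields a missing frequency.
#'
#' @param G a [GenotypeMatrix-class].
#' @param labels breed labels as returned by [readBreedLabels()], or any
#'   data.frame with columns `animal_id` and `breed`. Only labelled animals
#'   present in `G` contribute.
#' @return An [AlleleFreqTable-class] with `nObs` filled, breeds in first
#'   appearance order.
#' @examples
#' g <- GenotypeMatrix(matrix(c(2, 1), 2, 1,
#'        dimnames = list(c("a1", "a2"), "s1")))
#' lab <- data.frame(animal_id = c("a1", "a2"), breed = "Angus")
#' freq(alleleFrequencies(g, lab))  # (2+1)/4 = 0.75
#' @export
alleleFrequencies <- function(G, labels) {
  if (!all(c("animal_id", "breed") %in% names(labels)))
    stop("labels must have columns animal_id and breed")
  labels <- labels[labels$animal_id %in% animalIds(G), , drop = FALSE]
  brds <- unique(labels$breed)
  if (!length(brds)) stop("no labelled animals found in the genotype matrix")
  d <- dosage(G)
  f <- matrix(NA_real_, ncol(d), length(brds),
              dimnames = list(colnames(d), brds))
  nob <- matrix(0, ncol(d), length(brds), dimnames = dimnames(f))
  for (b in brds) {
    ids <- labels$animal_id[labels$breed == b]
    if (!length(ids)) stop("breed with zero animals: ", b)
    db <- d[ids, , drop = FALSE]
    cnt <- 2 * colSums(!is.na(db))
    s <- colSums(db, na.rm = TRUE)
    f[, b] <- ifelse(cnt > 0, s / cnt, NA_real_)
    nob[, b] <- cnt
  }
  AlleleFreqTable(f, nob)
}

#' Standardize a vector to zero mean and unit sample SD
#'
#' Centring and scaling with the sample (n-1) standard deviation; the
#' standardization underlying path coefficients as standardized regression
#' coefficients.
#'
#' @param v numeric vector, length >= 2, non-constant.
#' @return `(v - mean(v)) / sd(v)`.
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
#' @export
standardize <- function(v) {
  if (length(v) < 2) stop("standardize needs length >= 2")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (v - mean(v)) / s
}

#' Correlations of a target with reference breeds, and between breeds
#'
#' Computes the inputs of the path analysis: the per-breed correlation
#' `rYX` of the target with each breed's allele frequencies and the
#' breed-by-breed correlation matrix `RXX`, both over loci with
#' pairwise-complete observations. The target is either a per-animal dosage
#' vector (`targetType = "dosage"`, rescaled by /2 to the individual
#' allele-frequency scale -- the "genotype data" mode) or a composite
#' population's allele-frequency vector (`targetType = "frequency"`, the
#' "correlation data" mode).
#'
#' @param y numeric target vector aligned to the SNPs of `F`.
#' @param F an [AlleleFreqTable-class].
#' @param method `"pearson"` (default) or `"spearman"` (average ranks on
#'   ties).
#' @param targetType `"frequency"` or `"dosage"`.
#' @return A [CorrelationStructure-class].
#' @export
correlationStructure <- function(y, F, method = c("pearson", "spearman"),
                                 targetType = c("frequency", "dosage")) {
  method <- match.arg(method)
  targetType <- match.arg(targetType)
  f <- freq(F)
  if (length(y) != nrow(f))
    stop("target length must equal the number of SNPs in the table")
  if (targetType == "dosage") y <- y / 2
  complete <- !is.na(y) & rowSums(is.na(f)) == 0
  if (sum(!is.na(y) & !is.na(f[, 1])) < 3 || sum(complete) < 3)
    stop("need at least 3 complete loci for correlations")
  m <- cbind(y = y, f)
  cc <- stats::cor(m, use = "pairwise.complete.obs", method = method)
  rYX <- cc[1, -1]
  RXX <- cc[-1, -1, drop = FALSE]
  RXX <- (RXX + t(RXX)) / 2  # enforce exact symmetry
  diag(RXX) <- 1
  if (anyNA(rYX) || anyNA(RXX))
    stop("need at least 3 complete loci for every breed pair")
  new("CorrelationStructure", rYX = rYX, RXX = RXX, method = method,
      nLoci = as.integer(sum(complete)))
}
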