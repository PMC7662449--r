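## GBC by adjusted linear regression: coded genotypes (allele-A proportion
## per individual, dosage/2) regressed with intercept on the reference
## breeds' allele frequencies; coefficients then projected to the simplex.

#' Ordinary least squares of coded genotypes on breed frequencies
#'
#' Fits `y = mu + sum_j b_j x_j + e` over loci complete in both the target
#' and every breed column, where `y` is the animal's genotype coded on the
#' allele-frequency scale (AA = 1, AB = 0.5, BB = 0, i.e. dosage/2) and
#' `x_j` the allele-A frequencies of breed `j`. The coefficients are
#' unconstrained; [adjustCoefficients()] maps them to the breed simplex.
#'
#' @param y numeric vector in \[0,1\] (dosage/2), aligned to `F`'s SNPs;
#'   `NA` allowed.
#' @param F an [AlleleFreqTable-class].
#' @return A [LinRegFit-class] with intercept, per-breed coefficients,
#'   residual variance and the condition diagnostic (ratio of extreme
#'   singular values of the centered design).
#' @export
fitLinReg <- function(y, F) {
  f <- freq(F)
  if (length(y) != nrow(f))
    stop("target length must equal the number of SNPs in the table")
  keep <- !is.na(y) & rowSums(is.na(f)) == 0
  K <- ncol(f)
  if (sum(keep) < K + 2)
    stop("need at least K + 2 complete loci to fit the regression")
  yy <- y[keep]
  X <- cbind(`(Intercept)` = 1, f[keep, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[seq(qx$rank + 1, ncol(X))]
    stop("rank-deficient design; collinear breeds: ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  beta <- qr.coef(qx, yy)
  res <- yy - X %*% beta
  sv <- svd(scale(f[keep, , drop = FALSE], center = TRUE, scale = FALSE),
            nu = 0, nv = 0)$d
  new("LinRegFit",
      intercept = unname(beta[1]),
      coef = stats::setNames(beta[-1], colnames(f)),
      sigma2 = sum(res^2) / (sum(keep) - ncol(X)),
      condition = sv[1] / sv[length(sv)],
      nLoci = as.integer(sum(keep)))
}

#' Project regression coefficients onto the breed simplex
#'
#' Negative coefficients are truncated to zero and the remainder rescaled
#' to sum to one -- the simplest adjustment consistent with bounding the
#' estimated composition and restricting the coefficient sum to 1. A
#' non-negative least squares fit is available upstream as a policy choice
#' but is not the default.
#'
#' @param b numeric vector of per-breed regression coefficients.
#' @return Named non-negative vector summing to 1.
#' @examples
#' adjustCoefficients(c(A = 0.7, B = 0.35))      # 2/3, 1/3
#' adjustCoefficients(c(0.5, -0.1, 0.6))         # 0.4545, 0, 0.5455
#' @export
adjustCoefficients <- function(b) {
  if (!length(b)) stop("empty coefficient vector")
  b <- pmax(b, 0)
  s <- sum(b)
  if (s <= 0)
    stop("no admissible composition: all coefficients are non-positive")
  b / s
}

#' Regression-based GBC for every animal in a genotype matrix
#'
#' Runs [fitLinReg()] + [adjustCoefficients()] per animal.
#'
#' @param G a [GenotypeMatrix-class] (SNPs already aligned to `F`, see
#'   [alignPanels()]).
#' @param F an [AlleleFreqTable-class].
#' @return data.frame with one row per animal: `id`, one column per breed,
#'   `n_loci`, `condition`.
#' @export
linregGBC <- function(G, F) {
  d <- dosage(G)
  out <- lapply(rownames(d), function(a) {
    fit <- fitLinReg(d[a, ] / 2, F)
    comp <- adjustCoefficients(fit@coef)
    c(list(id = a), as.list(comp),
      list(n_loci = fit@nLoci, condition = fit@condition))
  })
  do.call(rbind, lapply(out, function(x)
    as.data.frame(x, check.names = FALSE)))
}
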