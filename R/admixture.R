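## Supervised admixture model: reference allele frequencies are treated as
## known, and the ancestry proportions W maximise a binomial genotype
## likelihood under Hardy-Weinberg equilibrium at each locus.

#' Mixed allele frequency under admixture proportions
#'
#' The allele-A frequency a crossbred genome presents at each SNP is the
#' convex combination of the reference breeds' frequencies weighted by the
#' ancestry proportions, `f_i = sum_j x_ij w_j`, clipped to
#' `[eps, 1 - eps]` so monomorphic reference SNPs cannot produce log(0) in
#' the likelihood.
#'
#' @param W admixture proportions on the simplex (named or in breed column
#'   order).
#' @param F an [AlleleFreqTable-class] with complete frequencies for the
#'   loci used.
#' @param eps clipping bound, default `1e-6`.
#' @param tol tolerance for the simplex check on `W`.
#' @return numeric vector of per-SNP mixed frequencies in `[eps, 1 - eps]`.
#' @examples
#' f <- AlleleFreqTable(matrix(c(0.2, 0.6), 1, 2,
#'        dimnames = list("s1", c("A", "B"))))
#' mixtureFrequency(c(0.5, 0.5), f)  # 0.4
#' @export
mixtureFrequency <- function(W, F, eps = 1e-6, tol = 1e-6) {
  f <- freq(F)
  if (length(W) != ncol(f))
    stop("W must have one weight per breed")
  if (any(W < -tol) || abs(sum(W) - 1) > tol)
    stop("W is not on the simplex (weights >= 0 summing to 1)")
  mix <- as.vector(f %*% W)
  pmin(pmax(mix, eps), 1 - eps)
}

#' Genotype log-likelihood given mixed allele frequencies
#'
#' Under HWE the genotype at locus i is Binomial(2, f_i), so up to a
#' W-independent binomial constant the log-likelihood of a dosage vector is
#' `sum_i [ y_i ln f_i + (2 - y_i) ln(1 - f_i) ]`. The constant term is
#' omitted throughout the package (it cancels in optimisation and in any
#' comparison across W).
#'
#' @param y dosage vector (0/1/2, `NA` skipped).
#' @param f per-locus mixed frequencies in (0, 1), aligned to `y`.
#' @return The log-likelihood value (constant omitted).
#' @examples
#' genotypeLogLik(2, 0.5)          # 2 log 0.5
#' genotypeLogLik(c(2, 0), c(0.9, 0.1))  # 4 log 0.9
#' @export
genotypeLogLik <- function(y, f) {
  if (length(y) != length(f)) stop("y and f must be aligned")
  keep <- !is.na(y)
  y <- y[keep]; f <- f[keep]
  if (any(f <= 0 | f >= 1)) stop("mixed frequencies must lie strictly in (0, 1)")
  sum(y * log(f) + (2 - y) * log(1 - f))
}

#' Maximum-likelihood admixture proportions for one animal
#'
#' Maximises [genotypeLogLik()] over the breed simplex. The sum-to-one
#' constraint is handled by evaluating the likelihood at `w / sum(w)`; by
#' default the raw weights are additionally box-constrained to be
#' non-negative (`constraint = "box"`, quasi-Newton L-BFGS-B with analytic
#' gradient), while `constraint = "rescale"` reproduces the pure
#' rescaling scheme with unconstrained BFGS.
#'
#' @param y dosage vector (0/1/2, `NA` for missing), aligned to `F`'s SNPs.
#' @param F an [AlleleFreqTable-class].
#' @param init starting simplex, or `"uniform"` (1/K per breed).
#' @param tol relative objective-change convergence tolerance, default
#'   `1e-10` (gradient tolerance `1e-8`).
#' @param maxit iteration cap, default 500.
#' @param eps frequency clipping bound passed to [mixtureFrequency()].
#' @param constraint `"box"` (default) or `"rescale"`.
#' @return An [AdmixtureFit-class]; `converged = FALSE` flags an optimizer
#'   that hit the iteration cap (the best iterate is still returned).
#' @export
fitAdmixture <- function(y, F, init = "uniform", tol = 1e-10, maxit = 500,
                         eps = 1e-6, constraint = c("box", "rescale")) {
  constraint <- match.arg(constraint)
  f <- freq(F)
  if (ncol(f) < 2) stop("need at least 2 reference breeds")
  keep <- !is.na(y) & rowSums(is.na(f)) == 0
  yy <- y[keep]
  X <- f[keep, , drop = FALSE]
  M <- nrow(X)
  if (M < 50)
    warning("fewer than 50 complete loci; admixture estimates will be noisy")
  if (M < 1) stop("no complete loci")
  K <- ncol(X)
  if (max(apply(X, 1, function(r) diff(range(r)))) < 1e-12)
    warning("all breed columns identical: admixture solution is non-unique")

  w0 <- if (identical(init, "uniform")) rep(1 / K, K) else {
    if (length(init) != K || any(init < 0) || abs(sum(init) - 1) > 1e-6)
      stop("init must be 'uniform' or a simplex of length K")
    as.numeric(init)
  }

  clip <- function(v) pmin(pmax(v, eps), 1 - eps)
  negll <- function(w) {
    s <- sum(w)
    if (s <= 0) return(.Machine$double.xmax)
    fi <- clip(as.vector(X %*% w) / s)
    -sum(yy * log(fi) + (2 - yy) * log(1 - fi))
  }
  grad <- function(w) {
    s <- sum(w)
    fi <- clip(as.vector(X %*% w) / s)
    g <- yy / fi - (2 - yy) / (1 - fi)      # dL/df_i
    -as.vector(crossprod(X - fi, g)) / s    # df_i/dw_j = (x_ij - f_i)/s
  }

  if (constraint == "box") {
    opt <- stats::optim(pmax(w0, eps), negll, grad, method = "L-BFGS-B",
                        lower = rep(1e-9, K),
                        control = list(maxit = maxit,
                                       factr = tol / .Machine$double.eps,
                                       pgtol = 1e-8))
  } else {
    opt <- stats::optim(w0, negll, method = "BFGS",
                        control = list(maxit = maxit, reltol = tol))
  }
  W <- opt$par / sum(opt$par)
  W <- pmax(W, 0); W <- W / sum(W)
  new("AdmixtureFit",
      W = stats::setNames(W, colnames(f)),
      loglik = -negll(W),
      nIter = as.integer(opt$counts[["function"]]),
      converged = opt$convergence == 0L,
      nLoci = as.integer(M))
}

#' Admixture-model GBC for every animal in a genotype matrix
#'
#' @param G a [GenotypeMatrix-class] aligned to `F`.
#' @param F an [AlleleFreqTable-class].
#' @param ... passed to [fitAdmixture()].
#' @return data.frame with one row per animal: `id`, one column per breed,
#'   `loglik`, `converged`, `n_loci`.
#' @export
admixtureGBC <- function(G, F, ...) {
  d <- dosage(G)
  rows <- lapply(rownames(d), function(a) {
    fit <- fitAdmixture(d[a, ], F, ...)
    c(list(id = a), as.list(fit@W),
      list(loglik = fit@loglik, converged = fit@converged,
           n_loci = fit@nLoci))
  })
  do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE)))
}
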