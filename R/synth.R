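## Synthetic multi-breed data under the models the estimators assume:
## Balding-Nichols reference-breed allele frequencies (one differentiation
## parameter F controls between-breed correlation through a shared
## ancestral frequency) and crossbred genotypes drawn per locus from
## Binomial(2, mixture frequency) or as ancestry-block mosaics.

## independently reproducible substreams: one global seed, fixed offsets
.substream <- function(seed, offset) {
  if (!is.null(seed)) set.seed((as.integer(seed) + offset) %% 2147483647L)
}

#' Simulate reference-breed allele frequencies (Balding-Nichols)
#'
#' Per SNP an ancestral frequency `p0 ~ Uniform(low, high)` is drawn; each
#' breed's frequency is then `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, so the
#' breeds share the ancestral draw and the differentiation parameter `F`
#' (an Fst analogue in (0,1)) controls the between-breed correlation:
#' smaller `F` means tighter clustering around `p0`, hence higher
#' correlation. With `sharedAncestor = FALSE` each breed draws its own
#' `p0`, giving essentially uncorrelated breeds at any `F`.
#'
#' @param M SNP count.
#' @param K breed count.
#' @param F differentiation parameter in (0, 1), default 0.2.
#' @param ancestralRange `c(low, high)` for the ancestral uniform, default
#'   `c(0.1, 0.9)`.
#' @param breeds breed names, default `B1..BK`.
#' @param sharedAncestor share the ancestral draw across breeds (default
#'   TRUE).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An [AlleleFreqTable-class] of population frequencies (no
#'   observation counts); all values strictly inside (0, 1).
#' @export
simulateBreedFrequencies <- function(M, K, F = 0.2,
                                     ancestralRange = c(0.1, 0.9),
                                     breeds = paste0("B", seq_len(K)),
                                     sharedAncestor = TRUE, seed = NULL) {
  if (F <= 0 || F >= 1) stop("F must lie strictly in (0, 1)")
  if (ancestralRange[1] <= 0 || ancestralRange[2] >= 1 ||
      ancestralRange[1] >= ancestralRange[2])
    stop("ancestralRange must satisfy 0 < low < high < 1")
  .substream(seed, 0L)
  shape <- (1 - F) / F
  f <- matrix(NA_real_, M, K,
              dimnames = list(sprintf("snp%05d", seq_len(M)), breeds))
  p0 <- stats::runif(M, ancestralRange[1], ancestralRange[2])
  for (k in seq_len(K)) {
    if (!sharedAncestor && k > 1)
      p0 <- stats::runif(M, ancestralRange[1], ancestralRange[2])
    f[, k] <- stats::rbeta(M, p0 * shape, (1 - p0) * shape)
  }
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  AlleleFreqTable(f)
}

#' Simulate crossbred genotypes
#'
#' Two generating modes:
#' * `"hwe"`: each dosage is an independent draw from
#'   `Binomial(2, sum_j w_j x_ij)` -- the admixture model's own
#'   assumption.
#' * `"block"`: each of the two gametes is an ancestry mosaic: positions
#'   are cut into blocks of `blockLength` base pairs per chromosome, each
#'   block's breed is drawn from `W`, and the allele is Bernoulli at that
#'   breed's frequency. Requires a SNP `map`; approximates haplotype
#'   inheritance (one haplotype from each parent) without recombination
#'   modelling inside blocks.
#'
#' @param F an [AlleleFreqTable-class] of reference frequencies (complete).
#' @param W true admixture simplex over the breeds of `F`.
#' @param n number of animals.
#' @param mode `"hwe"` (default) or `"block"`.
#' @param map SNP map (`snp_id`, `chrom`, `pos`) for block mode; rows must
#'   cover the SNPs of `F`.
#' @param blockLength ancestry-block length in bp, default 5e6.
#' @param seed integer seed, or `NULL`.
#' @param prefix animal-id prefix, default `"X"`.
#' @return A [GenotypeMatrix-class], n x M.
#' @export
simulateCrossbreds <- function(F, W, n, mode = c("hwe", "block"),
                               map = NULL, blockLength = 5e6, seed = NULL,
                               prefix = "X") {
  mode <- match.arg(mode)
  f <- freq(F)
  if (length(W) != ncol(f)) stop("W must have one weight per breed")
  if (any(W < 0) || abs(sum(W) - 1) > 1e-6)
    stop("W is not on the simplex")
  if (n < 1) stop("n must be at least 1")
  .substream(seed, 1L)
  M <- nrow(f)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  if (mode == "hwe") {
    mix <- as.vector(f %*% W)
    d <- matrix(stats::rbinom(n * M, 2L, rep(mix, each = n)), n, M,
                dimnames = list(ids, rownames(f)))
  } else {
    if (is.null(map)) stop("block mode requires a SNP map")
    map <- map[match(rownames(f), map$snp_id), , drop = FALSE]
    if (anyNA(map$snp_id)) stop("map does not cover all SNPs in F")
    block <- paste(map$chrom, floor(map$pos / blockLength))
    blocks <- unique(block)
    d <- matrix(0L, n, M, dimnames = list(ids, rownames(f)))
    K <- ncol(f)
    for (a in seq_len(n)) {
      for (g in 1:2) {  # two gametes
        anc <- sample.int(K, length(blocks), replace = TRUE, prob = W)
        ancPerSnp <- anc[match(block, blocks)]
        p <- f[cbind(seq_len(M), ancPerSnp)]
        d[a, ] <- d[a, ] + stats::rbinom(M, 1L, p)
      }
    }
  }
  GenotypeMatrix(d)
}

#' Named scenario fixtures for the package's estimators
#'
#' Three seeded scenarios mirroring the composite-cattle structures the
#' estimators are designed for:
#' * `brangus_like`: two distant (uncorrelated) reference breeds,
#'   crossbreds at `W = (0.625, 0.375)` -- the 5/8:3/8 composite.
#' * `beefmaster_like`: three reference breeds of which two are drawn from
#'   a shared ancestor with `F = 0.4`, targeting a between-breed
#'   correlation near 0.4 (moment identity
#'   `r = Var(p0) / (Var(p0) + E[p0(1-p0)] F)`), crossbreds at
#'   `W = (0.5, 0.25, 0.25)`.
#' * `ultrablack_like`: the brangus-like breeds, a composite generation at
#'   `W = (0.625, 0.375)`, then a 50/50 backcross of the composite to
#'   breed 1, so the crossbreds carry an expected `(0.8125, 0.1875)`
#'   composition; the composite's population frequency vector is included
#'   for correlation-mode estimation.
#'
#' Every scenario is reproducible from the single `seed` via fixed
#' per-scenario substreams.
#'
#' @param seed integer master seed, default 1.
#' @param M loci per scenario, default 5000.
#' @param n animals per scenario, default 100.
#' @return named list of scenarios; each holds `freq`
#'   ([AlleleFreqTable-class]), `genotypes` ([GenotypeMatrix-class]), the
#'   true `W`, and for `ultrablack_like` also `compositeFreq`.
#' @export
makeScenarios <- function(seed = 1, M = 5000, n = 100) {
  seed <- as.integer(seed)
  ## brangus-like: two distant breeds, independent ancestors
  fb <- simulateBreedFrequencies(M, 2, F = 0.2,
                                 breeds = c("breedA", "breedB"),
                                 sharedAncestor = FALSE, seed = seed + 11L)
  Wb <- c(breedA = 0.625, breedB = 0.375)
  gb <- simulateCrossbreds(fb, Wb, n, seed = seed + 12L)

  ## beefmaster-like: breed1 independent; breeds 2 and 3 share an ancestor
  ## with F = 0.4 so their frequency correlation lands near 0.4
  .substream(seed + 21L, 0L)
  pair <- simulateBreedFrequencies(M, 2, F = 0.4,
                                   breeds = c("breedH", "breedS"),
                                   sharedAncestor = TRUE, seed = seed + 22L)
  solo <- simulateBreedFrequencies(M, 1, F = 0.2, breeds = "breedB",
                                   sharedAncestor = FALSE, seed = seed + 23L)
  fm <- AlleleFreqTable(cbind(freq(solo), freq(pair)))
  Wm <- c(breedB = 0.5, breedH = 0.25, breedS = 0.25)
  gm <- simulateCrossbreds(fm, Wm, n, seed = seed + 24L)

  ## ultrablack-like: composite then 50/50 backcross to breed 1
  Wu <- c(breedA = 0.8125, breedB = 0.1875)
  gu <- simulateCrossbreds(fb, Wu, n, seed = seed + 31L)
  compositeFreq <- as.vector(freq(fb) %*% Wb)

  list(
    brangus_like = list(freq = fb, genotypes = gb, W = Wb),
    beefmaster_like = list(freq = fm, genotypes = gm, W = Wm),
    ultrablack_like = list(freq = fb, genotypes = gu, W = Wu,
                           compositeW = Wb,
                           compositeFreq = stats::setNames(compositeFreq,
                                                           snpIds(fb)))
  )
}
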