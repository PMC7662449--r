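## Reference-panel QC: a per-animal breed-membership purity score from the
## HWE genotype likelihood, outlier filtering on that score, and
## deterministic selection of uniformly spaced SNP panels.

#' Breed-membership purity score
#'
#' Scores how plausibly a dosage vector was drawn from a breed's allele
#' frequencies: per locus the HWE genotype probability (f^2, 2f(1-f) or
#' (1-f)^2 for dosage 2/1/0) is evaluated at the breed frequency, and the
#' score is `-2 x mean(log10 P)` over usable loci. Purebred members of the
#' breed score near 0; migrants from a divergent breed score high. The
#' per-locus averaging makes the conventional cutoff of 2 comparable
#' across panel sizes; `base` and `normalize` expose the scale choices.
#'
#' @param y dosage vector (0/1/2, `NA` skipped).
#' @param f breed allele-frequency vector aligned to `y`; clipped to
#'   `[eps, 1 - eps]`.
#' @param eps clipping bound, default `1e-6`.
#' @param base logarithm base, default 10.
#' @param normalize divide by the locus count (default TRUE); FALSE gives
#'   the raw `-2 log L`.
#' @return list with `score` and `nLoci`.
#' @examples
#' purityScore(rep(2, 100), rep(0.99, 100))$score  # -2 log10(0.9801)
#' @export
purityScore <- function(y, f, eps = 1e-6, base = 10, normalize = TRUE) {
  if (length(y) != length(f)) stop("y and f must be aligned")
  keep <- !is.na(y) & !is.na(f)
  y <- y[keep]; f <- pmin(pmax(f[keep], eps), 1 - eps)
  if (!length(y)) stop("no usable loci for the purity score")
  p <- ifelse(y == 2, f^2, ifelse(y == 1, 2 * f * (1 - f), (1 - f)^2))
  s <- -2 * sum(log(p, base = base))
  if (normalize) s <- s / length(y)
  list(score = s, nLoci = length(y))
}

#' Filter reference animals by breed purity
#'
#' Scores every labelled animal against its own breed's allele frequencies
#' and removes those whose [purityScore()] exceeds the threshold. With
#' `leaveOneOut = TRUE` each animal is scored against frequencies computed
#' from its breed excluding itself (removing the animal's own pull on the
#' frequencies); the default scores against the full-breed frequencies.
#'
#' @param G a [GenotypeMatrix-class].
#' @param labels breed labels (`animal_id`, `breed`).
#' @param threshold score cutoff, default 2.
#' @param leaveOneOut logical, default FALSE.
#' @param ... passed to [purityScore()].
#' @return list with `retained` (a [GenotypeMatrix-class]) and `excluded`
#'   (data.frame `animal_id`, `breed`, `score`). A warning is raised for
#'   any breed losing all its animals.
#' @export
filterReference <- function(G, labels, threshold = 2, leaveOneOut = FALSE,
                            ...) {
  labels <- labels[labels$animal_id %in% animalIds(G), , drop = FALSE]
  d <- dosage(G)
  F <- alleleFrequencies(G, labels)
  scores <- data.frame(animal_id = character(0), breed = character(0),
                       score = numeric(0))
  for (b in unique(labels$breed)) {
    ids <- labels$animal_id[labels$breed == b]
    db <- d[ids, , drop = FALSE]
    S <- colSums(db, na.rm = TRUE)
    C <- 2 * colSums(!is.na(db))
    for (a in ids) {
      ya <- db[a, ]
      if (leaveOneOut) {
        obs <- !is.na(ya)
        Cl <- C - 2 * obs
        fb <- ifelse(Cl > 0, (S - ifelse(obs, ya, 0)) / Cl, NA_real_)
      } else {
        fb <- freq(F)[, b]
      }
      sc <- purityScore(ya, fb, ...)
      scores <- rbind(scores, data.frame(animal_id = a, breed = b,
                                         score = sc$score))
    }
  }
  bad <- scores$score > threshold
  excluded <- scores[bad, , drop = FALSE]
  for (b in unique(labels$breed)) {
    idsLeft <- setdiff(labels$animal_id[labels$breed == b],
                       excluded$animal_id)
    if (!length(idsLeft))
      warning("purity filter removed every animal of breed ", b)
  }
  keep <- setdiff(rownames(d), excluded$animal_id)
  dk <- d[keep, , drop = FALSE]
  dimnames(dk) <- list(keep, colnames(d))  # kept even when keep is empty
  list(retained = GenotypeMatrix(dk), excluded = excluded)
}

#' Select a uniformly spaced SNP panel
#'
#' Deterministic grid selection: the target count is allocated to
#' chromosomes proportionally to their physical span (largest-remainder
#' rounding, every chromosome with SNPs getting at least one pick when the
#' budget allows), grid points are placed evenly across each chromosome's
#' span (endpoints included; the midpoint for a single pick), and the
#' nearest not-yet-chosen SNP to each grid point is selected, lower
#' position winning ties.
#'
#' @param map SNP map data.frame (`snp_id`, `chrom`, `pos`), e.g. from
#'   [readSNPMap()].
#' @param n target panel size; must not exceed the number of mapped SNPs.
#' @return character vector of selected SNP ids, sorted by (chrom, pos),
#'   duplicate-free.
#' @export
selectUniformSNPs <- function(map, n) {
  if (n > nrow(map)) stop("requested more SNPs than the map contains")
  if (n < 1) stop("n must be at least 1")
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  chroms <- unique(map$chrom)
  span <- vapply(chroms, function(ch) {
    p <- map$pos[map$chrom == ch]
    max(diff(range(p)), 1)  # single-SNP chromosomes get a token span
  }, numeric(1))
  avail <- vapply(chroms, function(ch) sum(map$chrom == ch), numeric(1))
  ## largest-remainder allocation proportional to span, capped by
  ## availability
  quota <- n * span / sum(span)
  alloc <- pmin(floor(quota), avail)
  while (sum(alloc) < n) {
    room <- avail - alloc > 0
    if (!any(room)) break
    rem <- ifelse(room, quota - alloc, -Inf)
    i <- which.max(rem)
    alloc[i] <- alloc[i] + 1
  }
  sel <- character(0)
  for (k in seq_along(chroms)) {
    nk <- alloc[k]
    if (nk == 0) next
    sub <- map[map$chrom == chroms[k], , drop = FALSE]
    lo <- min(sub$pos); hi <- max(sub$pos)
    grid <- if (nk == 1) (lo + hi) / 2 else seq(lo, hi, length.out = nk)
    used <- rep(FALSE, nrow(sub))
    for (g in grid) {
      dist <- abs(sub$pos - g)
      dist[used] <- Inf
      i <- which.min(dist)  # which.min takes the first (lowest pos) on ties
      used[i] <- TRUE
    }
    sel <- c(sel, sub$snp_id[used])
  }
  sel
}
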