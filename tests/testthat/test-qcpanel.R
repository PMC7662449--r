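test_that("purity score matches direct HWE arithmetic", {
  s <- purityScore(rep(2, 100), rep(0.99, 100))
  expect_equal(s$score, -2 * log10(0.99^2), tolerance = 1e-12)
  expect_lt(s$score, 2)
  s0 <- purityScore(rep(0, 50), rep(0.99, 50))
  expect_equal(s0$score, -2 * log10(0.01^2), tolerance = 1e-10)
  expect_gt(s0$score, 2)
  ## mixed vector, hand-computed
  y <- c(2, 1, 0); f <- c(0.8, 0.5, 0.3)
  p <- c(0.64, 0.5, 0.49)
  expect_equal(purityScore(y, f)$score, -2 * mean(log10(p)),
               tolerance = 1e-12)
  ## invariant to locus order; NA skipped
  set.seed(21)
  y <- sample(0:2, 80, TRUE); f <- runif(80, 0.1, 0.9)
  o <- sample(80)
  expect_equal(purityScore(y, f)$score, purityScore(y[o], f[o])$score)
  y[1] <- NA
  expect_equal(purityScore(y, f)$nLoci, 79L)
  expect_error(purityScore(NA, 0.5), "no usable")
})

test_that("own-breed genotypes score below divergent-breed genotypes", {
  F <- simulateBreedFrequencies(500, 2, sharedAncestor = FALSE, seed = 31)
  set.seed(32)
  wins <- 0
  for (i in 1:100) {
    own <- rbinom(500, 2, freq(F)[, 1])
    mig <- rbinom(500, 2, freq(F)[, 2])
    sOwn <- purityScore(own, freq(F)[, 1])$score
    sMig <- purityScore(mig, freq(F)[, 1])$score
    wins <- wins + (sOwn < sMig)
  }
  expect_gte(wins, 95)
})

test_that("reference filtering removes planted migrants and only them", {
  ## constructed fixture: the home breed is near-fixed for allele A, the
  ## migrant's source breed near-fixed for the alternative, so the
  ## migrant's expected purity score (~3.5) clears the cutoff of 2 while
  ## home animals stay near 0.5
  set.seed(42)
  M <- 300
  home <- matrix(rbinom(20 * M, 2, 0.9), 20, M)
  migrant <- rbinom(M, 2, 0.1)
  d <- rbind(home, migrant)
  dimnames(d) <- list(c(sprintf("h%02d", 1:20), "migrant"),
                      sprintf("s%03d", 1:M))
  G <- GenotypeMatrix(d)
  lab <- data.frame(animal_id = rownames(d), breed = "Angus")
  res <- filterReference(G, lab, threshold = 2)
  expect_equal(res$excluded$animal_id, "migrant")
  expect_equal(nrow(dosage(res$retained)), 20)

  ## homogeneous breed: zero exclusions at the default threshold
  Gh <- GenotypeMatrix(d[1:20, ])
  resh <- filterReference(Gh, lab[1:20, ], threshold = 2)
  expect_equal(nrow(resh$excluded), 0)

  ## infinite threshold is the identity
  resi <- filterReference(G, lab, threshold = Inf)
  expect_equal(animalIds(resi$retained), rownames(d))

  ## a lower threshold excludes a superset
  resLow <- suppressWarnings(filterReference(G, lab, threshold = 0.2))
  expect_true(all(res$excluded$animal_id %in% resLow$excluded$animal_id))
  expect_gt(nrow(resLow$excluded), nrow(res$excluded))

  ## leave-one-out scoring also isolates the migrant
  resLoo <- filterReference(G, lab, threshold = 2, leaveOneOut = TRUE)
  expect_true("migrant" %in% resLoo$excluded$animal_id)
})

test_that("uniform SNP selection follows the span-proportional grid rule", {
  map1 <- data.frame(snp_id = paste0("s", 1:10), chrom = "1",
                     pos = (1:10) * 1e6)
  expect_equal(selectUniformSNPs(map1, 2), c("s1", "s10"))  # endpoints
  expect_equal(selectUniformSNPs(map1, 10), paste0("s", 1:10))
  expect_error(selectUniformSNPs(map1, 11), "more SNPs")

  ## two chromosomes: allocation proportional to span
  map2 <- rbind(map1,
                data.frame(snp_id = paste0("t", 1:10), chrom = "2",
                           pos = (1:10) * 3e6))
  sel <- selectUniformSNPs(map2, 8)
  expect_equal(sum(startsWith(sel, "t")), 6)  # span 27Mb vs 9Mb -> 6:2

  ## spacing property on seeded uniform maps
  set.seed(51)
  for (i in 1:5) {
    start <- sample(1e6:2e6, 1)
    pos <- round(seq(start, start + 99e6, length.out = 400))
    mp <- data.frame(snp_id = paste0("x", seq_along(pos)), chrom = "1",
                     pos = pos)
    n <- sample(20:60, 1)
    ids <- selectUniformSNPs(mp, n)
    expect_equal(anyDuplicated(ids), 0L)
    p <- mp$pos[match(ids, mp$snp_id)]
    expect_equal(p, sort(p))  # sorted output
    span <- diff(range(mp$pos))
    expect_lte(max(diff(p)), 2 * span / (n - 1))
  }
})
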