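test_that("TSV genotypes parse with missing tokens masked", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsnp1\tsnp2", "A1\t2\t1", "A2\t0\tNA"), tf)
  g <- readGenotypes(tf, format = "tsv")
  expect_equal(animalIds(g), c("A1", "A2"))
  expect_equal(snpIds(g), c("snp1", "snp2"))
  expect_equal(unname(dosage(g)[1, ]), c(2, 1))
  expect_equal(unname(dosage(g)[2, 1]), 0)
  expect_identical(unname(isMissing(g)),
                   matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
})

test_that("plink_raw dosages match an independent text-splitting parse", {
  fx <- writeRawFixture()
  g <- readGenotypes(fx$path, format = "plink_raw")
  expect_equal(dosage(g), fx$oracle,
               ignore_attr = "counted_allele")
  expect_equal(unname(attr(dosage(g), "counted_allele")), c("A", "G"))
  expect_equal(unname(dosage(g)["A1", "rs1"]), 2)
})

test_that("malformed genotype input is rejected with informative errors", {
  empty <- tempfile(); file.create(empty)
  expect_error(readGenotypes(empty, format = "tsv"), "malformed|empty")
  badhdr <- tempfile()
  writeLines(c("FID\tIID\tSEX\trs1_A", "F\tA\t1\t2"), badhdr)
  expect_error(readGenotypes(badhdr, format = "plink_raw"), "header")
  badval <- tempfile()
  writeLines(c("id\ts1", "A1\t3"), badval)
  expect_error(readGenotypes(badval, format = "tsv"), "A1.*s1|s1.*A1")
  expect_error(readGenotypes(tempfile(), format = "tsv"), "not found")
})

test_that("frequency tables parse, reject bad values, and round-trip", {
  tf <- tempfile()
  writeLines(c("snp\tAngus\tBrahman", "rs1\t0.2\t0.9"), tf)
  F <- readFrequencyTable(tf)
  expect_equal(dim(freq(F)), c(1L, 2L))
  expect_equal(breeds(F), c("Angus", "Brahman"))
  expect_equal(unname(freq(F)[1, ]), c(0.2, 0.9))

  bad <- tempfile()
  writeLines(c("snp\tA", "rs1\t1.2"), bad)
  expect_error(readFrequencyTable(bad), "outside")
  dup <- tempfile()
  writeLines(c("snp\tA", "rs1\t0.2", "rs1\t0.3"), dup)
  expect_error(readFrequencyTable(dup), "duplicate")

  ## round-trip lossless at 6 decimals, including a missing cell
  set.seed(42)
  f0 <- matrix(round(runif(20), 6), 10, 2,
               dimnames = list(paste0("s", 1:10), c("A", "B")))
  f0[3, 1] <- NA
  rt <- tempfile()
  writeFrequencyTable(AlleleFreqTable(f0), rt)
  expect_equal(freq(readFrequencyTable(rt)), f0, tolerance = 1e-9)
})

test_that("SNP maps and breed labels validate their dialects", {
  mp <- tempfile()
  writeLines(c("snp_id\tchrom\tpos", "s2\t1\t500", "s1\t1\t100",
               "s3\t2\t50"), mp)
  map <- readSNPMap(mp)
  expect_equal(map$snp_id, c("s1", "s2", "s3"))  # sorted by (chrom, pos)
  pm <- tempfile()
  writeLines(c("1 s1 0 100", "1 s2 0 500"), pm)
  expect_equal(readSNPMap(pm, format = "plink_map")$pos, c(100, 500))

  lb <- tempfile()
  writeLines(c("animal_id\tbreed", "a1\tAngus", "a2\tBrahman"), lb)
  expect_equal(readBreedLabels(lb)$breed, c("Angus", "Brahman"))
  dupl <- tempfile()
  writeLines(c("animal_id\tbreed", "a1\tAngus", "a1\tBrahman"), dupl)
  expect_error(readBreedLabels(dupl), "more than one breed")
})

test_that("alignPanels intersects on the frequency table's order and is idempotent", {
  g <- gmat(matrix(0, 1, 3), snps = c("a", "b", "c"))
  F <- ftab(matrix(0.5, 3, 1), snps = c("d", "c", "b"))
  suppressMessages(al <- alignPanels(g, F))
  expect_equal(snpIds(al$genotypes), c("c", "b"))  # frequency-table order
  expect_equal(snpIds(al$freq), c("c", "b"))
  al2 <- alignPanels(al$genotypes, al$freq)
  expect_identical(dosage(al2$genotypes), dosage(al$genotypes))
  expect_identical(freq(al2$freq), freq(al$freq))

  same <- alignPanels(gmat(matrix(1, 1, 2)), ftab(matrix(0.5, 2, 1)))
  expect_equal(snpIds(same$genotypes), c("s1", "s2"))
  disjoint <- ftab(matrix(0.5, 2, 1), snps = c("x", "y"))
  expect_error(alignPanels(g, disjoint), "no SNPs shared")
})

test_that("GenotypeMatrix validity enforces the dosage domain", {
  expect_error(gmat(matrix(c(0, 3), 1, 2)), "0, 1 or 2")
  expect_error(GenotypeMatrix(matrix(0, 1, 1)), "names")
  expect_error(gmat(matrix(0, 2, 1), animals = c("a", "a")), "unique")
})
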