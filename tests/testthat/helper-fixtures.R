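## Shared fixture builders; everything is generated in code.

## small frequency table with given matrix
ftab <- function(f, breeds = NULL, snps = NULL) {
  f <- as.matrix(f)
  if (is.null(breeds)) breeds <- paste0("b", seq_len(ncol(f)))
  if (is.null(snps)) snps <- paste0("s", seq_len(nrow(f)))
  dimnames(f) <- list(snps, breeds)
  AlleleFreqTable(f)
}

gmat <- function(d, animals = NULL, snps = NULL) {
  d <- as.matrix(d)
  if (is.null(animals)) animals <- paste0("a", seq_len(nrow(d)))
  if (is.null(snps)) snps <- paste0("s", seq_len(ncol(d)))
  dimnames(d) <- list(animals, snps)
  GenotypeMatrix(d)
}

## random uncorrelated frequency table (uniform, away from the bounds)
randomFreq <- function(M, K, seed) {
  set.seed(seed)
  ftab(matrix(runif(M * K, 0.05, 0.95), M, K))
}

## write a tiny hand-built PLINK .raw fixture and return its path plus the
## dosage matrix an independent text-splitting parse yields
writeRawFixture <- function() {
  path <- tempfile(fileext = ".raw")
  lines <- c("FID\tIID\tPAT\tMAT\tSEX\tPHENOTYPE\trs1_A\trs2_G",
             "F1\tA1\t0\t0\t1\t-9\t2\t0",
             "F1\tA2\t0\t0\t2\t-9\t1\tNA",
             "F2\tA3\t0\t0\t1\t-9\t0\t2")
  writeLines(lines, path)
  oracle <- t(vapply(strsplit(lines[-1], "\t"), function(x)
    suppressWarnings(as.numeric(x[7:8])), numeric(2)))
  dimnames(oracle) <- list(c("A1", "A2", "A3"), c("rs1", "rs2"))
  list(path = path, oracle = oracle)
}

## the packaged two-generation composite diagram
ultrablackDiagram <- function() {
  readPathDiagram(system.file("extdata", "ultrablack_diagram.json",
                              package = "pathGBC"))
}

## three-breed correlation matrix used by the worked composite system
beefmasterR <- function(rBH = 0.10, rBS = 0.05, rHS = 0.40) {
  R <- matrix(c(1, rBH, rBS,
                rBH, 1, rHS,
                rBS, rHS, 1), 3, 3)
  dimnames(R) <- list(c("Brahman", "Hereford", "Shorthorn"),
                      c("Brahman", "Hereford", "Shorthorn"))
  R
}
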