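## File I/O for the dialects the package exchanges with PLINK and plain
## TSV pipelines. All tables are tab-separated with a header row, UTF-8.

#' Read a genotype matrix from PLINK .raw or plain TSV
#'
#' Parses additive allele dosages into a [GenotypeMatrix-class]. Two
#' dialects are supported:
#' * `plink_raw`: the PLINK 1.9 `--recode A` export. The first six columns
#'   are `FID IID PAT MAT SEX PHENOTYPE`; each remaining column is named
#'   `<snp>_<allele>` and holds the dosage (0/1/2) of the counted allele
#'   named in the suffix. `IID` becomes the animal id and the suffix is
#'   stripped from the SNP id.
#' * `tsv`: first column animal id, one column per SNP, values 0/1/2.
#'
#' @param path file to read.
#' @param format `"plink_raw"` or `"tsv"`.
#' @param missing_code character vector of tokens read as missing
#'   (mask = TRUE); `"NA"`, `"-9"` and the empty string by default.
#' @return A [GenotypeMatrix-class]; the counted-allele letter per SNP is
#'   attached as attribute `"counted_allele"` of the dosage matrix for
#'   `plink_raw` input.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tsnp1\tsnp2", "A1\t2\t1", "A2\t0\tNA"), tf)
#' g <- readGenotypes(tf, format = "tsv")
#' dosage(g)
#' @export
readGenotypes <- function(path, format = c("plink_raw", "tsv"),
                          missing_code = c("NA", "-9", "")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", quote = "",
                      blank.lines.skip = TRUE),
    error = function(e)
      stop("malformed genotype file (", conditionMessage(e), "): ", path))
  if (format == "plink_raw" && ncol(tab) == 1) {
    ## PLINK writes .raw space-delimited; retry with whitespace splitting
    tab <- utils::read.table(path, header = TRUE, colClasses = "character",
                             check.names = FALSE, comment.char = "",
                             quote = "")
  }
  if (nrow(tab) == 0 || ncol(tab) < 2)
    stop("malformed genotype file (empty or header-only): ", path)

  if (format == "plink_raw") {
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) < 7 || !identical(toupper(names(tab)[1:6]), fixed))
      stop("malformed plink_raw header: expected columns ",
           paste(fixed, collapse = " "), " then SNP_allele columns")
    ids <- tab[["IID"]]
    gcols <- names(tab)[-(1:6)]
    if (!all(grepl("_[A-Za-z0-9]+$", gcols)))
      stop("malformed plink_raw header: SNP columns must end in _<allele>")
    snps <- sub("_[A-Za-z0-9]+$", "", gcols)
    alleles <- sub("^.*_", "", gcols)
    raw <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    ids <- tab[[1]]
    snps <- names(tab)[-1]
    alleles <- NULL
    raw <- as.matrix(tab[, -1, drop = FALSE])
  }

  raw[raw %in% missing_code] <- NA
  d <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.na(d) & !(d %in% c(0, 1, 2)), arr.ind = TRUE)
  bad2 <- which(is.na(d) & !is.na(raw), arr.ind = TRUE)  # unparseable tokens
  bad <- rbind(bad, bad2)
  if (nrow(bad))
    stop(sprintf("dosage outside {0,1,2} at animal '%s', SNP '%s' (value '%s')",
                 ids[bad[1, 1]], snps[bad[1, 2]], raw[bad[1, 1], bad[1, 2]]))
  dimnames(d) <- list(ids, snps)
  if (!is.null(alleles)) attr(d, "counted_allele") <- stats::setNames(alleles, snps)
  GenotypeMatrix(d)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of `readGenotypes(format = "tsv")`; missing dosages are written
#' as `NA`.
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(G, path) {
  d <- dosage(G)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency table
#'
#' TSV with a `snp_id` (or any first) column then one numeric column per
#' breed; values are allele-A frequencies in \[0,1\], `NA` allowed.
#'
#' @param path file to read.
#' @return An [AlleleFreqTable-class] (without observation counts).
#' @export
readFrequencyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "", quote = "")
  if (nrow(tab) == 0 || ncol(tab) < 2)
    stop("malformed frequency table (need snp column + >=1 breed): ", path)
  snps <- as.character(tab[[1]])
  if (anyDuplicated(snps))
    stop("duplicate snp_id in frequency table: ",
         snps[duplicated(snps)][1])
  f <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(f) <- "double"
  out <- f[!is.na(f) & (f < 0 | f > 1)]
  if (length(out))
    stop("allele frequency outside [0, 1]: ", out[1])
  rownames(f) <- snps
  AlleleFreqTable(f)
}

#' Write an allele-frequency table as TSV
#'
#' Frequencies are written with 6 decimal places, giving lossless
#' round-trips at that precision.
#'
#' @param F an [AlleleFreqTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(F, path) {
  f <- freq(F)
  ch <- apply(f, 2, function(x) formatC(x, digits = 6, format = "f"))
  if (is.null(dim(ch))) ch <- matrix(ch, nrow = nrow(f), ncol = ncol(f))
  ch[is.na(f)] <- NA  # formatC prints "NA" strings; keep real NA
  dimnames(ch) <- dimnames(f)
  df <- data.frame(snp_id = rownames(f), ch, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP map
#'
#' Either PLINK 1.9 `.map` (chrom, snp id, cM, bp; no header, whitespace
#' separated) or a headered TSV with columns `snp_id`, `chrom`, `pos`.
#' Rows are sorted by (chrom, pos).
#'
#' @param path file to read.
#' @param format `"plink_map"` or `"tsv"`.
#' @return data.frame with columns `snp_id`, `chrom` (character), `pos`
#'   (1-based bp).
#' @export
readSNPMap <- function(path, format = c("tsv", "plink_map")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink_map") {
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) < 4) stop("malformed .map: expected 4 columns")
    map <- data.frame(snp_id = as.character(tab[[2]]),
                      chrom = as.character(tab[[1]]),
                      pos = as.numeric(tab[[4]]))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(tab)))
      stop("map TSV must have columns snp_id, chrom, pos")
    map <- data.frame(snp_id = as.character(tab$snp_id),
                      chrom = as.character(tab$chrom),
                      pos = as.numeric(tab$pos))
  }
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  if (any(map$pos <= 0)) stop("map positions must be positive")
  map[order(map$chrom, map$pos), , drop = FALSE]
}

#' Read breed labels
#'
#' Headered TSV with columns `animal_id`, `breed` and optionally `role`
#' (one of `ancestral`, `non-ancestral`, `composite`).
#'
#' @param path file to read.
#' @return data.frame with columns `animal_id`, `breed`, `role`.
#' @export
readBreedLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("animal_id", "breed") %in% names(tab)))
    stop("labels TSV must have columns animal_id, breed")
  if (anyDuplicated(tab$animal_id))
    stop("animal appears under more than one breed: ",
         tab$animal_id[duplicated(tab$animal_id)][1])
  if (is.null(tab$role)) tab$role <- NA_character_
  ok <- is.na(tab$role) | tab$role %in%
    c("ancestral", "non-ancestral", "composite")
  if (!all(ok)) stop("unknown breed role: ", tab$role[!ok][1])
  tab[, c("animal_id", "breed", "role")]
}

#' Intersect a genotype matrix and a frequency table on shared SNPs
#'
#' Restricts both inputs to the SNPs they share. The output follows the
#' frequency table's SNP order so downstream results are reproducible
#' regardless of genotype-file column order; the number of loci dropped
#' from each side is reported via `message()`.
#'
#' @param G a [GenotypeMatrix-class].
#' @param F an [AlleleFreqTable-class].
#' @return list with elements `genotypes` and `freq`, both restricted to
#'   the shared SNPs in identical order.
#' @export
alignPanels <- function(G, F) {
  gs <- snpIds(G); fs <- snpIds(F)
  common <- fs[fs %in% gs]  # frequency-table order
  if (!length(common))
    stop("no SNPs shared between genotypes and frequency table")
  if (length(common) < length(gs) || length(common) < length(fs))
    message(sprintf("alignPanels: retained %d shared SNPs (dropped %d from genotypes, %d from frequencies)",
                    length(common), length(gs) - length(common),
                    length(fs) - length(common)))
  Fo <- AlleleFreqTable(freq(F)[common, , drop = FALSE],
                        if (is.null(nObs(F))) NULL
                        else nObs(F)[common, , drop = FALSE])
  Go <- GenotypeMatrix(dosage(G)[, common, drop = FALSE])
  list(genotypes = Go, freq = Fo)
}
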