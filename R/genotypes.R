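## GenotypeMatrix construction, accessors, allele/genotype frequencies,
## and genotype I/O (0/1/2 CSV matrix and VCF).

#' Construct a GenotypeMatrix
#'
#' @param geno numeric matrix, individuals x SNPs, entries 0/1/2/NA counting
#'   copies of the alt allele; rownames are individual ids.
#' @param snpInfo data.frame or DataFrame with columns \code{name},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt} (1-based positions).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(geno, snpInfo) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  si <- as(as.data.frame(snpInfo), "DataFrame")
  if (is.null(colnames(geno))) colnames(geno) <- si$name
  if (is.null(rownames(geno))) rownames(geno) <- as.character(seq_len(nrow(geno)))
  new("GenotypeMatrix", geno = geno, snpInfo = si)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)

#' @rdname GenotypeMatrix-class
#' @export
nSnps <- function(x) ncol(x@geno)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@geno), "individuals x",
      ncol(object@geno), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@snpInfo$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(object@geno))
  if (miss > 0) cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' Genotype and allele frequencies per SNP
#'
#' Genotype frequencies are computed over non-missing individuals; the
#' allele frequency follows as f(allele) = f(hom) + f(het)/2.  SNPs with
#' no non-missing call are flagged (\code{ok = FALSE}) so callers can
#' exclude them downstream.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param digits optional number of decimals; when given, frequencies are
#'   rounded half away from zero (the convention of printed frequency
#'   tables).  Default \code{NULL} returns full precision.
#' @return data.frame, one row per SNP: \code{name, ref, alt, n,
#'   freqHomRef, freqHet, freqHomAlt, freqRef, freqAlt, ok}.
#' @examples
#' si <- data.frame(name = "snp1", chrom = "19", pos = 1L, ref = "T", alt = "C")
#' g <- GenotypeMatrix(matrix(c(rep(0, 40), rep(1, 46), rep(2, 14))), si)
#' alleleFreqs(g, digits = 2)  # f(T) = 0.63
#' @export
alleleFreqs <- function(g, digits = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  m <- g@geno
  si <- g@snpInfo
  n <- colSums(!is.na(m))
  cnt <- function(code) colSums(m == code, na.rm = TRUE)
  fRR <- ifelse(n > 0, cnt(0L) / n, NA_real_)
  fRA <- ifelse(n > 0, cnt(1L) / n, NA_real_)
  fAA <- ifelse(n > 0, cnt(2L) / n, NA_real_)
  fR <- fRR + fRA / 2
  fA <- fAA + fRA / 2
  if (!is.null(digits)) {
    fRR <- roundHalfUp(fRR, digits); fRA <- roundHalfUp(fRA, digits)
    fAA <- roundHalfUp(fAA, digits)
    fR <- roundHalfUp(fR, digits);   fA <- roundHalfUp(fA, digits)
  }
  data.frame(name = si$name, ref = si$ref, alt = si$alt, n = as.integer(n),
             freqHomRef = fRR, freqHet = fRA, freqHomAlt = fAA,
             freqRef = fR, freqAlt = fA, ok = n > 0,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## I/O
## ---------------------------------------------------------------------------

#' Read / write genotypes as a 0/1/2 CSV matrix
#'
#' The CSV holds one row per individual (first column \code{id}) and one
#' column per SNP with codes 0/1/2 (alt-allele count) or empty for missing.
#' SNP metadata travels in a companion file \code{<path>.snps.csv}.
#'
#' @param path CSV path.
#' @return \code{readGenotypesCSV}: a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypesCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  si <- read.csv(paste0(path, ".snps.csv"), colClasses = c(pos = "integer"))
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- as.character(df[[1]])
  GenotypeMatrix(geno, si)
}

#' @rdname readGenotypesCSV
#' @param g a \linkS4class{GenotypeMatrix}.
#' @export
writeGenotypesCSV <- function(g, path) {
  df <- data.frame(id = rownames(g@geno), g@geno, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(g@snpInfo), paste0(path, ".snps.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes to a minimal VCF
#'
#' Emits a VCFv4.2 file with a GT FORMAT field, one sample column per
#' individual; genotypes are unphased (\code{"/"}) by default.  Phased
#' output (\code{"|"}) is available when writing from known diplotypes.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param path output path (plain text).
#' @param phased logical; write \code{|} separators.  Only meaningful when
#'   \code{haps} is supplied.
#' @param haps optional list of two character matrices (individual x SNP
#'   allele codes 0/1) giving the phase to write.
#' @export
writeGenotypesVCF <- function(g, path, phased = FALSE, haps = NULL) {
  si <- g@snpInfo
  m <- g@geno
  sep <- if (phased) "|" else "/"
  gtOf <- function(j) {
    if (!is.null(haps)) {
      paste(haps[[1]][, j], haps[[2]][, j], sep = sep)
    } else {
      c(`0` = paste(0, 0, sep = sep), `1` = paste(0, 1, sep = sep),
        `2` = paste(1, 1, sep = sep))[as.character(m[, j])]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=milkQTL",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(m)), collapse = "\t")), con)
  for (j in seq_len(nrow(si))) {
    gt <- gtOf(j)
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(si$chrom[j], si$pos[j], si$name[j], si$ref[j],
                       si$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Parses via \pkg{vcfR} and converts GT calls to alt-allele counts.
#'
#' @param path VCF path.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  geno <- t(matrix(code(gt), nrow(gt), ncol(gt)))  # individuals x SNPs
  colnames(geno) <- rownames(gt)
  rownames(geno) <- colnames(gt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  si <- data.frame(name = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  GenotypeMatrix(geno, si)
}

#' Genotype class labels for one SNP
#'
#' Maps 0/1/2 codes at one SNP to allele-pair labels (e.g. "CC", "CT",
#' "TT"), the factor used for single-locus association fits.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param snp SNP column index or name.
#' @param ids optional subset of individual ids.
#' @return named character vector (NA for missing calls), names = ids.
#' @export
genotypeClasses <- function(g, snp, ids = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (is.character(snp)) snp <- match(snp, g@snpInfo$name)
  ids <- ids %||% rownames(g@geno)
  code <- g@geno[ids, snp]
  si <- g@snpInfo[snp, ]
  lab <- c(paste0(si$ref, si$ref), paste0(si$ref, si$alt),
           paste0(si$alt, si$alt))
  setNames(lab[code + 1L], ids)
}
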