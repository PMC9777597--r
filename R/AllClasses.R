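#' @import methods
#' @importFrom stats pf pt rbinom rgeom rnorm runif setNames var sd
#' @importFrom utils read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree of a half-sib (or arbitrary) population
#'
#' Stores a topologically sorted pedigree: every parent precedes its
#' offspring.  Parents are kept as integer indices into the id vector, with
#' \code{0L} meaning unknown, so that downstream algorithms (tabular
#' relationship matrix, gene dropping) can run without repeated id lookups.
#'
#' Construct with [Pedigree()], which accepts records in any order,
#' normalises unknown-parent codes and performs the topological sort.
#'
#' @slot id character vector of unique individual ids, sorted so parents
#'   precede offspring.
#' @slot sire integer vector, index of each individual's sire (0 = unknown).
#' @slot dam integer vector, index of each individual's dam (0 = unknown).
#' @seealso [buildA()], [sortPedigree()], [simulatePedigree()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer"),
  validity = function(object) {
    n <- length(object@id)
    if (length(object@sire) != n || length(object@dam) != n)
      return("id, sire and dam must have equal length")
    if (anyDuplicated(object@id))
      return("individual ids must be unique")
    bad <- function(p) any(p < 0L | p > n) || any(p[p > 0L] >= seq_len(n)[p > 0L])
    if (bad(object@sire) || bad(object@dam))
      return("parents must precede offspring (pedigree not topologically sorted)")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Unphased SNP genotypes with marker metadata
#'
#' Individuals x SNPs matrix of alternate-allele counts (0, 1, 2 or NA),
#' together with per-SNP metadata (name, chromosome, 1-based position, ref
#' and alt allele labels).  Allele labels are opaque strings: they are never
#' parsed out of SNP names, which in candidate-gene reports may disagree
#' with the alleles actually segregating.
#'
#' @slot geno integer matrix (individuals x SNPs); entries 0/1/2/NA count
#'   copies of the alt allele.  Rownames are individual ids.
#' @slot snpInfo a [S4Vectors::DataFrame] with one row per SNP and columns
#'   \code{name}, \code{chrom}, \code{pos}, \code{ref}, \code{alt} (plus any
#'   extra annotation columns).
#' @seealso [GenotypeMatrix()], [alleleFreqs()], [emHaplotypeFreqs()]
#' @export
setClass("GenotypeMatrix",
  representation(geno = "matrix", snpInfo = "DataFrame"),
  validity = function(object) {
    g <- object@geno
    if (!is.numeric(g)) return("genotype codes must be numeric")
    v <- g[!is.na(g)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      return("genotype codes must be 0, 1, 2 or NA")
    si <- object@snpInfo
    need <- c("name", "chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(si)))
      return(paste("snpInfo must have columns:", paste(need, collapse = ", ")))
    if (nrow(si) != ncol(g))
      return("snpInfo rows must match genotype columns")
    for (ch in unique(si$chrom)) {
      p <- si$pos[si$chrom == ch]
      if (any(diff(p) <= 0))
        return(sprintf("positions not strictly increasing on chromosome %s", ch))
    }
    TRUE
  }
)

## ---------------------------------------------------------------------------
## HaplotypeBlock
## ---------------------------------------------------------------------------

#' A haplotype block with EM-estimated haplotype frequencies
#'
#' A contiguous run of SNPs (by map order) plus the haplotypes observed in
#' it and their EM frequencies.  Haplotypes are labelled H1, H2, ... in
#' decreasing frequency order; haplotypes at frequency greater than the
#' retention threshold (default 0.05) are flagged as retained and are the
#' ones used for diplotype (haplotype-combination) association analysis.
#'
#' @slot snps integer indices of the member SNPs (columns of the source
#'   [GenotypeMatrix]).
#' @slot snpNames character names of the member SNPs.
#' @slot haplotypes character allele strings, one per haplotype.
#' @slot freq numeric EM frequencies, same order as \code{haplotypes}.
#' @slot retained logical, frequency above the retention threshold.
#' @seealso [detectBlocks()], [assignDiplotypes()]
#' @export
setClass("HaplotypeBlock",
  representation(snps = "integer", snpNames = "character",
                 haplotypes = "character", freq = "numeric",
                 retained = "logical"),
  validity = function(object) {
    if (length(object@haplotypes) != length(object@freq) ||
        length(object@freq) != length(object@retained))
      return("haplotypes, freq and retained must align")
    if (any(object@freq < -1e-9) || sum(object@freq) > 1 + 1e-6)
      return("haplotype frequencies must be in [0,1] and sum to at most 1")
    if (length(object@snps) && any(diff(object@snps) != 1L))
      return("block SNPs must be contiguous")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## AnimalModelFit
## ---------------------------------------------------------------------------

#' Fitted animal model for one trait, lactation and genotype factor
#'
#' Result of solving Henderson's mixed-model equations for the model
#' y = mu + HYS + b M + G + a + e with a ~ N(0, A sigma_a^2) and
#' e ~ N(0, I sigma_e^2).  Holds fixed-effect solutions, BLUPs of the
#' additive effects, least-squares means of the genotype classes with
#' their covariance, the overall Wald F test of the genotype factor and
#' Bonferroni-adjusted pairwise comparisons with compact-letter displays.
#'
#' @slot beta named numeric, fixed-effect solutions.
#' @slot u named numeric, BLUPs of additive genetic effects (empty when
#'   sigma_a^2 = 0).
#' @slot lsm data.frame with columns class, n, lsm, se.
#' @slot vcovLsm covariance matrix of the least-squares means.
#' @slot overall list with elements F, df1, df2, p (genotype Wald test).
#' @slot pairwise data.frame of pairwise LSM contrasts with raw and
#'   Bonferroni-adjusted p values.
#' @slot letters list of compact-letter displays, one per alpha level.
#' @slot sigmaE2,lambda numeric; residual variance and variance ratio used.
#' @slot nObs,rankX integer; records used and fixed-design rank.
#' @slot meta list; trait, lactation, factor name.
#' @seealso [fitAnimalModel()], [lsMeans()], [pairwiseLetters()]
#' @export
setClass("AnimalModelFit",
  representation(beta = "numeric", u = "numeric", lsm = "data.frame",
                 vcovLsm = "matrix", overall = "list", pairwise = "data.frame",
                 letters = "list", sigmaE2 = "numeric", lambda = "numeric",
                 nObs = "integer", rankX = "integer", meta = "list"))

## ---------------------------------------------------------------------------
## Motif
## ---------------------------------------------------------------------------

#' Transcription-factor binding motif (position frequency matrix)
#'
#' A 4 x L matrix of observed base counts (rows A, C, G, T) for a
#' transcription factor, as distributed in JASPAR flat files.
#'
#' @slot name transcription-factor name.
#' @slot id matrix identifier (e.g. a JASPAR accession), may be "".
#' @slot counts 4 x L numeric matrix with rownames A, C, G, T.
#' @seealso [readJaspar()], [pfmToPwm()], [scanAlleles()]
#' @export
setClass("Motif",
  representation(name = "character", id = "character", counts = "matrix"),
  validity = function(object) {
    m <- object@counts
    if (!identical(rownames(m), c("A", "C", "G", "T")))
      return("counts must have rownames A, C, G, T")
    if (any(m < 0)) return("counts must be non-negative")
    if (ncol(m) < 4) return("motif length must be at least 4")
    if (any(colSums(m) <= 0)) return("every column must have positive total count")
    TRUE
  }
)
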