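## Synthetic half-sib study generator: pedigree, phased diplotypes drawn
## from a haplotype pool (no recombination within the short candidate-gene
## region), and phenotypes from the animal model, with full ground truth
## retained for parameter-recovery studies.

#' Simulation configuration for a half-sib candidate-gene study
#'
#' Holds the design of the emulated study: sire families with a given
#' daughter-number distribution, herd/year/season structure, a haplotype
#' pool defining the LD structure of the candidate region, and per-trait
#' generative parameters (mean, covariate slope, HYS spread, additive and
#' residual variances, per-SNP additive/dominance effects).
#'
#' @slot nSires number of sire families.
#' @slot daughterRange integer c(min, max) daughters per sire.
#' @slot meanDaughters target mean daughters per sire (the count is
#'   min + a truncated geometric with this mean).
#' @slot nHerds,nYears,nSeasons herd-year-season structure.
#' @slot pool data.frame with columns \code{haplotype} (allele string) and
#'   \code{freq} (summing to 1).
#' @slot snpInfo data.frame of the pool's SNPs (name, chrom, pos, ref, alt).
#' @slot traits named list; each element a list with \code{mu},
#'   \code{betaM}, \code{hysSd}, \code{sigmaA2}, \code{sigmaE2},
#'   \code{snpA}, \code{snpD} (per-SNP effects, alt-allele homozygote
#'   = +a, heterozygote = d, ref homozygote = -a).
#' @slot mAgeRange month age of calving at first lactation, uniform range.
#' @slot fracLact1 fraction of cows with a first-lactation record.
#' @slot fracLact2 fraction of first-lactation cows that also have a
#'   second-lactation record (an independent residual, the same breeding
#'   value).
#' @slot seed master RNG seed; per-stage child seeds are derived from it.
#' @seealso [simConfig()], [simulateStudy()]
#' @export
setClass("SimConfig",
  representation(nSires = "integer", daughterRange = "integer",
                 meanDaughters = "numeric", nHerds = "integer",
                 nYears = "integer", nSeasons = "integer",
                 pool = "data.frame", snpInfo = "data.frame",
                 traits = "list", mAgeRange = "numeric",
                 fracLact1 = "numeric", fracLact2 = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nSires < 1) return("nSires must be at least 1")
    dr <- object@daughterRange
    if (length(dr) != 2 || dr[1] > dr[2] || dr[1] < 1)
      return("daughterRange must be a valid [min, max] with min <= max")
    if (object@meanDaughters < dr[1] || object@meanDaughters > dr[2])
      return("meanDaughters must lie within daughterRange")
    if (abs(sum(object@pool$freq) - 1) > 1e-9)
      return("haplotype pool frequencies must sum to 1")
    if (length(unique(nchar(object@pool$haplotype))) != 1 ||
        nchar(object@pool$haplotype[1]) != nrow(object@snpInfo))
      return("all pool haplotypes must cover exactly the configured SNPs")
    k <- nrow(object@snpInfo)
    for (tr in names(object@traits)) {
      t <- object@traits[[tr]]
      if (t$sigmaA2 < 0 || t$sigmaE2 <= 0)
        return(sprintf("trait %s: need sigmaA2 >= 0 and sigmaE2 > 0", tr))
      if (length(t$snpA) != k || length(t$snpD) != k)
        return(sprintf("trait %s: snpA/snpD must have one entry per SNP", tr))
    }
    TRUE
  }
)

#' ACADVL-like haplotype pool (8 SNPs, 5 haplotypes, one block)
#'
#' The candidate-gene block used as the default simulation region: eight
#' SNPs in near-complete LD carried by five haplotypes at frequencies
#' 0.42 / 0.23 / 0.16 / 0.13 / 0.06.
#'
#' @return list with \code{pool} (haplotype, freq) and \code{snpInfo}.
#' @export
acadvlPool <- function() {
  haps <- c("CCCCGAGA", "TCCGTCAG", "CCCGGCGA", "CTCGGCGA", "CCGGGCGA")
  freq <- c(0.42, 0.23, 0.16, 0.13, 0.06)
  pos <- c(26933503L, 26936476L, 26936494L, 26937081L, 26940095L,
           26941116L, 26941290L, 26941299L)
  mat <- do.call(rbind, strsplit(haps, ""))
  ref <- mat[1, ]
  alt <- apply(mat, 2, function(col) setdiff(unique(col), col[1])[1])
  list(pool = data.frame(haplotype = haps, freq = freq,
                         stringsAsFactors = FALSE),
       snpInfo = data.frame(name = paste0("g.", pos), chrom = "19",
                            pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE))
}

#' IRF6-like haplotype pool (two 3-SNP blocks around a free SNP)
#'
#' Seven SNPs: a 3-SNP block (haplotypes GCA/ATG/GCG/GTG at 0.513 / 0.265
#' / 0.115 / 0.107), one freely recombining SNP at frequency 0.5, and a
#' second 3-SNP block (CCC/CCG/TTG at 0.587 / 0.360 / 0.053).  Segments
#' combine independently, emulating recombination between blocks while
#' haplotypes stay intact within each.
#'
#' @return list with \code{pool} and \code{snpInfo} as in [acadvlPool()].
#' @export
irf6Pool <- function() {
  b1 <- data.frame(h = c("GCA", "ATG", "GCG", "GTG"),
                   f = c(0.513, 0.265, 0.115, 0.107) / 1.000)
  b1$f <- b1$f / sum(b1$f)
  mid <- data.frame(h = c("A", "G"), f = c(0.5, 0.5))
  b2 <- data.frame(h = c("CCC", "CCG", "TTG"), f = c(0.587, 0.360, 0.053))
  b2$f <- b2$f / sum(b2$f)
  gr <- expand.grid(i = seq_len(nrow(b1)), j = seq_len(nrow(mid)),
                    k = seq_len(nrow(b2)))
  pool <- data.frame(
    haplotype = paste0(b1$h[gr$i], mid$h[gr$j], b2$h[gr$k]),
    freq = b1$f[gr$i] * mid$f[gr$j] * b2$f[gr$k],
    stringsAsFactors = FALSE)
  pos <- c(73506456L, 73507276L, 73510990L, 73513000L, 73515941L,
           73516019L, 73517802L)
  mat <- do.call(rbind, strsplit(pool$haplotype, ""))
  ref <- mat[1, ]
  alt <- vapply(seq_along(ref), function(j)
    setdiff(unique(mat[, j]), ref[j])[1], character(1))
  list(pool = pool,
       snpInfo = data.frame(name = paste0("g.", pos), chrom = "16",
                            pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE))
}

#' Construct a simulation configuration
#'
#' Defaults emulate the study design the package targets: 110 sire
#' families with 5-80 daughters each (mean 11, about 1186 cows), two
#' herds, per-lactation records (about 95% of cows with a first and 55%
#' of those with a second lactation), the ACADVL-like 8-SNP haplotype
#' pool, and five milk production traits at dairy-realistic means and
#' heritabilities (0.3 for yields, 0.5 for percentages) with an additive
#' effect a = 4.8 kg and dominance d = -1.9 kg of fat yield at SNP 1.
#'
#' @param nSires,daughterRange,meanDaughters,nHerds,nYears,nSeasons design
#'   parameters (see \linkS4class{SimConfig}).
#' @param pool,snpInfo haplotype pool; default [acadvlPool()].
#' @param traits per-trait generative parameters; default five milk traits.
#' @param mAgeRange,fracLact1,fracLact2 record structure.
#' @param seed master seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSires = 110, daughterRange = c(5, 80),
                      meanDaughters = 11, nHerds = 2, nYears = 3,
                      nSeasons = 4, pool = NULL, snpInfo = NULL,
                      traits = NULL, mAgeRange = c(22, 40),
                      fracLact1 = 1122 / 1186, fracLact2 = 617 / 1122,
                      seed = 1) {
  if (is.null(pool) || is.null(snpInfo)) {
    def <- acadvlPool()
    pool <- pool %||% def$pool
    snpInfo <- snpInfo %||% def$snpInfo
  }
  k <- nrow(snpInfo)
  zero <- numeric(k)
  fatA <- zero; fatA[1] <- 4.8
  fatD <- zero; fatD[1] <- -1.9
  traits <- traits %||% list(
    milk_kg     = list(mu = 8500, betaM = 15, hysSd = 300,
                       sigmaA2 = 432000, sigmaE2 = 1008000,
                       snpA = zero, snpD = zero),
    fat_kg      = list(mu = 300, betaM = 0.5, hysSd = 10,
                       sigmaA2 = 480, sigmaE2 = 1120,
                       snpA = fatA, snpD = fatD),
    fat_pct     = list(mu = 3.6, betaM = 0, hysSd = 0.08,
                       sigmaA2 = 0.06, sigmaE2 = 0.06,
                       snpA = zero, snpD = zero),
    protein_kg  = list(mu = 260, betaM = 0.4, hysSd = 8,
                       sigmaA2 = 270, sigmaE2 = 630,
                       snpA = zero, snpD = zero),
    protein_pct = list(mu = 3.1, betaM = 0, hysSd = 0.05,
                       sigmaA2 = 0.02, sigmaE2 = 0.02,
                       snpA = zero, snpD = zero))
  new("SimConfig", nSires = as.integer(nSires),
      daughterRange = as.integer(daughterRange),
      meanDaughters = meanDaughters, nHerds = as.integer(nHerds),
      nYears = as.integer(nYears), nSeasons = as.integer(nSeasons),
      pool = pool, snpInfo = snpInfo, traits = traits,
      mAgeRange = mAgeRange, fracLact1 = fracLact1, fracLact2 = fracLact2,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d sires x %d-%d daughters (mean %.1f), %d SNPs, %d traits, seed %d\n",
              object@nSires, object@daughterRange[1], object@daughterRange[2],
              object@meanDaughters, nrow(object@snpInfo),
              length(object@traits), object@seed))
})

#' Simulate the three-generation half-sib pedigree
#'
#' Each sire gets two founder parents (the grandparent generation) and a
#' number of daughters equal to the range minimum plus a truncated
#' geometric draw calibrated to the configured mean; each daughter has a
#' distinct founder dam (paternal half-sib design).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed (default: derived from the config's master seed).
#' @return a \linkS4class{Pedigree}; daughters carry ids starting "C".
#' @export
simulatePedigree <- function(config, seed = childSeed(config@seed, 1L)) {
  stopifnot(is(config, "SimConfig"))
  set.seed(seed)
  ns <- config@nSires
  lo <- config@daughterRange[1]
  hi <- config@daughterRange[2]
  nd <- if (lo == hi) rep(lo, ns) else {
    p <- 1 / (config@meanDaughters - lo + 1)
    lo + pmin(rgeom(ns, p), hi - lo)
  }
  sire <- sprintf("S%03d", seq_len(ns))
  gs <- sprintf("GS%03d", seq_len(ns))
  gd <- sprintf("GD%03d", seq_len(ns))
  nTot <- sum(nd)
  dam <- sprintf("D%05d", seq_len(nTot))
  cow <- sprintf("C%05d", seq_len(nTot))
  cowSire <- rep(sire, nd)
  Pedigree(id = c(gs, gd, dam, sire, cow),
           sire = c(rep(NA, 2 * ns + nTot), gs, cowSire),
           dam = c(rep(NA, 2 * ns + nTot), gd, dam))
}

#' Drop haplotypes through a pedigree
#'
#' Founders draw two haplotypes i.i.d. from the pool; non-founders inherit
#' one whole haplotype from each parent uniformly at random (no
#' recombination within the short candidate-gene region).  An unknown
#' parent side is drawn from the pool.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param pool data.frame with \code{haplotype}, \code{freq}.
#' @param snpInfo data.frame of the pool SNPs (for allele coding).
#' @param seed RNG seed.
#' @return list with \code{hap1}, \code{hap2} (pool indices per
#'   individual, named), \code{pool}, \code{bits} (haplotype x SNP 0/1
#'   matrix of alt-allele indicators).
#' @export
simulateDiplotypes <- function(pedigree, pool, snpInfo, seed = 1) {
  stopifnot(is(pedigree, "Pedigree"), nrow(pool) >= 1)
  set.seed(seed)
  n <- length(pedigree@id)
  nh <- nrow(pool)
  bits <- t(vapply(strsplit(pool$haplotype, ""), function(al)
    as.integer(al == snpInfo$alt), integer(nrow(snpInfo))))
  h1 <- integer(n)
  h2 <- integer(n)
  drawPool <- function(m) sample.int(nh, m, replace = TRUE, prob = pool$freq)
  pick <- sample(c(TRUE, FALSE), 2L * n, replace = TRUE)  # which parental hap
  for (i in seq_len(n)) {
    s <- pedigree@sire[i]
    d <- pedigree@dam[i]
    h1[i] <- if (s > 0L) { if (pick[2L * i - 1L]) h1[s] else h2[s] } else drawPool(1L)
    h2[i] <- if (d > 0L) { if (pick[2L * i]) h1[d] else h2[d] } else drawPool(1L)
  }
  names(h1) <- names(h2) <- pedigree@id
  list(hap1 = h1, hap2 = h2, pool = pool, bits = bits)
}

#' Unphased genotypes from phased diplotypes
#'
#' @param diplos result of [simulateDiplotypes()].
#' @param snpInfo SNP metadata (name, chrom, pos, ref, alt).
#' @param ids optional subset/order of individual ids (default: all).
#' @return a \linkS4class{GenotypeMatrix} of alt-allele counts.
#' @export
diplotypesToGenotypes <- function(diplos, snpInfo, ids = NULL) {
  ids <- ids %||% names(diplos$hap1)
  geno <- diplos$bits[diplos$hap1[ids], , drop = FALSE] +
    diplos$bits[diplos$hap2[ids], , drop = FALSE]
  rownames(geno) <- ids
  colnames(geno) <- snpInfo$name
  GenotypeMatrix(geno, snpInfo)
}

## herd/year/season/month-age record skeleton for the phenotyped daughters
.recordSkeleton <- function(config, cows, seed) {
  set.seed(seed)
  n1 <- round(config@fracLact1 * length(cows))
  cows1 <- sort(sample(cows, n1))
  n2 <- round(config@fracLact2 * n1)
  cows2 <- sort(sample(cows1, n2))
  herd <- setNames(sample.int(config@nHerds, length(cows), replace = TRUE), cows)
  mk <- function(cc, lact) {
    m1 <- runif(length(cc), config@mAgeRange[1], config@mAgeRange[2])
    data.frame(cow_id = cc, lactation = lact, herd = herd[cc],
               year = sample.int(config@nYears, length(cc), replace = TRUE) +
                 (lact - 1L),
               season = sample.int(config@nSeasons, length(cc), replace = TRUE),
               month_age = round(m1 + (lact - 1L) * runif(length(cc), 11, 15), 1),
               stringsAsFactors = FALSE)
  }
  rbind(mk(cows1, 1L), mk(cows2, 2L))
}

#' Simulate phenotype records from the animal model
#'
#' Generates, per trait, y = mu + HYS + b M + G(genotype) + u + e with
#' u = L z sqrt(sigma_a^2) (L the Cholesky factor of A), HYS effects
#' i.i.d. normal with the configured spread, and independent residuals per
#' record.  Second-lactation records reuse the cow's breeding value with a
#' fresh residual.  The per-SNP genotype contribution is +a / d / -a for
#' the alt homozygote / heterozygote / ref homozygote.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param diplos diplotypes from [simulateDiplotypes()].
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed.
#' @param cholA optional precomputed \code{chol(buildA(pedigree))}.
#' @param records optional precomputed record skeleton (reuse across
#'   seeds to hold the cohort structure fixed).
#' @return list with \code{pheno} (record data.frame), \code{u} (matrix
#'   individuals x traits of true breeding values), \code{hys} (list of
#'   per-trait HYS effect lookups), \code{records}.
#' @export
simulatePhenotypes <- function(pedigree, diplos, config,
                               seed = childSeed(config@seed, 3L),
                               cholA = NULL, records = NULL) {
  stopifnot(is(pedigree, "Pedigree"), is(config, "SimConfig"))
  cows <- pedigree@id[grepl("^C", pedigree@id)]
  records <- records %||% .recordSkeleton(config, cows, seed)
  set.seed(seed + 1L)
  if (is.null(cholA)) cholA <- chol(buildA(pedigree))
  n <- length(pedigree@id)
  geno <- diplos$bits[diplos$hap1, , drop = FALSE] +
    diplos$bits[diplos$hap2, , drop = FALSE]
  rownames(geno) <- pedigree@id

  cells <- unique(with(records, paste(herd, year, season, sep = ":")))
  recCell <- with(records, paste(herd, year, season, sep = ":"))
  recIdx <- match(records$cow_id, pedigree@id)

  traits <- config@traits
  u <- matrix(0, n, length(traits),
              dimnames = list(pedigree@id, names(traits)))
  hysOut <- list()
  pheno <- records
  for (tr in names(traits)) {
    t <- traits[[tr]]
    if (t$sigmaA2 > 0)
      u[, tr] <- sqrt(t$sigmaA2) * crossprod(cholA, rnorm(n))
    hys <- setNames(rnorm(length(cells), 0, t$hysSd), cells)
    ## genotype contribution: +a (code 2), d (code 1), -a (code 0)
    gEff <- as.numeric((geno == 2L) %*% t$snpA - (geno == 0L) %*% t$snpA +
                         (geno == 1L) %*% t$snpD)
    e <- rnorm(nrow(records), 0, sqrt(t$sigmaE2))
    pheno[[tr]] <- t$mu + hys[recCell] + t$betaM * records$month_age +
      gEff[recIdx] + u[recIdx, tr] + e
    hysOut[[tr]] <- hys
  }
  list(pheno = pheno, u = u, hys = hysOut, records = records)
}

#' Simulate a complete synthetic study with ground truth
#'
#' Runs [simulatePedigree()], [simulateDiplotypes()] and
#' [simulatePhenotypes()] with per-stage child seeds derived from the
#' config's master seed, so the whole study is reproducible from one
#' integer.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list (truth set): \code{pedigree}, \code{diplotypes},
#'   \code{genotypes} (all individuals), \code{phenotypes} (records for
#'   the phenotyped daughters), \code{u}, \code{hys}, \code{config}.
#' @examples
#' study <- simulateStudy(simConfig(nSires = 15, seed = 42))
#' head(study$phenotypes)
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SimConfig"))
  ped <- simulatePedigree(config)
  diplos <- simulateDiplotypes(ped, config@pool, config@snpInfo,
                               seed = childSeed(config@seed, 2L))
  phen <- simulatePhenotypes(ped, diplos, config)
  geno <- diplotypesToGenotypes(diplos, config@snpInfo)
  list(pedigree = ped, diplotypes = diplos, genotypes = geno,
       phenotypes = phen$pheno, u = phen$u, hys = phen$hys,
       config = config)
}

#' Write a simulated study to disk
#'
#' Emits pedigree CSV, genotype CSV matrix and VCF for the phenotyped
#' cows, phenotype CSV, and a truth JSON (breeding values, HYS effects,
#' diplotype labels).
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePedigree(study$pedigree, file.path(dir, "pedigree.csv"))
  cows <- unique(study$phenotypes$cow_id)
  g <- diplotypesToGenotypes(study$diplotypes, study$config@snpInfo, cows)
  writeGenotypesCSV(g, file.path(dir, "genotypes.csv"))
  writeGenotypesVCF(g, file.path(dir, "genotypes.vcf"))
  write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- list(
    u = as.data.frame(study$u),
    hys = study$hys,
    diplotypes = data.frame(
      id = names(study$diplotypes$hap1),
      hap1 = study$diplotypes$pool$haplotype[study$diplotypes$hap1],
      hap2 = study$diplotypes$pool$haplotype[study$diplotypes$hap2]))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readSimConfig}: a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simConfig(nSires = y$nSires, daughterRange = unlist(y$daughterRange),
            meanDaughters = y$meanDaughters, nHerds = y$nHerds,
            nYears = y$nYears, nSeasons = y$nSeasons,
            pool = as.data.frame(y$pool, stringsAsFactors = FALSE),
            snpInfo = as.data.frame(y$snpInfo, stringsAsFactors = FALSE),
            traits = lapply(y$traits, function(t) {
              t$snpA <- as.numeric(unlist(t$snpA))
              t$snpD <- as.numeric(unlist(t$snpD))
              t
            }),
            mAgeRange = unlist(y$mAgeRange), fracLact1 = y$fracLact1,
            fracLact2 = y$fracLact2, seed = y$seed)
}

#' @rdname readSimConfig
#' @param config a \linkS4class{SimConfig}.
#' @export
writeSimConfig <- function(config, path) {
  y <- list(nSires = config@nSires,
            daughterRange = as.list(config@daughterRange),
            meanDaughters = config@meanDaughters, nHerds = config@nHerds,
            nYears = config@nYears, nSeasons = config@nSeasons,
            pool = as.list(config@pool), snpInfo = as.list(config@snpInfo),
            traits = config@traits,
            mAgeRange = as.list(config@mAgeRange),
            fracLact1 = config@fracLact1, fracLact2 = config@fracLact2,
            seed = config@seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
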