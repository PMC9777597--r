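test_that("simulated pedigree has the half-sib three-generation structure", {
  cfg <- simConfig(nSires = 110, seed = 21)
  ped <- simulatePedigree(cfg)
  df <- as.data.frame(ped)
  cows <- df[grepl("^C", df$id), ]
  expect_gte(nrow(cows), 110 * 5)
  expect_lte(nrow(cows), 110 * 80)
  ## every daughter has exactly one sire and one dam; dams unique
  expect_true(all(!is.na(cows$sire) & !is.na(cows$dam)))
  expect_false(anyDuplicated(cows$dam) > 0)
  ## sires have founder parents (grandparent generation)
  sires <- df[grepl("^S", df$id), ]
  expect_true(all(grepl("^GS", sires$sire)))
  ## dams are founders
  dams <- df[df$id %in% cows$dam, ]
  expect_true(all(is.na(dams$sire) & is.na(dams$dam)))

  ## minimal design: one sire, two daughters -> half sibs, distinct dams
  p1 <- simulatePedigree(simConfig(nSires = 1, daughterRange = c(2, 2),
                                   meanDaughters = 2, seed = 1))
  d1 <- as.data.frame(p1)
  kids <- d1[grepl("^C", d1$id), ]
  expect_equal(nrow(kids), 2L)
  expect_equal(kids$sire[1], kids$sire[2])
  expect_false(kids$dam[1] == kids$dam[2])
  expect_error(simConfig(daughterRange = c(10, 5)), "min <= max")
})

test_that("daughters per sire average about 11 over many seeds", {
  means <- vapply(1:100, function(s) {
    ped <- simulatePedigree(simConfig(nSires = 110, seed = s))
    sum(grepl("^C", pedId(ped))) / 110
  }, numeric(1))
  ## SE of the grand mean: sd(single-seed mean)/sqrt(100)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 11), 2 * se + 0.05)
})

test_that("haplotype dropping follows the pool and Mendelian inheritance", {
  si <- data.frame(name = paste0("s", 1:3), chrom = "1", pos = 1:3 * 100L,
                   ref = c("A", "A", "A"), alt = c("B", "B", "B"))
  ## degenerate pool: everyone homozygous for the single haplotype
  ped <- simulatePedigree(simConfig(nSires = 5, seed = 2))
  pool1 <- data.frame(haplotype = "AAA", freq = 1)
  d1 <- simulateDiplotypes(ped, pool1, si, seed = 3)
  expect_true(all(d1$hap1 == 1L & d1$hap2 == 1L))
  g1 <- diplotypesToGenotypes(d1, si)
  expect_true(all(genotypes(g1) == 0L))

  ## founder haplotype frequency ~ pool frequency (binomial SE)
  pool2 <- data.frame(haplotype = c("AAA", "BBB"), freq = c(0.5, 0.5))
  bigPed <- Pedigree(sprintf("F%05d", 1:10000))
  d2 <- simulateDiplotypes(bigPed, pool2, si, seed = 4)
  f1 <- mean(c(d2$hap1, d2$hap2) == 1L)
  se <- sqrt(0.5 * 0.5 / 20000)
  expect_lt(abs(f1 - 0.5), 3 * se)

  ## parent H1/H2 x parent H1/H1: offspring H1H1 or H1H2, each ~1/2
  trio <- Pedigree(c("P1", "P2", rep(paste0("K", 1:4000), 1)),
                   c(NA, NA, rep("P1", 4000)), c(NA, NA, rep("P2", 4000)))
  d3 <- simulateDiplotypes(trio, pool2, si, seed = 5)
  ## force parental diplotypes by conditioning: P1 must be het, P2 hom H1
  ## (resample seeds until the founders have the wanted diplotypes)
  s <- 5
  while (!(sort(c(d3$hap1["P1"], d3$hap2["P1"])) [1] == 1 &&
           sort(c(d3$hap1["P1"], d3$hap2["P1"])) [2] == 2 &&
           d3$hap1["P2"] == 1 && d3$hap2["P2"] == 1)) {
    s <- s + 1
    d3 <- simulateDiplotypes(trio, pool2, si, seed = s)
  }
  kids <- paste0("K", 1:4000)
  kinds <- paste(pmin(d3$hap1[kids], d3$hap2[kids]),
                 pmax(d3$hap1[kids], d3$hap2[kids]))
  expect_setequal(unique(kinds), c("1 1", "1 2"))
  pHet <- mean(kinds == "1 2")
  expect_lt(abs(pHet - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("founder genotypes are near Hardy-Weinberg for the pool alleles", {
  cfg <- simConfig(seed = 31)
  ped <- Pedigree(sprintf("F%05d", 1:5000))
  d <- simulateDiplotypes(ped, cfg@pool, cfg@snpInfo, seed = 32)
  g <- diplotypesToGenotypes(d, cfg@snpInfo)
  af <- alleleFreqs(g)
  for (j in seq_len(nSnps(g))) {
    p <- af$freqAlt[j]
    expHet <- 2 * p * (1 - p)
    se <- sqrt(expHet * (1 - expHet) / 5000)
    expect_lt(abs(af$freqHet[j] - expHet), 4 * se + 1e-3)
  }
})

test_that("phenotypes equal mu + HYS exactly in the noise-free limit", {
  cfg <- simConfig(nSires = 5, seed = 41)
  cfg@traits <- list(flat = list(mu = 100, betaM = 0, hysSd = 5,
                                 sigmaA2 = 0, sigmaE2 = 1e-20,
                                 snpA = numeric(8), snpD = numeric(8)))
  st <- simulateStudy(cfg)
  ph <- st$phenotypes
  cell <- paste(ph$herd, ph$year, ph$season, sep = ":")
  expect_equal(ph$flat, 100 + unname(st$hys$flat[cell]), tolerance = 1e-6)
})

test_that("homozygote phenotype difference recovers 2a in a large unrelated sample", {
  k <- 3
  si <- data.frame(name = paste0("s", 1:k), chrom = "1", pos = 1:k * 10L,
                   ref = rep("A", k), alt = rep("B", k))
  pool <- data.frame(haplotype = c("AAA", "BBB"), freq = c(0.5, 0.5))
  cfg <- simConfig(nSires = 500, daughterRange = c(10, 10), meanDaughters = 10,
                   pool = pool, snpInfo = si,
                   traits = list(y = list(mu = 50, betaM = 0, hysSd = 0,
                                          sigmaA2 = 0, sigmaE2 = 25,
                                          snpA = c(4.8, 0, 0),
                                          snpD = c(0, 0, 0))),
                   fracLact1 = 1, seed = 51)
  st <- simulateStudy(cfg)
  ph <- st$phenotypes[st$phenotypes$lactation == 1, ]
  code <- genotypes(st$genotypes)[ph$cow_id, 1]
  mAA <- mean(ph$y[code == 2])
  m00 <- mean(ph$y[code == 0])
  seDiff <- sqrt(25 / sum(code == 2) + 25 / sum(code == 0))
  expect_lt(abs((mAA - m00) - 2 * 4.8), 2 * seDiff + 0.1)
})

test_that("breeding values match sigma_a2 and half-sib correlation 1/4", {
  cfg <- simConfig(nSires = 110, seed = 61)
  st <- simulateStudy(cfg)
  u <- st$u[, "fat_kg"]
  f <- founders(st$pedigree)
  expect_lt(abs(var(u[f]) - 480) / 480, 0.2)  # founders: var = sigma_a2
  ## paternal half-sib covariance ~ sigma_a2 / 4
  df <- as.data.frame(st$pedigree)
  cows <- df[grepl("^C", df$id), ]
  bySire <- split(cows$id, cows$sire)
  prs <- do.call(rbind, lapply(bySire, function(ids) {
    if (length(ids) < 2) return(NULL)
    t(combn(ids, 2))
  }))
  cv <- cov(u[prs[, 1]], u[prs[, 2]])
  expect_lt(abs(cv - 480 / 4) / (480 / 4), 0.35)
})

test_that("the same master seed reproduces the study exactly", {
  s1 <- simulateStudy(simConfig(nSires = 10, seed = 77))
  s2 <- simulateStudy(simConfig(nSires = 10, seed = 77))
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  expect_identical(genotypes(s1$genotypes), genotypes(s2$genotypes))
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- simulateStudy(simConfig(nSires = 10, seed = 78))
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("study files round-trip: pedigree, genotype CSV/VCF, config YAML", {
  st <- cachedStudy()
  dir <- file.path(tempdir(), "studyout")
  writeStudy(st, dir)
  ped2 <- readPedigree(file.path(dir, "pedigree.csv"))
  expect_equal(as.data.frame(ped2), as.data.frame(st$pedigree))
  gCsv <- readGenotypesCSV(file.path(dir, "genotypes.csv"))
  gVcf <- readGenotypesVCF(file.path(dir, "genotypes.vcf"))
  cows <- unique(st$phenotypes$cow_id)
  ref <- genotypes(st$genotypes)[cows, ]
  expect_equal(unname(genotypes(gCsv)), unname(ref))
  expect_equal(unname(genotypes(gVcf)), unname(ref))
  expect_equal(as.data.frame(snpInfo(gVcf))$pos, as.data.frame(snpInfo(st$genotypes))$pos)
  ## truth JSON exists and parses
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true(all(c("u", "hys", "diplotypes") %in% names(truth)))

  cfgPath <- file.path(dir, "sim.yaml")
  writeSimConfig(st$config, cfgPath)
  cfg2 <- readSimConfig(cfgPath)
  expect_equal(cfg2@pool$freq, st$config@pool$freq)
  expect_equal(cfg2@traits$fat_kg$snpA, st$config@traits$fat_kg$snpA)
  expect_identical(cfg2@seed, st$config@seed)
})
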