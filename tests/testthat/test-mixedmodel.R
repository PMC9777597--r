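## small study with a genotype effect, reused across tests
smallFit <- function(seed = 301, sigmaA2 = 480, trait = "fat_kg",
                     nSires = 25) {
  st <- cachedStudy(nSires = nSires, seed = seed)
  A <- buildA(st$pedigree)
  cows <- unique(st$phenotypes$cow_id)
  classes <- genotypeClasses(st$genotypes, 1, cows)
  fit <- fitAnimalModel(st$phenotypes, classes, A,
                        vc = list(sigmaA2 = sigmaA2, sigmaE2 = 1120),
                        trait = trait, lactation = 1)
  list(st = st, A = A, classes = classes, fit = fit)
}

test_that("MME solutions equal dense GLS and reduce to OLS at sigma_a2 = 0", {
  st <- cachedStudy(nSires = 15, seed = 311)
  A <- buildA(st$pedigree)
  ph <- st$phenotypes[st$phenotypes$lactation == 1, ]
  hys <- interaction(ph$herd, ph$year, ph$season, drop = TRUE)
  G <- factor(genotypeClasses(st$genotypes, 1)[ph$cow_id])
  X <- model.matrix(~ hys + M + G, data.frame(hys = hys, M = ph$month_age, G = G))
  idx <- match(ph$cow_id, rownames(A))
  y <- ph$fat_kg
  sa2 <- 480; se2 <- 1120
  des <- mmeDesign(X, idx, chol2inv(chol(A)), lambda = se2 / sa2)
  sol <- mmeSolve(des, y)
  betaGLS <- oracleGLS(X, idx, A, sa2, se2, y)
  expect_lt(max(abs(sol$beta - betaGLS)) / max(abs(betaGLS)), 1e-6)

  ## sigma_a2 = 0: fit equals lm() on the same fixed design
  classes <- genotypeClasses(st$genotypes, 1, unique(st$phenotypes$cow_id))
  fit0 <- fitAnimalModel(st$phenotypes, classes, A,
                         vc = list(sigmaA2 = 0, sigmaE2 = se2),
                         trait = "fat_kg", lactation = 1, minCell = 1)
  ols <- lm(y ~ hys + M + G, data.frame(hys = hys, M = ph$month_age, G = G))
  expect_equal(unname(fit0@beta), unname(coef(ols)), tolerance = 1e-8)
})

test_that("with lambda -> infinity a balanced one-way design returns raw class means", {
  set.seed(321)
  n <- 60
  ids <- sprintf("C%03d", 1:n)
  ped <- Pedigree(ids)
  A <- buildA(ped)
  cls <- setNames(rep(c("AA", "AB", "BB"), each = n / 3), ids)
  pheno <- data.frame(cow_id = ids, lactation = 1, herd = 1, year = 1,
                      season = 1, month_age = 30,
                      y = rnorm(n, 100 + (cls == "AB") * 5 + (cls == "BB") * 9, 3))
  fit <- fitAnimalModel(pheno, cls, A, vc = list(sigmaA2 = 1e-9, sigmaE2 = 10),
                        trait = "y")
  raw <- tapply(pheno$y, cls[pheno$cow_id], mean)
  expect_equal(unname(setNames(fit@lsm$lsm, fit@lsm$class)),
               as.numeric(raw[fit@lsm$class]), tolerance = 1e-5)
})

test_that("LSMs weight unequal HYS cells equally, unlike raw class means", {
  ## 6 observations, two herds of unequal size per class; hand oracle
  pheno <- data.frame(
    cow_id = sprintf("C%d", 1:6), lactation = 1,
    herd = c(1, 1, 1, 2, 1, 2), year = 1, season = 1, month_age = 30,
    y = c(10, 12, 14, 30, 16, 34))
  cls <- setNames(rep(c("AA", "BB"), each = 3), pheno$cow_id)
  ped <- Pedigree(pheno$cow_id)
  A <- buildA(ped)
  fit <- fitAnimalModel(pheno, cls, A, vc = list(sigmaA2 = 0, sigmaE2 = 1),
                        trait = "y", minCell = 1)
  ## OLS by hand: y = b0 + h2*I(herd2) + gBB*I(BB)
  X <- cbind(1, c(0, 0, 0, 1, 0, 1), c(0, 0, 0, 1, 1, 1))
  b <- solve(crossprod(X), crossprod(X, pheno$y))
  lsmHand <- c(AA = b[1] + b[2] / 2, BB = b[1] + b[2] / 2 + b[3])
  expect_equal(setNames(fit@lsm$lsm, fit@lsm$class), lsmHand, tolerance = 1e-8)
  ## differs from the raw class means because cells are unbalanced
  expect_gt(abs(fit@lsm$lsm[1] - mean(pheno$y[1:3])), 1e-6)
})

test_that("LSMs are invariant to the reference level of the genotype factor", {
  base <- smallFit()
  relab <- c(CC = "xCC", CT = "aCT", TT = "mTT")  # changes factor ordering
  classes2 <- setNames(unname(relab[base$classes]), names(base$classes))
  fit2 <- fitAnimalModel(base$st$phenotypes, classes2, base$A,
                         vc = list(sigmaA2 = 480, sigmaE2 = 1120),
                         trait = "fat_kg", lactation = 1)
  l1 <- setNames(base$fit@lsm$lsm, base$fit@lsm$class)
  l2 <- setNames(fit2@lsm$lsm, fit2@lsm$class)
  expect_equal(unname(l2[relab[names(l1)]]), unname(l1), tolerance = 1e-8)
  expect_equal(fit2@overall$p, base$fit@overall$p, tolerance = 1e-8)
})

test_that("p-values are invariant to trait rescaling", {
  base <- smallFit()
  st <- base$st
  ph <- st$phenotypes
  ph$fat_scaled <- ph$fat_kg * 1000
  fit2 <- fitAnimalModel(ph, base$classes, base$A,
                         vc = list(sigmaA2 = 480 * 1e6, sigmaE2 = 1120 * 1e6),
                         trait = "fat_scaled", lactation = 1)
  expect_equal(fit2@overall$p, base$fit@overall$p, tolerance = 1e-6)
  expect_equal(fit2@pairwise$pAdj, base$fit@pairwise$pAdj, tolerance = 1e-6)
})

test_that("a no-noise dataset with identical class means gives F = 0, p = 1", {
  ids <- sprintf("C%02d", 1:30)
  ped <- Pedigree(ids)
  A <- buildA(ped)
  cls <- setNames(rep(c("AA", "AB", "BB"), 10), ids)
  pheno <- data.frame(cow_id = ids, lactation = 1,
                      herd = rep(1:2, 15), year = 1, season = 1,
                      month_age = 30, y = rep(c(5, 9), 15))
  fit <- fitAnimalModel(pheno, cls, A, vc = list(sigmaA2 = 0, sigmaE2 = 1),
                        trait = "y", minCell = 1)
  expect_equal(fit@overall$F, 0, tolerance = 1e-20)
  expect_equal(testGenotypeEffect(fit), 1)
  ## all classes share a letter at both levels
  expect_true(all(fit@lsm$letters == "a/A"))
})

test_that("degenerate inputs are caught: aliasing, missing cows, empty classes", {
  base <- smallFit()
  st <- base$st
  ## genotype confounded with HYS: make class a copy of the herd factor
  ph <- st$phenotypes
  cls <- setNames(paste0("H", ph$herd[match(names(base$classes), ph$cow_id)]),
                  names(base$classes))
  ph2 <- ph
  ph2$year <- 1
  ph2$season <- 1
  expect_error(
    fitAnimalModel(ph2, cls, base$A, vc = list(sigmaA2 = 0, sigmaE2 = 1),
                   trait = "fat_kg", lactation = 1),
    "aliased")
  ## cow absent from A
  drop <- match(st$phenotypes$cow_id[1], rownames(base$A))
  A2 <- base$A[-drop, -drop]
  expect_error(
    fitAnimalModel(st$phenotypes, base$classes, A2,
                   vc = list(sigmaA2 = 480, sigmaE2 = 1120),
                   trait = "fat_kg", lactation = 1),
    "missing from the relationship matrix")
})

test_that("compact letter displays follow the insert-absorb construction", {
  ## significant (1,3) only -> a / ab / b
  l <- compactLetters(c("g1", "g2", "g3"),
                      data.frame(a = "g1", b = "g3"))
  expect_equal(unname(l), c("a", "ab", "b"))
  ## nothing significant -> everyone shares "a"
  l2 <- compactLetters(c("x", "y", "z"), data.frame(a = character(0),
                                                    b = character(0)))
  expect_equal(unname(l2), c("a", "a", "a"))
  ## everything significant -> distinct letters
  prs <- t(combn(c("x", "y", "z"), 2))
  l3 <- compactLetters(c("x", "y", "z"),
                       data.frame(a = prs[, 1], b = prs[, 2]))
  expect_equal(unname(l3), c("a", "b", "c"))
  ## order-independence of the pair list
  l4 <- compactLetters(c("x", "y", "z"),
                       data.frame(a = rev(prs[, 1]), b = rev(prs[, 2])))
  expect_equal(l3, l4)
  ## letters consistent with the fitted pairwise table
  fit <- smallFit()$fit
  for (a in c(0.05, 0.01)) {
    lt <- pairwiseLetters(fit, a)[[1]]
    pw <- fit@pairwise
    for (r in seq_len(nrow(pw))) {
      shares <- any(strsplit(lt[pw$class1[r]], "")[[1]] %in%
                      strsplit(lt[pw$class2[r]], "")[[1]])
      expect_equal(shares, pw$pAdj[r] >= a)
    }
  }
})

test_that("BLUPs shrink toward zero and follow family structure", {
  base <- smallFit()
  fit <- base$fit
  u <- fit@u
  expect_equal(length(u), nIndividuals(base$st$pedigree))
  ## mean BLUP near zero
  expect_lt(abs(mean(u)), 2)
  ## BLUPs correlate positively with true breeding values
  cows <- unique(base$st$phenotypes$cow_id)
  expect_gt(cor(u[cows], base$st$u[cows, "fat_kg"]), 0.3)
})
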