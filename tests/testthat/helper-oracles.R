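## Independent oracles used across the suite.  These deliberately avoid
## the package's own algorithms: kinship by direct recursion, relationship
## by gene-dropping Monte Carlo, GLS by dense matrix algebra, D' and PWM
## scores by brute-force enumeration.

## recursive kinship phi(i,j); a_ij = 2 phi_ij, a_ii = 1 + F_i
oracleKinshipMatrix <- function(ped) {
  df <- as.data.frame(ped)
  n <- nrow(df)
  s <- match(df$sire, df$id)
  d <- match(df$dam, df$id)
  phi <- matrix(NA_real_, n, n)
  getPhi <- function(i, j) {
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + if (!is.na(s[i]) && !is.na(d[i])) getPhi(s[i], d[i]) else 0)
    } else {
      a <- max(i, j)  # later individual cannot be the other's ancestor
      b <- min(i, j)
      half <- function(p) if (is.na(p)) 0 else getPhi(p, b)
      0.5 * (half(s[a]) + half(d[a]))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in i:n) getPhi(i, j)
  A <- 2 * phi
  diag(A) <- diag(phi) * 2
  dimnames(A) <- list(df$id, df$id)
  A
}

## gene-dropping estimate of relationship entries for selected id pairs:
## founders get unique allele labels, alleles drop through the pedigree,
## a_ij is estimated by allele-sharing counts over replicates.
## Returns per pair the estimate and its Monte Carlo standard error.
oracleGeneDrop <- function(ped, pairs, nRep = 1e5, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(ped)
  n <- nrow(df)
  s <- match(df$sire, df$id)
  d <- match(df$dam, df$id)
  a1 <- matrix(0L, n, nRep)
  a2 <- matrix(0L, n, nRep)
  nextLab <- 0L
  for (i in seq_len(n)) {
    if (is.na(s[i])) {
      a1[i, ] <- nextLab + 1L
      nextLab <- nextLab + 1L
    } else {
      pick <- runif(nRep) < 0.5
      a1[i, ] <- ifelse(pick, a1[s[i], ], a2[s[i], ])
    }
    if (is.na(d[i])) {
      a2[i, ] <- nextLab + 1L
      nextLab <- nextLab + 1L
    } else {
      pick <- runif(nRep) < 0.5
      a2[i, ] <- ifelse(pick, a1[d[i], ], a2[d[i], ])
    }
  }
  t(apply(pairs, 1, function(pr) {
    i <- pr[1]
    j <- pr[2]
    x <- if (i == j) {
      1 + (a1[i, ] == a2[i, ])  # a_ii = 1 + F
    } else {
      ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
         (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 2
    }
    c(est = mean(x), se = sd(x) / sqrt(nRep))
  }))
}

## random pedigree with founders, matings of earlier individuals, and the
## occasional parent-offspring loop, for property tests
randomPedigree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("I%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < 0.3) next  # founder
    pool <- seq_len(i - 1L)
    pick <- sample(pool, 2)
    sire[i] <- id[pick[1]]
    dam[i] <- id[pick[2]]
  }
  Pedigree(id, sire, dam)
}

## dense GLS with V = Z A Z' sa2 + I se2 (small n only)
oracleGLS <- function(X, Zidx, A, sa2, se2, y) {
  n <- length(y)
  Z <- matrix(0, n, nrow(A))
  Z[cbind(seq_len(n), Zidx)] <- 1
  V <- Z %*% A %*% t(Z) * sa2 + diag(n) * se2
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  drop(beta)
}

## D' by direct arithmetic from gamete counts
oracleDprime <- function(nAB, nAb, naB, nab) {
  tot <- nAB + nAb + naB + nab
  pAB <- nAB / tot
  pA <- (nAB + nAb) / tot
  pB <- (nAB + naB) / tot
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
}

## brute-force relative score: enumerate every k-mer, score by direct
## lookup sums, min-max normalise over the enumeration
oracleRelativeScores <- function(pwm) {
  L <- ncol(pwm)
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(expand.grid, rep(list(bases), L))
  raw <- apply(kmers, 1, function(k)
    sum(vapply(seq_len(L), function(j) pwm[k[j], j], numeric(1))))
  names(raw) <- apply(kmers, 1, paste, collapse = "")
  (raw - min(raw)) / (max(raw) - min(raw))
}

## small ACADVL-like default study, cached per session for reuse in tests
cachedStudy <- local({
  env <- new.env()
  function(nSires = 30, seed = 101) {
    key <- paste(nSires, seed)
    if (is.null(env[[key]]))
      env[[key]] <- simulateStudy(simConfig(nSires = nSires, seed = seed))
    env[[key]]
  }
})
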