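## EM haplotype-frequency estimation from unphased genotypes, Lewontin D'
## with likelihood confidence intervals, Gabriel-style block detection and
## per-individual diplotype assignment.

## haplotypes over k biallelic SNPs are coded as integers 1..2^k
## (bit j set = alt allele at SNP j)
.hapBits <- function(id, k) {
  bits <- matrix(0L, length(id), k)
  x <- id - 1L
  for (j in seq_len(k)) {
    bits[, j] <- x %% 2L
    x <- x %/% 2L
  }
  bits
}

.hapId <- function(bits) as.integer(sum(bits * 2L^(seq_along(bits) - 1L))) + 1L

.hapString <- function(id, ref, alt) {
  k <- length(ref)
  bits <- .hapBits(id, k)
  apply(bits, 1, function(b) paste(ifelse(b == 1L, alt, ref), collapse = ""))
}

## all haplotype pairs compatible with one multilocus genotype pattern
## (codes 0/1/2, no missing); first heterozygous site anchors the phase so
## each unordered pair appears once
.compatiblePairs <- function(pattern) {
  k <- length(pattern)
  het <- which(pattern == 1L)
  base <- as.integer(pattern == 2L)
  if (!length(het)) {
    id <- .hapId(base)
    return(matrix(c(id, id), 1L))
  }
  free <- het[-1L]
  combos <- if (length(free)) {
    as.matrix(expand.grid(rep(list(0:1), length(free))))
  } else {
    matrix(integer(0), 1L, 0L)
  }
  out <- matrix(0L, nrow(combos), 2L)
  for (r in seq_len(nrow(combos))) {
    h1 <- base
    h1[het] <- 0L
    h1[free] <- as.integer(combos[r, ])
    h2 <- base
    h2[het] <- 1L
    h2[free] <- 1L - as.integer(combos[r, ])
    out[r, ] <- c(.hapId(h1), .hapId(h2))
  }
  out
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Expectation-maximisation over multilocus genotypes assuming
#' Hardy-Weinberg pairing of haplotypes: the E-step distributes each
#' individual's mass over its phase-compatible haplotype pairs under the
#' current frequencies, the M-step re-estimates frequencies from the
#' expected haplotype counts.  Individuals with a missing genotype at any
#' of the selected SNPs are excluded (complete-case, as in Haploview).
#' Initialisation is the product of single-SNP allele frequencies (linkage
#' equilibrium), which avoids the symmetric saddle point except for
#' exactly symmetric data.  The log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param snps integer indices of the SNPs to phase (default: all; at most
#'   14 so the haplotype space stays enumerable).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-6).
#' @param maxit maximum EM iterations (default 1000).
#' @return named numeric vector of haplotype frequencies (names are allele
#'   strings over the selected SNPs; only haplotypes with nonzero support
#'   are reported), with attributes \code{logLik}, \code{iterations},
#'   \code{converged}, \code{n} (individuals used) and \code{hapId}.
#' @examples
#' cfg <- simConfig(nSires = 20, seed = 7)
#' study <- simulateStudy(cfg)
#' f <- emHaplotypeFreqs(study$genotypes, snps = 1:4)
#' @export
emHaplotypeFreqs <- function(g, snps = NULL, tol = 1e-6, maxit = 1000) {
  stopifnot(is(g, "GenotypeMatrix"))
  snps <- snps %||% seq_len(ncol(g@geno))
  k <- length(snps)
  if (k > 14) stop("at most 14 SNPs can be phased jointly (2^k haplotypes)")
  m <- g@geno[, snps, drop = FALSE]
  cc <- !apply(is.na(m), 1, any)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m)
  if (n == 0) stop("no individuals with complete genotypes at the selected SNPs")

  key <- apply(m, 1, paste, collapse = "")
  tabs <- table(key)
  patterns <- do.call(rbind, lapply(names(tabs),
                                    function(s) as.integer(strsplit(s, "")[[1]])))
  counts <- as.numeric(tabs)
  pairs <- lapply(seq_len(nrow(patterns)), function(r) .compatiblePairs(patterns[r, ]))

  H <- 2L^k
  pAlt <- colMeans(m) / 2
  f <- vapply(seq_len(H), function(id) {
    b <- .hapBits(id, k)[1, ]
    prod(ifelse(b == 1L, pAlt, 1 - pAlt))
  }, numeric(1))
  f <- f / sum(f)

  ll0 <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    hapCount <- numeric(H)
    ll <- 0
    for (r in seq_along(pairs)) {
      pr <- pairs[[r]]
      w <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
      tot <- sum(w)
      if (tot <= 0) {
        w <- rep(1 / length(w), length(w))
        tot <- .Machine$double.xmin
      } else {
        w <- w / tot
      }
      ll <- ll + counts[r] * log(tot)
      inc <- counts[r] * w
      for (p in seq_len(nrow(pr))) {
        hapCount[pr[p, 1L]] <- hapCount[pr[p, 1L]] + inc[p]
        hapCount[pr[p, 2L]] <- hapCount[pr[p, 2L]] + inc[p]
      }
    }
    if (ll < ll0 - 1e-8)
      stop("EM log-likelihood decreased; this should not happen")
    done <- abs(ll - ll0) < tol
    ll0 <- ll
    f <- hapCount / (2 * n)
    if (done) { converged <- TRUE; break }
    if (iter >= maxit) break
  }

  keep <- which(f > 1e-9)
  si <- g@snpInfo[snps, , drop = FALSE]
  out <- f[keep]
  names(out) <- .hapString(keep, si$ref, si$alt)
  ord <- order(out, decreasing = TRUE)
  out <- out[ord]
  structure(out, logLik = ll0, iterations = iter, converged = converged,
            n = n, hapId = keep[ord])
}

## ---------------------------------------------------------------------------
## D' and confidence intervals
## ---------------------------------------------------------------------------

#' Lewontin's D and D' from two-locus haplotype frequencies
#'
#' @param pAB,pAb,paB,pab frequencies of the four gametes for alleles
#'   A/a at locus 1 and B/b at locus 2 (must sum to 1).
#' @return list with \code{D} (coupling disequilibrium \eqn{p_{AB} - p_A
#'   p_B}), \code{Dprime} (D divided by its attainable maximum given the
#'   allele frequencies), and the allele frequencies \code{pA}, \code{pB}.
#' @examples
#' dprimeFromFreqs(0.4, 0.1, 0.1, 0.4)$Dprime  # 0.6
#' @export
dprimeFromFreqs <- function(pAB, pAb, paB, pab) {
  tot <- pAB + pAb + paB + pab
  if (abs(tot - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  pA <- pAB + pAb
  pB <- pAB + paB
  qA <- 1 - pA
  qB <- 1 - pB
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  dp <- if (dmax <= 0) NA_real_ else D / dmax
  list(D = D, Dprime = dp, pA = pA, pB = pB)
}

## likelihood of the 3x3 two-locus genotype table as a function of D'
## (allele frequencies fixed; one-sided 5% tails as in Haploview)
.dprimeCI <- function(tab, pA, pB, step = 0.001) {
  grid <- seq(0, 1, by = step)
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  ## ordered haplotype pairs -> genotype cell (altcount1, altcount2), with
  ## locus alleles: index 1 = "A"/"B" carrying D > 0 in coupling
  h <- function(D) {
    cbind(pA * pB + D,             # AB
          pA * (1 - pB) - D,       # Ab
          (1 - pA) * pB - D,       # aB
          (1 - pA) * (1 - pB) + D) # ab
  }
  hp <- pmax(h(grid * dmax), 0)
  a1 <- c(1, 1, 0, 0)  # count of allele A per gamete
  b1 <- c(1, 0, 1, 0)  # count of allele B per gamete
  ll <- numeric(length(grid))
  probs <- matrix(0, length(grid), 9L)
  for (i in 1:4) for (j in 1:4) {
    cell <- 3L * (a1[i] + a1[j]) + (b1[i] + b1[j]) + 1L
    probs[, cell] <- probs[, cell] + hp[, i] * hp[, j]
  }
  cnt <- as.numeric(tab)  # cells: (gA, gB) with gB fastest, 0..2 each
  ll <- probs
  ll[ll < 1e-300] <- 1e-300
  logl <- log(ll) %*% cnt
  lik <- exp(logl - max(logl))
  lik <- lik / sum(lik)
  cdf <- cumsum(lik)
  lower <- grid[which(cdf >= 0.05)[1L]]
  upper <- grid[which(cdf >= 0.95)[1L]]
  if (is.na(upper)) upper <- 1
  c(lower = lower, upper = upper)
}

#' Pairwise D' between two SNPs with a likelihood confidence interval
#'
#' Two-locus haplotype frequencies come from the EM on the SNP pair; D and
#' D' follow [dprimeFromFreqs()].  The confidence interval on |D'| is
#' computed from the likelihood of the observed 3x3 genotype table over a
#' grid of D' values in [0, 1] (step 0.001) with allele frequencies held
#' at their sample values, taking the one-sided 5% points of the
#' normalised likelihood as bounds (Haploview's method).
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param i,j SNP column indices.
#' @return list with \code{D}, \code{Dprime}, \code{ci} (lower, upper on
#'   |D'|), and \code{n} individuals used; all NA when either SNP is
#'   monomorphic in the complete cases.
#' @export
pairwiseDprime <- function(g, i, j) {
  m <- g@geno[, c(i, j), drop = FALSE]
  cc <- !is.na(m[, 1]) & !is.na(m[, 2])
  m <- m[cc, , drop = FALSE]
  n <- nrow(m)
  mono <- function(x) length(unique(x)) < 2
  if (n == 0 || mono(m[, 1]) || mono(m[, 2]))
    return(list(D = NA_real_, Dprime = NA_real_,
                ci = c(lower = NA_real_, upper = NA_real_), n = n))
  sub <- GenotypeMatrix(m, g@snpInfo[c(i, j), , drop = FALSE])
  f <- emHaplotypeFreqs(sub, tol = 1e-9)
  ids <- attr(f, "hapId")
  ff <- numeric(4)
  ff[ids] <- f  # ids: 1="00", 2="10", 3="01", 4="11" (bit1 = SNP i alt)
  ## alleles: A = alt at locus i, B = alt at locus j
  res <- dprimeFromFreqs(ff[4], ff[2], ff[3], ff[1])
  tab <- table(factor(m[, 1], 0:2), factor(m[, 2], 0:2))
  pA <- res$pA
  pB <- res$pB
  if (!is.na(res$D) && res$D < 0) {
    ## flip locus j coding so the CI grid runs over coupling D >= 0
    tab <- tab[, 3:1]
    pB <- 1 - pB
  }
  ## table cells in row-major (gA, gB): convert to the vector order used
  ## by .dprimeCI (cell = 3*gA + gB + 1)
  cnt <- as.numeric(t(tab))
  ci <- .dprimeCI(cnt, pA, pB)
  list(D = res$D, Dprime = abs(res$Dprime), ci = ci, n = n)
}

#' Pairwise LD over all SNP pairs
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return data.frame with one row per pair (i < j): indices, names, D,
#'   Dprime, ciLower, ciUpper, n.
#' @export
ldMatrix <- function(g) {
  k <- ncol(g@geno)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      r <- pairwiseDprime(g, i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, snpI = g@snpInfo$name[i], snpJ = g@snpInfo$name[j],
        D = r$D, Dprime = r$Dprime, ciLower = unname(r$ci[1]),
        ciUpper = unname(r$ci[2]), n = r$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Gabriel block detection
## ---------------------------------------------------------------------------

#' Detect haplotype blocks by the Gabriel confidence-interval rule
#'
#' A SNP pair is in "strong LD" when the confidence interval on |D'| has
#' lower bound >= \code{ciLower} and upper bound >= \code{ciUpper}; it
#' shows "strong recombination" when the upper bound < \code{recombUpper}.
#' A candidate block (contiguous span of >= 2 SNPs) is accepted when at
#' least \code{informativeFrac} of its informative pairs (strong LD or
#' strong recombination) are strong LD.  Maximal non-overlapping accepted
#' spans are returned in map order, each with EM haplotype frequencies;
#' haplotypes above \code{minHapFreq} are marked retained.  Defaults are
#' the Haploview defaults for the Gabriel et al. rule.
#'
#' @param g a \linkS4class{GenotypeMatrix} with SNPs in map order.
#' @param ld optional precomputed [ldMatrix()] result.
#' @param ciLower,ciUpper strong-LD bounds on the D' CI (0.70, 0.98).
#' @param recombUpper strong-recombination bound (0.90).
#' @param informativeFrac required strong-LD fraction (0.95).
#' @param minHapFreq retention threshold for block haplotypes (0.05).
#' @return list of \linkS4class{HaplotypeBlock} (possibly empty).
#' @export
detectBlocks <- function(g, ld = NULL, ciLower = 0.70, ciUpper = 0.98,
                         recombUpper = 0.90, informativeFrac = 0.95,
                         minHapFreq = 0.05) {
  k <- ncol(g@geno)
  if (k < 2) return(list())
  ld <- ld %||% ldMatrix(g)
  cls <- matrix(NA_character_, k, k)
  for (r in seq_len(nrow(ld))) {
    lab <- if (is.na(ld$ciLower[r])) {
      NA_character_
    } else if (ld$ciLower[r] >= ciLower && ld$ciUpper[r] >= ciUpper) {
      "LD"
    } else if (ld$ciUpper[r] < recombUpper) {
      "REC"
    } else {
      NA_character_
    }
    cls[ld$i[r], ld$j[r]] <- lab
  }
  cand <- list()
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      sub <- cls[a:b, a:b]
      nLD <- sum(sub == "LD", na.rm = TRUE)
      nREC <- sum(sub == "REC", na.rm = TRUE)
      if (nLD + nREC == 0) next
      if (nLD / (nLD + nREC) >= informativeFrac)
        cand[[length(cand) + 1L]] <- c(a, b)
    }
  }
  if (!length(cand)) return(list())
  sizes <- vapply(cand, function(x) x[2] - x[1], numeric(1))
  ord <- order(-sizes, vapply(cand, `[`, numeric(1), 1))
  taken <- logical(k)
  accepted <- list()
  for (idx in ord) {
    span <- cand[[idx]][1]:cand[[idx]][2]
    if (any(taken[span])) next
    taken[span] <- TRUE
    accepted[[length(accepted) + 1L]] <- span
  }
  accepted <- accepted[order(vapply(accepted, min, numeric(1)))]
  lapply(accepted, function(span) {
    f <- emHaplotypeFreqs(g, snps = span)
    new("HaplotypeBlock", snps = as.integer(span),
        snpNames = as.character(g@snpInfo$name[span]),
        haplotypes = names(f), freq = as.numeric(f),
        retained = as.numeric(f) > minHapFreq)
  })
}

#' @rdname HaplotypeBlock-class
#' @export
setMethod("blockSnps", "HaplotypeBlock", function(x) x@snps)

#' @rdname HaplotypeBlock-class
#' @export
setMethod("blockHaplotypes", "HaplotypeBlock", function(x)
  data.frame(label = paste0("H", seq_along(x@haplotypes)),
             haplotype = x@haplotypes, freq = x@freq, retained = x@retained,
             stringsAsFactors = FALSE))

setMethod("show", "HaplotypeBlock", function(object) {
  cat("HaplotypeBlock:", length(object@snps), "SNPs (",
      paste(range(object@snps), collapse = "-"), ")\n")
  df <- blockHaplotypes(object)
  df$freq <- sprintf("%.3f", df$freq)
  print(df, row.names = FALSE)
})

## ---------------------------------------------------------------------------
## Diplotype (haplotype combination) assignment
## ---------------------------------------------------------------------------

#' Assign per-individual haplotype pairs within a block
#'
#' Maximum-a-posteriori haplotype pair for every individual with complete
#' genotypes at the block SNPs, under the block's EM frequencies and
#' Hardy-Weinberg pairing.  Haplotypes below the retention threshold are
#' pooled into a "rare" label; combination labels are sorted so H1H2 and
#' H2H1 coincide.  Exact MAP ties are broken by lexicographic haplotype
#' order and flagged.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param block a \linkS4class{HaplotypeBlock} from [detectBlocks()].
#' @return data.frame: id, hap1, hap2 (allele strings), combination
#'   (e.g. "H1H2"), prob (posterior of the MAP pair), tie (logical).
#'   The attribute \code{"counts"} holds the combination count table.
#' @export
assignDiplotypes <- function(g, block) {
  stopifnot(is(block, "HaplotypeBlock"))
  snps <- block@snps
  k <- length(snps)
  si <- g@snpInfo[snps, , drop = FALSE]
  m <- g@geno[, snps, drop = FALSE]
  cc <- which(!apply(is.na(m), 1, any))
  f <- numeric(2L^k)
  ids <- vapply(block@haplotypes, function(s) {
    alleles <- strsplit(s, "")[[1]]
    .hapId(as.integer(alleles == si$alt))
  }, integer(1))
  f[ids] <- block@freq
  lab <- rep(NA_character_, 2L^k)
  lab[ids] <- ifelse(block@retained, paste0("H", seq_along(ids)), "rare")
  hapStr <- rep(NA_character_, 2L^k)
  hapStr[ids] <- block@haplotypes

  out <- lapply(cc, function(r) {
    pr <- .compatiblePairs(m[r, ])
    w <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
    if (sum(w) <= 0) return(NULL)  # genotype incompatible with block haplotypes
    w <- w / sum(w)
    best <- max(w)
    cand <- which(w >= best - 1e-12)
    tie <- length(cand) > 1L
    if (tie) {
      key <- vapply(cand, function(p)
        paste(sort(c(hapStr[pr[p, 1L]], hapStr[pr[p, 2L]])), collapse = "/"),
        character(1))
      cand <- cand[order(key)]
    }
    p <- cand[1L]
    h <- sort(c(pr[p, 1L], pr[p, 2L]))
    l1 <- lab[h[1L]]
    l2 <- lab[h[2L]]
    if (is.na(l1)) l1 <- "rare"
    if (is.na(l2)) l2 <- "rare"
    combo <- paste(sort(c(l1, l2)), collapse = "")
    data.frame(id = rownames(m)[r],
               hap1 = hapStr[h[1L]] %||% NA_character_,
               hap2 = hapStr[h[2L]] %||% NA_character_,
               combination = combo, prob = best, tie = tie,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id = character(0), hap1 = character(0),
                      hap2 = character(0), combination = character(0),
                      prob = numeric(0), tie = logical(0))
  attr(res, "counts") <- sort(table(res$combination), decreasing = TRUE)
  res
}
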