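## Henderson's mixed-model equations for the animal model
##   y = mu + HYS + b*M + G + a + e,  a ~ N(0, A sigma_a^2), e ~ N(0, I sigma_e^2)
## with variance components supplied by the caller (not estimated), plus
## least-squares means, the genotype Wald F test, and Bonferroni pairwise
## comparisons with compact-letter displays.

#' Precompute the MME design factorisation
#'
#' Builds the pieces of Henderson's coefficient matrix
#' \deqn{C = [X'X, X'Z; Z'X, Z'Z + \lambda A^{-1}]}
#' that depend only on the design: the Cholesky factor of
#' \eqn{M = Z'Z + \lambda A^{-1}}, the absorbed fixed-effect system
#' \eqn{S = X'X - X'Z M^{-1} Z'X} and its inverse (which equals the
#' fixed-effect block of \eqn{C^{-1}}).  Z is the record-to-individual
#' incidence matrix, passed implicitly as an index vector.  Reusing the
#' design across many response vectors (simulation studies) makes each
#' subsequent solve cheap.
#'
#' @param X fixed-effect design matrix (records x p), full column rank.
#' @param indIdx integer vector, for each record the index of its
#'   individual among the rows of \code{Ainv}.
#' @param Ainv inverse of the numerator relationship matrix (all pedigree
#'   individuals).
#' @param lambda variance ratio sigma_e^2 / sigma_a^2.
#' @return list with elements \code{X}, \code{indIdx}, \code{cholM},
#'   \code{W} (\eqn{M^{-1} Z'X}), \code{S}, \code{Sinv}, \code{q}, \code{p}.
#' @seealso [mmeSolve()], [fitAnimalModel()]
#' @param cholM optional precomputed Cholesky factor of
#'   \eqn{Z'Z + \lambda A^{-1}} from an earlier design with the same
#'   records, \code{lambda} and \code{Ainv} (the factor does not depend on
#'   X, so it can be reused while the genotype factor changes).
#' @export
mmeDesign <- function(X, indIdx, Ainv = NULL, lambda, cholM = NULL) {
  q <- if (is.null(cholM)) nrow(Ainv) else nrow(cholM)
  p <- ncol(X)
  stopifnot(length(indIdx) == nrow(X), all(indIdx >= 1L), all(indIdx <= q),
            lambda > 0)
  if (is.null(cholM)) {
    M <- lambda * Ainv
    cnt <- tabulate(indIdx, q)
    diag(M) <- diag(M) + cnt
    cholM <- chol(M)
  }
  ZtX <- matrix(0, q, p)
  sums <- rowsum(X, group = indIdx)
  ZtX[as.integer(rownames(sums)), ] <- sums
  colnames(ZtX) <- colnames(X)
  W <- backsolve(cholM, backsolve(cholM, ZtX, transpose = TRUE))
  S <- crossprod(X) - crossprod(ZtX, W)
  Sinv <- chol2inv(chol(S))
  dimnames(Sinv) <- list(colnames(X), colnames(X))
  list(X = X, indIdx = indIdx, cholM = cholM, ZtX = ZtX, W = W,
       S = S, Sinv = Sinv, q = q, p = p, lambda = lambda)
}

#' Solve the MME for one response vector
#'
#' @param design a design factorisation from [mmeDesign()].
#' @param y numeric response, one entry per record.
#' @return list with \code{beta} (fixed-effect solutions), \code{u}
#'   (additive-effect BLUPs for all individuals) and \code{Cxx} (the
#'   fixed-effect block of the inverse coefficient matrix; multiply by
#'   sigma_e^2 for the sampling covariance of \code{beta}).
#' @export
mmeSolve <- function(design, y) {
  stopifnot(length(y) == nrow(design$X))
  Xty <- crossprod(design$X, y)
  Zty <- numeric(design$q)
  sums <- rowsum(y, group = design$indIdx)
  Zty[as.integer(rownames(sums))] <- sums
  beta <- design$Sinv %*% (Xty - crossprod(design$W, Zty))
  r <- Zty - design$ZtX %*% beta
  u <- backsolve(design$cholM, backsolve(design$cholM, r, transpose = TRUE))
  list(beta = setNames(as.numeric(beta), colnames(design$X)),
       u = as.numeric(u), Cxx = design$Sinv)
}

## merge herd-year-season cells with fewer than minCell records
.hysFactor <- function(records, minCell) {
  hys <- interaction(records$herd, records$year, records$season,
                     drop = TRUE, sep = ":")
  small <- names(which(table(hys) < minCell))
  if (length(small)) {
    warning(length(small), " HYS cell(s) below ", minCell,
            " records merged into a pooled cell")
    lv <- levels(hys)
    lv[lv %in% small] <- "pooled"
    levels(hys) <- lv
  }
  droplevels(hys)
}

#' Fit the animal model for one trait, lactation and genotype factor
#'
#' Solves Henderson's mixed-model equations for
#' \deqn{y = \mu + HYS + b M + G + a + e}
#' with \eqn{a \sim N(0, A\sigma_a^2)} and \eqn{e \sim N(0, I\sigma_e^2)},
#' where HYS is the herd-year-season cross-classification, M the calving
#' month-age covariate and G the genotype (or haplotype-combination)
#' factor.  Variance components are inputs; when \code{sigmaA2 = 0} the
#' model degrades to ordinary least squares on the fixed design.
#' Least-squares means average HYS levels with equal weight and evaluate
#' the covariate at its mean; their standard errors come from the inverse
#' coefficient matrix.  The overall genotype test is a Wald F with
#' numerator df = classes - 1 and denominator df = N - rank(X) (residual
#' method); pairwise LSM contrasts are t tests with Bonferroni adjustment
#' over the pairs within this SNP x trait x lactation cell, summarised as
#' compact-letter displays at each alpha level.
#'
#' @param pheno phenotype data.frame with columns \code{cow_id},
#'   \code{lactation}, \code{herd}, \code{year}, \code{season},
#'   \code{month_age} and the trait columns.
#' @param classes named character vector: genotype class per cow id (NA
#'   drops the cow).
#' @param A numerator relationship matrix from [buildA()] covering every
#'   phenotyped cow (rownames = ids).
#' @param vc list with \code{sigmaA2} and \code{sigmaE2} for this trait.
#' @param trait name of the trait column to analyse.
#' @param lactation which lactation's records to use (1 or 2).
#' @param minCell HYS cells below this size are pooled (default 3).
#' @param alpha significance levels for the letter displays.
#' @param Ainv optional precomputed \code{solve(A)}.
#' @param cholM optional precomputed Cholesky factor passed to
#'   [mmeDesign()] (reusable across fits that share records and variance
#'   ratio while the genotype factor changes).
#' @param design optional precomputed [mmeDesign()] (advanced; must match
#'   the records and factor coding this call would build).
#' @return an \linkS4class{AnimalModelFit}.
#' @export
fitAnimalModel <- function(pheno, classes, A, vc, trait, lactation = 1,
                           minCell = 3, alpha = c(0.05, 0.01), Ainv = NULL,
                           cholM = NULL, design = NULL) {
  stopifnot(trait %in% names(pheno), !is.null(names(classes)))
  rec <- pheno[pheno$lactation == lactation, , drop = FALSE]
  rec$G <- unname(classes[as.character(rec$cow_id)])
  rec <- rec[!is.na(rec$G) & !is.na(rec[[trait]]), , drop = FALSE]
  if (!nrow(rec)) stop("no usable records for trait ", trait,
                       ", lactation ", lactation)
  rec$G <- factor(rec$G)
  if (nlevels(rec$G) < 1) stop("genotype factor has no classes")
  nG <- table(rec$G)
  if (any(nG == 1))
    message("genotype class(es) with a single record retained: ",
            paste(names(nG)[nG == 1], collapse = ", "))
  hys <- .hysFactor(rec, minCell)
  M <- rec$month_age
  y <- rec[[trait]]

  ## drop degenerate terms: a single HYS cell or a constant covariate
  terms <- c(if (nlevels(hys) > 1) "hys",
             if (length(unique(M)) > 1) "M",
             if (nlevels(rec$G) > 1) "G")
  form <- stats::reformulate(if (length(terms)) terms else "1")
  X <- stats::model.matrix(form, data = data.frame(hys = hys, M = M,
                                                   G = rec$G))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is singular; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  sigmaA2 <- vc$sigmaA2
  sigmaE2 <- vc$sigmaE2
  stopifnot(sigmaA2 >= 0, sigmaE2 > 0)

  if (sigmaA2 > 0) {
    idx <- match(as.character(rec$cow_id), rownames(A))
    if (anyNA(idx))
      stop("cow id(s) missing from the relationship matrix: ",
           paste(unique(rec$cow_id[is.na(idx)]), collapse = ", "))
    lambda <- sigmaE2 / sigmaA2
    if (is.null(design)) {
      if (is.null(cholM)) Ainv <- Ainv %||% chol2inv(chol(A))
      design <- mmeDesign(X, idx, Ainv, lambda, cholM = cholM)
    }
    sol <- mmeSolve(design, y)
    beta <- sol$beta
    u <- setNames(sol$u, rownames(A))
    Cxx <- sol$Cxx
  } else {
    lambda <- Inf
    XtXinv <- chol2inv(chol(crossprod(X)))
    dimnames(XtXinv) <- list(colnames(X), colnames(X))
    beta <- setNames(as.numeric(XtXinv %*% crossprod(X, y)), colnames(X))
    u <- numeric(0)
    Cxx <- XtXinv
  }

  ## least-squares means: equal HYS weights, covariate at its mean
  gLev <- levels(rec$G)
  L <- matrix(0, length(gLev), ncol(X), dimnames = list(gLev, colnames(X)))
  L[, "(Intercept)"] <- 1
  hysCols <- grep("^hys", colnames(X), value = TRUE)
  L[, hysCols] <- 1 / nlevels(hys)
  if ("M" %in% colnames(X)) L[, "M"] <- mean(M)
  if (nlevels(rec$G) > 1)
    for (g in gLev[-1]) L[g, paste0("G", g)] <- 1
  lsm <- as.numeric(L %*% beta)
  vcovLsm <- L %*% Cxx %*% t(L) * sigmaE2
  lsmDf <- data.frame(class = gLev, n = as.integer(nG[gLev]), lsm = lsm,
                      se = sqrt(diag(vcovLsm)), stringsAsFactors = FALSE)

  dfDen <- nrow(rec) - qrX$rank
  gCols <- paste0("G", gLev[-1])
  overall <- if (length(gLev) >= 2) {
    bG <- beta[gCols]
    VG <- Cxx[gCols, gCols, drop = FALSE] * sigmaE2
    Fstat <- as.numeric(crossprod(bG, solve(VG, bG))) / length(bG)
    list(F = Fstat, df1 = length(bG), df2 = dfDen,
         p = pf(Fstat, length(bG), dfDen, lower.tail = FALSE))
  } else {
    list(F = NA_real_, df1 = NA_integer_, df2 = dfDen, p = NA_real_)
  }

  ## pairwise LSM contrasts, Bonferroni within this SNP x trait x lactation
  pairs <- if (length(gLev) >= 2) t(utils::combn(seq_along(gLev), 2)) else
    matrix(integer(0), 0, 2)
  nPairs <- nrow(pairs)
  pw <- data.frame(class1 = character(0), class2 = character(0),
                   diff = numeric(0), se = numeric(0), t = numeric(0),
                   p = numeric(0), pAdj = numeric(0))
  if (nPairs) {
    d <- lsm[pairs[, 1]] - lsm[pairs[, 2]]
    v <- diag(vcovLsm)[pairs[, 1]] + diag(vcovLsm)[pairs[, 2]] -
      2 * vcovLsm[pairs]
    se <- sqrt(pmax(v, 0))
    tval <- ifelse(se > 0, d / se, 0)
    praw <- 2 * pt(-abs(tval), dfDen)
    pw <- data.frame(class1 = gLev[pairs[, 1]], class2 = gLev[pairs[, 2]],
                     diff = d, se = se, t = tval, p = praw,
                     pAdj = pmin(1, praw * nPairs), stringsAsFactors = FALSE)
  }

  letters <- lapply(alpha, function(a) {
    sig <- pw[pw$pAdj < a, c("class1", "class2"), drop = FALSE]
    compactLetters(gLev, sig)
  })
  names(letters) <- paste0("alpha", alpha)
  lsmDf$letters <- if (length(letters)) {
    apply(do.call(cbind, lapply(seq_along(letters), function(i) {
      l <- letters[[i]][lsmDf$class]
      if (i > 1) toupper(l) else l
    })), 1, paste, collapse = "/")
  } else ""

  new("AnimalModelFit", beta = beta, u = u, lsm = lsmDf, vcovLsm = vcovLsm,
      overall = overall, pairwise = pw, letters = letters,
      sigmaE2 = sigmaE2, lambda = lambda, nObs = nrow(rec),
      rankX = as.integer(qrX$rank),
      meta = list(trait = trait, lactation = lactation))
}

#' @rdname AnimalModelFit-class
#' @export
setMethod("lsMeans", "AnimalModelFit", function(fit) fit@lsm)

#' Overall genotype-effect test of a fitted animal model
#'
#' @param fit an \linkS4class{AnimalModelFit}.
#' @return the p value of the Wald F test that all genotype-class effects
#'   are equal (NA with fewer than two classes).
#' @export
testGenotypeEffect <- function(fit) {
  stopifnot(is(fit, "AnimalModelFit"))
  fit@overall$p
}

#' Compact-letter displays of the pairwise comparisons
#'
#' @param fit an \linkS4class{AnimalModelFit}.
#' @param alpha significance levels (default the levels stored in the fit).
#' @return named list of letter vectors, one per alpha level; classes
#'   sharing a letter are not significantly different after Bonferroni
#'   adjustment.
#' @export
pairwiseLetters <- function(fit, alpha = NULL) {
  stopifnot(is(fit, "AnimalModelFit"))
  if (is.null(alpha)) return(fit@letters)
  pw <- fit@pairwise
  out <- lapply(alpha, function(a)
    compactLetters(fit@lsm$class, pw[pw$pAdj < a, c("class1", "class2")]))
  names(out) <- paste0("alpha", alpha)
  out
}

#' Compact-letter display by insert-and-absorb
#'
#' Builds the letter display from a set of significantly different pairs:
#' starting from one group holding all classes, each significant pair
#' splits every group containing both members, and groups that become
#' subsets of another are absorbed.  Classes sharing a letter are not
#' significantly different.  The result is independent of the order in
#' which pairs are processed and of class labelling.
#'
#' @param classes character vector of class labels.
#' @param sigPairs two-column data.frame (or matrix) of significantly
#'   different label pairs.
#' @return named character vector of letter strings, one per class.
#' @examples
#' compactLetters(c("CC", "CT", "TT"), data.frame(a = "CC", b = "TT"))
#' @export
compactLetters <- function(classes, sigPairs) {
  groups <- list(classes)
  sigPairs <- as.data.frame(sigPairs, stringsAsFactors = FALSE)
  if (nrow(sigPairs)) {
    ord <- order(match(sigPairs[[1]], classes), match(sigPairs[[2]], classes))
    for (r in ord) {
      a <- sigPairs[[1]][r]
      b <- sigPairs[[2]][r]
      newGroups <- list()
      for (grp in groups) {
        if (a %in% grp && b %in% grp) {
          newGroups <- c(newGroups, list(setdiff(grp, a)), list(setdiff(grp, b)))
        } else {
          newGroups <- c(newGroups, list(grp))
        }
      }
      ## absorb subsets
      keep <- rep(TRUE, length(newGroups))
      for (i in seq_along(newGroups)) {
        for (j in seq_along(newGroups)) {
          if (i != j && keep[j] &&
              all(newGroups[[i]] %in% newGroups[[j]]) &&
              (length(newGroups[[i]]) < length(newGroups[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      groups <- newGroups[keep]
    }
  }
  ## stable order: by first member's position among the classes
  first <- vapply(groups, function(g) min(match(g, classes)), numeric(1))
  groups <- groups[order(first)]
  out <- setNames(rep("", length(classes)), classes)
  for (i in seq_along(groups)) {
    mem <- classes %in% groups[[i]]
    out[mem] <- paste0(out[mem], letters[i])
  }
  out
}

setMethod("show", "AnimalModelFit", function(object) {
  cat(sprintf("AnimalModelFit: trait %s, lactation %s (n = %d records)\n",
              object@meta$trait, object@meta$lactation, object@nObs))
  df <- object@lsm
  df$lsm <- sprintf("%.2f", df$lsm)
  df$se <- sprintf("%.3f", df$se)
  print(df, row.names = FALSE)
  cat(sprintf("genotype effect: F(%d, %d) = %.3f, p = %.4g\n",
              object@overall$df1, object@overall$df2,
              object@overall$F, object@overall$p))
})
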