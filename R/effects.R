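## Decomposition of genotype-class least-squares means into additive,
## dominance and allele-substitution effects.

#' Additive, dominance and allele-substitution effects from genotype LSMs
#'
#' For genotype classes AA, AB, BB (A the caller-designated first allele)
#' the effects are
#' \deqn{a = (AA - BB)/2, \quad d = AB - (AA + BB)/2, \quad
#'       \alpha = a + d(q - p)}
#' with p the frequency of allele A and q = 1 - p.  When the heterozygote
#' LSM is missing, a is still computed and d and alpha are NA.  Standard
#' errors come from the delta method on the LSM covariance (the three
#' effects are linear in the LSMs), with p treated as fixed.
#'
#' @param lsmAA,lsmAB,lsmBB least-squares means of the three genotype
#'   classes (trait units); \code{lsmAB} may be NA.
#' @param p frequency of allele A in the analysed sample (0 < p < 1).
#' @param vcov optional 3 x 3 covariance matrix of (lsmAA, lsmAB, lsmBB);
#'   rows/columns for a missing heterozygote may be NA.
#' @param df degrees of freedom for the t-based p values (default Inf,
#'   i.e. normal).
#' @return one-row data.frame: a, d, alpha, seA, seD, seAlpha, pA, pD,
#'   pAlpha.
#' @examples
#' computeEffects(311.33, 304.66, 301.73, p = 0.27)  # a = 4.80, d = -1.87
#' @export
computeEffects <- function(lsmAA, lsmAB, lsmBB, p, vcov = NULL, df = Inf) {
  stopifnot(p > 0, p < 1)
  q <- 1 - p
  a <- (lsmAA - lsmBB) / 2
  d <- if (is.na(lsmAB)) NA_real_ else lsmAB - (lsmAA + lsmBB) / 2
  alpha <- if (is.na(d)) NA_real_ else a + d * (q - p)
  la <- c(0.5, 0, -0.5)
  ld <- c(-0.5, 1, -0.5)
  lal <- la + (q - p) * ld
  seOf <- function(l) {
    if (is.null(vcov)) return(NA_real_)
    v <- as.numeric(t(l) %*% vcov %*% l)
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }
  seA <- seOf(la)
  seD <- if (is.na(d)) NA_real_ else seOf(ld)
  seAlpha <- if (is.na(alpha)) NA_real_ else seOf(lal)
  pv <- function(est, se) {
    if (is.na(est) || is.na(se) || se <= 0) return(NA_real_)
    2 * pt(-abs(est / se), df)
  }
  data.frame(a = a, d = d, alpha = alpha, seA = seA, seD = seD,
             seAlpha = seAlpha, pA = pv(a, seA), pD = pv(d, seD),
             pAlpha = pv(alpha, seAlpha))
}

#' Genetic effects from a fitted animal model
#'
#' Convenience wrapper mapping the LSMs of a three-class genotype fit onto
#' [computeEffects()].  Allele A is the allele whose homozygote is given
#' first in \code{classes}; its sample frequency defaults to the
#' frequency implied by the class sizes of the fit.
#'
#' @param fit an \linkS4class{AnimalModelFit} with genotype classes.
#' @param classes character of length 3: the class labels of (AA, AB, BB)
#'   in that order.
#' @param p optional frequency of allele A; default: computed from the
#'   fit's class counts as f(AA) + f(AB)/2.
#' @return one-row data.frame as in [computeEffects()].
#' @export
geneticEffects <- function(fit, classes, p = NULL) {
  stopifnot(is(fit, "AnimalModelFit"), length(classes) == 3)
  lsm <- fit@lsm
  idx <- match(classes, lsm$class)
  if (is.na(idx[1]) || is.na(idx[3]))
    stop("both homozygote classes must be present in the fit")
  if (is.null(p)) {
    n <- lsm$n[idx]
    n[is.na(n)] <- 0
    p <- (n[1] + n[2] / 2) / sum(n)
  }
  getLsm <- function(k) if (is.na(idx[k])) NA_real_ else lsm$lsm[idx[k]]
  v <- matrix(NA_real_, 3, 3)
  ok <- !is.na(idx)
  v[ok, ok] <- fit@vcovLsm[idx[ok], idx[ok]]
  computeEffects(getLsm(1), getLsm(2), getLsm(3), p = p, vcov = v,
                 df = fit@overall$df2)
}
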