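#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

#' @rdname GenotypeMatrix-class
#' @param x a \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname Pedigree-class
#' @param x a \linkS4class{Pedigree}.
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname AnimalModelFit-class
#' @param fit an \linkS4class{AnimalModelFit}.
#' @export
setGeneric("lsMeans", function(fit) standardGeneric("lsMeans"))

#' @rdname HaplotypeBlock-class
#' @param x a \linkS4class{HaplotypeBlock}.
#' @export
setGeneric("blockSnps", function(x) standardGeneric("blockSnps"))

#' @rdname HaplotypeBlock-class
#' @export
setGeneric("blockHaplotypes", function(x) standardGeneric("blockHaplotypes"))
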