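#' Half-maximal dose of a fitted curve
#'
#' @param object a \linkS4class{FourPLFit}.
#' @return EC50 in dose units (\code{10^log10Ec50}).
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' Number of objects passing the area filter
#' @param object an \linkS4class{OrganoidSegmentation}.
#' @export
setGeneric("organoidCount", function(object) standardGeneric("organoidCount"))

#' Total area (um^2) of objects passing the area filter
#' @param object an \linkS4class{OrganoidSegmentation}.
#' @export
setGeneric("totalAreaUm2", function(object) standardGeneric("totalAreaUm2"))

#' Per-object areas in um^2
#' @param object an \linkS4class{OrganoidSegmentation}.
#' @export
setGeneric("objectAreas", function(object) standardGeneric("objectAreas"))

#' Normalization state of an expression container
#' @param object an \linkS4class{ExpressionExperiment}.
#' @return one of \code{"raw"}, \code{"log2"}, \code{"log2_quantile"}.
#' @export
setGeneric("exprsScale", function(object) standardGeneric("exprsScale"))

#' Genes of a signature
#' @param object a \linkS4class{GeneSignature}.
#' @export
setGeneric("signatureGenes",
    function(object) standardGeneric("signatureGenes"))

#' Ranked entries of a correlation ranking
#' @param object a \linkS4class{CorrelationRanking}.
#' @export
setGeneric("rankedEntries", function(object) standardGeneric("rankedEntries"))
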