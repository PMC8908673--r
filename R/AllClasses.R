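#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Expression matrix container with a normalization-state flag
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' genes-by-samples assay (\code{"exprs"}) plus a \code{scale} flag recording
#' whether values are raw intensities, log2, or log2 quantile-normalized.
#' The flag gates the normalization operations: \code{\link{log2QuantileNormalize}}
#' refuses already-normalized input, and the Z-score/classification steps
#' require a log scale.
#'
#' @slot scale character, one of \code{"raw"}, \code{"log2"},
#'   \code{"log2_quantile"}.
#' @export
setClass("ExpressionExperiment",
    contains = "SummarizedExperiment",
    slots = c(scale = "character"))

setValidity("ExpressionExperiment", function(object) {
    msg <- NULL
    if (length(object@scale) != 1L ||
        !object@scale %in% c("raw", "log2", "log2_quantile"))
        msg <- c(msg, "scale must be one of 'raw', 'log2', 'log2_quantile'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (is.null(msg)) TRUE else msg
})

#' Named gene set
#'
#' @slot name signature name (e.g. \code{"BASAL"}).
#' @slot genes character vector of unique gene ids.
#' @export
setClass("GeneSignature",
    slots = c(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "signature must contain at least one gene")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "signature genes must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Ranking of genes by Pearson correlation with a per-sample score
#'
#' @slot entries data.frame with columns \code{gene_id}, \code{r},
#'   \code{rank}, sorted by \code{r} descending (ties by gene id ascending).
#' @slot scoreName name of the score the genes were correlated against.
#' @slot nExcluded number of genes dropped because their correlation is
#'   undefined (zero variance) or they contain missing values.
#' @export
setClass("CorrelationRanking",
    slots = c(entries = "data.frame", scoreName = "character",
              nExcluded = "integer"))

setValidity("CorrelationRanking", function(object) {
    e <- object@entries
    msg <- NULL
    if (!all(c("gene_id", "r", "rank") %in% names(e)))
        msg <- c(msg, "entries needs columns gene_id, r, rank")
    else {
        if (nrow(e) && (is.unsorted(rev(e$r)) && any(diff(e$r) > 1e-15)))
            msg <- c(msg, "entries must be sorted by r descending")
        if (nrow(e) && max(abs(e$r)) > 1 + 1e-12)
            msg <- c(msg, "|r| must be <= 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Four-parameter logistic dose-response fit
#'
#' Parameters of the curve
#' \deqn{r(d) = bottom + (top - bottom) / (1 + 10^{((log10EC50 - log10 d) \cdot hill)})}
#' fitted by minimizing a soft-L1 (smooth robust) loss.
#'
#' @slot bottom,top response asymptotes (\%), \code{top >= bottom}.
#' @slot log10Ec50 log10 of the half-maximal dose, in log10 dose units.
#' @slot hillSlope Hill slope; sign encodes curve direction.
#' @slot loss robust loss at the optimum.
#' @slot converged logical, optimizer convergence.
#' @slot hillIdentifiable logical; \code{FALSE} for flat (degenerate) data.
#' @slot nPoints number of data points fitted.
#' @export
setClass("FourPLFit",
    slots = c(bottom = "numeric", top = "numeric", log10Ec50 = "numeric",
              hillSlope = "numeric", loss = "numeric", converged = "logical",
              hillIdentifiable = "logical", nPoints = "integer"))

setValidity("FourPLFit", function(object) {
    if (object@top < object@bottom - 1e-9)
        "top must be >= bottom" else TRUE
})

#' Labeled organoid segmentation with calibrated areas
#'
#' @slot labels integer label matrix (0 = background), 8-connected objects.
#' @slot areasUm2 per-object areas in square micrometers, named by label.
#' @slot umPerPixel image calibration (micrometers per pixel).
#' @slot thresholdUm2 minimum area applied; objects below it were removed.
#'   \code{0} means no filter applied yet.
#' @slot borderTouching logical per object: touches the image border
#'   (retained, but flagged).
#' @export
setClass("OrganoidSegmentation",
    slots = c(labels = "matrix", areasUm2 = "numeric", umPerPixel = "numeric",
              thresholdUm2 = "numeric", borderTouching = "logical"))

setValidity("OrganoidSegmentation", function(object) {
    msg <- NULL
    if (object@umPerPixel <= 0) msg <- c(msg, "umPerPixel must be > 0")
    if (length(object@areasUm2) != length(object@borderTouching))
        msg <- c(msg, "areasUm2 and borderTouching lengths differ")
    if (is.null(msg)) TRUE else msg
})

#' Scenario configuration for the study simulator
#'
#' Captures the designed truth of an 8-organoid niche-dependency study:
#' which samples exist, their differentiation grades and designed niche
#' scores, how signature and mevalonate-pathway genes are coupled to the
#' design, expected growth per grade and medium, 4PL drug-potency truths,
#' image object layouts, and qPCR Ct means. Every generator consumes this
#' object and a seed; the same configuration and seed reproduce identical
#' outputs.
#'
#' @slot seed integer base seed.
#' @slot samples data.frame: \code{sample_id}, \code{grade} (1/2/3),
#'   \code{niche_score} (> 0), \code{subtype} (designed expression subtype,
#'   \code{"Classical"}/\code{"Basal-like"}).
#' @slot nBackgroundGenes number of unstructured background genes.
#' @slot signatureSizes named integer: \code{basal}, \code{classical},
#'   \code{mevalonate} set sizes.
#' @slot signatureEffect log2 shift added to a signature gene in samples of
#'   its designed subtype.
#' @slot mevalonateSlope log2 expression increase per unit designed niche
#'   score for mevalonate genes.
#' @slot exprNoiseSd gene-level log2 Gaussian noise SD.
#' @slot mevalonateNoiseSd noise SD for mevalonate genes (\code{NA} = use
#'   \code{exprNoiseSd}).
#' @slot growth data.frame: \code{grade}, \code{medium}, \code{fold}
#'   (expected day-10/day-0 fold change) and \code{cv} (lognormal replicate CV).
#' @slot dropout data.frame: \code{grade}, \code{factor}, \code{multiplier}
#'   applied to the niche-medium fold when the factor is withdrawn.
#' @slot seedingCells cells seeded per well at day 0.
#' @slot blankLum medium-only baseline luminescence.
#' @slot perCellSignal luminescence units per cell.
#' @slot nReplicates day-10 replicate wells per condition (triplicate wells
#'   times independent repeats, treated as exchangeable).
#' @slot drugs data.frame of 4PL truths: \code{drug}, \code{sample_id},
#'   \code{bottom}, \code{top}, \code{ec50}, \code{hill}, \code{dose_unit}.
#' @slot doseGrids named list of strictly increasing positive dose grids,
#'   one per drug.
#' @slot doseCV multiplicative (lognormal) replicate CV of responses.
#' @slot doseReplicates replicates per dose.
#' @slot imageObjects data.frame: \code{image_id}, \code{area_um2} of the
#'   bright ellipses drawn per organoid image.
#' @slot umPerPixel image calibration for generated images.
#' @slot imageSize image side length in pixels.
#' @slot stainFractions data.frame: \code{grade}, \code{fraction} -- designed
#'   stain-positive area fraction per grade (percent).
#' @slot qpcr data.frame: \code{gene}, \code{condition}, \code{ct_mean},
#'   \code{ct_sd}; must include the reference gene in every condition.
#' @slot qpcrReplicates qPCR replicates per gene and condition.
#' @export
setClass("ScenarioConfig",
    slots = c(seed = "integer", samples = "data.frame",
              nBackgroundGenes = "integer", signatureSizes = "integer",
              signatureEffect = "numeric", mevalonateSlope = "numeric",
              exprNoiseSd = "numeric", mevalonateNoiseSd = "numeric",
              growth = "data.frame", dropout = "data.frame",
              seedingCells = "numeric", blankLum = "numeric",
              perCellSignal = "numeric", nReplicates = "integer",
              drugs = "data.frame", doseGrids = "list", doseCV = "numeric",
              doseReplicates = "integer",
              imageObjects = "data.frame", umPerPixel = "numeric",
              imageSize = "integer", stainFractions = "data.frame",
              qpcr = "data.frame", qpcrReplicates = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- NULL
    s <- object@samples
    if (!all(c("sample_id", "grade", "niche_score", "subtype") %in% names(s)))
        msg <- c(msg, "samples needs sample_id, grade, niche_score, subtype")
    else {
        if (anyDuplicated(s$sample_id)) msg <- c(msg, "duplicate sample ids")
        if (!all(s$grade %in% 1:3)) msg <- c(msg, "grades must be 1, 2 or 3")
        if (any(s$niche_score <= 0))
            msg <- c(msg, "designed niche scores must be > 0")
        if (!all(s$subtype %in% c("Classical", "Basal-like")))
            msg <- c(msg, "subtype must be Classical or Basal-like")
    }
    if (!all(c("basal", "classical", "mevalonate") %in%
             names(object@signatureSizes)))
        msg <- c(msg, "signatureSizes needs basal, classical, mevalonate")
    for (nm in names(object@doseGrids)) {
        g <- object@doseGrids[[nm]]
        if (any(g <= 0) || is.unsorted(g, strictly = TRUE))
            msg <- c(msg, sprintf(
                "dose grid for '%s' must be strictly increasing and positive",
                nm))
    }
    if (object@exprNoiseSd < 0 || object@doseCV < 0)
        msg <- c(msg, "noise parameters must be >= 0")
    if (is.null(msg)) TRUE else msg
})
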