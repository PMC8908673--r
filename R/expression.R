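#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats sd cor median
NULL

#' Construct an ExpressionExperiment
#'
#' @param values genes-by-samples numeric matrix with row and column names.
#' @param scale normalization state: \code{"raw"}, \code{"log2"} or
#'   \code{"log2_quantile"}.
#' @param colData optional per-sample annotation.
#' @return an \linkS4class{ExpressionExperiment}.
#' @examples
#' m <- matrix(2^rnorm(20, 8), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' ExpressionExperiment(m)
#' @export
ExpressionExperiment <- function(values, scale = "raw", colData = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix needs gene (row) and sample (column) names")
    se <- if (is.null(colData))
        SummarizedExperiment(assays = list(exprs = values))
    else SummarizedExperiment(assays = list(exprs = values),
                              colData = colData)
    new("ExpressionExperiment", se, scale = scale)
}

#' @describeIn ExpressionExperiment expression values (genes x samples).
#' @param x an \linkS4class{ExpressionExperiment}.
#' @export
exprs <- function(x) assay(x, "exprs")

#' @rdname exprsScale
#' @export
setMethod("exprsScale", "ExpressionExperiment", function(object) object@scale)

setMethod("show", "ExpressionExperiment", function(object) {
    cat(sprintf("ExpressionExperiment: %d genes x %d samples [scale: %s]\n",
                nrow(object), ncol(object), object@scale))
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param genes character vector of gene ids.
#' @return a \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(name, genes) {
    new("GeneSignature", name = name, genes = as.character(genes))
}

#' @rdname signatureGenes
#' @export
setMethod("signatureGenes", "GeneSignature", function(object) object@genes)

setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature '%s': %d genes\n", object@name,
                length(object@genes)))
})

#' Log2-transform and quantile-normalize a raw expression matrix
#'
#' Raw intensities are log2-transformed, then every sample (column) is
#' mapped onto the common reference distribution -- the mean of the sorted
#' columns -- so that after normalization each column holds the identical
#' sorted multiset of values. Tied values receive the mean of the reference
#' values at the ranks they occupy. The quantile step delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param m an \linkS4class{ExpressionExperiment} with scale \code{"raw"}
#'   and strictly positive values.
#' @return an \linkS4class{ExpressionExperiment} with scale
#'   \code{"log2_quantile"}; gene and sample ids preserved.
#' @examples
#' m <- ExpressionExperiment(matrix(c(4, 16, 16, 4), 2, 2,
#'     dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' exprs(log2QuantileNormalize(m))
#' @export
log2QuantileNormalize <- function(m) {
    stopifnot(is(m, "ExpressionExperiment"))
    if (exprsScale(m) != "raw")
        stop("input is already on scale '", exprsScale(m),
             "'; log2QuantileNormalize expects raw intensities")
    v <- exprs(m)
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "nonpositive intensity at gene '%s', sample '%s' (%g)",
            rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]],
            v[bad[1, 1], bad[1, 2]]))
    lg <- log2(v)
    q <- limma::normalizeQuantiles(lg, ties = TRUE)
    dimnames(q) <- dimnames(v)
    ExpressionExperiment(q, scale = "log2_quantile",
                         colData = colData(m))
}

#' Per-gene Z-scores across samples
#'
#' Centers and scales each gene across samples using the sample SD
#' (n - 1 denominator). Zero-variance genes yield an all-zero row and a
#' warning; their ids are attached as \code{attr(z, "zeroVarianceGenes")}.
#'
#' @param m an \linkS4class{ExpressionExperiment} on a log scale
#'   (\code{"log2"} or \code{"log2_quantile"}), with at least two samples.
#' @return numeric matrix of Z-scores with the input's dimnames.
#' @export
zscoreByGene <- function(m) {
    stopifnot(is(m, "ExpressionExperiment"))
    if (!exprsScale(m) %in% c("log2", "log2_quantile"))
        stop("zscoreByGene expects log2 or log2_quantile scale, got '",
             exprsScale(m), "'")
    v <- exprs(m)
    if (ncol(v) < 2L) stop("need at least 2 samples")
    mu <- rowMeans(v)
    s <- apply(v, 1L, sd)
    zeroVar <- s == 0 | is.na(s)
    s[zeroVar] <- 1
    z <- (v - mu) / s
    z[zeroVar, ] <- 0
    if (any(zeroVar)) {
        warning(sum(zeroVar), " zero-variance gene(s) set to Z = 0")
        attr(z, "zeroVarianceGenes") <- rownames(v)[zeroVar]
    }
    z
}

#' Classical/Basal-like subtype scores from signature Z-score sums
#'
#' For every sample, sums the per-gene Z-scores of the Basal-like and
#' Classical signature genes present in the matrix. The total score is the
#' Basal-like sum minus the Classical sum; samples with total score >= 0
#' are labeled \code{"Basal-like"}, otherwise \code{"Classical"}. Signature
#' genes missing from the matrix are dropped and recorded.
#'
#' @param m an \linkS4class{ExpressionExperiment} on a log scale.
#' @param basal,classical \linkS4class{GeneSignature}s.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{z_basal_sum}, \code{z_classical_sum}, \code{total_score},
#'   \code{label}, \code{n_basal_used}, \code{n_classical_used}; missing
#'   gene ids in \code{attr(, "missingGenes")}.
#' @examples
#' v <- matrix(c(1, 2, 5, 8, 3, 6, 1, 2), 4, 2,
#'     dimnames = list(c("b1", "b2", "c1", "c2"), c("s1", "s2")))
#' moffittClassify(ExpressionExperiment(v, scale = "log2"),
#'     GeneSignature("BASAL", c("b1", "b2")),
#'     GeneSignature("CLASSICAL", c("c1", "c2")))
#' @export
moffittClassify <- function(m, basal, classical) {
    stopifnot(is(basal, "GeneSignature"), is(classical, "GeneSignature"))
    z <- suppressWarnings(zscoreByGene(m))
    useB <- intersect(signatureGenes(basal), rownames(z))
    useC <- intersect(signatureGenes(classical), rownames(z))
    if (!length(useB))
        stop("no genes of signature '", basal@name, "' found in the matrix")
    if (!length(useC))
        stop("no genes of signature '", classical@name,
             "' found in the matrix")
    zb <- colSums(z[useB, , drop = FALSE])
    zc <- colSums(z[useC, , drop = FALSE])
    total <- zb - zc
    out <- data.frame(
        sample_id = colnames(z),
        z_basal_sum = unname(zb),
        z_classical_sum = unname(zc),
        total_score = unname(total),
        label = ifelse(total >= 0, "Basal-like", "Classical"),
        n_basal_used = length(useB),
        n_classical_used = length(useC),
        stringsAsFactors = FALSE)
    missing <- c(setdiff(signatureGenes(basal), useB),
                 setdiff(signatureGenes(classical), useC))
    if (length(missing)) {
        message(length(missing), " signature gene(s) absent from matrix")
        attr(out, "missingGenes") <- missing
    }
    rownames(out) <- NULL
    out
}

#' Rank genes by Pearson correlation with a per-sample score
#'
#' Computes the Pearson correlation of each gene's expression with the
#' score vector and returns genes sorted by r descending (ties broken by
#' gene id ascending). Genes with undefined correlation (zero variance) or
#' any missing value are excluded and counted.
#'
#' @param m an \linkS4class{ExpressionExperiment} with >= 3 samples.
#' @param scores named numeric vector covering every sample of \code{m}.
#' @param scoreName label stored with the ranking.
#' @return a \linkS4class{CorrelationRanking}.
#' @export
correlateWithScore <- function(m, scores, scoreName = "niche_dependency") {
    stopifnot(is(m, "ExpressionExperiment"))
    v <- exprs(m)
    if (ncol(v) < 3L) stop("need at least 3 samples to correlate")
    if (is.null(names(scores)))
        stop("scores must be named by sample id")
    if (!all(colnames(v) %in% names(scores)))
        stop("scores missing for sample(s): ",
             paste(setdiff(colnames(v), names(scores)), collapse = ", "))
    sc <- scores[colnames(v)]
    ok <- rowSums(is.na(v)) == 0L
    s <- apply(v, 1L, sd)
    defined <- ok & !is.na(s) & s > 0
    r <- as.numeric(cor(t(v[defined, , drop = FALSE]), sc))
    e <- data.frame(gene_id = rownames(v)[defined], r = r,
                    stringsAsFactors = FALSE)
    e <- e[order(-e$r, e$gene_id), , drop = FALSE]
    e$rank <- seq_len(nrow(e))
    rownames(e) <- NULL
    new("CorrelationRanking", entries = e, scoreName = scoreName,
        nExcluded = sum(!defined))
}

#' @rdname rankedEntries
#' @export
setMethod("rankedEntries", "CorrelationRanking",
    function(object) object@entries)

setMethod("show", "CorrelationRanking", function(object) {
    cat(sprintf(
        "CorrelationRanking vs '%s': %d genes ranked, %d excluded\n",
        object@scoreName, nrow(object@entries), object@nExcluded))
})

#' Extract the top-k and bottom-k correlated genes
#'
#' @param ranking a \linkS4class{CorrelationRanking}.
#' @param k number of genes per tail (default 1000). Must not exceed half
#'   the number of ranked genes, so the tails cannot overlap.
#' @return list with character vectors \code{top} (k highest r, rank order)
#'   and \code{bottom} (k lowest r, most negative first). Both tails are
#'   slices of the single canonical ranking (r descending, ties by gene id
#'   ascending), so they are disjoint by construction.
#' @export
extractTopBottom <- function(ranking, k = 1000L) {
    stopifnot(is(ranking, "CorrelationRanking"))
    e <- rankedEntries(ranking)
    if (k > nrow(e) / 2)
        stop("k = ", k, " exceeds half of the ", nrow(e), " ranked genes")
    list(top = e$gene_id[seq_len(k)],
         bottom = rev(e$gene_id)[seq_len(k)])
}
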