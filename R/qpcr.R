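#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged on the Ct scale per gene and
#' condition. For each condition, Delta-Ct is the mean target Ct minus the
#' mean reference-gene Ct; Delta-Delta-Ct subtracts the Delta-Ct of the
#' baseline condition, and fold change is \code{2^(-DDCt)} (amplification
#' efficiency fixed at 2). The baseline condition has fold 1 exactly.
#'
#' @param records data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct} (Ct in (0, 45]).
#' @param targetGene gene to quantify.
#' @param refGene reference (housekeeping) gene, e.g. \code{"GAPDH"}; must
#'   be measured in every condition.
#' @param referenceCondition baseline condition for the second delta.
#' @return data.frame with one row per condition: \code{gene},
#'   \code{condition}, \code{reference_condition}, \code{delta_ct},
#'   \code{delta_delta_ct}, \code{fold}.
#' @examples
#' r <- data.frame(
#'     gene = rep(c("T", "GAPDH"), each = 2),
#'     condition = rep(c("ctrl", "treat"), 2),
#'     replicate = 1, ct = c(26, 24, 20, 20))
#' deltaDeltaCt(r, "T", "GAPDH", "ctrl")  # fold 4 in 'treat'
#' @export
deltaDeltaCt <- function(records, targetGene, refGene, referenceCondition) {
    need <- c("gene", "condition", "replicate", "ct")
    if (!all(need %in% names(records)))
        stop("Ct records need columns: ", paste(need, collapse = ", "))
    if (any(records$ct <= 0 | records$ct > 45))
        stop("Ct values must lie in (0, 45]")
    conds <- unique(records$condition)
    if (!referenceCondition %in% conds)
        stop("reference condition '", referenceCondition, "' not in data")
    meanCt <- function(gene, cond) {
        v <- records$ct[records$gene == gene & records$condition == cond]
        if (!length(v))
            stop("gene '", gene, "' not measured in condition '", cond, "'")
        mean(v)
    }
    dct <- vapply(conds, function(cc)
        meanCt(targetGene, cc) - meanCt(refGene, cc), numeric(1))
    ddct <- dct - dct[[referenceCondition]]
    out <- data.frame(
        gene = targetGene, condition = conds,
        reference_condition = referenceCondition,
        delta_ct = unname(dct), delta_delta_ct = unname(ddct),
        fold = 2^(-unname(ddct)), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
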