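#' @importFrom stats median
NULL

checkGrowthRecords <- function(records) {
    need <- c("sample_id", "condition", "day", "replicate",
              "luminescence", "is_blank")
    if (!all(need %in% names(records)))
        stop("growth records need columns: ", paste(need, collapse = ", "))
    if (any(records$luminescence < 0))
        stop("luminescence must be >= 0")
    invisible(records)
}

#' Subtract the medium-only baseline from well luminescence
#'
#' Each well's signal is its raw luminescence minus the mean blank of its
#' condition (falling back to the global mean blank when a condition has no
#' blank wells). Negative signals are clipped to zero with a warning.
#' Blank wells are removed from the output.
#'
#' @param records long-format growth data.frame (see
#'   \code{\link{generateGrowthPlates}} for the columns).
#' @return the records without blank rows, with \code{luminescence}
#'   replaced by the blank-subtracted signal.
#' @examples
#' r <- data.frame(sample_id = c("a", "blank"), condition = "niche",
#'     day = c(10, 10), replicate = 1, luminescence = c(1100, 100),
#'     is_blank = c(FALSE, TRUE))
#' subtractBlank(r)$luminescence  # 1000
#' @export
subtractBlank <- function(records) {
    checkGrowthRecords(records)
    blanks <- records[records$is_blank, , drop = FALSE]
    if (!nrow(blanks))
        stop("no blank wells present; cannot subtract baseline")
    perCond <- tapply(blanks$luminescence, blanks$condition, mean)
    globalBlank <- mean(blanks$luminescence)
    out <- records[!records$is_blank, , drop = FALSE]
    base <- perCond[out$condition]
    base[is.na(base)] <- globalBlank
    sig <- out$luminescence - as.numeric(base)
    if (any(sig < 0)) {
        warning(sum(sig < 0),
                " well(s) below blank baseline; clipped to 0")
        sig[sig < 0] <- 0
    }
    out$luminescence <- sig
    rownames(out) <- NULL
    out
}

## blank-subtract if blanks are still present, else pass through
ensureSubtracted <- function(records) {
    checkGrowthRecords(records)
    if (any(records$is_blank)) subtractBlank(records) else records
}

#' Day-10 / day-0 proliferation fold change
#'
#' Ratio of the mean blank-subtracted day-10 signal under a condition to
#' the mean day-0 control signal of the sample (the seeded-cell
#' measurement, shared across conditions). Blank wells in the input are
#' subtracted first.
#'
#' @param records growth records.
#' @param sample sample id.
#' @param condition condition token (e.g. \code{"niche"}, \code{"serum"},
#'   \code{"niche-RSPO1"}).
#' @return fold change (positive real).
#' @export
foldChange <- function(records, sample, condition) {
    r <- ensureSubtracted(records)
    r <- r[r$sample_id == sample, , drop = FALSE]
    d0 <- r$luminescence[r$day == 0]
    d10 <- r$luminescence[r$day != 0 & r$condition == condition]
    if (!length(d0))
        stop("no day-0 control wells for sample '", sample, "'")
    if (!length(d10))
        stop("no day-10 wells for sample '", sample, "', condition '",
             condition, "'")
    if (mean(d0) == 0)
        stop("day-0 control mean is zero for sample '", sample, "'")
    mean(d10) / mean(d0)
}

#' Niche-dependency score of one sample
#'
#' The ratio of the proliferation fold change in niche medium to that in
#' serum medium; high values mean growth requires the niche factors.
#'
#' @param records growth records.
#' @param sample sample id.
#' @param nicheCondition,serumCondition condition tokens (defaults
#'   \code{"niche"} and \code{"serum"}).
#' @return one-row data.frame: \code{sample_id}, \code{fold_niche},
#'   \code{fold_serum}, \code{score}.
#' @export
nicheDependencyScore <- function(records, sample,
                                 nicheCondition = "niche",
                                 serumCondition = "serum") {
    r <- ensureSubtracted(records)
    fn <- foldChange(r, sample, nicheCondition)
    fs <- foldChange(r, sample, serumCondition)
    data.frame(sample_id = sample, fold_niche = fn, fold_serum = fs,
               score = fn / fs, stringsAsFactors = FALSE)
}

#' Niche-dependency scores for every sample in a record table
#'
#' @param records growth records.
#' @param samples sample ids to score (default: all non-blank samples with
#'   both conditions). Use this include-list to restrict analysis to a
#'   subset of lines.
#' @inheritParams nicheDependencyScore
#' @return data.frame with one row per sample.
#' @export
nicheDependencyScores <- function(records, samples = NULL,
                                  nicheCondition = "niche",
                                  serumCondition = "serum") {
    r <- ensureSubtracted(records)
    if (is.null(samples)) samples <- unique(r$sample_id)
    out <- do.call(rbind, lapply(samples, function(s)
        nicheDependencyScore(r, s, nicheCondition, serumCondition)))
    rownames(out) <- NULL
    out
}

#' Relative proliferation on withdrawal of one niche factor
#'
#' Fold change in niche medium lacking the factor, relative to the fold
#' change in full niche medium. Values near 1 mean the factor is
#' dispensable; values well below 1 mean growth depends on it.
#'
#' @param records growth records.
#' @param sample sample id.
#' @param omittedFactor factor name (e.g. \code{"RSPO1"}); the dropout
#'   condition token is \code{paste0("niche-", omittedFactor)}.
#' @return relative proliferation (positive real).
#' @export
dropoutRelativeProliferation <- function(records, sample, omittedFactor) {
    r <- ensureSubtracted(records)
    foldChange(r, sample, paste0("niche-", omittedFactor)) /
        foldChange(r, sample, "niche")
}

#' Assign High/Low niche-dependency subtypes
#'
#' Splits samples at a threshold on their niche-dependency score. The
#' default policy is a median split over the analyzed samples (scores
#' strictly above the median are \code{"High"}); a fixed threshold labels
#' scores >= threshold as \code{"High"}.
#'
#' @param scores data.frame from \code{\link{nicheDependencyScores}} (needs
#'   \code{sample_id} and \code{score}).
#' @param policy \code{"median"} or \code{"fixed"}.
#' @param threshold cut value, required for \code{policy = "fixed"}.
#' @return the input with columns \code{subtype}, \code{policy} and
#'   \code{cutoff} appended.
#' @export
assignNicheSubtype <- function(scores, policy = c("median", "fixed"),
                               threshold = NULL) {
    policy <- match.arg(policy)
    if (!all(c("sample_id", "score") %in% names(scores)))
        stop("scores needs columns sample_id and score")
    if (any(scores$score <= 0)) stop("scores must be > 0")
    if (policy == "median") {
        if (length(unique(scores$score)) < 2L)
            stop("all scores are equal; median split impossible")
        cut <- median(scores$score)
        high <- scores$score > cut
    } else {
        if (is.null(threshold)) stop("fixed policy needs a threshold")
        cut <- threshold
        high <- scores$score >= cut
    }
    scores$subtype <- ifelse(high, "High", "Low")
    scores$policy <- policy
    scores$cutoff <- cut
    scores
}
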