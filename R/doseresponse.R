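#' @importFrom stats optim quantile t.test cor.test
NULL

#' Normalize dose-response wells to a reference dose
#'
#' Scales every response so that the mean response at the reference dose is
#' 100\%. This is how viability screens anchor curves: e.g. the lowest
#' gemcitabine dose (0.001 nM) as 100\% response, or the top RSPO1 dose
#' (1000 ng/ml) when comparing R-spondin potencies.
#'
#' @param points data.frame with columns \code{dose} and \code{response}
#'   (other columns pass through).
#' @param referenceDose dose whose mean response defines 100\%.
#' @param referencePoints optional second table supplying the reference
#'   wells (used when the anchor curve is a different drug, as in the
#'   R-spondin comparison); defaults to \code{points}.
#' @return \code{points} with \code{response} rescaled; the scale factor is
#'   attached as \code{attr(, "referenceMean")}.
#' @export
normalizeToReference <- function(points, referenceDose,
                                 referencePoints = points) {
    stopifnot(all(c("dose", "response") %in% names(points)))
    ref <- referencePoints$response[referencePoints$dose == referenceDose]
    if (!length(ref))
        stop("reference dose ", referenceDose, " not present in the data")
    m <- mean(ref)
    if (m == 0) stop("mean response at the reference dose is zero")
    points$response <- points$response * 100 / m
    attr(points, "referenceMean") <- m
    points
}

## 4PL response at dose d (vectorized over d)
fourPL <- function(p, log10d) {
    p[1] + (p[2] - p[1]) / (1 + 10^((p[3] - log10d) * p[4]))
}

## soft-L1 robust loss: fScale^2 * sum(2 * (sqrt(1 + (r/fScale)^2) - 1))
softL1 <- function(resid, fScale) {
    fScale^2 * sum(2 * (sqrt(1 + (resid / fScale)^2) - 1))
}

#' Robust four-parameter logistic fit on the log10-dose axis
#'
#' Fits \deqn{r(d) = bottom + (top - bottom)/(1 + 10^{((log10EC50 - log10
#' d) \cdot hill)})} by minimizing a soft-L1 loss of the residuals (a
#' smooth approximation to least absolute deviations that downweights
#' outlier wells), with box constraints \code{bottom >= 0} and
#' \code{top <= topMax} to stabilize small-n fits, and multi-start
#' initialization over both Hill-slope signs and several EC50 starting
#' positions along the dose grid. The fitted curve is canonicalized so
#' \code{top >= bottom} (the 4PL is invariant under swapping the
#' asymptotes and negating the Hill slope).
#'
#' @param dose positive dose vector (one entry per well).
#' @param response response vector (same length), typically normalized \%.
#' @param fScale soft-L1 scale in response units; residuals beyond it are
#'   progressively downweighted.
#' @param bottomMin,topMax asymptote box constraints (default 0 and 150 for
#'   normalized percent responses); widen for unnormalized data.
#' @param maxit iteration cap per start.
#' @return a \linkS4class{FourPLFit}.
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' y <- 10 + 90 / (1 + 10^((log10(3) - log10(d)) * -1.2))
#' fit <- fit4PL(d, y)
#' ec50(fit)
#' @export
fit4PL <- function(dose, response, fScale = 5, bottomMin = 0, topMax = 150,
                   maxit = 400L) {
    stopifnot(length(dose) == length(response))
    if (any(dose <= 0)) stop("doses must be > 0 (dose 0 is disallowed)")
    if (length(unique(dose)) < 4L)
        stop("need at least 4 distinct doses to fit a 4PL")
    ld <- log10(dose)
    y <- response
    n <- length(y)

    if (diff(range(y)) < 1e-9 * max(1, max(abs(y)))) {
        ## flat data: asymptotes coincide, Hill slope meaningless
        lev <- min(max(mean(y), bottomMin), topMax)
        return(new("FourPLFit", bottom = lev, top = lev,
                   log10Ec50 = mean(range(ld)), hillSlope = 0,
                   loss = softL1(y - lev, fScale), converged = TRUE,
                   hillIdentifiable = FALSE, nPoints = as.integer(n)))
    }

    obj <- function(p) softL1(y - fourPL(p, ld), fScale)
    lower <- c(bottomMin, bottomMin, min(ld) - 2, -10)
    upper <- c(topMax, topMax, max(ld) + 2, 10)
    b0 <- min(max(min(y), bottomMin), topMax)
    t0 <- max(min(max(y), topMax), bottomMin)
    ecStarts <- quantile(ld, c(0.25, 0.5, 0.75), names = FALSE)
    best <- NULL
    for (h0 in c(1, -1)) for (e0 in ecStarts) {
        fit <- tryCatch(
            optim(c(b0, t0, e0, h0), obj, method = "L-BFGS-B",
                  lower = lower, upper = upper,
                  control = list(maxit = maxit, factr = 1e4)),
            error = function(e) NULL)
        if (!is.null(fit) &&
            (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best))
        stop("4PL optimization failed from every start")
    ## L-BFGS-B can stop with a line-search code at an (near-)exact
    ## optimum; call the fit converged when a restart from the optimum
    ## yields no further improvement (stationarity), not just on code 0
    polish <- tryCatch(
        optim(best$par, obj, method = "L-BFGS-B", lower = lower,
              upper = upper, control = list(maxit = maxit, factr = 1e4)),
        error = function(e) NULL)
    if (!is.null(polish) && polish$value < best$value) best <- polish
    stationary <- is.null(polish) ||
        best$value - polish$value <= 1e-8 * (1 + abs(best$value))
    p <- best$par
    if (p[2] < p[1]) {  # canonicalize: top >= bottom
        p[1:2] <- p[2:1]
        p[4] <- -p[4]
    }
    new("FourPLFit", bottom = p[1], top = p[2], log10Ec50 = p[3],
        hillSlope = p[4], loss = best$value,
        converged = best$convergence == 0L || stationary,
        hillIdentifiable = TRUE, nPoints = as.integer(n))
}

#' @rdname ec50
#' @export
setMethod("ec50", "FourPLFit", function(object) 10^object@log10Ec50)

setMethod("show", "FourPLFit", function(object) {
    cat(sprintf(
        paste0("FourPLFit: bottom %.3g, top %.3g, EC50 %.4g, hill %.3g",
               " (loss %.4g, %s, n = %d)\n"),
        object@bottom, object@top, 10^object@log10Ec50, object@hillSlope,
        object@loss,
        if (object@converged) "converged" else "NOT converged",
        object@nPoints))
})

#' Area under the fitted response curve over log10 dose
#'
#' Integrates the fitted 4PL over \code{log10(dose)} across the stated
#' range by the trapezoid rule on a fine grid. Units are percent times
#' log10-dose; a larger AUC means more of the viability curve survives the
#' dose range, i.e. a more resistant sample.
#'
#' @param fit a \linkS4class{FourPLFit}, or a data.frame with columns
#'   \code{dose} and \code{response} to integrate the observed points
#'   directly (replicates averaged per dose).
#' @param doseRange numeric length-2: (min dose, max dose), positive;
#'   defaults to the observed dose range when points are supplied.
#' @param nGrid grid points for the trapezoid rule on a fitted curve.
#' @return AUC (\% x log10-dose units).
#' @export
aucLogDose <- function(fit, doseRange = NULL, nGrid = 513L) {
    if (is.data.frame(fit)) {
        stopifnot(all(c("dose", "response") %in% names(fit)))
        mu <- tapply(fit$response, fit$dose, mean)
        d <- as.numeric(names(mu))
        o <- order(d)
        lg <- log10(d[o]); y <- as.numeric(mu)[o]
        if (!is.null(doseRange)) {
            keep <- d[o] >= doseRange[1] & d[o] <= doseRange[2]
            lg <- lg[keep]; y <- y[keep]
        }
        return(sum((y[-1] + y[-length(y)]) / 2 * diff(lg)))
    }
    stopifnot(is(fit, "FourPLFit"), length(doseRange) == 2L,
              all(doseRange > 0))
    lg <- seq(log10(doseRange[1]), log10(doseRange[2]),
              length.out = nGrid)
    y <- fourPL(c(fit@bottom, fit@top, fit@log10Ec50, fit@hillSlope), lg)
    sum((y[-1] + y[-length(y)]) / 2 * diff(lg))
}

#' Fit every (drug, sample) curve in a long dose-response table
#'
#' Convenience wrapper: optionally normalizes each curve to a reference
#' dose, fits the robust 4PL, and tabulates EC50 and log-dose AUC over the
#' observed dose range.
#'
#' @param data long data.frame with columns \code{drug}, \code{sample_id},
#'   \code{dose}, \code{response} (\code{dose_unit} passed through if
#'   present).
#' @param referenceDose per-curve reference dose for
#'   \code{\link{normalizeToReference}}, or \code{NULL} to skip
#'   normalization.
#' @param ... passed to \code{\link{fit4PL}}.
#' @return data.frame with one row per (drug, sample): EC50, AUC, the dose
#'   range used and convergence; the fits themselves in
#'   \code{attr(, "fits")}.
#' @export
fitDoseResponse <- function(data, referenceDose = NULL, ...) {
    need <- c("drug", "sample_id", "dose", "response")
    stopifnot(all(need %in% names(data)))
    keys <- unique(data[, c("drug", "sample_id")])
    fits <- list()
    rows <- list()
    for (i in seq_len(nrow(keys))) {
        d <- data[data$drug == keys$drug[i] &
                  data$sample_id == keys$sample_id[i], , drop = FALSE]
        if (!is.null(referenceDose))
            d <- normalizeToReference(d, referenceDose)
        fit <- fit4PL(d$dose, d$response, ...)
        rng <- range(d$dose)
        key <- paste(keys$drug[i], keys$sample_id[i], sep = ":")
        fits[[key]] <- fit
        rows[[i]] <- data.frame(
            drug = keys$drug[i], sample_id = keys$sample_id[i],
            ec50 = ec50(fit), auc = aucLogDose(fit, rng),
            dose_min = rng[1], dose_max = rng[2],
            converged = fit@converged, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "fits") <- fits
    out
}

#' Compare drug sensitivity between two subtypes
#'
#' Unpaired two-tailed Student's t-test (equal variances) of per-sample AUC
#' values between the two label groups.
#'
#' @param sens data.frame with \code{sample_id} and \code{auc} (e.g. from
#'   \code{\link{fitDoseResponse}} for one drug).
#' @param labels named character vector (\code{sample_id} ->
#'   \code{"High"}/\code{"Low"} or any two groups).
#' @return list: \code{groups} (named mean AUCs), \code{t}, \code{df},
#'   \code{p_value}.
#' @export
compareSubtypes <- function(sens, labels) {
    stopifnot(all(c("sample_id", "auc") %in% names(sens)))
    lab <- labels[sens$sample_id]
    if (any(is.na(lab)))
        stop("labels missing for sample(s): ",
             paste(sens$sample_id[is.na(lab)], collapse = ", "))
    gr <- unique(lab)
    if (length(gr) != 2L) stop("need exactly two groups, got ", length(gr))
    x <- sens$auc[lab == gr[1]]
    y <- sens$auc[lab == gr[2]]
    if (sd(x) == 0 && sd(y) == 0) {
        ## degenerate pooled variance: identical constants give no evidence
        ## of a difference; separated constants give unbounded evidence
        same <- mean(x) == mean(y)
        return(list(groups = stats::setNames(c(mean(x), mean(y)), gr),
                    t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                    df = length(x) + length(y) - 2,
                    p_value = if (same) 1 else 0))
    }
    tt <- t.test(x, y, var.equal = TRUE)
    list(groups = stats::setNames(c(mean(x), mean(y)), gr),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Spearman correlation of niche-dependency score vs drug AUC
#'
#' @param scores data.frame with \code{sample_id} and \code{score}.
#' @param sens data.frame with \code{sample_id} and \code{auc}.
#' @return list: \code{rho}, \code{p_value}, \code{n}.
#' @export
spearmanNicheVsAuc <- function(scores, sens) {
    m <- merge(scores[, c("sample_id", "score")],
               sens[, c("sample_id", "auc")], by = "sample_id")
    if (nrow(m) < 3L) stop("need at least 3 paired samples")
    ct <- suppressWarnings(
        cor.test(m$score, m$auc, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}
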